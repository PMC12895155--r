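# Lexer, parser, AST and serializer for the extended compositional grammar.
#
# ABNF profile implemented (whitespace permitted between any two tokens):
#
#   expression   = ws subExpr ws
#   subExpr      = focus [ws ":" ws refinements]
#   focus        = cref *(ws "+" ws cref)
#   refinements  = (attrSet / group) *(ws (attrSet / group))
#   group        = "{" ws attrSet ws "}"
#   attrSet      = attr *(ws "," ws attr)
#   attr         = cref ws "=" ws value
#   value        = cref / ("(" ws subExpr ws ")") / concrete
#   concrete     = ("#" number) / quotedString
#   cref         = (sctId / externalRef) [ws "|" term "|"]
#   externalRef  = "~" seg "~" [seg "~"] seg "~"
#   sctId        = 6*18 DIGIT
#
# Within expressions, external-ref segments exclude the structural
# characters = ( ) { } , : + (besides ~, | and whitespace) so that
# tokenization stays unambiguous and whitespace-invariant; the standalone
# parse_external_ref() accepts the full printable segment class.

# ---- AST constructors -------------------------------------------------------

concept_token_sct <- function(id, term = NULL) {
  structure(list(kind = "sct", id = id, term = term),
            class = "fdg_concept_token")
}

concept_token_ext <- function(key, local_id, version = NULL, term = NULL) {
  structure(list(kind = "ext", key = key, version = version,
                 local_id = local_id, term = term),
            class = "fdg_concept_token")
}

concrete_value <- function(kind, lexeme) {
  structure(list(kind = kind, lexeme = lexeme), class = "fdg_concrete_value")
}

refinement <- function(attribute, value) {
  structure(list(attribute = attribute, value = value),
            class = "fdg_refinement")
}

new_expression <- function(focus, ungrouped = list(), groups = list()) {
  structure(list(focus = focus, ungrouped = ungrouped, groups = groups),
            class = "fdg_expression")
}

#' @export
print.fdg_expression <- function(x, ...) {
  cat("<expression> ", serialize_expression(x, canonical = FALSE), "\n", sep = "")
  invisible(x)
}

# ---- errors -----------------------------------------------------------------

syntax_error <- function(msg, position, expected = NULL) {
  abort(
    paste0("Syntax error at position ", position, ": ", msg,
           if (length(expected))
             paste0(" (expected ", paste(expected, collapse = " / "), ")")),
    class = "fdg_syntax_error", position = position, expected = expected
  )
}

# ---- lexer ------------------------------------------------------------------

.seg_chars <- "[^~|=(){},:+[:space:]]"

.lex_patterns <- list(
  DEFSTATUS = "^(===|<<<)",
  EXTREF = paste0("^~(", .seg_chars, "*)~(", .seg_chars, "*)~(?:(",
                  .seg_chars, "*)~)?"),
  NUMBER = "^#[+-]?[0-9]+(?:\\.[0-9]+)?",
  STRING = '^"[^"]*"',
  TERM = "^\\|[^|]*\\|",
  ID = "^[0-9]+"
)

.punct_tokens <- c(":" = "COLON", "+" = "PLUS", "," = "COMMA", "=" = "EQ",
                   "{" = "LBRACE", "}" = "RBRACE", "(" = "LPAREN",
                   ")" = "RPAREN")

lex_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  n <- stri_length(text)
  pos <- 1L
  types <- character(0)
  values <- character(0)
  positions <- integer(0)
  push <- function(type, value, at) {
    types[[length(types) + 1L]] <<- type
    values[[length(values) + 1L]] <<- value
    positions[[length(positions) + 1L]] <<- at
  }
  while (pos <= n) {
    rest <- stri_sub(text, pos)
    ws <- stri_match_first_regex(rest, "^[[:space:]]+")[1, 1]
    if (!is.na(ws)) {
      pos <- pos + stri_length(ws)
      next
    }
    rest <- stri_sub(text, pos)
    ch <- stri_sub(rest, 1L, 1L)
    matched <- FALSE
    for (type in names(.lex_patterns)) {
      m <- stri_match_first_regex(rest, .lex_patterns[[type]])[1, 1]
      if (!is.na(m)) {
        push(type, m, pos)
        pos <- pos + stri_length(m)
        matched <- TRUE
        break
      }
    }
    if (matched) next
    if (!is.na(.punct_tokens[ch])) {
      push(.punct_tokens[[ch]], ch, pos)
      pos <- pos + 1L
      next
    }
    if (ch == "~") {
      syntax_error("malformed external reference", pos,
                   expected = "~key~[version~]id~")
    }
    syntax_error(paste0("unexpected character '", ch, "'"), pos)
  }
  list(types = c(types, "EOF"), values = c(values, ""),
       positions = c(positions, n + 1L))
}

# ---- external references ----------------------------------------------------

#' Parse a tilde-delimited external concept reference
#'
#' External vocabulary concepts are embedded in expressions as
#' `~key~id~` (two segments) or `~key~version~id~` (three segments, the
#' middle one a version label), e.g. `~Pango~B.1.1.7~` or
#' `~CTCAE~v5.0~4028512~`.
#'
#' @param token A string beginning and ending with `~`.
#' @return An `fdg_external_ref` with fields `key`, `version` (`NULL` when
#'   absent) and `local_id`.
#' @export
parse_external_ref <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  if (!stri_startswith_fixed(token, "~") || !stri_endswith_fixed(token, "~") ||
      stri_length(token) < 2L) {
    abort("External reference must begin and end with '~'.",
          class = c("fdg_bad_external_ref", "fdg_syntax_error"))
  }
  parts <- stri_split_fixed(token, "~")[[1]]
  interior <- parts[c(-1L, -length(parts))]
  if (!length(interior) %in% c(2L, 3L)) {
    abort(paste0("External reference must have 2 or 3 segments, got ",
                 length(interior), "."),
          class = c("fdg_segment_count", "fdg_bad_external_ref"))
  }
  if (any(!nzchar(interior))) {
    abort("External reference contains an empty segment.",
          class = c("fdg_empty_segment", "fdg_bad_external_ref"))
  }
  if (any(stri_detect_regex(interior, "[|[:space:]]|[^\\x21-\\x7E]"))) {
    abort("External reference segments may not contain '|', whitespace or non-printable characters.",
          class = c("fdg_forbidden_character", "fdg_bad_external_ref"))
  }
  if (length(interior) == 2L) {
    structure(list(key = interior[[1]], version = NULL,
                   local_id = interior[[2]]), class = "fdg_external_ref")
  } else {
    structure(list(key = interior[[1]], version = interior[[2]],
                   local_id = interior[[3]]), class = "fdg_external_ref")
  }
}

# ---- parser -----------------------------------------------------------------

#' Parse an expression in the extended compositional grammar
#'
#' Parses a postcoordinated expression into its AST: one or more focus
#' concepts, optionally refined by ungrouped and grouped attribute-value
#' pairs. Values may be concepts, parenthesized nested expressions,
#' hash-prefixed numbers or quoted strings (dates travel as quoted ISO 8601
#' strings; their date-ness is decided by the concept-model range that
#' applies, not by the lexer). Display terms (`|...|`) are captured but
#' carry no meaning. Definition-status prefixes (`===`, `<<<`) are accepted
#' with a warning and ignored.
#'
#' @param text Expression string.
#' @return An `fdg_expression`.
#' @examples
#' parse_expression("71388002 : 45169001 |Without| = 260787004")
#' parse_expression("~CTCAE~v5.0~4028512~")
#' @export
parse_expression <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(stri_trim_both(text))) {
    abort("Expression text must be a non-empty string.",
          class = "fdg_syntax_error")
  }
  toks <- lex_expression(text)
  cur <- 1L
  peek <- function() toks$types[[cur]]
  advance <- function() {
    v <- list(type = toks$types[[cur]], value = toks$values[[cur]],
              pos = toks$positions[[cur]])
    cur <<- cur + 1L
    v
  }
  expect <- function(type, what) {
    if (peek() != type) {
      syntax_error(paste0("unexpected ", peek()), toks$positions[[cur]],
                   expected = what)
    }
    advance()
  }

  parse_cref <- function() {
    t <- peek()
    if (t == "ID") {
      tok <- advance()
      if (!validate_sctid(tok$value)) {
        abort(paste0("Malformed concept id at position ", tok$pos, ": '",
                     tok$value, "' (wrong length, leading zero, or bad check digit)."),
              class = c("fdg_malformed_id", "fdg_syntax_error"),
              position = tok$pos)
      }
      out <- concept_token_sct(tok$value)
    } else if (t == "EXTREF") {
      tok <- advance()
      ref <- parse_external_ref(tok$value)
      out <- concept_token_ext(ref$key, ref$local_id, version = ref$version)
    } else {
      syntax_error(paste0("unexpected ", t), toks$positions[[cur]],
                   expected = c("concept id", "external reference"))
    }
    if (peek() == "TERM") {
      term <- advance()
      out$term <- stri_sub(term$value, 2L, -2L)
    }
    out
  }

  parse_value <- function() {
    t <- peek()
    if (t == "LPAREN") {
      advance()
      sub <- parse_subexpr()
      expect("RPAREN", "')'")
      sub
    } else if (t == "NUMBER") {
      tok <- advance()
      concrete_value("number", stri_sub(tok$value, 2L))
    } else if (t == "STRING") {
      tok <- advance()
      concrete_value("string", stri_sub(tok$value, 2L, -2L))
    } else {
      parse_cref()
    }
  }

  parse_attr <- function() {
    attribute <- parse_cref()
    expect("EQ", "'='")
    refinement(attribute, parse_value())
  }

  parse_attr_set <- function() {
    attrs <- list(parse_attr())
    while (peek() == "COMMA") {
      advance()
      attrs[[length(attrs) + 1L]] <- parse_attr()
    }
    attrs
  }

  parse_subexpr <- function() {
    focus <- list(parse_cref())
    while (peek() == "PLUS") {
      advance()
      focus[[length(focus) + 1L]] <- parse_cref()
    }
    ungrouped <- list()
    groups <- list()
    if (peek() == "COLON") {
      advance()
      if (!peek() %in% c("ID", "EXTREF", "LBRACE")) {
        syntax_error(paste0("unexpected ", peek()), toks$positions[[cur]],
                     expected = c("attribute", "'{'"))
      }
      repeat {
        t <- peek()
        if (t == "LBRACE") {
          advance()
          if (peek() == "RBRACE") {
            syntax_error("empty attribute group", toks$positions[[cur]],
                         expected = "attribute")
          }
          groups[[length(groups) + 1L]] <- parse_attr_set()
          expect("RBRACE", "'}'")
        } else if (t %in% c("ID", "EXTREF")) {
          ungrouped <- c(ungrouped, parse_attr_set())
        } else {
          break
        }
      }
    }
    new_expression(focus, ungrouped, groups)
  }

  if (peek() == "DEFSTATUS") {
    tok <- advance()
    warn(paste0("Definition status prefix '", tok$value,
                "' accepted but ignored."))
  }
  expr <- parse_subexpr()
  if (peek() != "EOF") {
    syntax_error(paste0("unexpected ", peek(), " after expression"),
                 toks$positions[[cur]], expected = "end of input")
  }
  expr
}

# ---- serialization ----------------------------------------------------------

normalize_number_lexeme <- function(lexeme) {
  s <- stri_replace_first_regex(lexeme, "^\\+", "")
  neg <- stri_startswith_fixed(s, "-")
  if (neg) s <- stri_sub(s, 2L)
  parts <- stri_split_fixed(s, ".")[[1]]
  int <- stri_replace_first_regex(parts[[1]], "^0+(?=[0-9])", "")
  frac <- if (length(parts) > 1L) stri_replace_last_regex(parts[[2]], "0+$", "") else ""
  out <- if (nzchar(frac)) paste0(int, ".", frac) else int
  if (out == "0") neg <- FALSE
  if (neg) paste0("-", out) else out
}

serialize_token <- function(token, with_term = FALSE) {
  body <- if (token$kind == "sct") {
    token$id
  } else if (is.null(token$version)) {
    paste0("~", token$key, "~", token$local_id, "~")
  } else {
    paste0("~", token$key, "~", token$version, "~", token$local_id, "~")
  }
  if (with_term && !is.null(token$term)) {
    paste0(body, " |", token$term, "|")
  } else {
    body
  }
}

token_sort_key <- function(token) {
  if (token$kind == "sct") {
    paste0("0", formatC(stri_length(token$id), width = 2, flag = "0"), token$id)
  } else {
    paste0("1", serialize_token(token))
  }
}

serialize_value <- function(value, canonical, with_term) {
  if (inherits(value, "fdg_concept_token")) {
    serialize_token(value, with_term = with_term)
  } else if (inherits(value, "fdg_concrete_value")) {
    if (value$kind == "number") {
      paste0("#", if (canonical) normalize_number_lexeme(value$lexeme) else value$lexeme)
    } else {
      paste0('"', value$lexeme, '"')
    }
  } else if (inherits(value, "fdg_expression")) {
    paste0("(", serialize_subexpr(value, canonical, with_term), ")")
  } else {
    abort("Unknown attribute value node.")
  }
}

serialize_refinement <- function(ref, canonical, with_term) {
  paste0(serialize_token(ref$attribute, with_term = with_term), " = ",
         serialize_value(ref$value, canonical, with_term))
}

serialize_subexpr <- function(expr, canonical, with_term) {
  focus <- expr$focus
  ungrouped <- expr$ungrouped
  groups <- expr$groups
  if (canonical) {
    focus <- focus[order(map_chr(focus, token_sort_key), method = "radix")]
    sort_refs <- function(refs) {
      keys1 <- map_chr(refs, function(r) token_sort_key(r$attribute))
      keys2 <- map_chr(refs, function(r) serialize_value(r$value, TRUE, FALSE))
      refs[order(keys1, keys2, method = "radix")]
    }
    ungrouped <- sort_refs(ungrouped)
    groups <- lapply(groups, sort_refs)
    gstr <- map_chr(groups, function(g)
      paste0("{ ", paste(map_chr(g, serialize_refinement, TRUE, FALSE),
                         collapse = ", "), " }"))
    groups_str <- sort(gstr, method = "radix")
    ungrouped_str <- map_chr(ungrouped, serialize_refinement, TRUE, FALSE)
  } else {
    groups_str <- map_chr(groups, function(g)
      paste0("{ ", paste(map_chr(g, serialize_refinement, FALSE, with_term),
                         collapse = ", "), " }"))
    ungrouped_str <- map_chr(ungrouped, serialize_refinement, FALSE, with_term)
  }
  out <- paste(map_chr(focus, serialize_token, with_term = !canonical && with_term),
               collapse = " + ")
  tail <- c(
    if (length(ungrouped_str)) paste(ungrouped_str, collapse = ", "),
    groups_str
  )
  if (length(tail)) out <- paste0(out, " : ", paste(tail, collapse = " "))
  out
}

#' Serialize an expression
#'
#' With `canonical = TRUE` (default) produces the unique canonical form:
#' focus concepts sorted (native ids numerically, then external references
#' lexically), refinements sorted by attribute id then serialized value,
#' groups sorted by their serialized form, display terms dropped, single
#' spaces between tokens, numbers normalized. Canonical serialization is a
#' fixed point of `parse_expression()` followed by `serialize_expression()`.
#' With `canonical = FALSE` stored order and display terms are preserved.
#'
#' @param expr An `fdg_expression`.
#' @param canonical Emit the canonical form?
#' @return A single string.
#' @export
serialize_expression <- function(expr, canonical = TRUE) {
  stopifnot(inherits(expr, "fdg_expression"))
  serialize_subexpr(expr, canonical = canonical, with_term = !canonical)
}

#' Canonical equality of two expressions
#'
#' @param a,b `fdg_expression` objects or expression strings.
#' @return `TRUE` when both have the same canonical serialization.
#' @export
expression_equal <- function(a, b) {
  if (is.character(a)) a <- parse_expression(a)
  if (is.character(b)) b <- parse_expression(b)
  identical(serialize_expression(a), serialize_expression(b))
}

# ---- feature analysis -------------------------------------------------------

all_refinements <- function(expr) {
  c(expr$ungrouped, do.call(c, c(expr$groups, list(list()))))
}

walk_expression <- function(expr, fn) {
  # depth-first application of fn to every node (tokens, values, refinements)
  for (f in expr$focus) fn(f)
  for (r in all_refinements(expr)) {
    fn(r)
    fn(r$attribute)
    if (inherits(r$value, "fdg_expression")) {
      walk_expression(r$value, fn)
    } else {
      fn(r$value)
    }
  }
  invisible(NULL)
}

#' Which grammar features an expression uses
#'
#' Reports whether the expression is a postcoordinated expression at all
#' (has refinements), and whether — anywhere, including nested
#' sub-expressions — it embeds an external vocabulary reference, a concrete
#' value, or an attribute from a supplied extension-attribute set.
#'
#' @param expr An `fdg_expression` (or expression string).
#' @param extension_attributes Character vector of attribute ids counted as
#'   grammar extensions (e.g. [extension_attribute_ids()]).
#' @return Named logical vector with elements `has_refinements`,
#'   `uses_external_ref`, `uses_concrete_value`, `uses_extension_attribute`.
#' @export
features_used <- function(expr, extension_attributes = character(0)) {
  if (is.character(expr)) expr <- parse_expression(expr)
  out <- c(has_refinements = length(expr$ungrouped) + length(expr$groups) > 0L,
           uses_external_ref = FALSE, uses_concrete_value = FALSE,
           uses_extension_attribute = FALSE)
  env <- environment()
  walk_expression(expr, function(node) {
    if (inherits(node, "fdg_concept_token") && node$kind == "ext") {
      env$out[["uses_external_ref"]] <- TRUE
    }
    if (inherits(node, "fdg_concrete_value")) {
      env$out[["uses_concrete_value"]] <- TRUE
    }
    if (inherits(node, "fdg_refinement") &&
        node$attribute$kind == "sct" &&
        node$attribute$id %in% extension_attributes) {
      env$out[["uses_extension_attribute"]] <- TRUE
    }
  })
  out
}

#' Expression AST as plain lists (for JSON output)
#'
#' @param expr An `fdg_expression`.
#' @return Nested plain lists mirroring the AST, suitable for
#'   `jsonlite::toJSON()`.
#' @export
expression_to_list <- function(expr) {
  stopifnot(inherits(expr, "fdg_expression"))
  token_list <- function(t) {
    if (t$kind == "sct") {
      list(kind = "sct", id = t$id, term = t$term)
    } else {
      list(kind = "ext", key = t$key, version = t$version,
           local_id = t$local_id, term = t$term)
    }
  }
  value_list <- function(v) {
    if (inherits(v, "fdg_concept_token")) {
      c(list(node = "concept"), token_list(v))
    } else if (inherits(v, "fdg_concrete_value")) {
      list(node = "concrete", kind = v$kind, value = v$lexeme)
    } else {
      c(list(node = "expression"), expression_to_list(v))
    }
  }
  ref_list <- function(r) {
    list(attribute = token_list(r$attribute), value = value_list(r$value))
  }
  list(
    focus = lapply(expr$focus, token_list),
    ungrouped = lapply(expr$ungrouped, ref_list),
    groups = lapply(expr$groups, function(g) lapply(g, ref_list))
  )
}
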