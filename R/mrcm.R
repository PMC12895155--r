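# The machine-readable concept model: permissive attribute rules (which
# concepts may be refined, by which attribute, to which values) expressed in
# a small constraint language, plus the validation engine that applies a
# rule set to a parsed expression over a concept graph.
#
# Constraint syntax (textual form used in rule files):
#   << 404684003          descendant-or-self
#   <  404684003          strict descendant
#   404684003             self only
#   ext:Pango             any reference of that external vocabulary
#   num / str / date      concrete value of that type
#   A OR B OR ...         union (any branch suffices)

# ---- constraint expressions -------------------------------------------------

new_constraint <- function(op, arg = NULL, branches = NULL) {
  structure(list(op = op, arg = arg, branches = branches),
            class = "fdg_constraint")
}

#' Parse a constraint expression
#'
#' @param text Constraint in the textual syntax, e.g.
#'   `"<< 404684003 OR << 71388002"`, `"num"`, `"ext:Pango"`.
#' @return An `fdg_constraint`.
#' @export
parse_constraint <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  src <- stri_trim_both(text)
  if (!nzchar(src)) {
    abort("Empty constraint.", class = "fdg_constraint_syntax")
  }
  branches <- lapply(stri_split_regex(src, "\\s+OR\\s+")[[1]], function(b) {
    b <- stri_trim_both(b)
    if (b %in% c("num", "number")) return(new_constraint("concrete", "number"))
    if (b %in% c("str", "string")) return(new_constraint("concrete", "string"))
    if (b == "date") return(new_constraint("concrete", "date"))
    m <- stri_match_first_regex(b, "^ext:(\\S+)$")
    if (!is.na(m[1, 1])) return(new_constraint("ext_cluster", m[1, 2]))
    m <- stri_match_first_regex(b, "^(<<|<)?\\s*([0-9]+|~[^\\s]+~)$")
    if (is.na(m[1, 1])) {
      abort(paste0("Cannot parse constraint: '", b, "'"),
            class = "fdg_constraint_syntax")
    }
    op <- if (is.na(m[1, 2])) "self" else if (m[1, 2] == "<<") "desc_or_self" else "desc"
    new_constraint(op, m[1, 3])
  })
  if (length(branches) == 1L) branches[[1]] else
    new_constraint("union", branches = branches)
}

#' Textual form of a constraint
#'
#' @param c An `fdg_constraint`.
#' @return A string in the syntax accepted by [parse_constraint()].
#' @export
format_constraint <- function(c) {
  stopifnot(inherits(c, "fdg_constraint"))
  switch(c$op,
    desc_or_self = paste0("<< ", c$arg),
    desc = paste0("< ", c$arg),
    self = c$arg,
    ext_cluster = paste0("ext:", c$arg),
    concrete = switch(c$arg, number = "num", string = "str", date = "date"),
    union = paste(map_chr(c$branches, format_constraint), collapse = " OR ")
  )
}

is_iso8601 <- function(x) {
  # calendar date, optionally followed by a time-of-day (T separator)
  date_part <- "[0-9]{4}-(0[1-9]|1[0-2])-(0[1-9]|[12][0-9]|3[01])"
  time_part <- "T([01][0-9]|2[0-3]):[0-5][0-9](:[0-5][0-9](\\.[0-9]+)?)?(Z|[+-][01][0-9]:?[0-5][0-9])?"
  if (!stri_detect_regex(x, paste0("^", date_part, "(", time_part, ")?$"))) {
    return(FALSE)
  }
  !is.na(as.Date(stri_sub(x, 1L, 10L), format = "%Y-%m-%d"))
}

#' Evaluate a constraint against a value
#'
#' Subsumption constraints (`<<`, `<`, self) are evaluated through the
#' concept graph; `ext:` matches any external reference of that vocabulary
#' (case-sensitive key); concrete-type constraints match the value kind,
#' with `date` meaning a quoted string that parses under ISO 8601; unions
#' succeed when any branch does. A nested expression satisfies a
#' subsumption constraint when all of its focus concepts do.
#'
#' @param c An `fdg_constraint` (or constraint string).
#' @param value An attribute value node (`fdg_concept_token`,
#'   `fdg_concrete_value` or nested `fdg_expression`) or a concept id
#'   string.
#' @param graph A `concept_graph`.
#' @return A single logical.
#' @export
evaluate_constraint <- function(c, value, graph) {
  if (is.character(c)) c <- parse_constraint(c)
  if (is.character(value)) {
    value <- if (stri_startswith_fixed(value, "~")) {
      ref <- parse_external_ref(value)
      concept_token_ext(ref$key, ref$local_id, version = ref$version)
    } else {
      concept_token_sct(value)
    }
  }
  switch(c$op,
    union = any(vapply(c$branches, evaluate_constraint, logical(1),
                       value = value, graph = graph)),
    concrete = {
      if (!inherits(value, "fdg_concrete_value")) return(FALSE)
      switch(c$arg,
        number = value$kind == "number",
        string = value$kind == "string",
        date = value$kind == "string" && is_iso8601(value$lexeme)
      )
    },
    ext_cluster = inherits(value, "fdg_concept_token") &&
      value$kind == "ext" && value$key == c$arg,
    { # subsumption family: self / desc / desc_or_self
      foci <- if (inherits(value, "fdg_expression")) {
        value$focus
      } else if (inherits(value, "fdg_concept_token")) {
        list(value)
      } else {
        return(FALSE)
      }
      all(vapply(foci, function(f) {
        id <- normalize_ref(f)
        anc <- normalize_ref(c$arg)
        switch(c$op,
          self = id == anc,
          desc_or_self = is_subsumed_by(id, anc, graph),
          desc = id != anc && is_subsumed_by(id, anc, graph)
        )
      }, logical(1)))
    }
  )
}

# ---- rule sets --------------------------------------------------------------

#' Construct an MRCM rule set
#'
#' @param rules A data frame with columns `attribute` (attribute id),
#'   `domain` and `range` (constraint strings or `fdg_constraint` lists),
#'   and optionally `cardinality` (one of `"optional-many"`,
#'   `"optional-one"`, `"required-one"`; default `"optional-many"`) and
#'   `groupable` (logical, default `TRUE`).
#' @param name,version Labels for the rule set.
#' @return An `mrcm_rules` object.
#' @export
mrcm_rules <- function(rules, name = "mrcm", version = "0") {
  rules <- as_tibble(rules)
  if (!all(c("attribute", "domain", "range") %in% names(rules))) {
    abort("Rules need columns attribute, domain, range.",
          class = "fdg_rules_error")
  }
  rules$attribute <- as.character(rules$attribute)
  if (!is.list(rules$domain)) rules$domain <- lapply(rules$domain, parse_constraint)
  if (!is.list(rules$range)) rules$range <- lapply(rules$range, parse_constraint)
  if (!"cardinality" %in% names(rules)) rules$cardinality <- "optional-many"
  if (!"groupable" %in% names(rules)) rules$groupable <- TRUE
  bad <- setdiff(unique(rules$cardinality),
                 c("optional-many", "optional-one", "required-one"))
  if (length(bad)) {
    abort(paste0("Unknown cardinality: ", paste(bad, collapse = ", ")),
          class = "fdg_rules_error")
  }
  dup <- duplicated(paste(rules$attribute, map_chr(rules$domain, format_constraint)))
  if (any(dup)) {
    abort("Duplicate (attribute, domain) rule.", class = "fdg_rules_error")
  }
  structure(list(name = name, version = version, rules = rules),
            class = "mrcm_rules")
}

#' @export
print.mrcm_rules <- function(x, ...) {
  cat("<mrcm_rules> ", x$name, " v", x$version, ": ", nrow(x$rules),
      " rules over ", length(unique(x$rules$attribute)),
      " attributes\n", sep = "")
  invisible(x)
}

#' Extend a rule set
#'
#' Extensions are strictly permissive: a widening replaces a rule's domain
#' or range by the union of the old constraint and the new one, and a new
#' rule adds sayable refinements without touching existing rules. Every
#' expression valid under the base set therefore remains valid under the
#' extended set.
#'
#' @param base An `mrcm_rules` object.
#' @param deltas A list of deltas, each created by [rule_addition()],
#'   [domain_widening()] or [range_widening()].
#' @param name,version Labels for the extended set (default: base name with
#'   `"+ext"`).
#' @return The extended `mrcm_rules`.
#' @export
extend_rules <- function(base, deltas, name = NULL, version = NULL) {
  stopifnot(inherits(base, "mrcm_rules"))
  rules <- base$rules
  widen <- function(old, extra) {
    branches_of <- function(c) if (c$op == "union") c$branches else list(c)
    existing <- branches_of(old)
    added <- keep(branches_of(extra), function(b) {
      !format_constraint(b) %in% map_chr(existing, format_constraint)
    })
    all_b <- c(existing, added)
    if (length(all_b) == 1L) all_b[[1]] else new_constraint("union", branches = all_b)
  }
  for (d in deltas) {
    if (d$kind == "add") {
      rules <- bind_rows(rules, tibble(
        attribute = d$attribute, domain = list(parse_constraint(d$domain)),
        range = list(parse_constraint(d$range)),
        cardinality = d$cardinality, groupable = d$groupable
      ))
    } else {
      idx <- which(rules$attribute == d$attribute)
      if (length(idx) == 0L) {
        abort(paste0("Cannot widen nonexistent rule for attribute ", d$attribute),
              class = "fdg_rules_error")
      }
      for (i in idx) {
        col <- if (d$kind == "widen_domain") "domain" else "range"
        rules[[col]][[i]] <- widen(rules[[col]][[i]], parse_constraint(d$constraint))
      }
    }
  }
  mrcm_rules(rules, name = name %||% paste0(base$name, "+ext"),
             version = version %||% base$version)
}

#' Rule-set deltas
#'
#' Building blocks for [extend_rules()]: add a complete new attribute rule,
#' or widen the domain/range of every existing rule for an attribute by
#' union with an additional constraint.
#'
#' @param attribute Attribute id.
#' @param domain,range,constraint Constraint strings.
#' @param cardinality,groupable As in [mrcm_rules()].
#' @return A delta object consumed by [extend_rules()].
#' @export
rule_addition <- function(attribute, domain, range,
                          cardinality = "optional-many", groupable = TRUE) {
  list(kind = "add", attribute = as.character(attribute), domain = domain,
       range = range, cardinality = cardinality, groupable = groupable)
}

#' @rdname rule_addition
#' @export
domain_widening <- function(attribute, constraint) {
  list(kind = "widen_domain", attribute = as.character(attribute),
       constraint = constraint)
}

#' @rdname rule_addition
#' @export
range_widening <- function(attribute, constraint) {
  list(kind = "widen_range", attribute = as.character(attribute),
       constraint = constraint)
}

#' Read / write MRCM rule files
#'
#' Tab-separated, one rule per row:
#' `attribute<TAB>domain<TAB>range<TAB>cardinality<TAB>groupable`, with
#' domain/range in the [parse_constraint()] syntax. Round-trips exactly.
#'
#' @param path File path.
#' @param name,version Labels for the loaded set (default: file name).
#' @return `read_rules()` returns an `mrcm_rules`; `write_rules()` returns
#'   `path` invisibly.
#' @export
read_rules <- function(path, name = NULL, version = "0") {
  tab <- utils::read.delim(path, colClasses = "character", quote = "",
                           stringsAsFactors = FALSE)
  required <- c("attribute", "domain", "range", "cardinality", "groupable")
  if (!all(required %in% names(tab))) {
    abort("Rules file needs columns attribute, domain, range, cardinality, groupable.",
          class = "fdg_rules_error")
  }
  parsed_domain <- vector("list", nrow(tab))
  parsed_range <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    parsed_domain[[i]] <- tryCatch(parse_constraint(tab$domain[[i]]),
      error = function(e) abort(paste0("Row ", i, " domain: ", conditionMessage(e)),
                                class = "fdg_constraint_syntax"))
    parsed_range[[i]] <- tryCatch(parse_constraint(tab$range[[i]]),
      error = function(e) abort(paste0("Row ", i, " range: ", conditionMessage(e)),
                                class = "fdg_constraint_syntax"))
  }
  mrcm_rules(
    tibble(attribute = tab$attribute, domain = parsed_domain,
           range = parsed_range, cardinality = tab$cardinality,
           groupable = as.logical(tab$groupable)),
    name = name %||% sub("\\.tsv$", "", basename(path)), version = version
  )
}

#' @rdname read_rules
#' @param rules An `mrcm_rules` object.
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "mrcm_rules"))
  out <- data.frame(
    attribute = rules$rules$attribute,
    domain = map_chr(rules$rules$domain, format_constraint),
    range = map_chr(rules$rules$range, format_constraint),
    cardinality = rules$rules$cardinality,
    groupable = rules$rules$groupable
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- validation engine ------------------------------------------------------

violation <- function(code, path, message) {
  tibble(code = code, path = path, message = message)
}

#' Validate an expression against an MRCM rule set
#'
#' Applies the permissive concept-model semantics: every refinement
#' (grouped or not) must be licensed by some rule for its attribute whose
#' domain is satisfied by every focus concept and whose range is satisfied
#' by the value. Nested expression values are validated recursively against
#' their own focus concepts. Cardinality is checked per attribute per scope
#' (each group is its own scope, the ungrouped refinements another). All
#' violations are collected, not only the first.
#'
#' @param expr An `fdg_expression` or expression string.
#' @param rules An `mrcm_rules` object.
#' @param graph A `concept_graph` (with any external vocabularies already
#'   attached).
#' @return An `fdg_validation` object: `verdict` (`"valid"`/`"invalid"`)
#'   plus a tibble of violations with codes among `UNKNOWN_CONCEPT`,
#'   `UNKNOWN_VOCABULARY`, `ATTRIBUTE_NOT_PERMITTED`, `DOMAIN_MISMATCH`,
#'   `RANGE_MISMATCH`, `BAD_CONCRETE_TYPE`, `CARDINALITY`.
#' @export
validate_expression <- function(expr, rules, graph) {
  if (is.character(expr)) expr <- parse_expression(expr)
  stopifnot(inherits(expr, "fdg_expression"), inherits(rules, "mrcm_rules"),
            inherits(graph, "concept_graph"))
  violations <- list()
  add <- function(v) violations[[length(violations) + 1L]] <<- v

  check_token_known <- function(token, path) {
    id <- normalize_ref(token)
    if (id %in% graph$concepts$id) return(TRUE)
    if (token$kind == "ext" && !token$key %in% names(graph$vocabularies)) {
      add(violation("UNKNOWN_VOCABULARY", path,
                    paste0("Vocabulary not attached: ", token$key)))
    } else {
      add(violation("UNKNOWN_CONCEPT", path, paste0("Unknown concept: ", id)))
    }
    FALSE
  }

  range_ok <- function(rule_range, value) {
    # distinguish BAD_CONCRETE_TYPE (concrete value where the range wanted a
    # different concrete type, or any concrete where none allowed) from a
    # plain RANGE_MISMATCH
    evaluate_constraint(rule_range, value, graph)
  }

  check_subexpr <- function(expr, path) {
    for (i in seq_along(expr$focus)) {
      check_token_known(expr$focus[[i]], paste0(path, "/focus[", i, "]"))
    }
    scopes <- c(list(list(refs = expr$ungrouped, label = "ungrouped")),
                imap(expr$groups, function(g, i)
                  list(refs = g, label = paste0("group[", i, "]"))))
    for (scope in scopes) {
      counts <- list()
      for (j in seq_along(scope$refs)) {
        ref <- scope$refs[[j]]
        rpath <- paste0(path, "/", scope$label, "[", j, "]")
        attr_tok <- ref$attribute
        attr_known <- check_token_known(attr_tok, paste0(rpath, "/attribute"))
        value <- ref$value
        value_known <- TRUE
        if (inherits(value, "fdg_concept_token")) {
          value_known <- check_token_known(value, paste0(rpath, "/value"))
        } else if (inherits(value, "fdg_expression")) {
          check_subexpr(value, paste0(rpath, "/value"))
          value_known <- all(map_lgl(seq_along(value$focus), function(k)
            normalize_ref(value$focus[[k]]) %in% graph$concepts$id))
        }
        if (!attr_known) next
        attr_id <- normalize_ref(attr_tok)
        counts[[attr_id]] <- (counts[[attr_id]] %||% 0L) + 1L
        cand <- rules$rules[rules$rules$attribute == attr_id, ]
        if (nrow(cand) == 0L) {
          add(violation("ATTRIBUTE_NOT_PERMITTED", rpath,
                        paste0("No rule permits attribute ", attr_id)))
          next
        }
        domain_ok_idx <- which(map_lgl(seq_len(nrow(cand)), function(k) {
          all(map_lgl(expr$focus, function(f) {
            tryCatch(evaluate_constraint(cand$domain[[k]], f, graph),
                     fdg_unknown_concept = function(e) FALSE)
          }))
        }))
        if (length(domain_ok_idx) == 0L) {
          add(violation("DOMAIN_MISMATCH", rpath,
                        paste0("No rule for attribute ", attr_id,
                               " has a domain covering every focus concept")))
          next
        }
        if (!value_known) next
        ok <- any(map_lgl(domain_ok_idx, function(k) {
          tryCatch(range_ok(cand$range[[k]], value),
                   fdg_unknown_concept = function(e) FALSE)
        }))
        if (!ok) {
          ranges <- cand$range[domain_ok_idx]
          wants_concrete <- any(map_lgl(ranges, function(r) {
            r$op == "concrete" ||
              (r$op == "union" && any(map_chr(r$branches, "op") == "concrete"))
          }))
          if (inherits(value, "fdg_concrete_value") && wants_concrete) {
            add(violation("BAD_CONCRETE_TYPE", rpath,
                          paste0("Concrete value of kind '", value$kind,
                                 "' does not satisfy the permitted concrete range")))
          } else {
            add(violation("RANGE_MISMATCH", rpath,
                          paste0("Value does not satisfy any permitted range for attribute ",
                                 attr_id)))
          }
        }
      }
      # cardinality per attribute within this scope
      for (attr_id in names(counts)) {
        card <- unique(rules$rules$cardinality[rules$rules$attribute == attr_id])
        if (length(card) == 0L) next
        if (any(card %in% c("optional-one", "required-one")) && counts[[attr_id]] > 1L) {
          add(violation("CARDINALITY", paste0(path, "/", scope$label),
                        paste0("Attribute ", attr_id, " used ", counts[[attr_id]],
                               " times in one scope but is limited to one")))
        }
      }
    }
    # required-one attributes must appear somewhere in the sub-expression
    req <- unique(rules$rules$attribute[rules$rules$cardinality == "required-one"])
    if (length(req)) {
      used <- unique(map_chr(all_refinements(expr),
                             function(r) normalize_ref(r$attribute)))
      applicable <- keep(req, function(a) {
        cand <- rules$rules[rules$rules$attribute == a, ]
        any(map_lgl(seq_len(nrow(cand)), function(k)
          all(map_lgl(expr$focus, function(f)
            tryCatch(evaluate_constraint(cand$domain[[k]], f, graph),
                     fdg_unknown_concept = function(e) FALSE)))))
      })
      for (a in setdiff(applicable, used)) {
        add(violation("CARDINALITY", path,
                      paste0("Required attribute ", a, " is missing")))
      }
    }
  }

  check_subexpr(expr, "expr")
  violations <- if (length(violations)) bind_rows(violations) else
    violation(character(0), character(0), character(0))
  structure(
    list(verdict = if (nrow(violations)) "invalid" else "valid",
         violations = violations, expression = expr),
    class = "fdg_validation"
  )
}

#' @export
print.fdg_validation <- function(x, ...) {
  cat("<validation> ", x$verdict, sep = "")
  if (nrow(x$violations)) {
    cat(" (", nrow(x$violations), " violation(s))\n", sep = "")
    for (i in seq_len(nrow(x$violations))) {
      cat("  [", x$violations$code[[i]], "] ", x$violations$path[[i]], ": ",
          x$violations$message[[i]], "\n", sep = "")
    }
  } else {
    cat("\n")
  }
  invisible(x)
}

#' @describeIn validate_expression Violations as a tibble (one row each).
#' @param x An `fdg_validation`.
#' @param ... Unused.
#' @export
tidy.fdg_validation <- function(x, ...) {
  x$violations
}

#' @describeIn validate_expression One-row tibble with the verdict and
#'   violation counts by code.
#' @export
glance.fdg_validation <- function(x, ...) {
  tibble(
    verdict = x$verdict,
    valid = x$verdict == "valid",
    n_violations = nrow(x$violations),
    n_codes = length(unique(x$violations$code))
  )
}

#' Is a validation verdict valid?
#'
#' @param report An `fdg_validation`.
#' @return A single logical.
#' @export
is_valid <- function(report) {
  stopifnot(inherits(report, "fdg_validation"))
  report$verdict == "valid"
}
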