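# Annotated-corpus storage and statistics: each record is a data element
# from some source collection, annotated with an expression and the number
# of data instances it covers. Expressions are classified as precoordinated
# (one concept, no refinements), postcoordinated (PCE), or extended PCE
# (uses an external reference or an extension attribute), and per-source
# usage is summarized in the style of an extension-usage table.

#' Percent conventions
#'
#' `pct_half_up()` is the summary-table convention: percentages to
#' `digits` decimals with halves rounded up (`235/699` prints `33.62`).
#' `pct_floor()` is the prose convention: whole percents truncated toward
#' zero (`834/2895 = 28.8%` prints `28`).
#'
#' @param numerator,denominator Numbers; a zero denominator yields 0.
#' @param digits Decimal places for `pct_half_up()`.
#' @return Numeric vector of percentages.
#' @export
pct_half_up <- function(numerator, denominator, digits = 2) {
  x <- ifelse(denominator == 0, 0, 100 * numerator / denominator)
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

#' @rdname pct_half_up
#' @export
pct_floor <- function(numerator, denominator) {
  ifelse(denominator == 0, 0, floor(100 * numerator / denominator))
}

#' Classify expressions by grammar feature use
#'
#' `"precoordinated"`: a single native focus concept, no refinements, no
#' external reference. `"extended_pce"`: uses an external reference or an
#' attribute from `extension_attributes` anywhere. `"pce"`: anything else
#' postcoordinated. A lone external focus concept counts as extended, not
#' precoordinated: it already uses the extended syntax.
#'
#' @param expressions Character vector of expression strings.
#' @param extension_attributes Attribute ids counted as grammar extensions
#'   (default [extension_attribute_ids()]).
#' @return Character vector in
#'   `c("precoordinated", "pce", "extended_pce")`.
#' @export
classify_expression <- function(expressions,
                                extension_attributes = extension_attribute_ids()) {
  uniq <- unique(expressions)
  cls <- vapply(uniq, function(s) {
    expr <- parse_expression(s)
    f <- features_used(expr, extension_attributes)
    if (f[["uses_external_ref"]] || f[["uses_extension_attribute"]]) {
      "extended_pce"
    } else if (!f[["has_refinements"]] && length(expr$focus) == 1L) {
      "precoordinated"
    } else {
      "pce"
    }
  }, character(1))
  unname(cls[match(expressions, uniq)])
}

#' Classify every record of a corpus
#'
#' @param corpus A corpus tibble (`source`, `element_id`, `expression`,
#'   `instance_count`).
#' @param extension_attributes As in [classify_expression()].
#' @return The corpus with an added `class` column.
#' @export
classify_corpus <- function(corpus, extension_attributes = extension_attribute_ids()) {
  corpus <- as_tibble(corpus)
  cls <- tryCatch(
    classify_expression(corpus$expression, extension_attributes),
    error = function(e) {
      # re-run expression by expression to attach the element id
      for (i in seq_len(nrow(corpus))) {
        ok <- tryCatch({classify_expression(corpus$expression[[i]],
                                            extension_attributes); TRUE},
                       error = function(e2) FALSE)
        if (!ok) {
          abort(paste0("Record ", corpus$element_id[[i]], ": ",
                       conditionMessage(e)),
                class = "fdg_corpus_error", parent = e)
        }
      }
      stop(e)
    }
  )
  mutate(corpus, class = cls)
}

#' Summarize extension usage per source
#'
#' Produces the per-source usage table: elements encoded, elements using
#' grammar extensions, instance sums for both, and the two percentage
#' columns under the 2-decimal half-up convention, with a `Total` row equal
#' to the column-wise sums. Unparseable expressions abort in strict mode;
#' with `strict = FALSE` they are counted in a separate `unparsed` column
#' and excluded from the percentages.
#'
#' @param corpus A corpus tibble.
#' @param extension_attributes As in [classify_expression()].
#' @param strict Abort on unparseable expressions?
#' @return An `fdg_corpus_summary` tibble: one row per source plus `Total`.
#' @export
summarize_corpus <- function(corpus, extension_attributes = extension_attribute_ids(),
                             strict = TRUE) {
  corpus <- as_tibble(corpus)
  if (nrow(corpus) == 0L) {
    out <- tibble(source = "Total", ids_encoded = 0, extensions_used = 0,
                  pct_extensions = 0, instances_encoded = 0,
                  extension_instances = 0, pct_extension_instances = 0,
                  unparsed = 0)
    return(structure(out, class = c("fdg_corpus_summary", class(out))))
  }
  if (any(corpus$instance_count < 0)) {
    abort("Negative instance_count.", class = "fdg_corpus_error")
  }
  parses <- rep(TRUE, nrow(corpus))
  if (!strict) {
    uniq <- unique(corpus$expression)
    ok <- vapply(uniq, function(s)
      tryCatch({parse_expression(s); TRUE}, error = function(e) FALSE),
      logical(1))
    parses <- unname(ok[match(corpus$expression, uniq)])
  }
  good <- corpus[parses, ]
  good <- classify_corpus(good, extension_attributes)
  per_source <- good |>
    mutate(extended = .data$class == "extended_pce") |>
    group_by(source = .data$source) |>
    summarise(
      ids_encoded = dplyr::n(),
      extensions_used = sum(.data$extended),
      instances_encoded = sum(.data$instance_count),
      extension_instances = sum(.data$instance_count[.data$extended]),
      .groups = "drop"
    )
  unparsed <- corpus[!parses, ] |>
    group_by(source = .data$source) |>
    summarise(unparsed = dplyr::n(), .groups = "drop")
  per_source <- left_join(per_source, unparsed, by = "source") |>
    mutate(unparsed = ifelse(is.na(.data$unparsed), 0L, .data$unparsed)) |>
    arrange(.data$source)
  total <- summarise(
    per_source,
    source = "Total",
    ids_encoded = sum(.data$ids_encoded),
    extensions_used = sum(.data$extensions_used),
    instances_encoded = sum(.data$instances_encoded),
    extension_instances = sum(.data$extension_instances),
    unparsed = sum(.data$unparsed)
  )
  out <- bind_rows(per_source, total) |>
    mutate(
      pct_extensions = pct_half_up(.data$extensions_used, .data$ids_encoded),
      pct_extension_instances = pct_half_up(.data$extension_instances,
                                            .data$instances_encoded)
    ) |>
    select("source", "ids_encoded", "extensions_used", "pct_extensions",
           "instances_encoded", "extension_instances",
           "pct_extension_instances", "unparsed")
  structure(out, class = c("fdg_corpus_summary", class(out)))
}

#' @describeIn summarize_corpus One-row tibble with the totals.
#' @param x An `fdg_corpus_summary`.
#' @param ... Unused.
#' @export
glance.fdg_corpus_summary <- function(x, ...) {
  tot <- x[x$source == "Total", ]
  tibble(
    n_sources = sum(x$source != "Total"),
    ids_encoded = tot$ids_encoded,
    extensions_used = tot$extensions_used,
    pct_extensions = tot$pct_extensions,
    instances_encoded = tot$instances_encoded,
    extension_instances = tot$extension_instances,
    pct_extension_instances = tot$pct_extension_instances
  )
}

#' @describeIn summarize_corpus Bar chart of the extension-usage
#'   percentage per source (elements and instances side by side).
#' @param object An `fdg_corpus_summary`.
#' @export
autoplot.fdg_corpus_summary <- function(object, ...) {
  df <- object[object$source != "Total", ] |>
    select("source", elements = "pct_extensions",
           instances = "pct_extension_instances") |>
    tidyr::pivot_longer(c("elements", "instances"),
                        names_to = "unit", values_to = "pct")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$source, .data$pct),
                                   y = .data$pct, fill = .data$unit)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "represented with grammar extensions (%)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Render an "n (%)" table cell
#'
#' @param n Count.
#' @param pct Percentage (already rounded).
#' @return Strings like `"235 (33.62)"`.
#' @export
format_count_pct <- function(n, pct) {
  sprintf("%s (%s)", format(n, scientific = FALSE, trim = TRUE),
          format(pct, scientific = FALSE, trim = TRUE))
}

#' Query records by numeric attribute value
#'
#' Returns the records whose expression carries a refinement with the given
#' attribute (optionally any attribute subsumed by it) whose numeric value
#' satisfies the comparison — e.g. every heart-rate element with a value
#' above 150. Nested sub-expressions are searched too.
#'
#' @param corpus A corpus tibble.
#' @param attribute Attribute concept reference.
#' @param op One of `"<", "<=", "=", ">=", ">"` (aliases
#'   `lt/le/eq/ge/gt`).
#' @param threshold Number compared against.
#' @param graph A `concept_graph`; required when `subsume_attribute`.
#' @param subsume_attribute Also match attributes subsumed by `attribute`?
#' @return The matching subset of `corpus`.
#' @export
query_numeric <- function(corpus, attribute, op, threshold, graph = NULL,
                          subsume_attribute = FALSE) {
  corpus <- as_tibble(corpus)
  ops <- c("<" = "<", "<=" = "<=", "=" = "==", ">=" = ">=", ">" = ">",
           lt = "<", le = "<=", eq = "==", ge = ">=", gt = ">")
  if (!op %in% names(ops)) {
    abort(paste0("Unknown operator '", op, "'"), class = "fdg_corpus_error")
  }
  cmp <- match.fun(ops[[op]])
  if (subsume_attribute && is.null(graph)) {
    abort("`subsume_attribute = TRUE` needs a concept graph.",
          class = "fdg_corpus_error")
  }
  if (!is.null(graph)) {
    attribute <- resolve_ref(attribute, graph)
  } else {
    attribute <- normalize_ref(attribute)
  }
  attr_matches <- function(tok) {
    id <- normalize_ref(tok)
    if (id == attribute) return(TRUE)
    if (subsume_attribute) return(is_subsumed_by(id, attribute, graph))
    FALSE
  }
  uniq <- unique(corpus$expression)
  hit <- vapply(uniq, function(s) {
    expr <- parse_expression(s)
    found <- FALSE
    walk_expression(expr, function(node) {
      if (!found && inherits(node, "fdg_refinement") &&
          inherits(node$value, "fdg_concrete_value") &&
          node$value$kind == "number" &&
          attr_matches(node$attribute) &&
          cmp(as.numeric(node$value$lexeme), threshold)) {
        found <<- TRUE
      }
    })
    found
  }, logical(1))
  corpus[unname(hit[match(corpus$expression, uniq)]), ]
}

#' Read / write corpora and summaries
#'
#' The corpus format is tab-separated:
#' `source<TAB>element_id<TAB>expression<TAB>instance_count`. Round-trips
#' exactly. `write_summary()` writes either plain TSV (`style = "tsv"`) or
#' an aligned text table whose count columns are rendered as `"n (%)"`
#' cells (`style = "table"`).
#'
#' @param path File path.
#' @return `read_corpus()` returns a corpus tibble; the writers return
#'   `path` invisibly.
#' @export
read_corpus <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character", quote = "",
                           stringsAsFactors = FALSE)
  required <- c("source", "element_id", "expression", "instance_count")
  if (!all(required %in% names(tab))) {
    abort("Corpus file needs columns source, element_id, expression, instance_count.",
          class = "fdg_corpus_error")
  }
  counts <- suppressWarnings(as.numeric(tab$instance_count))
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts))
  if (length(bad)) {
    abort(paste0("Malformed instance_count at line ", bad[[1]] + 1L, "."),
          class = "fdg_corpus_error")
  }
  dup <- duplicated(paste0(tab$source, "\r", tab$element_id))
  if (any(dup)) {
    abort(paste0("Duplicate element_id within source at line ",
                 which(dup)[[1]] + 1L, "."),
          class = "fdg_corpus_error")
  }
  tibble(source = tab$source, element_id = tab$element_id,
         expression = tab$expression, instance_count = counts)
}

#' @rdname read_corpus
#' @param corpus A corpus tibble.
#' @export
write_corpus <- function(corpus, path) {
  out <- as.data.frame(corpus[, c("source", "element_id", "expression",
                                  "instance_count")])
  out$instance_count <- format(out$instance_count, scientific = FALSE,
                               trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_corpus
#' @param summary An `fdg_corpus_summary`.
#' @param style `"tsv"` or `"table"`.
#' @export
write_summary <- function(summary, path, style = c("tsv", "table")) {
  style <- match.arg(style)
  df <- as.data.frame(summary)
  if (style == "tsv") {
    for (col in c("ids_encoded", "extensions_used", "instances_encoded",
                  "extension_instances")) {
      df[[col]] <- format(df[[col]], scientific = FALSE, trim = TRUE)
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    cells <- data.frame(
      Source = df$source,
      `IDs encoded` = format(df$ids_encoded, scientific = FALSE, trim = TRUE),
      `Extensions used` = format_count_pct(df$extensions_used, df$pct_extensions),
      `Instances encoded` = format(df$instances_encoded, scientific = FALSE,
                                   trim = TRUE),
      `Extension instances` = format_count_pct(df$extension_instances,
                                               df$pct_extension_instances),
      check.names = FALSE
    )
    widths <- pmax(nchar(names(cells)),
                   vapply(cells, function(c) max(nchar(c)), integer(1)))
    fmt_row <- function(vals) paste(mapply(formatC, vals, width = widths,
                                           MoreArgs = list(flag = "-")),
                                    collapse = "  ")
    writeLines(c(fmt_row(names(cells)),
                 vapply(seq_len(nrow(cells)), function(i)
                   fmt_row(unlist(cells[i, ])), character(1))), path)
  }
  invisible(path)
}
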