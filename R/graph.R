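# The is-a concept graph: an acyclic hierarchy of concepts, each primitive or
# fully defined, with a single root. External vocabularies are attached as
# subtrees whose node ids are canonical tilde tokens ("~Pango~B.1.1.7~"), so
# subsumption treats native and external concepts uniformly.

new_concept_graph <- function(concepts, root, vocabularies = list()) {
  structure(
    list(concepts = concepts, root = root, vocabularies = vocabularies),
    class = "concept_graph"
  )
}

#' Build a concept graph from a concept table
#'
#' @param concepts A data frame with columns `id` (identifier string),
#'   `term` (label), `definition_status` (`"primitive"` or
#'   `"fully_defined"`) and `parents` (either a list-column of character
#'   vectors or a pipe-separated string; empty for the root only).
#' @return A `concept_graph` object.
#' @details The is-a relation must be acyclic, every parent reference must
#'   resolve, exactly one concept may have no parents (the root), and every
#'   native identifier must pass [validate_sctid()].
#' @examples
#' g <- concept_graph(tibble::tibble(
#'   id = c("138875005", "404684003"),
#'   term = c("root", "Clinical finding"),
#'   definition_status = "primitive",
#'   parents = c("", "138875005")
#' ))
#' @export
concept_graph <- function(concepts) {
  concepts <- as_tibble(concepts)
  required <- c("id", "term", "definition_status", "parents")
  missing <- setdiff(required, names(concepts))
  if (length(missing)) {
    abort(paste0("Missing concept columns: ", paste(missing, collapse = ", ")),
          class = "fdg_graph_error")
  }
  concepts$id <- as.character(concepts$id)
  if (!is.list(concepts$parents)) {
    concepts$parents <- lapply(
      stri_split_fixed(ifelse(is.na(concepts$parents), "", concepts$parents), "|"),
      function(p) p[nzchar(p)]
    )
  }
  if (anyDuplicated(concepts$id)) {
    abort("Duplicate concept ids.", class = "fdg_graph_error")
  }
  bad_status <- setdiff(unique(concepts$definition_status),
                        c("primitive", "fully_defined"))
  if (length(bad_status)) {
    abort(paste0("Unknown definition_status: ", paste(bad_status, collapse = ", ")),
          class = "fdg_graph_error")
  }
  is_ext <- stri_detect_regex(concepts$id, "^~")
  bad_ids <- concepts$id[!is_ext & !validate_sctid(concepts$id)]
  if (length(bad_ids)) {
    abort(paste0("Malformed concept id(s): ", paste(bad_ids, collapse = ", ")),
          class = "fdg_malformed_id")
  }
  all_parents <- unique(unlist(concepts$parents))
  dangling <- setdiff(all_parents, concepts$id)
  if (length(dangling)) {
    abort(paste0("Dangling parent reference(s): ",
                 paste(dangling, collapse = ", ")),
          class = "fdg_dangling_parent")
  }
  plist <- stats::setNames(concepts$parents, concepts$id)
  assert_acyclic(plist)
  roots <- concepts$id[lengths(concepts$parents) == 0L]
  if (length(roots) != 1L) {
    abort(paste0("Graph must have exactly one root; found ", length(roots), "."),
          class = "fdg_graph_error")
  }
  vocabularies <- list()
  ext_ids <- concepts$id[is_ext]
  if (length(ext_ids)) {
    keys <- stri_match_first_regex(ext_ids, "^~([^~]+)~")[, 2]
    for (k in unique(keys)) {
      vocabularies[[k]] <- list(key = k, version = NA_character_,
                                attachment_parent = NA_character_)
    }
  }
  new_concept_graph(concepts, roots, vocabularies)
}

assert_acyclic <- function(plist) {
  # Kahn's algorithm over the child -> parent edges
  indeg <- stats::setNames(lengths(plist), names(plist))
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  children <- split(
    rep(names(plist), lengths(plist)),
    unlist(plist, use.names = FALSE)
  )
  while (length(queue)) {
    x <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[x]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(plist)) {
    abort("The is-a relation contains a cycle.", class = "fdg_cycle_error")
  }
  invisible(TRUE)
}

parent_map <- function(graph) {
  stats::setNames(graph$concepts$parents, graph$concepts$id)
}

#' @export
print.concept_graph <- function(x, ...) {
  cat("<concept_graph> ", nrow(x$concepts), " concepts, root ", x$root, sep = "")
  if (length(x$vocabularies)) {
    cat(", vocabularies: ", paste(names(x$vocabularies), collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Tabular view of a concept graph
#'
#' @param graph A `concept_graph`.
#' @return A tibble with one row per concept (`parents` as a list-column).
#' @export
graph_concepts <- function(graph) {
  stopifnot(inherits(graph, "concept_graph"))
  graph$concepts
}

# Normalise a concept reference to its node id in the graph:
# plain identifier strings pass through; external tokens (with or without a
# version segment) collapse to the canonical versionless "~key~id~" form;
# parsed concept tokens are accepted as well.
normalize_ref <- function(ref) {
  if (inherits(ref, "fdg_concept_token")) {
    if (ref$kind == "sct") return(ref$id)
    return(paste0("~", ref$key, "~", ref$local_id, "~"))
  }
  if (inherits(ref, "fdg_external_ref")) {
    return(paste0("~", ref$key, "~", ref$local_id, "~"))
  }
  stopifnot(is.character(ref), length(ref) == 1L)
  if (stri_startswith_fixed(ref, "~")) {
    ext <- parse_external_ref(ref)
    return(paste0("~", ext$key, "~", ext$local_id, "~"))
  }
  ref
}

resolve_ref <- function(ref, graph) {
  id <- normalize_ref(ref)
  if (!id %in% graph$concepts$id) {
    abort(paste0("Unknown concept: ", id), class = "fdg_unknown_concept")
  }
  id
}

#' Test subsumption between two concepts
#'
#' `is_subsumed_by(child, ancestor, graph)` is `TRUE` when `ancestor` is
#' reachable from `child` through zero or more is-a edges (the reflexive
#' `<<` descendant-or-self relation used by expression constraints).
#'
#' @param child,ancestor Concept references: identifier strings or external
#'   tokens such as `"~Pango~B.1.1.7~"` (which resolve through their
#'   attached vocabulary).
#' @param graph A `concept_graph`.
#' @return A single logical.
#' @export
is_subsumed_by <- function(child, ancestor, graph) {
  child <- resolve_ref(child, graph)
  ancestor <- resolve_ref(ancestor, graph)
  if (child == ancestor) return(TRUE)
  plist <- parent_map(graph)
  frontier <- plist[[child]]
  visited <- character(0)
  while (length(frontier)) {
    if (ancestor %in% frontier) return(TRUE)
    visited <- c(visited, frontier)
    frontier <- setdiff(unique(unlist(plist[frontier], use.names = FALSE)), visited)
  }
  FALSE
}

#' Ancestor-or-self closure of every concept
#'
#' Computes, for each concept, the set of concepts that subsume it
#' (including itself). This is the transitive closure of the is-a relation
#' and the efficient route for bulk subsumption queries.
#'
#' @param graph A `concept_graph`.
#' @return A named list mapping each concept id to a character vector of
#'   ancestor-or-self ids.
#' @export
subsumption_closure <- function(graph) {
  plist <- parent_map(graph)
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  anc <- function(id) {
    hit <- get0(id, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    res <- unique(c(id, unlist(lapply(plist[[id]], anc), use.names = FALSE)))
    assign(id, res, envir = cache)
    res
  }
  stats::setNames(lapply(names(plist), anc), names(plist))
}

# Depth of every concept: length of the LONGEST is-a chain from the root.
# "Deeper" therefore always means "more specific along some path".
concept_depths <- function(graph) {
  plist <- parent_map(graph)
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  depth <- function(id) {
    hit <- get0(id, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    ps <- plist[[id]]
    res <- if (length(ps) == 0L) 0L else max(vapply(ps, depth, integer(1))) + 1L
    assign(id, res, envir = cache)
    res
  }
  vapply(names(plist), depth, integer(1))
}

#' Describe an external vocabulary for attachment
#'
#' @param key Short alphanumeric vocabulary identifier (case-sensitive),
#'   e.g. `"Pango"`.
#' @param attachment_parent Identifier of the host concept the vocabulary is
#'   attached under.
#' @param concepts Data frame with columns `id` (local identifier) and
#'   optionally `parents` (list-column or pipe-separated local parent ids);
#'   concepts with no local parents become direct children of
#'   `attachment_parent`.
#' @param version Optional version label.
#' @return An `external_vocabulary` object.
#' @export
external_vocabulary <- function(key, attachment_parent, concepts, version = NULL) {
  stopifnot(is.character(key), length(key) == 1L, nzchar(key))
  if (stri_detect_regex(key, "[~|[:space:]]")) {
    abort("Vocabulary key may not contain '~', '|' or whitespace.",
          class = "fdg_bad_external_ref")
  }
  concepts <- as_tibble(concepts)
  if (!"id" %in% names(concepts)) {
    abort("Vocabulary concepts need an `id` column.", class = "fdg_graph_error")
  }
  concepts$id <- as.character(concepts$id)
  if (anyDuplicated(concepts$id)) {
    abort("Duplicate local ids in vocabulary.", class = "fdg_graph_error")
  }
  if (any(stri_detect_regex(concepts$id, "[~|[:space:]]"))) {
    abort("Local ids may not contain '~', '|' or whitespace.",
          class = "fdg_bad_external_ref")
  }
  if (!"parents" %in% names(concepts)) concepts$parents <- list(character(0))
  if (!is.list(concepts$parents)) {
    concepts$parents <- lapply(
      stri_split_fixed(ifelse(is.na(concepts$parents), "", concepts$parents), "|"),
      function(p) p[nzchar(p)]
    )
  }
  dangling <- setdiff(unique(unlist(concepts$parents)), concepts$id)
  if (length(dangling)) {
    abort(paste0("Local parent(s) not in vocabulary: ",
                 paste(dangling, collapse = ", ")),
          class = "fdg_dangling_parent")
  }
  structure(
    list(key = key, version = version %||% NA_character_,
         attachment_parent = as.character(attachment_parent),
         concepts = concepts),
    class = "external_vocabulary"
  )
}

#' Attach an external vocabulary beneath a host concept
#'
#' Every external concept becomes subsumed by the attachment parent; local
#' parent links are preserved beneath it (local roots become direct children
#' of the attachment parent). Host concepts and the subsumption relation
#' between them are untouched.
#'
#' @param graph A `concept_graph`.
#' @param vocab An [external_vocabulary()].
#' @return The updated `concept_graph`.
#' @export
attach_vocabulary <- function(graph, vocab) {
  stopifnot(inherits(graph, "concept_graph"),
            inherits(vocab, "external_vocabulary"))
  if (vocab$key %in% names(graph$vocabularies)) {
    abort(paste0("Vocabulary already attached: ", vocab$key),
          class = "fdg_duplicate_vocabulary")
  }
  if (!vocab$attachment_parent %in% graph$concepts$id) {
    abort(paste0("Unknown attachment parent: ", vocab$attachment_parent),
          class = "fdg_unknown_concept")
  }
  ext_id <- function(local) paste0("~", vocab$key, "~", local, "~")
  rows <- tibble(
    id = ext_id(vocab$concepts$id),
    term = vocab$concepts$id,
    definition_status = "primitive",
    parents = lapply(vocab$concepts$parents, function(p) {
      if (length(p) == 0L) vocab$attachment_parent else ext_id(p)
    })
  )
  graph$concepts <- bind_rows(graph$concepts, rows)
  graph$vocabularies[[vocab$key]] <- list(
    key = vocab$key, version = vocab$version,
    attachment_parent = vocab$attachment_parent
  )
  graph
}

#' Read a vocabulary registry document
#'
#' @param path Path to a JSON document
#'   `{key, version, attachment_parent, concepts: [{id, parents: [...]}]}`.
#' @return An [external_vocabulary()].
#' @export
read_vocabulary <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  concepts <- tibble(
    id = map_chr(doc$concepts, "id"),
    parents = map(doc$concepts, function(c) as.character(unlist(c$parents)))
  )
  external_vocabulary(doc$key, doc$attachment_parent, concepts,
                      version = doc$version)
}

#' Proximal primitive parents of a concept
#'
#' Walks the concept's genealogy and returns the nearest primitive
#' ancestors: every primitive concept P that is an ancestor-or-self of the
#' input with no primitive concept strictly between the input and P along
#' the path that reached P. A primitive concept is its own proximal
#' primitive parent. With multiple fully defined parents the result can be
#' a set; callers needing a single concept may take the numerically
#' smallest id.
#'
#' @param concept A concept reference.
#' @param graph A `concept_graph` (its root must be primitive).
#' @return Character vector of primitive concept ids (sorted).
#' @export
proximal_primitive_parent <- function(concept, graph) {
  id <- resolve_ref(concept, graph)
  status <- stats::setNames(graph$concepts$definition_status, graph$concepts$id)
  if (status[[graph$root]] != "primitive") {
    abort("Graph root must be primitive.", class = "fdg_graph_error")
  }
  plist <- parent_map(graph)
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  ppp <- function(x) {
    hit <- get0(x, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    res <- if (status[[x]] == "primitive") x else
      unique(unlist(lapply(plist[[x]], ppp), use.names = FALSE))
    assign(x, res, envir = cache)
    res
  }
  sort_ids(ppp(id))
}

# Deterministic id ordering: native ids numerically (length then lexical,
# valid because ids have no leading zeros), external tokens after, lexically.
sort_ids <- function(ids) {
  ext <- stri_startswith_fixed(ids, "~")
  native <- ids[!ext]
  native <- native[order(stri_length(native), native)]
  c(native, sort(ids[ext], method = "radix"))
}

#' Resolve a disjunctive ("or") label to a shared parent
#'
#' Labels joined by "or" are mapped to a single concept only when both
#' disjuncts share a sufficiently close common ancestor; otherwise they stay
#' unmapped rather than losing meaning to an over-broad parent. The deepest
#' common ancestors of `a` and `b` are computed (depth = longest is-a chain
#' from the root); if for some deepest common ancestor the smaller of the
#' two depth gaps `depth(a) - depth(lca)` and `depth(b) - depth(lca)` is at
#' most `max_depth_gap`, that ancestor is returned (ties broken by smallest
#' id), else `"unmapped"`.
#'
#' @param a,b Concept references.
#' @param graph A `concept_graph`.
#' @param max_depth_gap Non-negative integer; how far above the shallower
#'   disjunct the shared parent may sit before the mapping is rejected.
#' @return A concept id, or the string `"unmapped"`.
#' @export
resolve_disjunction <- function(a, b, graph, max_depth_gap = 2L) {
  stopifnot(max_depth_gap >= 0L)
  a <- resolve_ref(a, graph)
  b <- resolve_ref(b, graph)
  closure <- subsumption_closure(graph)
  common <- intersect(closure[[a]], closure[[b]])
  if (length(common) == 0L) return("unmapped")
  depths <- concept_depths(graph)
  dmax <- max(depths[common])
  deepest <- common[depths[common] == dmax]
  gap_ok <- vapply(deepest, function(l) {
    min(depths[[a]] - depths[[l]], depths[[b]] - depths[[l]]) <= max_depth_gap
  }, logical(1))
  if (!any(gap_ok)) return("unmapped")
  sort_ids(deepest[gap_ok])[1L]
}

#' Evaluate the five selection criteria for an external vocabulary
#'
#' A candidate vocabulary is accepted for integration only when all five
#' criteria hold: it covers an identified gap in the host terminology, it is
#' concept-based (not a thesaurus), it is hierarchical with graph-like
#' structure, it has versioning capabilities, and it is a recognized
#' standard accepted by its user community.
#'
#' @param gap_covered,concept_based,hierarchical,versioned,recognized_standard
#'   Logical verdicts, one per criterion.
#' @param notes Optional named character vector of free-text notes keyed by
#'   criterion name.
#' @return A `selection_criteria_report`: tibble of per-criterion verdicts
#'   plus an `accepted` attribute (the conjunction).
#' @export
evaluate_selection_criteria <- function(gap_covered, concept_based,
                                        hierarchical, versioned,
                                        recognized_standard,
                                        notes = character(0)) {
  verdicts <- c(
    gap_covered = gap_covered, concept_based = concept_based,
    hierarchical = hierarchical, versioned = versioned,
    recognized_standard = recognized_standard
  )
  stopifnot(is.logical(verdicts), length(verdicts) == 5L, !anyNA(verdicts))
  report <- tibble(
    criterion = names(verdicts),
    verdict = unname(verdicts),
    notes = ifelse(names(verdicts) %in% names(notes),
                   notes[names(verdicts)], NA_character_)
  )
  structure(report, accepted = all(verdicts),
            class = c("selection_criteria_report", class(report)))
}

#' @export
print.selection_criteria_report <- function(x, ...) {
  status <- if (attr(x, "accepted")) "ACCEPTED" else "REJECTED"
  cat("<selection_criteria_report> ", status, "\n", sep = "")
  failing <- x$criterion[!x$verdict]
  if (length(failing)) {
    cat("failing criteria: ", paste(failing, collapse = ", "), "\n", sep = "")
  }
  NextMethod()
}

#' Read / write a concept graph as TSV
#'
#' One concept per row: `id<TAB>term<TAB>definition_status<TAB>parents`,
#' parents pipe-separated (empty for the root). Reading a written graph
#' reproduces it exactly.
#'
#' @param path File path.
#' @return `read_concept_graph()` returns a `concept_graph`;
#'   `write_concept_graph()` returns `path` invisibly.
#' @export
read_concept_graph <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character", quote = "",
                           stringsAsFactors = FALSE)
  required <- c("id", "term", "definition_status", "parents")
  if (!all(required %in% names(tab))) {
    abort("Concept graph file needs columns id, term, definition_status, parents.",
          class = "fdg_graph_error")
  }
  concept_graph(tab[required])
}

#' @rdname read_concept_graph
#' @param graph A `concept_graph`.
#' @export
write_concept_graph <- function(graph, path) {
  stopifnot(inherits(graph, "concept_graph"))
  out <- graph$concepts
  out$parents <- map_chr(out$parents, paste, collapse = "|")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
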