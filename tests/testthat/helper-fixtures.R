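# Shared fixtures, built in code at test time.

# Hand-built six-concept graph with a diamond of fully defined concepts:
#   root -> CF(prim) -> Disease(prim) -> P1(def) -\
#                    \------------------> P2(def) --> leaf(def)
tiny_graph <- function() {
  concept_graph(tibble::tibble(
    id = c("138875005", "404684003", "64572001", "118234003", "127294003",
           "312608009"),
    term = c("root", "finding", "disease", "defined one", "defined two",
             "leaf"),
    definition_status = c("primitive", "primitive", "primitive",
                          "fully_defined", "fully_defined", "fully_defined"),
    parents = c("", "138875005", "404684003", "64572001", "404684003",
                "118234003|127294003")
  ))
}

small_fixture <- function(seed = 101, n_concepts = 12) {
  make_fixture_graph(generator_params(seed = seed, n_concepts = n_concepts))
}

pango_graph <- function(seed = 101, n_concepts = 12) {
  attach_vocabulary(small_fixture(seed, n_concepts), pango_fixture_vocabulary())
}

strain_rule_delta <- function() {
  rule_addition(fixture_strain_attribute_id(),
                domain = paste0("<< ", hierarchy_root_ids()[["organism"]]),
                range = "ext:Pango")
}

full_rule_set <- function() {
  extend_rules(extended_rule_set(), list(strain_rule_delta()))
}

# Independent subsumption oracle: boolean-matrix transitive closure
# (Warshall-style squaring), sharing no code with the package's BFS.
closure_matrix_oracle <- function(graph) {
  ids <- graph_concepts(graph)$id
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  parents <- graph_concepts(graph)$parents
  for (i in seq_len(n)) adj[i, parents[[i]]] <- TRUE
  reach <- adj | diag(n) > 0
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach # reach[child, ancestor]
}

# Random DAG as a concept table: node i picks parents among earlier nodes.
random_dag_graph <- function(n, seed, primitive_fraction = 0.6) {
  set.seed(seed)
  ids <- character(n)
  taken <- character(0)
  for (i in seq_len(n)) {
    repeat {
      id <- make_sctid(paste0(sample(1:9, 1),
                              paste(sample(0:9, 6, replace = TRUE), collapse = "")))
      if (!id %in% taken) break
    }
    ids[i] <- id
    taken <- c(taken, id)
  }
  parents <- vector("list", n)
  parents[[1]] <- character(0)
  for (i in 2:n) {
    k <- sample(seq_len(min(3L, i - 1L)), 1L)
    parents[[i]] <- sample(ids[seq_len(i - 1L)], k)
  }
  status <- ifelse(stats::runif(n) < primitive_fraction,
                   "primitive", "fully_defined")
  status[1] <- "primitive" # root must be primitive for PPP
  concept_graph(tibble::tibble(
    id = ids, term = paste0("node ", seq_len(n)),
    definition_status = status, parents = parents
  ))
}

package_closure_matrix <- function(graph) {
  closure <- subsumption_closure(graph)
  ids <- names(closure)
  out <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (id in ids) out[id, closure[[id]]] <- TRUE
  out
}
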