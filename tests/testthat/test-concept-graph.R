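# Concept graph construction, subsumption, vocabulary attachment,
# proximal primitive parents, disjunction resolution, IO.

test_that("constructor enforces graph invariants", {
  ok <- tiny_graph()
  expect_s3_class(ok, "concept_graph")
  base <- tibble::tibble(
    id = c("138875005", "404684003"),
    term = c("a", "b"), definition_status = "primitive",
    parents = c("404684003", "138875005"))
  expect_error(concept_graph(base), class = "fdg_cycle_error")
  expect_error(concept_graph(tibble::tibble(
    id = "138875005", term = "a", definition_status = "primitive",
    parents = "999")), class = "fdg_dangling_parent")
  expect_error(concept_graph(tibble::tibble(
    id = c("138875005", "404684003"), term = "a",
    definition_status = "primitive", parents = c("", ""))),
    class = "fdg_graph_error")  # two roots
  expect_error(concept_graph(tibble::tibble(
    id = "45169002", term = "a", definition_status = "primitive",
    parents = "")), class = "fdg_malformed_id")
})

test_that("subsumption is reflexive, follows chains, and rejects unknowns", {
  g <- tiny_graph()
  for (id in graph_concepts(g)$id) expect_true(is_subsumed_by(id, id, g))
  expect_true(is_subsumed_by("312608009", "404684003", g))
  expect_true(is_subsumed_by("118234003", "64572001", g))
  expect_false(is_subsumed_by("404684003", "312608009", g))
  expect_error(is_subsumed_by("45169001", "404684003", g),
               class = "fdg_unknown_concept")
})

test_that("subsumption agrees with matrix transitive closure on random DAGs", {
  for (seed in 1:8) {
    g <- random_dag_graph(n = 60, seed = 1000 + seed)
    expect_identical(package_closure_matrix(g), closure_matrix_oracle(g))
  }
  # spot-check the scalar API against the oracle on one graph
  g <- random_dag_graph(n = 40, seed = 77)
  oracle <- closure_matrix_oracle(g)
  ids <- graph_concepts(g)$id
  set.seed(77)
  for (i in 1:100) {
    a <- sample(ids, 1); b <- sample(ids, 1)
    expect_identical(is_subsumed_by(a, b, g), unname(oracle[a, b]))
  }
})

test_that("concepts in disjoint top-level hierarchies never subsume each other", {
  g <- small_fixture()
  closure <- subsumption_closure(g)
  h <- hierarchy_root_ids()
  cf <- names(closure)[vapply(closure, function(a)
    h[["clinical_finding"]] %in% a, logical(1))]
  pr <- names(closure)[vapply(closure, function(a)
    h[["procedure"]] %in% a, logical(1))]
  both <- intersect(cf, pr)
  expect_length(both, 0)
})

test_that("vocabulary attachment adds external concepts conservatively", {
  g <- small_fixture()
  before <- package_closure_matrix(g)
  g2 <- attach_vocabulary(g, pango_fixture_vocabulary())
  expect_true(is_subsumed_by("~Pango~B.1.1.7~", fixture_strain_parent_id(), g2))
  expect_true(is_subsumed_by("~Pango~B.1.1.7~", "~Pango~B~", g2))
  expect_true(is_subsumed_by("~Pango~B.1.1.7~",
                             hierarchy_root_ids()[["organism"]], g2))
  expect_false(is_subsumed_by("~Pango~B~", "~Pango~B.1.1.7~", g2))
  # conservativity: host-to-host subsumption unchanged
  after <- package_closure_matrix(g2)
  host <- rownames(before)
  expect_identical(after[host, host], before)
  # errors
  expect_error(attach_vocabulary(g2, pango_fixture_vocabulary()),
               class = "fdg_duplicate_vocabulary")
  ghost <- make_sctid("4217639958") # well-formed id absent from the graph
  expect_error(
    attach_vocabulary(g, pango_fixture_vocabulary(attachment_parent = ghost)),
    class = "fdg_unknown_concept")
})

test_that("registry JSON round-trips into an attachable vocabulary", {
  path <- system.file("extdata", "vocabulary_pango_synthetic.json",
                      package = "fdgrammar")
  v <- read_vocabulary(path)
  expect_identical(v$key, "Pango")
  expect_identical(v$attachment_parent, fixture_strain_parent_id())
  g <- attach_vocabulary(small_fixture(), v)
  expect_true(is_subsumed_by("~Pango~B.1~", "~Pango~B~", g))
})

test_that("proximal primitive parents are the nearest primitive ancestors", {
  g <- tiny_graph()
  # primitive concept is its own PPP
  expect_identical(proximal_primitive_parent("64572001", g), "64572001")
  # chain through a defined concept stops at the first primitive
  expect_identical(proximal_primitive_parent("118234003", g), "64572001")
  # diamond with two defined parents reaching distinct primitives
  expect_identical(proximal_primitive_parent("312608009", g),
                   sort_result <- c("64572001", "404684003"))
  expect_error(proximal_primitive_parent("99999", g),
               class = "fdg_unknown_concept")
})

test_that("PPP results are always primitive ancestors-or-self", {
  g <- random_dag_graph(n = 80, seed = 13, primitive_fraction = 0.4)
  tab <- graph_concepts(g)
  status <- stats::setNames(tab$definition_status, tab$id)
  oracle <- closure_matrix_oracle(g)
  for (id in sample(tab$id, 30)) {
    res <- proximal_primitive_parent(id, g)
    expect_true(length(res) >= 1)
    expect_true(all(status[res] == "primitive"))
    expect_true(all(oracle[id, res]))
  }
})

test_that("disjunction resolution follows the depth-gap rule", {
  g <- tiny_graph()
  expect_identical(resolve_disjunction("118234003", "118234003", g, 0), "118234003")
  # siblings under a shared parent resolve with gap >= 1, not with 0
  g2 <- concept_graph(tibble::tibble(
    id = c("138875005", "404684003", "118234003", "127294003"),
    term = c("root", "p", "s1", "s2"),
    definition_status = "primitive",
    parents = c("", "138875005", "404684003", "404684003")))
  expect_identical(resolve_disjunction("118234003", "127294003", g2, 1), "404684003")
  expect_identical(resolve_disjunction("118234003", "127294003", g2, 0), "unmapped")
  # symmetry
  expect_identical(resolve_disjunction("118234003", "127294003", g, 2),
                   resolve_disjunction("127294003", "118234003", g, 2))
})

test_that("disjunction resolution matches exhaustive search on random DAGs", {
  for (seed in 1:4) {
    g <- random_dag_graph(n = 50, seed = 500 + seed)
    oracle <- closure_matrix_oracle(g)
    ids <- graph_concepts(g)$id
    depths <- local({ # longest path from root, computed independently
      d <- stats::setNames(rep(NA_integer_, length(ids)), ids)
      parents <- stats::setNames(graph_concepts(g)$parents, ids)
      while (anyNA(d)) {
        for (id in ids[is.na(d)]) {
          ps <- parents[[id]]
          if (length(ps) == 0) d[id] <- 0L
          else if (!anyNA(d[ps])) d[id] <- max(d[ps]) + 1L
        }
      }
      d
    })
    set.seed(seed)
    for (rep in 1:40) {
      a <- sample(ids, 1); b <- sample(ids, 1); gap <- sample(0:3, 1)
      common <- ids[oracle[a, ] & oracle[b, ]]
      expected <- "unmapped"
      if (length(common)) {
        deepest <- common[depths[common] == max(depths[common])]
        hit <- deepest[pmin(depths[a] - depths[deepest],
                            depths[b] - depths[deepest]) <= gap]
        if (length(hit)) {
          expected <- hit[order(nchar(hit), hit)][1]
        }
      }
      expect_identical(resolve_disjunction(a, b, g, gap), expected)
    }
  }
})

test_that("selection criteria accept only a full house of verdicts", {
  r <- evaluate_selection_criteria(TRUE, TRUE, TRUE, TRUE, TRUE)
  expect_true(attr(r, "accepted"))
  r <- evaluate_selection_criteria(TRUE, FALSE, TRUE, TRUE, TRUE,
                                   notes = c(concept_based = "a thesaurus"))
  expect_false(attr(r, "accepted"))
  expect_identical(r$criterion[!r$verdict], "concept_based")
  r <- evaluate_selection_criteria(TRUE, TRUE, TRUE, FALSE, TRUE)
  expect_false(attr(r, "accepted"))
})

test_that("graph TSV IO round-trips, including attached vocabularies", {
  dir <- withr::local_tempdir()
  g <- pango_graph()
  path <- file.path(dir, "graph.tsv")
  write_concept_graph(g, path)
  g2 <- read_concept_graph(path)
  expect_identical(graph_concepts(g2), graph_concepts(g))
  expect_identical(g2$root, g$root)
  expect_setequal(names(g2$vocabularies), names(g$vocabularies))
  # cycle in the file is rejected
  writeLines(c("id\tterm\tdefinition_status\tparents",
               "138875005\ta\tprimitive\t404684003",
               "404684003\tb\tprimitive\t138875005"),
             file.path(dir, "cyc.tsv"))
  expect_error(read_concept_graph(file.path(dir, "cyc.tsv")),
               class = "fdg_cycle_error")
})
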