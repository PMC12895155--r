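# Deterministic, seedable generators: fixture ontologies, valid expressions,
# annotated corpora and negative-test mutants. The generators define the
# study conditions every other module is exercised under; identical
# parameters and seed give byte-identical output.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Generator parameters
#'
#' Bundles every knob of the synthetic generators. Defaults mirror the
#' reference corpus conditions: roughly 47% of unique expressions are
#' postcoordinated and 3.75% of elements use grammar extensions; instance
#' counts are log-uniform over 1..10^6 (heavy-tailed, as observed for
#' clinical collections ranging from single lab codes to billions of
#' instances).
#'
#' @param seed Integer master seed; all randomness derives from it.
#' @param n_concepts Synthetic concepts generated per content hierarchy.
#' @param primitive_fraction Probability a generated concept is primitive.
#' @param max_parents Maximum is-a parents per generated concept.
#' @param n_records Records per corpus source (sampled mode).
#' @param extension_fraction Probability a record uses a grammar extension.
#' @param pce_fraction Probability a record is postcoordinated at all.
#' @param instance_range Two numbers: log-uniform bounds for instance counts.
#' @return A `generator_params` list.
#' @export
generator_params <- function(seed = 1L, n_concepts = 30L,
                             primitive_fraction = 0.7, max_parents = 2L,
                             n_records = 100L, extension_fraction = 0.0375,
                             pce_fraction = 0.47,
                             instance_range = c(1, 1e6)) {
  stopifnot(
    primitive_fraction >= 0, primitive_fraction <= 1,
    extension_fraction >= 0, extension_fraction <= 1,
    pce_fraction >= 0, pce_fraction <= 1,
    n_concepts > 0, max_parents >= 1, n_records >= 0,
    length(instance_range) == 2L, all(instance_range >= 1)
  )
  structure(
    list(seed = as.integer(seed), n_concepts = as.integer(n_concepts),
         primitive_fraction = primitive_fraction,
         max_parents = as.integer(max_parents),
         n_records = as.integer(n_records),
         extension_fraction = extension_fraction,
         pce_fraction = pce_fraction, instance_range = instance_range),
    class = "generator_params"
  )
}

random_sctid <- function(taken) {
  repeat {
    body <- paste0(sample(1:9, 1), paste(sample(0:9, sample(6:8, 1), replace = TRUE),
                                         collapse = ""))
    id <- make_sctid(body)
    if (!id %in% taken) return(id)
  }
}

#' Generate a fixture ontology
#'
#' Builds an acyclic concept graph with a primitive root, the standard
#' top-level hierarchies (Clinical finding, Procedure, Body structure,
#' Organism, Observable entity, Physical object, Qualifier value, Situation),
#' an Attribute hierarchy carrying the 13 extension attribute concepts with
#' their real identifiers, the synthetic strain-category concept under
#' Organism, and `n_concepts` synthetic concepts per content hierarchy with
#' random is-a links inside their hierarchy. Every generated identifier
#' carries a computed Verhoeff check digit. Identical parameters give
#' identical graphs.
#'
#' @param params A [generator_params()].
#' @return A `concept_graph`.
#' @export
make_fixture_graph <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  local_seed(params$seed, {
    root <- "138875005"
    h <- hierarchy_root_ids()
    ext_ids <- extension_attribute_ids()
    rows <- list(
      tibble(id = root, term = "Concept (root)",
             definition_status = "primitive", parents = list(character(0)))
    )
    hier_terms <- c(
      clinical_finding = "Clinical finding", procedure = "Procedure",
      body_structure = "Body structure", organism = "Organism",
      observable_entity = "Observable entity",
      physical_object = "Physical object", qualifier_value = "Qualifier value",
      situation = "Situation with explicit context", attribute = "Attribute"
    )
    for (k in names(h)) {
      rows[[length(rows) + 1L]] <- tibble(
        id = h[[k]], term = hier_terms[[k]],
        definition_status = "primitive", parents = list(root)
      )
    }
    attr_terms <- c("Without", "Except for", "Finding context",
                    "Procedure context", "With size", "Date", "Resulting in",
                    "Quantity", "Score", "After", "Before", "During",
                    "Duration")
    for (i in seq_along(ext_ids)) {
      rows[[length(rows) + 1L]] <- tibble(
        id = unname(ext_ids[[i]]), term = paste0(attr_terms[[i]], " (attribute)"),
        definition_status = "primitive", parents = list(h[["attribute"]])
      )
    }
    core_attrs <- c("363698007" = "Finding site (attribute)",
                    "260686004" = "Method (attribute)")
    for (i in seq_along(core_attrs)) {
      rows[[length(rows) + 1L]] <- tibble(
        id = names(core_attrs)[[i]], term = unname(core_attrs[[i]]),
        definition_status = "primitive", parents = list(h[["attribute"]])
      )
    }
    rows[[length(rows) + 1L]] <- tibble(
      id = fixture_strain_parent_id(),
      term = "Microbiological strain category (synthetic)",
      definition_status = "primitive", parents = list(h[["organism"]])
    )
    rows[[length(rows) + 1L]] <- tibble(
      id = fixture_strain_attribute_id(),
      term = "Microbiological strain (synthetic attribute)",
      definition_status = "primitive", parents = list(h[["attribute"]])
    )
    content <- setdiff(names(h), "attribute")
    taken <- c(root, unname(h), unname(ext_ids), names(core_attrs),
               fixture_strain_parent_id(), fixture_strain_attribute_id())
    for (k in content) {
      hier_ids <- h[[k]]
      for (i in seq_len(params$n_concepts)) {
        id <- random_sctid(taken)
        taken <- c(taken, id)
        n_par <- sample(seq_len(min(params$max_parents, length(hier_ids))), 1L)
        parents <- sample(hier_ids, n_par)
        status <- if (stats::runif(1) < params$primitive_fraction)
          "primitive" else "fully_defined"
        rows[[length(rows) + 1L]] <- tibble(
          id = id, term = paste0(hier_terms[[k]], " ", i, " (synthetic)"),
          definition_status = status, parents = list(parents)
        )
        hier_ids <- c(hier_ids, id)
      }
    }
    concept_graph(bind_rows(rows))
  })
}

# ---- expression generation --------------------------------------------------

# Precompute, per rule, the pool of focus concepts satisfying the domain and
# a sampler for range-satisfying values.
rule_samplers <- function(graph, rules) {
  closure <- subsumption_closure(graph)
  ids <- names(closure)
  native <- ids[!stri_startswith_fixed(ids, "~")]
  descendants_or_self <- function(target) {
    ids[map_lgl(closure, function(a) target %in% a)]
  }
  pool_for <- function(constraint) {
    branches <- if (constraint$op == "union") constraint$branches else list(constraint)
    unique(unlist(lapply(branches, function(b) {
      switch(b$op,
        desc_or_self = descendants_or_self(normalize_ref(b$arg)),
        desc = setdiff(descendants_or_self(normalize_ref(b$arg)),
                       normalize_ref(b$arg)),
        self = normalize_ref(b$arg),
        ext_cluster = ids[stri_startswith_fixed(ids, paste0("~", b$arg, "~"))],
        concrete = character(0)
      )
    })))
  }
  value_sampler <- function(constraint) {
    branches <- if (constraint$op == "union") constraint$branches else list(constraint)
    function() {
      b <- branches[[sample(length(branches), 1L)]]
      if (b$op == "concrete") {
        switch(b$arg,
          number = paste0("#", sample(1:500, 1L)),
          string = paste0('"', sample(c("present", "absent", "left", "right"), 1L), '"'),
          date = paste0('"', sprintf("20%02d-%02d-%02d", sample(0:25, 1L),
                                     sample(1:12, 1L), sample(1:28, 1L)), '"')
        )
      } else {
        pool <- pool_for(b)
        if (length(pool) == 0L) return(NULL)
        sample(pool, 1L)
      }
    }
  }
  lapply(seq_len(nrow(rules$rules)), function(i) {
    list(
      attribute = rules$rules$attribute[[i]],
      focus_pool = intersect(pool_for(rules$rules$domain[[i]]), native),
      sample_value = value_sampler(rules$rules$range[[i]])
    )
  })
}

#' Generate valid expression strings
#'
#' Samples `n` expressions guaranteed valid under `rules` over `graph`:
#' generation picks a rule first, then a focus concept from its domain and a
#' value from its range. Fractions of postcoordinated and extension-using
#' expressions are achieved in expectation via `params`.
#'
#' @param graph A `concept_graph` (vocabularies attached if `rules` refer
#'   to them).
#' @param rules An `mrcm_rules` the expressions must satisfy.
#' @param n Number of expressions.
#' @param params A [generator_params()].
#' @param extension_attributes Attribute ids counted as extensions (default
#'   [extension_attribute_ids()]).
#' @return Character vector of `n` expression strings.
#' @export
make_expressions <- function(graph, rules, n, params = generator_params(),
                             extension_attributes = extension_attribute_ids()) {
  stopifnot(inherits(graph, "concept_graph"), inherits(rules, "mrcm_rules"))
  local_seed(params$seed + 104729L, {
    samplers <- rule_samplers(graph, rules)
    usable <- keep(samplers, function(s) length(s$focus_pool) > 0L)
    is_ext_rule <- map_lgl(usable, function(s) {
      s$attribute %in% extension_attributes ||
        {
          r <- rules$rules$range[[match(s$attribute, rules$rules$attribute)]]
          br <- if (r$op == "union") r$branches else list(r)
          any(map_chr(br, "op") == "ext_cluster")
        }
    })
    ext_rules <- usable[is_ext_rule]
    core_rules <- usable[!is_ext_rule]
    closure <- subsumption_closure(graph)
    attr_root <- hierarchy_root_ids()[["attribute"]]
    plain_pool <- names(closure)[map_lgl(closure, function(a) {
      !attr_root %in% a && !any(stri_startswith_fixed(a, "~"))
    })]
    plain_pool <- plain_pool[!stri_startswith_fixed(plain_pool, "~")]

    gen_one <- function(extended) {
      pool <- if (extended && length(ext_rules)) ext_rules else core_rules
      if (extended && length(ext_rules) == 0L) {
        abort("No extension rules usable with this graph.", class = "fdg_rules_error")
      }
      for (attempt in seq_len(50L)) {
        s <- pool[[sample(length(pool), 1L)]]
        focus <- sample(s$focus_pool, 1L)
        value <- s$sample_value()
        if (is.null(value)) next
        return(paste0(focus, " : ", s$attribute, " = ", value))
      }
      abort("Could not generate a valid refinement.", class = "fdg_rules_error")
    }

    vapply(seq_len(n), function(i) {
      extended <- stats::runif(1) < params$extension_fraction
      if (extended) return(gen_one(TRUE))
      if (stats::runif(1) < params$pce_fraction && length(core_rules)) {
        gen_one(FALSE)
      } else {
        sample(plain_pool, 1L)
      }
    }, character(1))
  })
}

#' Generate an annotated corpus
#'
#' In `"sampled"` mode each source gets `n_records` records whose extension
#' flags are independent Bernoulli draws at `extension_fraction` and whose
#' instance counts are log-uniform. In `"exact"` mode a `counts` table
#' (columns `source`, `ids_encoded`, `extensions_used`,
#' `instances_encoded`, `extension_instances`) is reproduced exactly:
#' element counts, extension counts and both instance sums match the table
#' bit-for-bit, so summary percentages are fully determined by the input
#' counts.
#'
#' @param graph,rules As in [make_expressions()]; `rules` must license both
#'   extension and core refinements.
#' @param params A [generator_params()].
#' @param sources Character vector of source labels (sampled mode).
#' @param counts Counts table (exact mode).
#' @param mode `"sampled"` or `"exact"`.
#' @param extension_attributes Attribute ids counted as extensions.
#' @return A corpus tibble: `source`, `element_id`, `expression`,
#'   `instance_count`.
#' @export
make_corpus <- function(graph, rules, params = generator_params(),
                        sources = usage_counts()$source,
                        counts = NULL, mode = c("sampled", "exact"),
                        extension_attributes = extension_attribute_ids()) {
  mode <- match.arg(mode)
  if (mode == "exact" && is.null(counts)) {
    abort("Exact mode needs a `counts` table.", class = "fdg_corpus_error")
  }
  local_seed(params$seed + 224737L, {
    samplers <- rule_samplers(graph, rules)
    usable <- keep(samplers, function(s) length(s$focus_pool) > 0L)
    is_ext_rule <- map_lgl(usable, function(s) {
      s$attribute %in% extension_attributes ||
        {
          r <- rules$rules$range[[match(s$attribute, rules$rules$attribute)]]
          br <- if (r$op == "union") r$branches else list(r)
          any(map_chr(br, "op") == "ext_cluster")
        }
    })
    ext_rules <- usable[is_ext_rule]
    core_rules <- usable[!is_ext_rule]
    if (length(ext_rules) == 0L) {
      abort("Rules license no extension refinements.", class = "fdg_rules_error")
    }
    closure <- subsumption_closure(graph)
    attr_root <- hierarchy_root_ids()[["attribute"]]
    plain_pool <- names(closure)[map_lgl(closure, function(a) !attr_root %in% a)]
    plain_pool <- plain_pool[!stri_startswith_fixed(plain_pool, "~")]

    gen_expr <- function(extended) {
      pool <- if (extended) ext_rules else core_rules
      if (!extended && (length(core_rules) == 0L || stats::runif(1) >= params$pce_fraction)) {
        return(sample(plain_pool, 1L))
      }
      for (attempt in seq_len(50L)) {
        s <- pool[[sample(length(pool), 1L)]]
        value <- s$sample_value()
        if (is.null(value)) next
        return(paste0(sample(s$focus_pool, 1L), " : ", s$attribute, " = ", value))
      }
      abort("Could not generate a refinement.", class = "fdg_rules_error")
    }

    # split `total` into `k` positive-or-zero integers summing exactly
    split_sum <- function(total, k) {
      if (k == 0L) return(numeric(0))
      base <- floor(total / k)
      out <- rep(base, k)
      out[seq_len(total - base * k)] <- base + 1
      out
    }

    if (mode == "exact") {
      counts <- as_tibble(counts)
      rows <- lapply(seq_len(nrow(counts)), function(i) {
        src <- counts$source[[i]]
        n_ids <- as.numeric(counts$ids_encoded[[i]])
        n_ext <- as.numeric(counts$extensions_used[[i]])
        if (n_ids == 0) return(NULL)
        stopifnot(n_ext <= n_ids)
        ext_flags <- c(rep(TRUE, n_ext), rep(FALSE, n_ids - n_ext))
        inst <- numeric(n_ids)
        inst[seq_len(n_ext)] <- split_sum(as.numeric(counts$extension_instances[[i]]), n_ext)
        rest <- as.numeric(counts$instances_encoded[[i]]) -
          as.numeric(counts$extension_instances[[i]])
        inst[which(!ext_flags)] <- split_sum(rest, n_ids - n_ext)
        tibble(
          source = src,
          element_id = sprintf("%s-%06d", gsub("[^A-Za-z]", "", src), seq_len(n_ids)),
          expression = vapply(ext_flags, gen_expr, character(1)),
          instance_count = inst
        )
      })
      bind_rows(rows)
    } else {
      rows <- lapply(seq_along(sources), function(i) {
        n <- params$n_records
        if (n == 0L) return(NULL)
        ext_flags <- stats::runif(n) < params$extension_fraction
        lo <- log(params$instance_range[[1]])
        hi <- log(params$instance_range[[2]])
        inst <- floor(exp(stats::runif(n, lo, hi)))
        tibble(
          source = sources[[i]],
          element_id = sprintf("%s-%06d", gsub("[^A-Za-z]", "", sources[[i]]), seq_len(n)),
          expression = vapply(ext_flags, gen_expr, character(1)),
          instance_count = inst
        )
      })
      bind_rows(rows)
    }
  })
}

#' Corrupt expressions into negative test cases
#'
#' Applies one corruption per mutant — dropping a tilde from an external
#' reference, breaking an identifier's check digit, removing an `=`, or
#' emptying a group — paired with the error class the parser is expected to
#' raise (`"fdg_syntax_error"` or `"fdg_malformed_id"`).
#'
#' @param expr_strings Source expressions (must parse).
#' @param n Number of mutants.
#' @param seed Seed.
#' @return A tibble: `original`, `mutant`, `mutation`, `expected_error`.
#' @export
make_mutations <- function(expr_strings, n, seed = 1L) {
  local_seed(seed + 15485863L, {
    mutate_one <- function(s) {
      ops <- list()
      if (stri_detect_fixed(s, "~")) {
        ops$drop_tilde <- function(x) {
          at <- stri_locate_last_fixed(x, "~")[1, 1]
          paste0(stri_sub(x, 1L, at - 1L), stri_sub(x, at + 1L))
        }
      }
      m <- stri_locate_first_regex(s, "[1-9][0-9]{5,17}")
      if (!is.na(m[1, 1])) {
        ops$bad_check_digit <- function(x) {
          last <- m[1, 2]
          digit <- as.integer(stri_sub(x, last, last))
          stri_sub(x, last, last) <- as.character((digit + 1L) %% 10L)
          x
        }
      }
      if (stri_detect_fixed(s, "=")) {
        ops$drop_equals <- function(x) stri_replace_first_fixed(x, "=", " ")
      }
      if (stri_detect_regex(s, "\\{[^}]*\\}")) {
        ops$empty_group <- function(x) stri_replace_first_regex(x, "\\{[^}]*\\}", "{}")
      }
      if (length(ops) == 0L) return(NULL)
      which_op <- sample(names(ops), 1L)
      expected <- if (which_op == "bad_check_digit") "fdg_malformed_id" else "fdg_syntax_error"
      list(mutant = ops[[which_op]](s), mutation = which_op,
           expected_error = expected)
    }
    out <- list()
    pool <- expr_strings
    guard <- 0L
    while (length(out) < n && guard < 20L * n) {
      guard <- guard + 1L
      s <- sample(pool, 1L)
      m <- mutate_one(s)
      if (is.null(m)) next
      out[[length(out) + 1L]] <- tibble(
        original = s, mutant = m$mutant, mutation = m$mutation,
        expected_error = m$expected_error
      )
    }
    bind_rows(out)
  })
}
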