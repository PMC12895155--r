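# Constraint language, validation engine, rule extension, rules IO.

test_that("constraint parsing and formatting round-trip", {
  cases <- c("<< 404684003", "< 404684003", "404684003", "ext:Pango",
             "num", "str", "date",
             "<< 404684003 OR << 71388002 OR date")
  for (s in cases) expect_identical(format_constraint(parse_constraint(s)), s)
  expect_error(parse_constraint("<<<x"), class = "fdg_constraint_syntax")
  expect_error(parse_constraint(""), class = "fdg_constraint_syntax")
})

test_that("constraint evaluation implements descendant/self/concrete semantics", {
  g <- pango_graph()
  cf <- hierarchy_root_ids()[["clinical_finding"]]
  expect_true(evaluate_constraint(paste0("<< ", cf), cf, g))   # reflexive
  expect_false(evaluate_constraint(paste0("< ", cf), cf, g))   # strict
  expect_true(evaluate_constraint(cf, cf, g))                  # self
  expect_false(evaluate_constraint(cf, "71388002", g))
  # external cluster matches by key, case-sensitively
  b <- parse_expression("~Pango~B~")$focus[[1]]
  expect_true(evaluate_constraint("ext:Pango", b, g))
  expect_false(evaluate_constraint("ext:pango", b, g))
  # concrete types; dates are ISO 8601 calendar dates
  num <- parse_expression("404684003 : 246262008 = #4")$ungrouped[[1]]$value
  d_ok <- parse_expression('404684003 : 410671006 = "2021-03-15"')$ungrouped[[1]]$value
  d_bad <- parse_expression('404684003 : 410671006 = "tomorrow"')$ungrouped[[1]]$value
  d_imp <- parse_expression('404684003 : 410671006 = "2021-02-30"')$ungrouped[[1]]$value
  expect_true(evaluate_constraint("num", num, g))
  expect_false(evaluate_constraint("date", num, g))
  expect_true(evaluate_constraint("date", d_ok, g))
  expect_false(evaluate_constraint("date", d_bad, g))
  expect_false(evaluate_constraint("date", d_imp, g))
  expect_true(evaluate_constraint("num OR date", num, g))      # union
})

test_that("context attributes validate under the extended model, not the base", {
  g <- pango_graph()
  qualifier <- graph_concepts(g)$id[
    vapply(subsumption_closure(g), function(a)
      hierarchy_root_ids()[["qualifier_value"]] %in% a, logical(1))][2]
  expr <- paste0("404684003 : 408729009 = ", qualifier)
  expect_true(is_valid(validate_expression(expr, extended_rule_set(), g)))
  base_report <- validate_expression(expr, base_rule_set(), g)
  expect_false(is_valid(base_report))
  expect_identical(base_report$violations$code, "DOMAIN_MISMATCH")
})

test_that("the strain-refinement scenario flips on the new rule", {
  g <- pango_graph()
  expr <- paste0(hierarchy_root_ids()[["organism"]], " : ",
                 fixture_strain_attribute_id(), " = ~Pango~B.1.1.7~")
  without_rule <- validate_expression(expr, extended_rule_set(), g)
  expect_false(is_valid(without_rule))
  expect_true("ATTRIBUTE_NOT_PERMITTED" %in% without_rule$violations$code)
  expect_true(is_valid(validate_expression(expr, full_rule_set(), g)))
})

test_that("concrete ranges distinguish type errors from range mismatches", {
  g <- pango_graph()
  rules <- extended_rule_set()
  expect_true(is_valid(validate_expression(
    "71388002 : 103373006 = #8", rules, g)))
  bad <- validate_expression('71388002 : 103373006 = "large"', rules, g)
  expect_false(is_valid(bad))
  expect_identical(bad$violations$code, "BAD_CONCRETE_TYPE")
  mismatch <- validate_expression("404684003 : 363698007 = 362981000",
                                  base_rule_set(), g)
  expect_false(is_valid(mismatch))
  expect_identical(mismatch$violations$code, "RANGE_MISMATCH")
})

test_that("unknown concepts and vocabularies are reported with paths", {
  g <- small_fixture() # Pango NOT attached
  rules <- full_rule_set()
  rep1 <- validate_expression(
    paste0(hierarchy_root_ids()[["organism"]], " : ",
           fixture_strain_attribute_id(), " = ~Pango~B~"), rules, g)
  expect_true("UNKNOWN_VOCABULARY" %in% rep1$violations$code)
  ghost <- make_sctid("99751233869") # well-formed but absent from the graph
  rep2 <- validate_expression(
    paste0("404684003 + ", ghost, " : 363698007 = 123037004"),
    base_rule_set(), g)
  expect_true("UNKNOWN_CONCEPT" %in% rep2$violations$code)
  expect_true(all(grepl("^expr(/|$)", rep2$violations$path)))
  # every violation path names a real AST location
  expect_true(all(grepl("focus\\[[0-9]+\\]|ungrouped\\[[0-9]+\\]|group\\[[0-9]+\\]",
                        rep2$violations$path)))
})

test_that("an expression with known focus concepts and no refinements is valid", {
  g <- small_fixture()
  rules <- base_rule_set()
  for (id in sample(graph_concepts(g)$id, 10)) {
    expect_true(is_valid(validate_expression(id, rules, g)))
  }
})

test_that("validation is order-independent", {
  g <- pango_graph()
  rules <- extended_rule_set()
  a <- "404684003 + 71388002 : 410671006 = \"2020-01-01\", 103335007 = #5"
  b <- "71388002 + 404684003 : 103335007 = #5, 410671006 = \"2020-01-01\""
  expect_identical(is_valid(validate_expression(a, rules, g)),
                   is_valid(validate_expression(b, rules, g)))
  expect_identical(serialize_expression(parse_expression(a)),
                   serialize_expression(parse_expression(b)))
})

test_that("cardinality limits are enforced per scope", {
  g <- small_fixture()
  rules <- mrcm_rules(tibble::tibble(
    attribute = "363698007", domain = "<< 404684003",
    range = "<< 123037004", cardinality = "optional-one", groupable = TRUE))
  bs <- graph_concepts(g)$id[vapply(subsumption_closure(g), function(a)
    hierarchy_root_ids()[["body_structure"]] %in% a, logical(1))][1:2]
  twice <- paste0("404684003 : 363698007 = ", bs[1], ", 363698007 = ", bs[2])
  rep <- validate_expression(twice, rules, g)
  expect_true("CARDINALITY" %in% rep$violations$code)
  # one per group is fine
  grouped <- paste0("404684003 : { 363698007 = ", bs[1],
                    " } { 363698007 = ", bs[2], " }")
  expect_true(is_valid(validate_expression(grouped, rules, g)))
})

test_that("validate agrees with a brute-force rule checker on small fixtures", {
  g <- pango_graph()
  rules <- full_rule_set()
  oracle <- closure_matrix_oracle(g)
  sat <- function(constraint, value) {
    # independent constraint checker over the closure matrix
    branches <- if (constraint$op == "union") constraint$branches else list(constraint)
    any(vapply(branches, function(b) {
      if (b$op == "concrete") {
        if (!inherits(value, "fdg_concrete_value")) return(FALSE)
        if (b$arg == "number") return(value$kind == "number")
        if (b$arg == "string") return(value$kind == "string")
        return(value$kind == "string" &&
                 grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}", value$lexeme) &&
                 !is.na(as.Date(substr(value$lexeme, 1, 10))))
      }
      if (!inherits(value, "fdg_concept_token")) return(FALSE)
      id <- if (value$kind == "sct") value$id else
        paste0("~", value$key, "~", value$local_id, "~")
      if (b$op == "ext_cluster") {
        return(value$kind == "ext" && value$key == b$arg)
      }
      if (!id %in% rownames(oracle) || !b$arg %in% rownames(oracle)) return(FALSE)
      switch(b$op,
        self = id == b$arg,
        desc_or_self = oracle[id, b$arg],
        desc = id != b$arg && oracle[id, b$arg])
    }, logical(1)))
  }
  brute_valid <- function(expr) {
    all(vapply(c(expr$ungrouped, unlist(expr$groups, recursive = FALSE)),
               function(r) {
      aid <- if (r$attribute$kind == "sct") r$attribute$id else NA
      cand <- rules$rules[rules$rules$attribute %in% aid, ]
      if (nrow(cand) == 0) return(FALSE)
      any(vapply(seq_len(nrow(cand)), function(k) {
        all(vapply(expr$focus, function(f) sat(cand$domain[[k]], f),
                   logical(1))) && sat(cand$range[[k]], r$value)
      }, logical(1)))
    }, logical(1)))
  }
  xs <- make_expressions(g, rules, 120,
                         generator_params(seed = 11, extension_fraction = 0.3,
                                          pce_fraction = 0.9))
  # add a few hand-made invalid ones
  xs <- c(xs,
          "404684003 : 103373006 = #8",            # attribute off-domain
          "71388002 : 45169001 = 362981000",       # value off-range
          '404684003 : 410671006 = "not-a-date"')  # bad concrete
  for (x in xs) {
    expr <- parse_expression(x)
    expect_identical(is_valid(validate_expression(expr, rules, g)),
                     brute_valid(expr), info = x)
  }
})

test_that("extension is strictly permissive and reproduces the shipped fixture", {
  base <- base_rule_set()
  # empty delta list is the identity
  same <- extend_rules(base, list())
  expect_identical(lapply(same$rules$domain, format_constraint),
                   lapply(base$rules$domain, format_constraint))
  expect_error(extend_rules(base, list(domain_widening("45169001", "<< 404684003"))),
               class = "fdg_rules_error") # cannot widen a nonexistent rule
  ext <- extended_rule_set()
  # widened domain is a union containing the old branch
  old_dom <- format_constraint(base$rules$domain[[
    which(base$rules$attribute == "408729009")]])
  new_dom <- format_constraint(ext$rules$domain[[
    which(ext$rules$attribute == "408729009")]])
  expect_true(grepl(old_dom, new_dom, fixed = TRUE))
  expect_true(grepl(" OR ", new_dom, fixed = TRUE))
  # the extended set restricted to the 13 extension attributes equals the
  # shipped fixture file
  ext_ids <- extension_rule_fixture()
  for (a in ext_ids$rules$attribute) {
    i <- which(ext$rules$attribute == a)
    j <- which(ext_ids$rules$attribute == a)
    expect_identical(format_constraint(ext$rules$domain[[i]]),
                     format_constraint(ext_ids$rules$domain[[j]]), info = a)
    expect_identical(format_constraint(ext$rules$range[[i]]),
                     format_constraint(ext_ids$rules$range[[j]]), info = a)
  }
})

test_that("extensions never invalidate expressions valid under the base", {
  g <- small_fixture()
  base <- base_rule_set()
  xs <- make_expressions(g, base, 200,
                         generator_params(seed = 23, extension_fraction = 0,
                                          pce_fraction = 0.8))
  ext <- extended_rule_set()
  for (x in xs) {
    expect_true(is_valid(validate_expression(x, base, g)), info = x)
    expect_true(is_valid(validate_expression(x, ext, g)), info = x)
  }
})

test_that("rules files round-trip and the fixture has 13 valid attribute ids", {
  dir <- withr::local_tempdir()
  base <- base_rule_set()
  path <- file.path(dir, "rules.tsv")
  write_rules(base, path)
  back <- read_rules(path)
  expect_identical(
    lapply(back$rules$domain, format_constraint),
    lapply(base$rules$domain, format_constraint))
  expect_identical(back$rules$attribute, base$rules$attribute)
  ext_ids <- extension_rule_fixture()
  expect_length(unique(ext_ids$rules$attribute), 13)
  expect_true(all(validate_sctid(ext_ids$rules$attribute)))
  expect_setequal(ext_ids$rules$attribute, unname(extension_attribute_ids()))
  writeLines(c("attribute\tdomain\trange\tcardinality\tgroupable",
               "45169001\t<<<x\tnum\toptional-many\tTRUE"),
             file.path(dir, "bad.tsv"))
  err <- tryCatch(read_rules(file.path(dir, "bad.tsv")), error = function(e) e)
  expect_s3_class(err, "fdg_constraint_syntax")
  expect_match(conditionMessage(err), "Row 1")
})

test_that("validation reports tidy into tibbles", {
  g <- small_fixture()
  rep <- validate_expression("404684003 : 103373006 = #8", base_rule_set(), g)
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("code", "path", "message") %in% names(td)))
  gl <- glance(rep)
  expect_identical(gl$verdict, "invalid")
  expect_identical(gl$n_violations, nrow(td))
})
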