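Package: fdgrammar
Title: Extended Compositional Grammar for Postcoordinated Clinical Expressions
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parse, validate and serialize postcoordinated clinical
    expressions written in an extended SNOMED CT compositional grammar that
    admits concrete values (hash-prefixed numbers, quoted strings and ISO
    8601 dates) and tilde-delimited references into external vocabularies
    such as Pango lineages. Provides a concept graph with subsumption,
    external-vocabulary attachment, proximal primitive parent attribution
    and disjunction resolution; a machine-readable concept model (MRCM)
    constraint language and validation engine with permissive rule
    extension; corpus-level classification and extension-usage summaries;
    and deterministic synthetic generators for fixture ontologies,
    expressions and corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringi,
    tibble,
    tidyr
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
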