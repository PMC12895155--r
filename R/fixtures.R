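# Shipped fixture constants and rule sets.
#
# The concept-model extension fixture reconstructs, from the extension
# inventory of the thirteen extension attributes, the attribute rules governing
# negation, scalar values, uncertainty and temporality. Where a domain or
# range is not spelled out, the shipped reconstruction uses: negation
# attributes range << Physical object OR << Clinical finding OR
# << Procedure; scalar attributes range concrete number (Date: date);
# temporality attributes domain << Clinical finding OR << Procedure and
# range << Clinical finding OR << Procedure OR date. The fixture is a plain
# rules file under inst/extdata and can be replaced wholesale.

#' Well-known fixture identifiers
#'
#' `extension_attribute_ids()` returns the 13 distinct attribute concept ids of
#' the shipped grammar-extension set (negation, scalars, uncertainty,
#' temporality). `hierarchy_root_ids()` returns the top-level hierarchy
#' concepts of the fixture ontology (real identifiers; the content beneath
#' them in generated graphs is synthetic). `fixture_strain_parent_id()` and
#' `fixture_strain_attribute_id()` are synthetic stand-ins for the
#' microbiological strain category under Organism and the "Microbiological
#' strain" attribute used in the external-vocabulary scenario.
#'
#' @return Character vector(s) of identifiers.
#' @export
extension_attribute_ids <- function() {
  c(without = "45169001",
    except_for = "5185003",
    finding_context = "408729009",
    procedure_context = "408730004",
    with_size = "103373006",
    date = "410671006",
    resulting_in = "79409006",
    quantity = "246205007",
    score = "246262008",
    after = "255234002",
    before = "288556008",
    during = "371881003",
    duration = "103335007")
}

#' @rdname extension_attribute_ids
#' @export
hierarchy_root_ids <- function() {
  c(clinical_finding = "404684003",
    procedure = "71388002",
    body_structure = "123037004",
    organism = "410607006",
    observable_entity = "363787002",
    physical_object = "260787004",
    qualifier_value = "362981000",
    situation = "243796009",
    attribute = "246061005")
}

#' @rdname extension_attribute_ids
#' @export
fixture_strain_parent_id <- function() "77700017"

#' @rdname extension_attribute_ids
#' @export
fixture_strain_attribute_id <- function() "77700029"

fdg_extdata <- function(file) {
  system.file("extdata", file, package = "fdgrammar", mustWork = TRUE)
}

#' Shipped rule sets
#'
#' `base_rule_set()` loads the compact base concept model (context
#' attributes confined to the Situation hierarchy, core attributes such as
#' Finding site and Method, temporality attributes over Clinical findings).
#' `extension_rule_deltas()` returns the list of permissive deltas — domain and
#' range widenings plus new attribute rules — that produce the extended
#' model; `extended_rule_set()` applies them to the base.
#'
#' @return An `mrcm_rules` object, or for `extension_rule_deltas()` a list of
#'   deltas for [extend_rules()].
#' @export
base_rule_set <- function() {
  read_rules(fdg_extdata("mrcm_base.tsv"), name = "base", version = "1")
}

#' @rdname base_rule_set
#' @export
extension_rule_deltas <- function() {
  h <- hierarchy_root_ids()
  cf <- h[["clinical_finding"]]; pr <- h[["procedure"]]
  po <- h[["physical_object"]]; oe <- h[["observable_entity"]]
  neg_range <- paste0("<< ", po, " OR << ", cf, " OR << ", pr)
  cf_or_pr <- paste0("<< ", cf, " OR << ", pr)
  list(
    # negation: new attributes + context attributes opened to findings and
    # procedures (also carries the uncertainty use of the same attributes)
    rule_addition("45169001", domain = cf_or_pr, range = neg_range),
    rule_addition("5185003", domain = cf_or_pr, range = neg_range),
    domain_widening("408729009", paste0("<< ", cf)),
    domain_widening("408730004", paste0("<< ", pr)),
    # scalars
    rule_addition("103373006", domain = paste0("<< ", po, " OR << ", pr),
                  range = "num"),
    rule_addition("410671006", domain = cf_or_pr, range = "date"),
    rule_addition("79409006", domain = cf_or_pr, range = "num"),
    rule_addition("246205007",
                  domain = paste0("<< ", cf, " OR << ", pr, " OR << ", po),
                  range = "num"),
    rule_addition("246262008", domain = paste0("<< ", cf, " OR << ", oe),
                  range = "num"),
    # temporality: procedures join the domains; Before/During ranges widened
    # to match After; dates allowed as values
    domain_widening("255234002", paste0("<< ", pr)),
    range_widening("255234002", "date"),
    domain_widening("288556008", paste0("<< ", pr)),
    range_widening("288556008", paste0("<< ", pr, " OR date")),
    domain_widening("371881003", paste0("<< ", pr)),
    range_widening("371881003", paste0("<< ", pr, " OR date")),
    rule_addition("103335007", domain = cf_or_pr, range = "num")
  )
}

#' @rdname base_rule_set
#' @export
extended_rule_set <- function() {
  extend_rules(base_rule_set(), extension_rule_deltas(),
               name = "extended", version = "1")
}

#' The grammar-extension rule fixture file
#'
#' Loads the shipped rules file covering exactly the 13 extension
#' attributes with their reconstructed extended domains and ranges.
#'
#' @return An `mrcm_rules` object with 13 distinct attribute ids.
#' @export
extension_rule_fixture <- function() {
  read_rules(fdg_extdata("mrcm_extension.tsv"), name = "extension", version = "1")
}

#' Published per-source extension-usage counts
#'
#' Per-source counts of encoded data elements, elements represented with
#' grammar extensions, encoded instances and extension instances, as
#' reported from a decade-long semantic-representation effort over a
#' hospital data warehouse. Used as the reference input for exact-mode
#' corpus construction and summary arithmetic.
#'
#' @return A tibble with columns `source`, `ids_encoded`,
#'   `extensions_used`, `instances_encoded`, `extension_instances` (one row
#'   per source; no total row).
#' @export
usage_counts <- function() {
  tab <- utils::read.delim(fdg_extdata("usage_counts.tsv"), quote = "",
                           stringsAsFactors = FALSE)
  as_tibble(tab) |>
    mutate(
      ids_encoded = as.numeric(.data$ids_encoded),
      extensions_used = as.numeric(.data$extensions_used),
      instances_encoded = as.numeric(.data$instances_encoded),
      extension_instances = as.numeric(.data$extension_instances)
    )
}

#' A small Pango-like lineage vocabulary (synthetic)
#'
#' Three SARS-CoV-2 lineage codes (B, B.1, B.1.1.7) with their dotted
#' lineage structure as local parent links, attached beneath the fixture
#' strain-category concept. A synthetic stand-in for the real lineage
#' nomenclature, sufficient for the integration scenario.
#'
#' @param attachment_parent Host concept to attach under (default: the
#'   fixture strain category).
#' @return An [external_vocabulary()].
#' @export
pango_fixture_vocabulary <- function(attachment_parent = fixture_strain_parent_id()) {
  external_vocabulary(
    key = "Pango",
    attachment_parent = attachment_parent,
    concepts = tibble(
      id = c("B", "B.1", "B.1.1.7"),
      parents = list(character(0), "B", "B.1")
    ),
    version = "v4.3"
  )
}
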