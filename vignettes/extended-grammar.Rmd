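---
title: "An extended compositional grammar for clinical expressions: models, rules and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An extended compositional grammar for clinical expressions: models, rules and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdgrammar)
```

## The problem this package addresses

Structured clinical data is routinely represented with single codes from a
terminology such as SNOMED CT. Single ("precoordinated") codes lose
information whenever reality does not match a predefined category: there is
no code for *hernia repair without mesh*, for a finding known on a
particular date, for a device of size 8, or for a SARS-CoV-2 infection with
a specific Pango lineage. SNOMED CT's compositional grammar allows
postcoordinated expressions (PCEs) — a focus concept refined by
attribute–value pairs — but its official concept model (the MRCM, which
says which concepts may be refined by which attribute to which values) is
restrictive, and the grammar admits only SNOMED CT concepts.

`fdgrammar` implements an *extended* compositional grammar and concept
model:

* **concrete values** — numbers with a `#` prefix (`#150`), quoted strings,
  and ISO 8601 dates — as attribute values;
* **permissive MRCM extensions** — domain and range widenings plus new
  attribute rules covering negation (`Without`, `Except for`), scalar
  values (`With size`, `Quantity`, `Score`, `Date`, `Duration`,
  `Resulting in`), uncertainty (`Finding context`, `Procedure context`
  opened to findings and procedures), and temporality (`After`, `Before`,
  `During`);
* **external vocabularies** — tilde-delimited tokens such as
  `~Pango~B.1.1.7~` or, version-carrying, `~CTCAE~v5.0~4028512~`, usable
  as focus concept, attribute, value, or alone, with the vocabulary
  attached into the concept hierarchy so that subsumption queries cross the
  boundary.

The package provides the parser and canonical serializer for this grammar,
the concept graph and its algorithms, the constraint language and
validation engine, corpus-level usage statistics, and deterministic
synthetic generators so that everything is testable without any terminology
release.

## The grammar profile

The implemented syntax (whitespace free between tokens):

```
expression   = ws subExpr ws
subExpr      = focus [ws ":" ws refinements]
focus        = cref *(ws "+" ws cref)
refinements  = (attrSet / group) *(ws (attrSet / group))
group        = "{" ws attrSet ws "}"
attrSet      = attr *(ws "," ws attr)
attr         = cref ws "=" ws value
value        = cref / ("(" ws subExpr ws ")") / concrete
concrete     = ("#" number) / quotedString
cref         = (sctId / externalRef) [ws "|" term "|"]
externalRef  = "~" seg "~" [seg "~"] seg "~"
sctId        = 6*18 DIGIT
```

Decisions worth knowing:

* **External-reference segments.** A reference has two interior segments
  (`key`, `id`) or three (`key`, `version`, `id`); nothing else. There is
  no escaping of `~`. When a reference is parsed *standalone*
  (`parse_external_ref()`), segments may contain any printable ASCII except
  `~` and `|`. When embedded in an expression, segments additionally
  exclude the structural characters `= ( ) { } , : +`. Without this
  restriction `~A~B~=~C~D~` would tokenize as a single three-segment
  reference whose version is `B~=`, and inserting or removing whitespace
  could change the parse; with it, tokenization is unambiguous and
  whitespace-invariant. Keys are case-sensitive exactly as registered.
* **Numbers** take an optional sign and decimal point, no exponent —
  clinical scalars in scope. Canonical serialization normalizes the lexeme
  (strips `+`, leading zeros, trailing fractional zeros).
* **Dates travel as quoted strings.** Whether `"2021-03-15"` is a date is
  decided by the concept-model range that applies (a `date` range demands
  an ISO 8601 calendar date, verified including month lengths), not by the
  lexer. This keeps the token grammar unambiguous.
* **Definition-status prefixes** (`===`, `<<<`) are accepted with a
  warning and ignored; they carry no semantics here.
* **Canonical form.** Focus concepts sort native-id-first (numerically;
  valid because identifiers have no leading zeros), then external
  references lexically; refinements sort by attribute id then serialized
  value; groups sort by their serialized form; display terms are dropped.
  Canonical serialization is a fixed point: serializing twice is
  byte-identical, and `parse()` ∘ `serialize()` is the identity on
  canonical strings.

## Identifiers

Native identifiers are 6–18 digit strings without a leading zero whose
final digit is a Verhoeff check digit over the rest. The Verhoeff tables
are implemented directly (dihedral group D5 with the standard position
permutation); partition digits are *not* interpreted — identifiers are
opaque tokens beyond length and checksum, which is how the grammar treats
them. `make_sctid()` mints synthetic identifiers by computing the check
digit, so generated fixtures always validate.

## The concept graph

The hierarchy is a DAG of concepts, each `primitive` or `fully_defined`,
with exactly one root. Three algorithms matter:

* **Subsumption** (`is_subsumed_by()`, `subsumption_closure()`) is
  reflexive reachability over is-a edges — the `<<` descendant-or-self
  relation constraints rely on. The closure is computed by memoized
  ancestor-set union; tests compare it against an independent
  boolean-matrix transitive closure on random DAGs.
* **Proximal primitive parents** (`proximal_primitive_parent()`): the
  nearest primitive ancestors-or-self, the anchor used when attaching an
  external code cluster. The procedure is usually described as a walk up a
  single genealogy; in a DAG a concept can have several defined parents
  whose genealogies reach *different* nearest primitives, so the function
  returns the full set (callers wanting one concept take the numerically
  smallest id — the package-wide tie-break, chosen for determinism).
* **Disjunction resolution** (`resolve_disjunction()`): labels containing
  "or" are mapped to a shared parent only when that parent is close enough
  to be meaningful; otherwise they stay unmapped rather than dissolving
  into something as broad as *Disorder of lung*. Depth is the longest is-a
  chain from the root (so "deeper" always means more specific along some
  path); among the deepest common ancestors, one qualifies when the
  *smaller* of the two depth gaps is at most `max_depth_gap`. The
  threshold is an explicit integer parameter because "sufficiently close"
  has no published numeric value; the default of 2 keeps siblings and
  grandchildren of a shared parent resolvable while rejecting
  root-level-only kinship, which matches the published examples of
  accepted and rejected mappings.

## External vocabularies

A candidate vocabulary passes five gates
(`evaluate_selection_criteria()`): it covers an identified gap, is
concept-based (not a thesaurus), is hierarchical, is versioned, and is a
recognized standard; acceptance is the conjunction. Attachment
(`attach_vocabulary()`) places each external concept beneath a chosen host
concept: local roots become direct children of the attachment parent and
local parent links are preserved beneath it, so `~Pango~B.1.1.7~` is
subsumed both by `~Pango~B.1~` and by the host strain-category concept.
The lineage structure is used hierarchically rather than flattened —
the dotted Pango names encode exactly the parent links a subsumption
query wants, and flattening would discard queryable information at no
cost saved.

Attachment is conservative by construction: it only adds nodes and edges
below the attachment parent, never touching host-to-host subsumption
(tested as a matrix identity). Reference resolution ignores the version
segment — `~CTCAE~v5.0~4028512~` and `~CTCAE~4028512~` resolve to the same
node — because a registry attaches one version of a vocabulary at a time;
the version is preserved in the AST and serialization for provenance.

## The concept model

Rules are *permissive*: a refinement is licensed if some rule for its
attribute has a domain satisfied by **every** focus concept (the
conjunctive reading — a refinement of a multi-focus expression must be
sayable of each focus) and a range satisfied by the value. An attribute
with no rule at all is `ATTRIBUTE_NOT_PERMITTED`. Nested expression values
are validated recursively against their own focus, and satisfy a
subsumption range through their focus concepts. Cardinality is checked per
attribute per scope (each group is its own scope); the default is
`optional-many` since no published rule states cardinalities. Grouped
refinements use the same domains as ungrouped ones. All violations are
collected with AST paths, not just the first.

The constraint language is deliberately small: `<< id`, `< id`, `id`,
`ext:Key`, `num`/`str`/`date`, and `OR` unions. Extension
(`extend_rules()`) is strictly permissive — widenings union the old and
new constraint, additions add rules — which yields the monotonicity
property the whole approach relies on: extending the model never
invalidates an expression that was already valid.

Where the published extension inventory names an attribute without
spelling out its new domain or range, the shipped fixture
(`inst/extdata/mrcm_extension.tsv`, `extension_rule_fixture()`) reconstructs one:
negation attributes range over physical objects, findings and procedures;
scalar attributes take numbers (the `Date` attribute a date); temporality
attributes apply to findings and procedures and accept findings,
procedures or dates. The fixture is a plain rules file, clearly labeled a
reconstruction, and replaceable wholesale; `extend_rules(base_rule_set(),
extension_rule_deltas())` reproduces it exactly (tested).

## Corpus statistics

Records (`source`, `element_id`, `expression`, `instance_count`) classify
into three classes: `precoordinated` (one native focus concept, nothing
else), `extended_pce` (uses an external reference or an extension
attribute anywhere, including nested), else `pce`. A lone external focus
concept counts as extended — it already requires the extended syntax. Two
percent conventions coexist because published usage tables mix them:
`pct_half_up()` (two decimals, halves up; the summary-table convention)
and `pct_floor()` (whole percents, truncated; the prose convention, under
which 28.8% prints as 28). The summary keeps full-precision counts so any
other formatting can be derived. Its `Total` row is defined as the
column-wise sum of the source rows — a conservation invariant the tests
enforce — so a reference table whose printed total disagrees with its own
column sum will reproduce cell-for-cell but not total-for-total.
Unparseable expressions abort a summary by default; lenient mode counts
them in a separate column rather than silently dropping them, which would
bias the percentages.

## The synthetic generators

The generators define the conditions everything is tested under. The
fixture ontology mirrors the standard top-level hierarchies (Clinical
finding, Procedure, Body structure, Organism, Observable entity, Physical
object, Qualifier value, Situation) with the real hierarchy and attribute
identifiers, and fills them with synthetic concepts: by default 30 per
hierarchy, 70% primitive, at most 2 parents — enough structure for
diamonds and multi-parent genealogies without leaving desk scale.
Expression and corpus generation sample a *rule first*, then a focus from
its domain and a value from its range, so every generated expression is
valid by construction (and independently re-validated in tests). Default
fractions are the reference corpus conditions: 47% of unique expressions
postcoordinated, 3.75% of elements using extensions; instance counts are
log-uniform over 1–10^6, reflecting the heavy-tailed collection sizes of
clinical sources.

Two corpus modes exist for two jobs. *Sampled* mode draws extension flags
Bernoulli(p) — the right model for parameter-recovery checks, where the
observed fraction must sit within binomial error of p. *Exact* mode
reproduces a counts table bit-for-bit (element counts, extension quota,
and both instance sums, distributed by integer division with the remainder
on the first records), which makes summary percentages fully determined by
the input counts — this is how the published usage table's arithmetic is
reproduced without any institutional data.

What the generators do *not* emulate: real label text, the breadth and
depth of a real terminology release (hundreds of thousands of concepts,
attribute hierarchies, role groups from logic definitions), annotator
variability, or corpora where expressions arrive malformed. Passing tests
demonstrate the algorithms and arithmetic, not coverage of any real data
warehouse.

Negative cases are generated too (`make_mutations()`): dropping a tilde,
breaking a check digit, removing an `=`, emptying a group — each paired
with the error class the parser must raise.

## Numerical and degenerate-input choices

* Ties anywhere a single concept must be chosen: numerically smallest id.
* Empty corpus: a summary with a single zero `Total` row.
* Zero denominators in percentages: 0, not `NaN`.
* A primitive concept is its own proximal primitive parent; the graph root
  must be primitive for the walk to terminate.
* `resolve_disjunction(x, x)` is `x` at any gap.
* Instance counts are stored as doubles (corpus sums exceed 32-bit
  integers); identifiers stay strings throughout (18-digit ids exceed
  exact double range).

## Package shape

Tabular surfaces (corpora, summaries, usage counts, violation tables) are
tibble-first and pipeable, with `tidy()`/`glance()` methods on validation
reports and summaries and an `autoplot()` for summaries. Structured
objects that are not naturally tabular — expression ASTs, the concept
graph, rule sets — are lightweight S3 objects with printers and explicit
accessors. The `fdg_main()` function (with the thin `inst/cli/fdg`
script) exposes parse/validate/attach-vocab/query/summarize/generate for
shell use; exit code 0 is success, 1 a domain failure, 2 a usage or IO
error, and stdout carries only machine-readable output.

## Problem sizes used by the checks

The shipped verification suite parses and round-trips 10,000 generated
expressions, compares subsumption with a brute-force transitive closure on
50 random DAGs of 20–200 nodes over all ordered pairs, re-validates 1,000
base-valid expressions under the extended model, reconstructs the full
~118,000-record usage corpus in exact mode, and recovers the sampled
extension fraction over 6,600 records across three seeds. These sizes
exercise every code path at comfortably more than fixture scale while
keeping a full run in the low minutes on one core.

## Known limitations

* No description-logic classification or reification: the formal negation
  operator route is out of scope, and the permissive extensions can create
  combinations a DL classifier would reject.
* No expression-constraint-language queries beyond the `<<`/`<`/self
  subset used in rules; no attribute hierarchies (is-a between attributes
  affects `query_numeric()` only via the explicit `subsume_attribute`
  option).
* No real terminology release loading (the flat TSV graph format is
  deliberately desk-scale); no range comparators inside expressions
  (`#>150` is a query, not an expression).
* Strings admit no escaping, so a quoted string cannot contain `"`.
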