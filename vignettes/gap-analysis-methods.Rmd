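---
title: "Methods: estimating distinct accessions and vault coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating distinct accessions and vault coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaultgap)
```

## The problem and the data model

A global safety-duplication facility (a "seed vault") holds backup copies
of genebank accessions. Asking *how complete* that backup is requires
reconciling three databases that count different things: an
institution-level registry reports how many accessions each genebank holds
per genus (WIEWS-style holdings summaries); an accession-level portal
carries passport records for a subset of genebanks (GENESYS-style); and
the vault's deposit log counts samples per depositor and genus. The raw
total of the registry is a poor benchmark because genebanks hold many
duplicates of each other's material — working and base collections within
a country, and national copies of international center material.

`vaultgap` models this with four tables (accessions, holdings summaries,
an institution registry, deposits) merged into a `vaultgap_world` with
enforced referential integrity. Passport columns follow MCPD v2 naming
(`INSTCODE`, `ACCENUMB`, `GENUS`, `SPECIES`, `ORIGCTY` accepted as
aliases). Country codes are ISO 3166-1 alpha-3 internally; alpha-2 input
is translated through a shipped lookup, and anything unmappable becomes
the explicit `UNKNOWN` sentinel. The sentinel is never equated with a host
country: whether a missing origin counts as "indigenous" is exactly the
kind of silent decision that changes an estimator, so it is surfaced as a
policy argument instead (below). Delimiters are explicit rather than
auto-detected — reproducibility over convenience.

Deposit "samples" and registry "accessions" are treated as the same unit
throughout, as is standard when vault totals are compared against registry
totals.

## Study-genus selection

The selection cascade runs in a fixed order, each stage recorded in an
audit object:

1. **Name cleanup**: trim, title-case, merge synonyms. The default synonym
   map is nearly empty — it only folds the botanical label of the wheat×rye
   hybrid into the genus-level name *Triticale*. *Lycopersicon* is kept
   distinct from *Solanum* because the holdings registries list both.
2. **Non-PGRFA filter**: drop genera that are not plant genetic resources
   for food and agriculture (default list: *Arabidopsis*, *Picea*,
   *Pinus*, *Populus*, *Pseudotsuga*, *Rhododendron*).
3. **Holdings threshold**: keep genera with strictly more than
   `min_accessions` (default 1000) accessions summed over all
   institutions. "More than 1000" is read literally: a genus with exactly
   1000 accessions is removed, and the boundary case is tested.
4. **Vault-presence filter** (optional, on by default): keep genera with
   at least one deposited sample. This is a study-design proxy — the
   current vault collection is taken as representative of what genebanks
   actually store as orthodox seed — not a biological rule, which is why
   it is a flag rather than hard-wired.

Seed-storage behaviour classification (`classify_seed_behavior()`) takes
the majority class over a genus's species entries and breaks ties
pessimistically (recalcitrant over intermediate over orthodox): a genus is
only treated as seed-bankable on positive evidence. The shipped
species-behaviour table is a small synthetic demonstration set; real
analyses should derive one from a seed-information database.

## The distinct-accession estimator

`estimate_distinct()` implements the FAO State of the World (SoW2)
counting rule: component (a) counts accessions in non-IARC collections
whose reported origin equals the holding institute's country; component
(b) counts everything at International Agricultural Research Centers. The
rationale is that indigenous national holdings are likely unique, while
foreign-origin national holdings are likely duplicates of material held
in the origin country, and IARC in-trust collections are globally
distinct by mandate.

Design choices the rule itself does not settle:

* **Unknown origins** default to *non-indigenous* (conservative). The
  `unknown_origin_policy` switch also offers `indigenous` (an upper
  bound) and `drop` (exclude such records everywhere, including the IARC
  component) for sensitivity analysis.
* **Data-path choice** is made per (institute, genus): the accession-level
  path is used where that institute reports passport records for that
  genus, the `n_indigenous` summary otherwise. Choosing per institute
  alone would return zero for a genus an institute reports only in its
  summary while having passport data for other genera. When both paths
  exist they are cross-checked and a disagreement warns (the accession
  path wins).
* **Regional and subnational institutes** are treated like national ones
  (component (a)); only institutes typed `international_IARC` enter
  component (b).

Two structural properties follow and are tested: adding a foreign-origin
accession to a national bank never changes the estimate, and adding any
accession to an IARC increases it by exactly one.

## Treaty (ITPGRFA) coverage

`treaty_coverage()` counts accessions in the Multilateral System as two
additive components: Annex 1 matching accessions held by institutes in
Contracting-Party countries *excluding* Article 15 institutes, plus all
accessions at Article 15 institutes. Excluding Article 15 institutes from
the first query is what prevents double counting; the per-institute
attribution is exposed on the result so the no-double-counting invariant
is directly assertable.

Annex 1 matching is species-level where the data allow: a rule matches
when the genus is listed, the epithet is within the rule's included list
(if it has one) and not in its excluded list. A genus-only record (empty
epithet) matches only rules without an inclusion restriction and is never
blocked by an exclusion list — at genus resolution, exclusion of a
specific species cannot be established. Summary-level rows (no passport
data) enter component 1 only when the genus matches an unrestricted rule,
and component 2 with their full count.

The shipped rule set is a curated, editable configuration: genus-level
rules for the benchmark genera inside Annex 1, species restrictions where
the Annex itself has them (maize's excluded wild relatives, cassava and
lentil as single-species crops, the listed forage species of *Medicago*
and *Trifolium*, potato excluding *phureja*), and no rule for the genera
footnoted as outside Annex 1. Those footnoted genera can still show
nonzero Treaty coverage — through Article 15 holdings, which carry no
species filter. The distinct-accession and Treaty estimators are kept
strictly separate; no combined "distinct-and-covered" figure is defined.

## Benchmarks, rounding and profiles

`build_coverage_rows()` assembles the five benchmark counts per genus
(registry total, accession-database total, distinct estimate, Treaty
coverage, vault deposits); `aggregate_groups()` sums them by crop group
with exact column-sum conservation under any grouping.

Percentages use `backup_share()`: `round(100·num/den)` with halves away
from zero, zero denominators rendered `na`, and values above 100 reported
as-is (a vault can hold more samples of a genus than an accession portal
records). Half-away-from-zero is stated explicitly because base R rounds
halves to even, and published benchmark tables follow the commercial
convention; profile averages round the same way to one decimal.

`profile_genus()` ranks an institute's collections per genus (descending
holdings, ties broken by institute code, truncated at `top_n = 10`) and
counts collections with at least one deposit (`n_in_sgsv`) and
collections under deposit-agreement conditions (`n_under_sda`). A nonzero
deposit implies an agreement — depositing requires a signed agreement —
but the converse is not assumed. Collections are profiled individually
even when one country holds several, matching the published table layout.

## The synthetic world generator

`generate_world()` emulates the statistical structure the estimators rely
on, with known ground truth. Founders get an origin country and an
indigenous home institute there; duplicates are then created by four
mechanisms, each with its own probability knob, and each mapping onto a
known bias of the counting rule:

| knob | mechanism | effect on estimate |
|---|---|---|
| `p_within_country_dup` | second domestic copy | overcount (+1 each) |
| `p_iarc_dup` | copy at an IARC | overcount (+1 each) |
| `p_cross_country_dup` | foreign-origin copy abroad | none (invisible) |
| `p_missing_origin` | home record origin reported UNKNOWN | undercount (−1 each) |

Duplicates inherit the founder's origin country — that is the passport
semantics the estimator assumes; a `p_wrong_origin` corruption knob
exists but is off by default. Per-institute backup fractions are drawn
once, recorded in the ground truth, and turned into deposit counts, so
vault-coverage recovery is testable. A `p_depositor` knob (default 0.6)
lets some institutes deposit nothing at all; without it every genus would
trivially pass the vault-presence filter and the cascade's last stage
would be untestable. With all corruption knobs at zero the estimator
recovers the true founder count exactly, per genus — this is the
generator's calibration contract, tested over 100 random worlds.

Randomness is seeded and consumed in a fixed order, and every duplication
decision compares a pre-drawn uniform against its knob (inversion
sampling) with all auxiliary choices drawn unconditionally. Consequences:
byte-identical regeneration from `(config, seed)`, and pathwise-monotone
coupling — at a fixed seed the duplicate set can only grow as a knob
increases, so `bias_experiment()` yields monotone bias curves rather than
merely monotone expectations. The experiment reports mean ± SD over
replicate seeds, not significance tests: the scientific claim of interest
is the *direction* of each bias, which supports reading the
distinct-accession estimate as an upper bound (within-country and IARC
duplication inflate it; only missing origins deflate it).

The generator's defaults (20 countries × 2 institutes, 3 IARCs, catalog
proportional to the benchmark distinct counts at about 5–450 founders per
genus, backup fractions uniform on 0.2–0.8, 70% Contracting Parties) are
chosen as a realistic miniature of the global system. What it does *not*
emulate: real-world genus abundance distributions beyond the configurable
catalog, passport-field errors other than the two modelled corruptions,
and within-institute duplication.

## Fixtures and their provenance

The shipped fixtures encode the published benchmark tables
cell-for-cell, with three documented judgement calls:

* One vault-count cell is printed with a corrupted thousands separator;
  the fixture stores the value implied by exact group-total arithmetic,
  with a note on the row.
* The candidate-genus list prints only the two exclusion lists (26 + 24
  names) and 46 of the 156 retained genera; the remaining 110 retained
  names are synthetic placeholders flagged `provenance = "synthetic"`.
  Counts, not identities, are what the cascade tests use. The source text
  also says twenty-three exclusions are seed-behaviour-related while
  printing twenty-four such names; the fixture stores the printed lists
  without resolving the discrepancy.
* In the institutional-profile table, some rows print more vault-present
  collections than they show nonzero bracket percentages (rounded
  brackets can mask small deposits). Those rows carry
  `bracket_consistent = FALSE`, and bracket-derived checks use only
  self-consistent rows.

## Problem sizes and test design

The property suites run on worlds of roughly 80–200 accessions (three
genera, five countries, two IARCs), 100 random worlds for the
oracle-equality and clean-recovery properties and 20 replicate seeds per
grid point for the bias-direction properties — sizes chosen so the full
suite exercises every code path in about a minute while keeping binomial
noise far smaller than the monotone effects under test. The brute-force
oracles in the test helpers are written in plain base R loops directly
from the definitions and share no code with the implementations.

## Known limitations

The package deliberately performs no passport-similarity deduplication:
the distinct-accession rule is a coarse global estimator, and
collection-level deduplication needs collection-specific analysis. There
is no live connectivity to the source databases, no authoritative
taxonomic backbone (the synonym map is a user-editable configuration),
and the shipped Annex 1 rules are a curated approximation of a legal text
whose species lists have several published interpretations.
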