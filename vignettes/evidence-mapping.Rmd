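---
title: "Mapping food contact chemicals to evidence of human exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping food contact chemicals to evidence of human exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fccmap)
```

## The problem

Thousands of food contact chemicals (FCCs) are known to be used in, or to
migrate from, food contact materials: packaging, tableware, processing
equipment. Two inventories describe that universe — an inventory of
chemicals potentially used in manufacture (FCCdb-style) and a database of
chemicals actually measured in migrates and extracts (FCCmigex-style). What
is far less organized is the evidence that these chemicals end up in
*people*. That evidence is scattered across population biomonitoring
programs (NHANES, CHMS, HBM4EU, KoNEHS, Biomonitoring California),
metabolome/exposome compilations (HMDB, the Blood Exposome Database,
Exposome Explorer), and the primary literature.

`fccmap` implements a two-step procedure for assembling that evidence into
one per-chemical status — `detected`, `monitored_not_detected`, or
`no_evidence` — plus a GHS-based concern tier, and ships a synthetic-universe
generator so every stage is testable without access to the external
databases.

## Step 1: identifier matching against programs and databases

Chemicals are matched across sources by CAS Registry Number, InChIKey, or
SMILES. The design decisions here, each genuinely open, were resolved as
follows:

* **Union semantics with precedence.** A pair matches if *any* identifier
  kind agrees exactly; `matched_on` records the first agreeing kind in the
  order CAS > InChIKey > SMILES. Conflicts (CAS agrees, InChIKeys differ)
  still match but are surfaced in an audit attribute, because silently
  dropping them would hide exactly the curation problems users need to see.
* **Invalid check digits are retained.** The CAS check digit (right-to-left
  weighted digit sum mod 10) is computed for every number, but numbers that
  fail it are kept and matchable: real source lists carry such registry
  numbers, and users must be able to reproduce matches verbatim. The
  registry reports them so either auditing choice (keep or filter) is
  available.
* **SMILES are exact strings.** No canonicalization is attempted; two valid
  encodings of one structure do not match. Structure-level matching is a
  different problem with different failure modes, and the sources this
  pipeline emulates were compared as identifier lists.
* **Mixtures carry CAS only.** Chlorinated paraffins and similar UVCB
  substances have no meaningful structural identifiers; the registry never
  requires them.
* **Names are not automatic match keys.** A case-insensitive name lookup
  helper exists for manual checks, but names are too inconsistent across
  sources to join on.

Biomonitoring programs often measure a metabolite as a proxy for its parent
(mono-ethyl phthalate for di-ethyl phthalate, for instance). Where a source
declares that link, `expand_metabolite_links()` emits an additional row
carrying the parent CAS with the same program and status, so a chemical is
credited regardless of which form was measured. Expansion applies to
biomonitoring sources only — metabolome databases do not systematically
report such links — and no metabolite *prediction* is attempted anywhere.

`resolve_step1()` then assigns the category. Any detection in any program,
or any listing in any metabolome/exposome database, yields `detected`:
listings alone are treated as evidence of presence (all three HMDB
metabolite statuses count, including "expected but not quantified"),
with per-database provenance retained so stricter users can filter.
`monitored_not_detected` is reserved for chemicals monitored somewhere,
detected nowhere, and listed nowhere.

## Step 2: prioritization and the literature evidence map

Chemicals invisible to all step-1 sources are candidates for a systematic
literature evidence map. Searching for thousands of chemicals is
impractical, so candidates are prioritized by their detection frequency in
food contact materials: at least five FCCmigex entries reporting detection
(`threshold = 5`, the default; only `detected = true` entries count —
chemicals targeted but never found in materials carry no weight).

The literature search and human screening are upstream of this package:
inputs are post-screening extraction records, one row per study x chemical
x sample type x analyte form. `classify_step2()` applies the same
any-detection dominance; `n_studies` counts distinct studies. Chemicals for
which searches ran but no study met eligibility are `no_evidence` — the
package does not distinguish "no studies found" from "found but ineligible"
as categories, but preserves `n_studies` so the distinction is recoverable.
Detections supported only by an unspecific shared metabolite count as
evidence but carry an `unspecific_only` flag.

## Hazard tiering

Concern tiers follow the GHS classification logic used in chemicals-policy
screening: `high` for CMR category 1A/1B or STOT RE category 1; `medium`
for the corresponding category-2 (suspected) classifications; then
`other_concern` (classified only for e.g. aquatic toxicity or skin
sensitization), `not_classified` (data exist, no classification), and
`no_hazard_data`. The two inventories (ECHA C&L, Japanese GHS) are pooled
with equal weight — no source precedence is defensible from first
principles — and the pooled maximum wins, with a `sources_disagree` flag
when the inventories would tier differently on their own. Endocrine
disruption, persistence, bioaccumulation and mobility are not tiered;
records for them still count as "data" for the
`not_classified`/`no_hazard_data` distinction.

The biomonitored hazard subset is defined operationally as (monitored in at
least one program) ∩ (at least one FCCmigex detection entry); an explicit
subset can be passed to `tier_table()` to override this.

## The synthetic-universe generator

`generate_universe()` is quota-constructive: memberships are *assigned* to
satisfy every count in a `universe_spec` exactly, rather than sampled from
probabilities, because the package's correctness claims are exact count
recovery (generate → pipeline → recover spec). Free attributes — material
and article labels, reference ids — are drawn from seeded uniform choices;
identical spec and seed give byte-identical bundles.

Synthetic CAS numbers come from a reserved high range (first block
9,000,001 upward; metabolite analytes from 8,000,001 upward) so they cannot
collide with real registry numbers, and all carry valid check digits.
Synthetic InChIKeys are format-valid encodings of the chemical's index. Ten
percent of biomonitoring detections are routed through metabolite rows with
parent links, and every seventh metabolome row matches via InChIKey only,
so both matching paths are always exercised by the default bundles.

`fcchumon_marginals()` pins the spec to the marginal structure reported for
the FCChumon resource (14,402 chemicals; 194 biomonitoring-detected; 3528
metabolome-listed with 184 overlap; 71 monitored-only of which 61 listed;
HMDB 367/1072/772; 175 prioritized with 68 studied and 5 all-negative;
hazard quotas 100/44/77/14 and 5/13/98/59; sample-type quotas; 13/8
all-five-program counts). Two joint constraints are not determined by
marginals alone and are therefore explicit spec fields:
`n_prioritized_no_data_no_evidence` (49 prioritized chemicals lack both
hazard data and any human study) and the curated `group_quota` sizes.
Within the merged other/not-classified hazard band the generator splits
roughly half/half; only the merged total is a reported quantity.

What the generator deliberately does **not** emulate: realistic chemical
structures or names, concentration values, per-program analyte panel sizes,
study-level method marginals, and the bibliographic churn upstream of the
extraction records. Passing tests on synthetic bundles therefore
demonstrate that the *set algebra and classification logic* are correct
under the stated marginal structure — not that real-world identifier
curation (typos, deprecated CAS, salt forms) would be handled without
manual review. The match-report attributes (skips, conflicts, invalid
check digits) exist precisely because real inputs are messier.

## Numerical and degenerate-input choices

* The headline percentage is rounded to the nearest integer (3601/14,402 →
  25%).
* Empty inputs are first-class: zero-row sources, empty subsets and
  header-only files all round-trip; aggregate tables always contain every
  vocabulary level with zero counts.
* Prioritization orders by (count desc, chem_id) for a deterministic
  tie-break; all writers sort before writing so output is a pure function
  of content.
* Strict loading (any invalid row errors) is the pipeline default; lenient
  loading drops and reports, for exploratory use. Load reports always
  conserve counts (read = kept + rejected).

## Problem sizes

The test suite runs the full pipeline once on the 14,402-chemical reference
bundle (a few seconds) and otherwise works on randomized universes of
roughly 10-50 chemicals, where nested-loop brute-force oracles over all
chemical x source-row pairs are feasible and every spec quota is checked
exactly. The acceptance script regenerates the reference bundle and
recomputes all reported quantities from scratch on each run.

## Known limitations

* Matching is identifier-exact; no structure standardization, tautomer
  handling, or CAS-to-structure resolution via external services.
* Group labels are curated inputs; no automated chemical grouping.
* The pipeline maps *presence* evidence only — no concentrations, no
  exposure levels, no dose context.
* Harmonized-versus-notified classification arbitration within an
  inventory is out of scope; records are taken as supplied.
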