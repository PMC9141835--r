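---
title: "Methods: hotspot panel coverage from variant names"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hotspot panel coverage from variant names}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelscope)
```

## The question and the model of it

A hotspot qPCR assay detects a fixed, finite list of variants; an NGS
panel reports whatever falls in its amplicons. Given a table of
NGS-identified mutations, `panelscope` estimates the fraction a
hotspot panel would have detected. The statistical object is simple —
per stratum (gene, tier, diagnosis, or unique sample), a ratio of a
matched count to a total — so nearly all of the method lives in what
"matched" means.

The package's central modeling decision is that **matching is string
comparison of canonical variant names**, not genomic-coordinate
comparison. Cohort exports and assay package inserts both speak in
HGVS-style *names* (`c.1799T>A`, `p.Val600Glu`, `p.V600E`); neither
reliably carries coordinates or transcript identifiers. Name-level
matching is exact, auditable, and requires no external reference data
— at the price of missing equivalences that only sequence-level
normalization could see (an indel written against two different
transcripts, a 3′-shifted spelling). For hotspot lists, where targets
are few, recurrent and conventionally spelled, this trade is the right
one; for arbitrary variant sets it would not be.

## Canonicalization and matching precedence

Every name parses to a structured event and renders to one canonical
key per representation level:

* protein level: the 1-letter short form (`p.Val600Glu` and `p.V600E`
  both render `p.V600E`), so the 3-letter/1-letter distinction
  disappears before comparison;
* cDNA level: normalized substitution/indel text with uppercase
  nucleotides and a mandatory `c.` prefix.

Two descriptors match only if their genes are equal. The protein
level is compared first; when both sides carry a protein form, that
comparison is decisive (a cDNA disagreement cannot overrule a protein
match, nor rescue a protein mismatch). Only when one side lacks a
protein form does comparison fall to the cDNA level; descriptors
sharing no level are *indeterminate* and counted not-detectable, with
the reason kept on the record. The precedence is a package decision —
an export's three name columns give no intrinsic ordering — chosen
because assay inserts define their targets at the protein level.

Two further normalization choices matter in practice:

* **Frameshifts** canonicalize to residue + position + `fs`,
  discarding extension lengths (`p.A379Vfs*12` → `p.A379fs`). Insert
  materials list frameshifts without extensions; keeping them would
  manufacture false negatives.
* **Unparsable names** are not dropped: the record falls back to its
  trimmed raw text as key, flagged non-canonical, and can then match
  only byte-identical text. This keeps provenance counts exact and
  makes parser gaps visible rather than silent.

## Cohort handling

Records are deduplicated by byte equality of all six retained columns
(study, specimen, gene, three name columns) — the least destructive
reading of "duplicate"; two records differing in any spelling are
kept. Unique specimens are counted by the concatenation
`study ‖ sample` with an explicit separator so `("ab","c")` and
`("a","bc")` cannot collide. Tier (AMP/ASCO/CAP 1–4) and diagnosis are
consumed as input annotations, never computed: tier assignment is a
clinical-judgment process outside this package's scope, and records
without annotations form their own `unknown`/`unspecified` strata
rather than being discarded.

In the disease-concordance table, positivity for a (gene, diagnosis)
pair is judged on the index gene's records only, but the
extra-mutation columns look at *all* of the sample's records in any
gene — co-mutations in genes the panel does not carry are precisely
the point of that analysis. The "extra and high-tier missed" column
requires both an extra record and a high-tier record the panel cannot
detect; `high_tiers` defaults to Tier 1 and may be set to
`c("1", "2")`.

## Rounding

Percentages round half-up (62.5% prints "63%") at 0 or 1 decimals,
matching the convention of clinical concordance tables; banker's
rounding would disagree with published renderings on exact-half
cells. Implementation adds 1e-9 before flooring to guard values
stored a hair below the tie point. The validation suite checks the
rendering against every arithmetically consistent percentage in the
reference tables the reconstruction targets come from;
`docs/errata.md` lists the handful of reference cells whose printed
percentage contradicts its own counts (transcription or truncation
slips) and which are therefore excluded.

## The synthetic-cohort generator

Patient-level data behind studies of this kind is generally not
depositable, so validation runs on generated cohorts whose truth is
known. A cohort is a list of strata; each stratum fixes gene,
diagnosis, index-record tier, and either an exact detectable count
(deterministic composition — used for the reference reconstructions,
because published tables are exact compositions, not draws) or a
detectable fraction (used for statistical property checks). Extra
co-mutations are placed on panel-positive cases in off-panel genes
(PIK3CA, MAP2K1, TET2, SF3B1, IDH1, TP53), Tier 1 when they are meant
to trip the "high-tier missed" column and Tier 3 otherwise. Duplicate
rows re-emit existing rows verbatim, to be removed again by
reader-side dedup. Name dialects (`cdna_only`, `long_protein`,
`short_protein`, `all_three`) exercise every parser path; a record
whose drawn dialect is unavailable for its descriptor (a panel entry
without a cDNA form) falls back to the short protein spelling.

Detectable records draw uniformly from the panel's entries for their
gene. Non-detectable records are plausible-looking missense events
(positions 200–1299, consistent cDNA spelling) whose keys are
verified absent from the panel at *both* levels, retrying up to 100
times — so truth labels are correct by construction, not by
assumption. Each stratum derives its own RNG substream from a stable
hash of its label mixed with the global seed: adding a stratum leaves
every other stratum's draws unchanged, and a fixed seed reproduces
the output byte for byte.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: allele fractions and qPCR
chemistry (a real cartridge can miss an on-panel variant at low VAF);
messy real-world spellings beyond the four dialects (whitespace
inside names, legacy nomenclature); transcript ambiguity in indel
names; diagnosis vocabulary drift; and correlated co-mutation
structure beyond one extra per case.

## Reference reconstructions and problem sizes

`reconstruction_specs()` fixes three cohorts whose compositions equal
the printed counts of a published NGS-versus-hotspot-panel
concordance analysis: a mutation-level clinical caseload (159 BRAF,
133 NRAS, 303 KRAS, 96 EGFR records with per-tier and per-diagnosis
detectable counts), eight disease-specific case series (3–158 cases
each, with exact extra-mutation compositions), and a unique-sample
aggregate (11,746 samples across the four genes). These sizes were
chosen to equal the study's own, and run in well under a minute on one
CPU; the statistical property checks use 2,000-record strata over 20
seeds (binomial mode) and 10,000-record cohorts for the
matcher-versus-oracle comparison. Because the reconstructions are
exact compositions, every reported percentage is seed-independent;
the seed only selects which concrete variants the generator draws.

## Triage rules

The decision engine is deliberately dumb: an ordered rule list over a
closed vocabulary, first match wins, terminal default mandatory,
every recommendation citing its rule. The shipped default encodes
widely stated practice points — scant tissue to NGS; ambiguous NGS
calls to orthogonal cartridge confirmation; cartridge-negative
samples reflexed to NGS; cartridge-first with reflex at sites without
on-site molecular labs; cartridge for urgent single-gene questions at
academic centers; NGS otherwise. Published routing flowcharts differ
between institutions on the finer branches (whether urgency alone
should trigger cartridge-first testing, for instance), so the shipped
file is a starting point meant to be edited, and the loader validates
any replacement against the same vocabulary.

## Known limitations

* Name-level matching cannot see sequence-level equivalence across
  transcripts or shifted indel spellings; a panel file and a cohort
  using different conventions for the same event will under-count
  coverage. Authoring the panel file in the cohort's dialect (both
  representations populated) is the practical mitigation.
* The shipped panel fixture is a reconstruction from public technical
  summaries, not a vendor document; analyses for any real decision
  should use a panel file authored from the exact assay version's
  insert.
* No statistical inference is attached to the ratios (no intervals,
  no concordance coefficients); the summaries are descriptive, as in
  the tables they mirror.
* VCF and coordinate-based inputs are out of scope by design; use a
  name-bearing export (cBioPortal dialect or MAF with HGVS columns).
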