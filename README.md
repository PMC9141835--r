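# panelscope

Clinical laboratories increasingly face a triage question: which tumor
specimens should go to a rapid, fully automated hotspot qPCR assay
(such as the Idylla BRAF / EGFR / KRAS / NRAS cartridges, which return
a result in hours from an FFPE section) and which need comprehensive
next-generation sequencing (days to weeks, but not limited to
hotspots)? The empirical basis for that decision is *panel coverage*:
of the mutations NGS actually finds in a given disease setting, what
fraction falls inside the hotspot assay's predefined target list?

`panelscope` computes exactly that, for molecular pathologists and
laboratory directors evaluating a hotspot panel against their own NGS
caseload or against public mutation aggregates (cBioPortal exports,
MAF tables). It also encodes the resulting triage policy as an
auditable, configurable rule engine.

## What it does

1. **Variant-name normalization** (`parse_cdna()`, `parse_protein()`,
   `canonical_key()`). Mutation tables spell the same event many ways:
   `c.1799T>A`, `p.Val600Glu`, `p.V600E`, `p.(V600E)`. Every name is
   parsed into a structured change and rendered as a canonical key —
   the 1-letter short form for protein-level events, normalized
   substitution/indel text for cDNA-level events. Matching is string
   comparison of canonical keys, by design: no transcript lookup, no
   3′-shifting, no reference-sequence validation (see the vignette for
   why, and what that implies).

2. **Panel matching** (`load_panel()`, `panel_contains()`,
   `classify()`). An assay's detectable-variant list is a versioned
   TSV/JSON file (`docs/panel_format.md`). Each cohort record is
   matched gene-first, then protein level (long and short spellings
   collapse to one key), then cDNA; a record sharing no representation
   level with any panel entry is conservatively counted
   not-detectable, with the reason recorded.

3. **Coverage summaries** (`variant_level_summary()`,
   `tier_stratified_summary()`, `sample_level_summary()`,
   `disease_concordance()`). For gene *g*, the variant-level coverage
   is

   &nbsp;&nbsp;&nbsp;&nbsp;cov(g) = #{records of g matching the panel} / #{records of g}

   stratified by AMP/ASCO/CAP tier and by diagnosis. Sample-level
   summaries first collapse records to unique `study ‖ sample` keys so
   a specimen with several detectable mutations counts once. The
   disease-concordance table reports, per (gene, diagnosis) pair:
   cases, panel-positive cases, cases with extra (co-occurring)
   mutations in any gene, and cases whose extra mutations include a
   high-tier variant the panel would miss — the clinically
   uncomfortable group, since a positive cartridge result would hide
   an actionable finding. Percentages are rounded half-up at 0 or 1
   decimals (`format_percent()`), the convention of clinical
   concordance tables.

4. **Synthetic cohorts with truth labels** (`stratum_spec()`,
   `generate_cohort()`). Patient-level source data for studies of this
   kind is rarely depositable, so the package ships a seeded generator
   that emulates cohort structure exactly (per-stratum detectable
   counts or fractions, tier mix, diagnoses, off-panel co-mutations,
   duplicate rows, mixed name dialects) and labels every record with
   its ground truth.

5. **Triage rules** (`load_ruleset()`, `recommend()`). An ordered,
   first-match-wins rule list over a controlled clinical vocabulary
   (tumor type, care setting, tissue adequacy, urgency, prior result),
   with a mandatory terminal default so every context gets an answer
   that cites the rule it came from.

A thin CLI wrapper lives at `inst/cli/panelscope.R`
(`validate-panel`, `summarize`, `simulate`, `triage`).

## Worked example

```r
library(panelscope)
panel <- load_panel(system.file("extdata", "idylla_panel_synthetic.tsv",
                                package = "panelscope"))
panel
#> <panel_definition> idylla_panel_synthetic.tsv: 66 variants across 4 genes (BRAF, EGFR, KRAS, NRAS)

cohort <- read_cbioportal_export("mutations.tsv")   # six-column export
cohort
#> <cohort_table> 5 records, 4 unique samples, genes: BRAF, EGFR, KRAS, PIK3CA
#> provenance:
#>          step rows_in rows_out                            note
#>          read       6        6                   mutations.tsv
#>  drop_unnamed       6        6 0 rows without any variant name
#>         dedup       6        5          1 exact-duplicate rows

cohort <- attach_annotations(cohort, annotations)   # tier + diagnosis
results <- classify(cohort, panel)
variant_level_summary(results)
#> Variant-level coverage by gene:
#>    gene n_records n_detectable pct_detectable pct
#>    BRAF         2            1            50%  50
#>    EGFR         1            1           100% 100
#>    KRAS         1            1           100% 100
#>  PIK3CA         1            0             0%   0

disease_concordance(results,
                    data.frame(gene = "BRAF", diagnosis = "cutaneous melanoma"))
#>   gene          diagnosis n_cases n_positive n_negative n_extra
#> 1 BRAF cutaneous melanoma       2          1          1       1
#>   n_extra_high_tier pct_positive pct_negative pct_extra pct_extra_high_tier
#> 1                 0          50%          50%       50%                  0%
```

Reading the output: of the two BRAF-mutant melanoma cases, one carries
`p.V600E` (on the panel, hence panel-positive) and one `p.G469A` (a
non-V600 hotspot miss); the positive case also carries a PIK3CA
co-mutation — an "extra" the cartridge would not see, though here not
a high-tier one. The duplicate export row was dropped before counting,
and the `c.35G>A` record matched at the cDNA level because its export
row carried no protein name.

## Name grammar

| level   | accepted                                               | canonical key      |
|---------|--------------------------------------------------------|--------------------|
| cDNA    | `c.` optional; substitution `901C>G`, `del`, `ins`, `dup`, `delins`; case-insensitive | `c.901C>G`         |
| protein | `p.` and parentheses optional; 3-letter or 1-letter residues; missense, nonsense, del, ins, dup, delins, frameshift (`fs*12` extensions discarded) | `p.V600E`, `p.A379fs` |

Out of scope: intronic/UTR/genomic (`g.`) notation, splice and allele
syntax, transcript-aware normalization.

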