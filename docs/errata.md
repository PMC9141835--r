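# Reference-table inconsistencies excluded from validation

The reference counts encoded in `reconstruction_specs()` follow the
summary tables of a published NGS-versus-hotspot-qPCR concordance
study. A few of that study's printed percentages disagree with their
own printed numerator/denominator. The validation suite asserts
half-up rounding against every *arithmetically consistent* cell and
excludes the cells below; for each, the package reports the value
recomputed from the printed counts.

| cell | printed | recomputed from counts |
|------|---------|------------------------|
| EGFR lung adenocarcinoma, panel-negative | 9 (7%) | 9/65 = **14%** |
| KRAS lung adenocarcinoma, cases with extra mutations (body text) | 25 (13%) | 25/158 = **16%** (the table's 16% is correct) |
| EGFR mutation-level detectable fraction | 78% (76 of 96) | 76/96 = **79%** |
| BRAF Tier-1 share of mutations | 93% (147 of 159) | 147/159 = **92%** |
| NRAS colorectal cancer, panel-positive | 2 (66%) | 2/3 = **67%** (truncated, not rounded) |
| NRAS colorectal cancer, panel-negative | 1 (33%) | 1/3 = 33% (consistent; listed for context) |
| BRAF melanoma, extra + Tier-1-missed | 2 (8%) | 2/27 = **7%** |
| BRAF melanoma, cases with extra mutations (body text) | "Eight (33%)" | 8/27 = **30%** (the table's 30% is correct) |
| BRAF hairy cell leukemia, cases with extra mutations (body text) | "Three (30%)" | 3/11 = **27%** (the table's 27% is correct) |

Counts themselves are never affected — every reconstruction target
uses the printed counts, and percentages are recomputed from them with
half-up rounding (`format_percent()`).
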