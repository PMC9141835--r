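# Panel-definition file format

A panel definition lists every variant an assay can detect, one row
per concrete change. `load_panel()` accepts a tab-separated file or a
JSON array of objects with the same field names.

## Columns

| column         | required | content                                                      |
|----------------|----------|--------------------------------------------------------------|
| `gene`         | yes      | gene symbol (case-folded to uppercase)                       |
| `cdna`         | no       | coding change, e.g. `c.1799T>A`; empty if not listed         |
| `protein`      | no       | protein change, long or short spelling, e.g. `p.V600E`       |
| `vendor_label` | yes      | the assay's own label for the target, e.g. `V600E`           |
| `class`        | yes      | `snv` or `indel`                                             |
| `cartridge`    | yes      | cartridge/assay name, e.g. `BRAF` or `NRAS/BRAF`             |

Each row needs at least one of `cdna`/`protein`. Rows are parsed and
validated at load time; a malformed name fails the load with its row
number. Two rows with the same gene and canonical protein key are
duplicates (error in strict mode, collapsed with a warning otherwise).

## Counting convention

Vendor sheets often group several concrete changes under one label
(e.g. a single "exon 19 deletion" entry covering many distinct
deletions, or "G719" covering G719A/C/S). In this format each concrete
change gets its own row, so row counts are *expanded* counts and will
not match a vendor's grouped-target count. `vendor_label` preserves
the grouping for reporting.

## The shipped fixture

`inst/extdata/idylla_panel_synthetic.tsv` is a best-effort,
protein-level-unique reconstruction of the four-cartridge
(BRAF, EGFR, KRAS, NRAS/BRAF) hotspot target set assembled from
publicly available technical summaries — hence the `synthetic` tag in
its name. It is intended for validation and demonstration; for any
clinical question, author a panel file from the package insert of the
exact assay version in use and pass its path to the analysis
functions, which are assay-agnostic.

## Worked example

```
gene	cdna	protein	vendor_label	class	cartridge
BRAF	c.1799T>A	p.V600E	V600E	snv	BRAF
EGFR		p.A767_V769dup	Exon 20 insertion	indel	EGFR
```

The first entry matches cohort records at the protein level
(`p.V600E`, `p.Val600Glu`) or the cDNA level (`c.1799T>A`); the
second, having no cDNA form, matches at the protein level only — a
cDNA-only cohort record can never match it and is conservatively
counted not-detectable with reason `"no shared representation"`.
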