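# Cohort ingestion, deduplication, filtering, annotation joins

cbio_header <- paste("study name", "specimen ID", "gene target",
                     "codon mutation name", "long protein mutation name",
                     "short protein mutation name", sep = "\t")

test_that("exact duplicate rows are removed and logged in provenance", {
  path <- write_tsv_lines(c(
    cbio_header,
    "s1\tA\tBRAF\tc.1799T>A\tp.Val600Glu\tp.V600E",
    "s1\tA\tBRAF\tc.1799T>A\tp.Val600Glu\tp.V600E",
    "s1\tB\tKRAS\tc.35G>A\tp.Gly12Asp\tp.G12D",
    "s2\tA\tNRAS\t\t\tp.Q61R",
    "s2\tC\tEGFR\tc.2573T>G\tp.Leu858Arg\tp.L858R"))
  tab <- read_cbioportal_export(path)
  expect_equal(nrow(tab$records), 4)
  dd <- tab$provenance[tab$provenance$step == "dedup", ]
  expect_equal(c(dd$rows_in, dd$rows_out), c(5L, 4L))
})

test_that("rows with only one name column populate only that representation", {
  path <- write_tsv_lines(c(
    cbio_header,
    "s1\tA\tKRAS\t\t\tp.A379V",
    "s1\tB\tKRAS\tc.901C>G\t\t"))
  rec <- read_cbioportal_export(path)$records
  expect_equal(rec$protein_key[1], "p.A379V")
  expect_true(is.na(rec$cdna_key[1]))
  expect_equal(rec$cdna_key[2], "c.901C>G")
  expect_true(is.na(rec$protein_key[2]))
})

test_that("rows without any variant name are dropped with a logged count", {
  path <- write_tsv_lines(c(
    cbio_header,
    "s1\tA\tBRAF\t\t\t",
    "s1\tB\tBRAF\t\t\tp.V600E"))
  tab <- read_cbioportal_export(path)
  expect_equal(nrow(tab$records), 1)
  du <- tab$provenance[tab$provenance$step == "drop_unnamed", ]
  expect_equal(c(du$rows_in, du$rows_out), c(2L, 1L))
})

test_that("missing mandatory columns raise a format error listing headers", {
  path <- write_tsv_lines(c(
    paste("study name", "gene target", "short protein mutation name",
          sep = "\t"),
    "s1\tBRAF\tp.V600E"))
  expect_error(read_cbioportal_export(path), "sample_id",
               class = "panelscope_format_error")
})

test_that("header synonyms are accepted", {
  path <- write_tsv_lines(c(
    "Study ID\tSample ID\tGene\tHGVSc\tHGVSp\tHGVSp_Short",
    "s1\tA\tBRAF\tc.1799T>A\tp.Val600Glu\tp.V600E"))
  rec <- read_cbioportal_export(path)$records
  expect_equal(rec$sample_id, "A")
  expect_equal(rec$protein_key, "p.V600E")
})

test_that("unparsable names fall back to raw-text keys flagged non-canonical", {
  path <- write_tsv_lines(c(
    cbio_header,
    "s1\tA\tBRAF\t\t\tp.V600E",
    "s1\tB\tBRAF\t\t\tp.?weird?"))
  rec <- read_cbioportal_export(path)$records
  expect_true(rec$canonical[1])
  expect_false(rec$canonical[2])
  expect_equal(rec$protein_key[2], "p.?weird?")
})

test_that("MAF subsets are mapped onto cohort records", {
  path <- write_tsv_lines(c(
    "#version 2.4",
    "Hugo_Symbol\tTumor_Sample_Barcode\tHGVSp_Short",
    "KRAS\tT1\tp.G12C",
    "TP53\tT2\tp.R175H"))
  tab <- read_maf_subset(path)
  expect_equal(nrow(tab$records), 2)
  expect_equal(tab$records$study_id,
               rep(sub("\\.tsv$", "", basename(path)), 2))
  expect_equal(tab$records$protein_key[1], "p.G12C")
  expect_true(is.na(tab$records$cdna_key[1]))

  no_hgvs <- write_tsv_lines(c("Hugo_Symbol\tTumor_Sample_Barcode",
                               "KRAS\tT1"))
  expect_error(read_maf_subset(no_hgvs), class = "panelscope_format_error")
})

test_that("gene filtering is case-insensitive and conserves provenance", {
  tab <- toy_cohort(data.frame(
    study_id = "s", sample_id = c("A", "B", "C", "D"),
    gene = c("KRAS", "KRAS", "KRAS", "TP53"),
    protein_short = c("p.G12C", "p.G12D", "p.G13D", "p.R175H")))
  f1 <- filter_genes(tab, "KRAS")
  f2 <- filter_genes(tab, "kras")
  expect_equal(nrow(f1$records), 3)
  expect_identical(f1$records, f2$records)
  expect_equal(nrow(filter_genes(tab, character(0))$records), 0)
  # conservation across the chain
  prov <- f1$provenance
  expect_true(all(diff(prov$rows_out) <= 0))
  expect_equal(prov$rows_in[-1], prov$rows_out[-nrow(prov)])
})

test_that("annotations attach by record and conflicts are fatal", {
  tab <- toy_cohort(data.frame(
    study_id = "s", sample_id = c("A", "A", "B"),
    gene = c("BRAF", "PIK3CA", "BRAF"),
    protein_short = c("p.V600E", "p.H1047R", "p.G469A")))
  ann <- data.frame(study_id = "s", sample_id = c("A", "A", "B"),
                    gene = c("BRAF", "PIK3CA", "BRAF"),
                    protein = c("p.Val600Glu", "p.H1047R", "p.G469A"),
                    tier = c("1", "3", "1"),
                    diagnosis = "cutaneous melanoma",
                    stringsAsFactors = FALSE)
  out <- attach_annotations(tab, ann)
  expect_equal(out$records$tier, c("1", "3", "1"))
  expect_equal(unique(out$records$diagnosis), "cutaneous melanoma")

  # an annotation key matching no record: warning, table unchanged
  ann_miss <- data.frame(study_id = "s", sample_id = "Z", gene = "BRAF",
                         protein = "p.V600E", tier = "1",
                         stringsAsFactors = FALSE)
  expect_warning(out2 <- attach_annotations(tab, ann_miss), "no cohort record")
  expect_equal(out2$records$tier, rep("unknown", 3))

  # conflicting duplicate annotation rows
  ann_conflict <- rbind(ann, transform(ann[1, ], tier = "3"))
  expect_error(attach_annotations(tab, ann_conflict),
               class = "panelscope_annotation_conflict")
})

test_that("the canonical cohort TSV round-trips records losslessly", {
  tab <- toy_cohort(data.frame(
    study_id = "s", sample_id = c("A", "B"),
    gene = c("BRAF", "KRAS"),
    cdna = c("c.1799T>A", ""),
    protein_long = c("p.Val600Glu", ""),
    protein_short = c("p.V600E", "p.G12D"),
    tier = c("1", "unknown"), diagnosis = c("cutaneous melanoma", "")))
  path <- tempfile(fileext = ".tsv")
  write_cohort(tab, path)
  back <- read_cohort(path)
  expect_identical(back$records, tab$records)
})

test_that("dedup and gene filtering are order-independent", {
  rows <- data.frame(
    study_id = "s", sample_id = c("A", "B", "C", "A", "D"),
    gene = c("KRAS", "KRAS", "TP53", "KRAS", "NRAS"),
    protein_short = c("p.G12C", "p.G12D", "p.R175H", "p.G12C", "p.Q61R"),
    stringsAsFactors = FALSE)
  canon <- function(df) {
    df <- df[order(df$sample_id, df$gene, df$protein_short), ]
    rownames(df) <- NULL
    df
  }
  run <- function(perm) {
    tab <- toy_cohort(rows[perm, ])
    deduped <- panelscope:::dedup_records(tab$records)
    tab2 <- panelscope:::new_cohort_table(deduped, tab$provenance)
    canon(filter_genes(tab2, c("KRAS", "NRAS"))$records)
  }
  set.seed(1)
  base <- run(seq_len(nrow(rows)))
  for (k in 1:5) expect_identical(run(sample(nrow(rows))), base)
})

test_that("record descriptors are reconstructable from the table", {
  tab <- toy_cohort(data.frame(
    study_id = "s", sample_id = "A", gene = "BRAF",
    cdna = "c.1799T>A", protein_long = "p.Val600Glu",
    protein_short = ""))
  d <- record_descriptor(tab, 1)
  expect_s3_class(d, "variant_descriptor")
  expect_equal(to_short_form(d$protein), "p.V600E")
  expect_equal(format(d$cdna), "c.1799T>A")
})
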