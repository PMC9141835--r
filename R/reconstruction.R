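# Reference cohort reconstructions. Clinical concordance cohorts of
# this kind cannot be deposited (patient consent), so the validation
# suite and the reproduction script rebuild cohorts whose composition
# equals the printed summary counts of such a study — per-gene and
# per-tier detectable mutations from a one-year clinical NGS caseload,
# a large multi-study mutation aggregate at the unique-sample level,
# and disease-specific case series with co-occurring extra mutations —
# and push them through the full parse / match / dedup / summarize
# pipeline. The generator compositions below are therefore fixed study
# conditions, not tuning knobs.

# split one (gene, diagnosis) block into tier-homogeneous strata
.vs <- function(gene, diagnosis, t1_n = 0, t1_det = 0, t3_n = 0, t3_det = 0) {
  out <- list()
  if (t1_n > 0) {
    out <- c(out, list(stratum_spec(
      gene, diagnosis, t1_n, detectable_count = t1_det,
      tier = "1", nondetectable_tier = "1",
      label = paste(gene, diagnosis, "t1", sep = "/"))))
  }
  if (t3_n > 0) {
    out <- c(out, list(stratum_spec(
      gene, diagnosis, t3_n, detectable_count = t3_det,
      tier = "3", nondetectable_tier = "3",
      label = paste(gene, diagnosis, "t3", sep = "/"))))
  }
  out
}

#' Reference cohort compositions for the validation pipeline
#'
#' Returns the three fixed synthetic-cohort specifications the package
#' uses to validate its pipeline end to end, plus the (gene,
#' diagnosis) pairs of the disease-concordance table:
#'
#' * `variant_cohort` — a clinical-caseload-style cohort at the
#'   mutation level: 159 BRAF, 133 NRAS, 303 KRAS and 96 EGFR records
#'   with fixed per-tier and per-diagnosis detectable counts
#'   (e.g. 123 of 159 BRAF records panel-detectable, 147 of them
#'   Tier 1 with 123 detectable).
#' * `disease_cohort` — eight disease-specific case series (melanoma,
#'   hairy cell leukemia, colorectal cancer, lung adenocarcinoma)
#'   with exact panel-positive, extra-mutation and high-tier-missed
#'   counts per series.
#' * `sample_cohort` — a multi-study-aggregate-style cohort at the
#'   unique-sample level: 2483 BRAF / 2960 EGFR / 4667 KRAS / 1636
#'   NRAS mutant samples with fixed panel-positive counts.
#'
#' @return A named list: `variant_cohort`, `disease_cohort`,
#'   `sample_cohort` (lists of [stratum_spec()]), and `disease_pairs`
#'   (data.frame of gene, diagnosis).
#' @export
reconstruction_specs <- function() {
  mel <- "cutaneous melanoma"; crc <- "colorectal cancer"
  lung <- "lung adenocarcinoma"; hcl <- "hairy cell leukemia"

  variant_cohort <- c(
    # BRAF: 159 records, 123 detectable; Tier 1: 147 with 123 detectable
    .vs("BRAF", mel,    t1_n = 25, t1_det = 21, t3_n = 2, t3_det = 0),
    .vs("BRAF", crc,    t1_n = 53, t1_det = 51),
    .vs("BRAF", hcl,    t1_n = 11, t1_det = 10),
    .vs("BRAF", lung,   t1_n = 29, t1_det = 25, t3_n = 1, t3_det = 0),
    .vs("BRAF", "other", t1_n = 29, t1_det = 16, t3_n = 9, t3_det = 0),
    # NRAS: 133 records, 118 detectable; Tier 1: 127 with 116 detectable
    .vs("NRAS", mel,    t1_n = 28, t1_det = 26),
    .vs("NRAS", crc,    t1_n = 3,  t1_det = 2),
    .vs("NRAS", "AML",  t1_n = 50, t1_det = 46),
    .vs("NRAS", lung,   t1_n = 5,  t1_det = 4),
    .vs("NRAS", "other", t1_n = 41, t1_det = 38, t3_n = 6, t3_det = 2),
    # KRAS: 303 records, 283 detectable; Tier 1: 294 with 276 detectable
    .vs("KRAS", lung,   t1_n = 158, t1_det = 147),
    .vs("KRAS", crc,    t1_n = 65,  t1_det = 62),
    .vs("KRAS", "other", t1_n = 71, t1_det = 67, t3_n = 9, t3_det = 7),
    # EGFR: 96 records, 76 detectable; Tier 1: 73 with 71 detectable
    .vs("EGFR", lung,   t1_n = 55, t1_det = 53, t3_n = 10, t3_det = 3),
    .vs("EGFR", mel,    t1_n = 5,  t1_det = 5),
    .vs("EGFR", "other", t1_n = 13, t1_det = 13, t3_n = 13, t3_det = 2))

  dc <- function(gene, diagnosis, n, det, extra, extra_high) {
    stratum_spec(gene, diagnosis, n, detectable_count = det,
                 tier = "1", nondetectable_tier = "3",
                 n_extra = extra, n_extra_high_tier = extra_high,
                 label = paste("dc", gene, diagnosis, sep = "/"))
  }
  disease_cohort <- list(
    dc("BRAF", mel,  27, 21, 8, 2),
    dc("NRAS", mel,  28, 26, 12, 5),
    dc("BRAF", hcl,  11, 10, 3, 3),
    dc("BRAF", crc,  53, 51, 17, 9),
    dc("KRAS", crc,  65, 62, 24, 17),
    dc("NRAS", crc,  3, 2, 2, 2),
    dc("EGFR", lung, 65, 56, 21, 7),
    dc("KRAS", lung, 158, 147, 25, 12))
  disease_pairs <- data.frame(
    gene = c("BRAF", "NRAS", "BRAF", "BRAF", "KRAS", "NRAS", "EGFR", "KRAS"),
    diagnosis = c(mel, mel, hcl, crc, crc, crc, lung, lung),
    stringsAsFactors = FALSE)

  agg <- function(gene, n, det) {
    stratum_spec(gene, "", n, detectable_count = det,
                 tier = "unknown", study_id = "aggregate",
                 label = paste("agg", gene, sep = "/"))
  }
  sample_cohort <- list(
    agg("BRAF", 2483, 1346),
    agg("EGFR", 2960, 1122),
    agg("KRAS", 4667, 4232),
    agg("NRAS", 1636, 1423))

  list(variant_cohort = variant_cohort,
       disease_cohort = disease_cohort,
       sample_cohort = sample_cohort,
       disease_pairs = disease_pairs)
}

#' Run the full reconstruction pipeline
#'
#' Generates the three [reconstruction_specs()] cohorts, writes each
#' to disk in the cBioPortal export dialect, re-ingests it through
#' the readers (exercising dedup and annotation joins), classifies
#' against the panel, and computes every summary surface.
#'
#' @param panel_path Panel-definition file; defaults to the shipped
#'   fixture.
#' @param seed Integer seed for the generator substreams.
#' @param workdir Directory for the intermediate files.
#' @return A list with `variant` (gene + tier summaries), `disease`
#'   (`disease_concordance` rows), and `samples` (per-gene
#'   sample-level totals).
#' @export
run_reconstruction <- function(panel_path = NULL, seed = 1L,
                               workdir = tempfile("reconstruction")) {
  panel_path <- panel_path %||% system.file(
    "extdata", "idylla_panel_synthetic.tsv", package = "panelscope")
  panel <- load_panel(panel_path)
  specs <- reconstruction_specs()
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)

  ingest <- function(spec, name) {
    dir <- file.path(workdir, name)
    paths <- run_simulate(spec, panel_path, dir, seed = seed)
    table <- read_cbioportal_export(paths$cohort)
    ann <- utils::read.delim(paths$annotations, colClasses = "character",
                             check.names = FALSE,
                             na.strings = character(0))
    attach_annotations(table, ann)
  }

  tab_v <- ingest(specs$variant_cohort, "variant")
  res_v <- classify(tab_v, panel)
  variant <- list(genes = variant_level_summary(res_v, decimals = 1),
                  tiers = tier_stratified_summary(res_v))

  tab_d <- ingest(specs$disease_cohort, "disease")
  res_d <- classify(tab_d, panel)
  disease <- disease_concordance(res_d, specs$disease_pairs,
                                 high_tiers = "1")

  tab_s <- ingest(specs$sample_cohort, "samples")
  res_s <- classify(filter_genes(tab_s, panel$genes), panel)
  samples <- sample_level_summary(res_s)

  list(variant = variant, disease = disease, samples = samples)
}
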