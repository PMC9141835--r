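# Report rendering and the high-level entry points the command-line
# wrapper (inst/cli/panelscope.R) delegates to. Every percentage cell
# in the TSV outputs sits next to its raw numerator/denominator so the
# tables stay auditable; markdown renderings mirror the "n (pct%)"
# cell style of clinical concordance tables.

md_table <- function(df) {
  if (!nrow(df)) return(paste0("| ", paste(names(df), collapse = " | "), " |\n",
                               "|", paste(rep("---", ncol(df)), collapse = "|"),
                               "|\n"))
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1)
  paste0(
    "| ", paste(names(df), collapse = " | "), " |\n",
    "|", paste(rep("---", ncol(df)), collapse = "|"), "|\n",
    paste(apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                             " |")),
          collapse = "\n"), "\n")
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Run the full coverage analysis and write a report bundle
#'
#' The end-to-end pipeline behind the `summarize` command: load the
#' panel, read the cohort (cBioPortal-export or MAF dialect), attach
#' optional annotations, filter to the panel's genes, classify every
#' record, and write the four summary surfaces as TSV, a combined
#' markdown report, and a JSON bundle with provenance.
#'
#' @param panel_path Panel-definition file.
#' @param cohort_path Cohort mutation table.
#' @param out_dir Output directory (created if missing).
#' @param dialect `"cbioportal"` or `"maf"`.
#' @param annotation_path Optional annotation TSV (see
#'   [attach_annotations()]).
#' @param genes Gene set to analyze; defaults to the panel's genes.
#' @param pairs Optional data.frame (`gene`, `diagnosis`) for the
#'   disease-concordance table; defaults to every (gene, diagnosis)
#'   combination observed.
#' @param decimals Percent precision (0 or 1).
#' @param high_tiers Tiers treated as high for the extra-mutation
#'   columns.
#' @return Invisibly, a list with the summaries and the paths written.
#' @export
run_summarize <- function(panel_path, cohort_path, out_dir,
                          dialect = c("cbioportal", "maf"),
                          annotation_path = NULL, genes = NULL, pairs = NULL,
                          decimals = 0, high_tiers = "1") {
  dialect <- match.arg(dialect)
  panel <- load_panel(panel_path)
  table <- if (dialect == "cbioportal") read_cbioportal_export(cohort_path)
           else read_maf_subset(cohort_path)
  if (!is.null(annotation_path)) {
    ann <- utils::read.delim(annotation_path, header = TRUE, sep = "\t",
                             colClasses = "character", check.names = FALSE,
                             na.strings = character(0),
                             stringsAsFactors = FALSE)
    table <- attach_annotations(table, ann)
  }
  genes <- toupper(genes %||% panel$genes)
  # the whole table is classified so the extra-mutation columns can see
  # co-mutations in genes outside the panel; the per-gene surfaces are
  # then restricted to the genes of interest
  results <- classify(table, panel)
  results_target <- results[results$gene %in% genes, , drop = FALSE]

  gene_sum <- variant_level_summary(results_target, decimals)
  tier_sum <- tier_stratified_summary(results_target, decimals)
  sample_sum <- sample_level_summary(results_target, decimals, high_tiers)
  if (is.null(pairs)) {
    df <- as.data.frame(results)
    obs <- unique(df[df$gene %in% genes & nzchar(df$diagnosis),
                     c("gene", "diagnosis")])
    pairs <- obs[order(obs$gene, obs$diagnosis), , drop = FALSE]
  }
  disease <- if (nrow(pairs)) disease_concordance(results, pairs, decimals,
                                                  high_tiers)
             else NULL

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    gene = write_tsv(gene_sum$genes, file.path(out_dir, "gene_summary.tsv")),
    tier = write_tsv(tier_sum, file.path(out_dir, "tier_summary.tsv")),
    samples = write_tsv(sample_sum$samples,
                        file.path(out_dir, "sample_summary.tsv")),
    sample_gene = write_tsv(sample_sum$by_gene,
                            file.path(out_dir, "sample_gene_summary.tsv")))
  if (!is.null(disease)) {
    paths <- c(paths, disease = write_tsv(
      disease, file.path(out_dir, "disease_concordance.tsv")))
  }

  t1 <- sample_sum$by_gene
  md1 <- if (nrow(t1)) {
    data.frame(Gene = t1$gene,
               `Panel Positive` = sprintf("%d (%s)", t1$n_positive,
                                          t1$pct_positive),
               `Panel Negative` = sprintf("%d (%s)", t1$n_negative,
                                          t1$pct_negative),
               check.names = FALSE, stringsAsFactors = FALSE)
  } else t1
  md <- c("# Hotspot panel coverage report\n",
          "## Variant-level coverage by gene\n", md_table(gene_sum$genes),
          "## Tier-stratified coverage\n", md_table(tier_sum),
          "## Unique-sample coverage by gene\n", md_table(md1))
  if (!is.null(disease)) {
    md2 <- data.frame(
      `Gene Mutation and Diagnosis` = paste(disease$gene, disease$diagnosis),
      `Case Numbers` = disease$n_cases,
      `Panel Positive` = sprintf("%d (%s)", disease$n_positive,
                                 disease$pct_positive),
      `Panel Negative` = sprintf("%d (%s)", disease$n_negative,
                                 disease$pct_negative),
      `Cases with Extra Mutations` = sprintf("%d (%s)", disease$n_extra,
                                             disease$pct_extra),
      `Cases with Extra and High-Tier Mutations Not Detected` =
        sprintf("%d (%s)", disease$n_extra_high_tier,
                disease$pct_extra_high_tier),
      check.names = FALSE, stringsAsFactors = FALSE)
    md <- c(md, "## Disease-specific concordance\n", md_table(md2))
  }
  md_path <- file.path(out_dir, "report.md")
  writeLines(paste(md, collapse = "\n"), md_path, useBytes = TRUE)

  bundle <- list(
    provenance = table$provenance,
    gene_summary = gene_sum$genes,
    tier_summary = tier_sum,
    by_diagnosis = gene_sum$by_diagnosis,
    sample_by_gene = sample_sum$by_gene,
    disease_concordance = disease)
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(bundle, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")

  invisible(list(results = results, gene_summary = gene_sum,
                 tier_summary = tier_sum, sample_summary = sample_sum,
                 disease_concordance = disease,
                 paths = c(paths, markdown = md_path, json = json_path)))
}

#' Generate a synthetic cohort bundle on disk
#'
#' The pipeline behind the `simulate` command: run
#' [generate_cohort()] and write the cohort (cBioPortal export
#' dialect), the truth labels and the annotation side table, so the
#' generated files can be fed straight back into [run_summarize()].
#'
#' @param spec List of [stratum_spec()]s, or a YAML/JSON file whose
#'   top-level `strata` array mirrors the `stratum_spec` fields.
#' @param panel_path Panel-definition file.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(spec, panel_path, out_dir, seed = 1L) {
  panel <- load_panel(panel_path)
  if (is.character(spec)) spec <- read_cohort_spec(spec)
  sim <- generate_cohort(spec, panel, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort_path <- file.path(out_dir, "cohort.tsv")
  write_cbioportal_export(sim$cohort, cohort_path)
  truth_path <- file.path(out_dir, "truth.tsv")
  write_truth(sim$truth, truth_path)
  ann_path <- file.path(out_dir, "annotations.tsv")
  write_tsv(sim$annotations, ann_path)
  invisible(list(cohort = cohort_path, truth = truth_path,
                 annotations = ann_path))
}

#' Read a cohort-simulation spec file
#'
#' @param path YAML or JSON file with a top-level `strata` array; each
#'   element carries the [stratum_spec()] fields.
#' @return A list of `stratum_spec` objects.
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) {
    ps_error(sprintf("simulation spec not found: %s", path),
             "panelscope_io_error")
  }
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  strata <- doc$strata %||% doc
  lapply(strata, function(s) {
    if (!is.null(s$dialect_mix)) s$dialect_mix <- unlist(s$dialect_mix)
    do.call(stratum_spec, s)
  })
}

#' Triage one clinical context
#'
#' The pipeline behind the `triage` command: build the context,
#' evaluate it against a ruleset (the shipped default unless another
#' file is given) and return the recommendation.
#'
#' @inheritParams decision_context
#' @param ruleset_path Optional ruleset file; defaults to the shipped
#'   ruleset.
#' @return A `triage_recommendation`.
#' @export
run_triage <- function(tumor_type, genes_in_question = character(0),
                       care_setting, tissue_adequacy = "adequate",
                       urgency = "routine", prior_result = "none",
                       ruleset_path = NULL) {
  path <- ruleset_path %||% system.file("extdata", "default_ruleset.yaml",
                                        package = "panelscope")
  rules <- load_ruleset(path)
  recommend(decision_context(tumor_type, genes_in_question, care_setting,
                             tissue_adequacy, urgency, prior_result),
            rules)
}
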