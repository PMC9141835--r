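# Cohort ingestion: cBioPortal-style mutation exports and MAF subsets,
# with column-synonym resolution, exact-row deduplication, gene
# filtering and tier/diagnosis annotation joins. A cohort_table keeps a
# provenance log (rows in/out per step) so filter-chain conservation
# can be audited.

SAMPLE_KEY_SEP <- "‖"  # explicit separator avoids ("ab","c") vs ("a","bc")

TIER_LEVELS <- c("1", "2", "3", "4", "unknown")

# header synonyms, case/space/underscore-insensitive (extensible)
COLUMN_SYNONYMS <- list(
  study_id      = c("study name", "study id", "cancer study", "study"),
  sample_id     = c("specimen id", "sample id", "specimen",
                    "tumor sample barcode"),
  gene          = c("gene target", "gene", "hugo symbol", "gene symbol"),
  cdna          = c("codon mutation name", "cdna change", "hgvsc"),
  protein_long  = c("long protein mutation name", "hgvsp"),
  protein_short = c("short protein mutation name", "protein change",
                    "hgvsp short")
)

.norm_header <- function(x) gsub("[ _.]+", " ", tolower(trimws(x)))

.resolve_columns <- function(headers) {
  normed <- .norm_header(headers)
  out <- lapply(COLUMN_SYNONYMS, function(syn) {
    hit <- which(normed %in% syn)
    if (length(hit)) headers[hit[1]] else NA_character_
  })
  out
}

new_cohort_table <- function(records, provenance) {
  structure(list(records = records, provenance = provenance),
            class = "cohort_table")
}

empty_records <- function(n = 0L) {
  data.frame(study_id = character(n), sample_id = character(n),
             gene = character(n), cdna = character(n),
             protein_long = character(n), protein_short = character(n),
             tier = character(n), diagnosis = character(n),
             stringsAsFactors = FALSE)
}

provenance_row <- function(step, rows_in, rows_out, note = "") {
  data.frame(step = step, rows_in = as.integer(rows_in),
             rows_out = as.integer(rows_out), note = note,
             stringsAsFactors = FALSE)
}

# derived columns: sample key, canonical match keys, canonical flag.
# unparsable name text falls back to its trimmed raw form, flagged
# non-canonical (it can then only match byte-identical text).
finalize_records <- function(df) {
  n <- nrow(df)
  df$gene <- toupper(trimws(df$gene))
  for (col in c("cdna", "protein_long", "protein_short", "tier", "diagnosis")) {
    if (is.null(df[[col]])) df[[col]] <- character(n)
    df[[col]][is.na(df[[col]])] <- ""
    df[[col]] <- trimws(df[[col]])
  }
  df$tier[!(df$tier %in% TIER_LEVELS)] <- "unknown"
  df$sample_key <- paste(df$study_id, df$sample_id, sep = SAMPLE_KEY_SEP)

  parse_key <- function(text, parser) {
    if (!nzchar(text)) return(c(NA_character_, "TRUE"))
    parsed <- tryCatch(parser(text), panelscope_error = function(e) NULL)
    if (is.null(parsed)) c(text, "FALSE")
    else c(if (inherits(parsed, "protein_change")) to_short_form(parsed)
           else format(parsed), "TRUE")
  }
  pk <- character(n); ck <- character(n); canon <- logical(n)
  for (i in seq_len(n)) {
    prot_text <- if (nzchar(df$protein_short[i])) df$protein_short[i]
                 else df$protein_long[i]
    p <- parse_key(prot_text, parse_protein)
    cc <- parse_key(df$cdna[i], parse_cdna)
    pk[i] <- p[1]; ck[i] <- cc[1]
    canon[i] <- as.logical(p[2]) && as.logical(cc[2])
  }
  df$protein_key <- pk
  df$cdna_key <- ck
  df$canonical <- canon
  rownames(df) <- NULL
  df
}

RETAINED_COLS <- c("study_id", "sample_id", "gene", "cdna",
                   "protein_long", "protein_short")

dedup_records <- function(df) {
  key <- do.call(paste, c(df[RETAINED_COLS], sep = "\r"))
  df[!duplicated(key), , drop = FALSE]
}

#' Read a cBioPortal-style mutation export
#'
#' Reads a tab-delimited mutation table whose header contains
#' recognizable synonyms of the six retained columns: study name,
#' specimen ID, gene target, codon mutation name (cDNA), long protein
#' mutation name, and short protein mutation name. Header matching is
#' case- and punctuation-insensitive (see the synonym table in
#' `COLUMN_SYNONYMS`). Rows whose three variant-name columns are all
#' empty are dropped; exact-duplicate rows (byte equality of all six
#' retained columns after whitespace trimming) are removed. Both steps
#' are logged in the returned table's provenance.
#'
#' @param path Path to the tab-delimited export.
#' @return A `cohort_table`: `records` data.frame (one row per retained
#'   mutation record, with canonical match keys) and `provenance`
#'   (rows in/out per filter step).
#' @export
read_cbioportal_export <- function(path) {
  if (!file.exists(path)) {
    ps_error(sprintf("cohort file not found: %s", path), "panelscope_io_error")
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0),
                           stringsAsFactors = FALSE)
  cols <- .resolve_columns(names(raw))
  mandatory <- c("study_id", "sample_id", "gene")
  missing <- mandatory[vapply(cols[mandatory], is.na, logical(1))]
  if (length(missing)) {
    ps_error(sprintf(
      "cohort file %s lacks mandatory column(s) %s; headers found: %s",
      path, paste(missing, collapse = ", "),
      paste(names(raw), collapse = ", ")), "panelscope_format_error")
  }
  df <- empty_records(nrow(raw))
  for (field in names(COLUMN_SYNONYMS)) {
    src <- cols[[field]]
    if (!is.na(src)) df[[field]] <- trimws(raw[[src]])
  }
  prov <- provenance_row("read", nrow(df), nrow(df), basename(path))

  named <- nzchar(df$cdna) | nzchar(df$protein_long) | nzchar(df$protein_short)
  df2 <- df[named, , drop = FALSE]
  prov <- rbind(prov, provenance_row("drop_unnamed", nrow(df), nrow(df2),
                                     sprintf("%d rows without any variant name",
                                             nrow(df) - nrow(df2))))
  df3 <- dedup_records(df2)
  prov <- rbind(prov, provenance_row("dedup", nrow(df2), nrow(df3),
                                     sprintf("%d exact-duplicate rows",
                                             nrow(df2) - nrow(df3))))
  new_cohort_table(finalize_records(df3), prov)
}

#' Read a MAF-subset mutation table
#'
#' Reads the subset of the Mutation Annotation Format needed for
#' name-level matching: `Hugo_Symbol`, `Tumor_Sample_Barcode`, and at
#' least one of `HGVSc`, `HGVSp`, `HGVSp_Short`. Lines starting with
#' `#` are skipped per the MAF convention. The study identifier
#' defaults to the file stem (there is no study column in MAF).
#'
#' @param path Path to the MAF file.
#' @return A `cohort_table` (same shape as [read_cbioportal_export()]).
#' @export
read_maf_subset <- function(path) {
  if (!file.exists(path)) {
    ps_error(sprintf("MAF file not found: %s", path), "panelscope_io_error")
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0),
                           stringsAsFactors = FALSE)
  if (!all(c("Hugo_Symbol", "Tumor_Sample_Barcode") %in% names(raw))) {
    ps_error(sprintf("MAF file %s lacks Hugo_Symbol/Tumor_Sample_Barcode", path),
             "panelscope_format_error")
  }
  hgvs_cols <- intersect(c("HGVSc", "HGVSp", "HGVSp_Short"), names(raw))
  if (!length(hgvs_cols)) {
    ps_error(sprintf("MAF file %s carries none of HGVSc/HGVSp/HGVSp_Short", path),
             "panelscope_format_error")
  }
  df <- empty_records(nrow(raw))
  df$study_id <- rep(sub("\\.[^.]*$", "", basename(path)), nrow(raw))
  df$sample_id <- trimws(raw$Tumor_Sample_Barcode)
  df$gene <- trimws(raw$Hugo_Symbol)
  if ("HGVSc" %in% hgvs_cols) df$cdna <- trimws(raw$HGVSc)
  if ("HGVSp" %in% hgvs_cols) df$protein_long <- trimws(raw$HGVSp)
  if ("HGVSp_Short" %in% hgvs_cols) df$protein_short <- trimws(raw$HGVSp_Short)
  prov <- provenance_row("read", nrow(df), nrow(df), basename(path))

  named <- nzchar(df$cdna) | nzchar(df$protein_long) | nzchar(df$protein_short)
  df2 <- df[named, , drop = FALSE]
  prov <- rbind(prov, provenance_row("drop_unnamed", nrow(df), nrow(df2), ""))
  df3 <- dedup_records(df2)
  prov <- rbind(prov, provenance_row("dedup", nrow(df2), nrow(df3), ""))
  new_cohort_table(finalize_records(df3), prov)
}

#' Restrict a cohort to a gene set
#'
#' @param table A `cohort_table`.
#' @param genes Character vector of gene symbols (case-insensitive).
#' @return The filtered `cohort_table`, provenance updated.
#' @export
filter_genes <- function(table, genes) {
  stopifnot(inherits(table, "cohort_table"))
  genes <- toupper(trimws(genes))
  keep <- table$records$gene %in% genes
  out <- table$records[keep, , drop = FALSE]
  rownames(out) <- NULL
  new_cohort_table(out, rbind(
    table$provenance,
    provenance_row("filter_genes", nrow(table$records), nrow(out),
                   paste(genes, collapse = ","))))
}

#' Attach tier and diagnosis annotations
#'
#' Joins a side table of per-record or per-sample annotations onto a
#' cohort. The annotation table must carry `study_id` and `sample_id`;
#' it may additionally carry `gene` and/or `protein` (canonical short
#' form or any parseable spelling) to scope an annotation to specific
#' records of a sample. Value columns are `tier` (1/2/3/4/unknown)
#' and/or `diagnosis`. Records without a matching annotation keep
#' `tier = "unknown"` and an empty diagnosis.
#'
#' Two annotation rows resolving to the same key with conflicting
#' values raise an annotation-conflict error; annotation keys that
#' match no record produce a warning.
#'
#' @param table A `cohort_table`.
#' @param annotations A data.frame as described above.
#' @return The annotated `cohort_table`.
#' @export
attach_annotations <- function(table, annotations) {
  stopifnot(inherits(table, "cohort_table"), is.data.frame(annotations))
  if (!all(c("study_id", "sample_id") %in% names(annotations))) {
    ps_error("annotation table needs study_id and sample_id columns",
             "panelscope_format_error")
  }
  has_gene <- "gene" %in% names(annotations)
  has_prot <- "protein" %in% names(annotations)
  value_cols <- intersect(c("tier", "diagnosis"), names(annotations))
  if (!length(value_cols)) {
    ps_error("annotation table carries neither tier nor diagnosis",
             "panelscope_format_error")
  }

  ann_key <- paste(trimws(annotations$study_id), trimws(annotations$sample_id),
                   sep = SAMPLE_KEY_SEP)
  if (has_gene) ann_key <- paste(ann_key, toupper(trimws(annotations$gene)),
                                 sep = SAMPLE_KEY_SEP)
  if (has_prot) {
    prot_norm <- vapply(as.character(annotations$protein), function(p) {
      p <- trimws(p)
      if (!nzchar(p)) return("")
      tryCatch(to_short_form(parse_protein(p)),
               panelscope_error = function(e) p)
    }, character(1), USE.NAMES = FALSE)
    ann_key <- paste(ann_key, prot_norm, sep = SAMPLE_KEY_SEP)
  }

  for (col in value_cols) {
    vals <- trimws(as.character(annotations[[col]]))
    agg <- tapply(vals, ann_key, function(v) unique(v[nzchar(v)]))
    conflict <- names(agg)[vapply(agg, length, integer(1)) > 1L]
    if (length(conflict)) {
      ps_error(sprintf("conflicting %s annotations for key(s): %s", col,
                       paste(conflict, collapse = "; ")),
               "panelscope_annotation_conflict")
    }
  }

  rec <- table$records
  rec_key <- rec$sample_key
  if (has_gene) rec_key <- paste(rec_key, rec$gene, sep = SAMPLE_KEY_SEP)
  if (has_prot) rec_key <- paste(rec_key, ifelse(is.na(rec$protein_key), "",
                                                 rec$protein_key),
                                 sep = SAMPLE_KEY_SEP)

  idx <- match(rec_key, ann_key)
  n_hit_records <- sum(!is.na(idx))
  unmatched_ann <- setdiff(ann_key, rec_key)
  if (length(unmatched_ann)) {
    warning(sprintf("%d annotation key(s) match no cohort record",
                    length(unmatched_ann)))
  }
  if ("tier" %in% value_cols) {
    tier <- trimws(as.character(annotations$tier))[idx]
    ok <- !is.na(tier) & tier %in% TIER_LEVELS
    rec$tier[ok] <- tier[ok]
  }
  if ("diagnosis" %in% value_cols) {
    diag <- trimws(as.character(annotations$diagnosis))[idx]
    ok <- !is.na(diag) & nzchar(diag)
    rec$diagnosis[ok] <- diag[ok]
  }
  new_cohort_table(rec, rbind(
    table$provenance,
    provenance_row("attach_annotations", nrow(rec), nrow(rec),
                   sprintf("%d of %d records annotated", n_hit_records,
                           nrow(rec)))))
}

#' Write / read the canonical cohort TSV
#'
#' The canonical writer emits the six retained columns plus tier and
#' diagnosis in fixed order, UTF-8, Unix newlines; [read_cohort()]
#' re-ingests it losslessly (record round-trip identity).
#'
#' @param table A `cohort_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  out <- table$records[, c(RETAINED_COLS, "tier", "diagnosis"), drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0), stringsAsFactors = FALSE)
  need <- c(RETAINED_COLS, "tier", "diagnosis")
  if (!all(need %in% names(raw))) {
    ps_error(sprintf("not a canonical cohort TSV: %s", path),
             "panelscope_format_error")
  }
  df <- empty_records(nrow(raw))
  for (col in need) df[[col]] <- raw[[col]]
  new_cohort_table(finalize_records(df),
                   provenance_row("read", nrow(df), nrow(df), basename(path)))
}

#' Write a cohort in the cBioPortal export dialect
#'
#' Emits the six-column header spelling used by cBioPortal mutation
#' exports so generated cohorts can be re-ingested through
#' [read_cbioportal_export()].
#'
#' @inheritParams write_cohort
#' @export
write_cbioportal_export <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  out <- table$records[, RETAINED_COLS, drop = FALSE]
  names(out) <- c("study name", "specimen ID", "gene target",
                  "codon mutation name", "long protein mutation name",
                  "short protein mutation name")
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Reconstruct the variant descriptor of one cohort record
#'
#' @param table A `cohort_table`.
#' @param i Row index.
#' @return A `variant_descriptor` (raw-text fallbacks preserved for
#'   non-canonical names).
#' @export
record_descriptor <- function(table, i) {
  stopifnot(inherits(table, "cohort_table"))
  r <- table$records[i, ]
  prot_text <- if (nzchar(r$protein_short)) r$protein_short else r$protein_long
  protein <- if (nzchar(prot_text)) {
    tryCatch(parse_protein(prot_text),
             panelscope_error = function(e) raw_protein_change(prot_text))
  }
  cdna <- if (nzchar(r$cdna)) {
    tryCatch(parse_cdna(r$cdna),
             panelscope_error = function(e) raw_cdna_change(r$cdna))
  }
  variant_descriptor(r$gene, cdna = cdna, protein = protein)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x$records), " records, ",
      length(unique(x$records$sample_key)), " unique samples, genes: ",
      paste(sort(unique(x$records$gene)), collapse = ", "), "\n", sep = "")
  cat("provenance:\n")
  print(x$provenance, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cohort_table <- function(object, ...) {
  rec <- object$records
  list(n_records = nrow(rec),
       n_samples = length(unique(rec$sample_key)),
       genes = sort(unique(rec$gene)),
       tiers = table(factor(rec$tier, levels = TIER_LEVELS)),
       n_noncanonical = sum(!rec$canonical))
}
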