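# Coverage analysis core: classify every cohort record as
# panel-detectable or not, then aggregate into the summary surfaces a
# concordance study reports — per-gene variant-level, tier-stratified,
# diagnosis distribution, unique-sample-level, and per-(gene,
# diagnosis) disease concordance with extra-mutation columns.

#' Round-half-up percentage formatting
#'
#' Formats `numerator/denominator` as a percentage string rounded
#' half-up (so 62.5 renders "63%", not banker's "62%") at 0 or 1
#' decimal places, matching how clinical concordance tables print
#' their cells.
#'
#' @param numerator,denominator Non-negative counts; vectors recycle.
#' @param decimals 0 or 1.
#' @return Character vector like `"77.4%"` / `"91%"`.
#' @examples
#' format_percent(123, 159, decimals = 1)  # "77.4%"
#' format_percent(4232, 4667)              # "91%"
#' @export
format_percent <- function(numerator, denominator, decimals = 0) {
  stopifnot(decimals %in% c(0, 1))
  if (any(denominator < 1)) {
    ps_error("undefined percentage: denominator is zero",
             "panelscope_percent_error")
  }
  v <- percent_value(numerator, denominator, decimals)
  sprintf(paste0("%.", decimals, "f%%"), v)
}

#' @rdname format_percent
#' @return `percent_value()`: the numeric percentage after half-up
#'   rounding (e.g. `77.4`).
#' @export
percent_value <- function(numerator, denominator, decimals = 0) {
  stopifnot(decimals %in% c(0, 1))
  if (any(denominator < 1)) {
    ps_error("undefined percentage: denominator is zero",
             "panelscope_percent_error")
  }
  x <- numerator / denominator * 100
  # epsilon guards exact .5 values stored just below the tie point
  floor(x * 10^decimals + 0.5 + 1e-9) / 10^decimals
}

#' Classify cohort records against a panel
#'
#' Produces one match verdict per cohort record: matched (with the
#' panel entry and the representation level that matched) or not
#' matched with a reason (`"gene not on panel"`, `"key not in panel"`,
#' `"no shared representation"`). Matching follows [panel_contains()]:
#' protein-level canonical keys first, cDNA second. The result is
#' deterministic and one row per input record.
#'
#' @param table A `cohort_table`.
#' @param panel A `panel_definition`.
#' @return An object of class `match_results`: the record data.frame
#'   augmented with `matched`, `match_level`, `panel_label`, `reason`.
#' @export
classify <- function(table, panel) {
  stopifnot(inherits(table, "cohort_table"),
            inherits(panel, "panel_definition"))
  rec <- table$records
  n <- nrow(rec)
  matched <- logical(n)
  level <- rep(NA_character_, n)
  label <- rep(NA_character_, n)
  reason <- rep("gene not on panel", n)
  pt <- panel_key_table(panel)

  for (g in intersect(unique(rec$gene), panel$genes)) {
    ri <- which(rec$gene == g)
    pi <- which(pt$gene == g)
    pk <- pt$protein_key[pi]; ck <- pt$cdna_key[pi]
    r_p <- rec$protein_key[ri]; r_c <- rec$cdna_key[ri]

    sent <- paste0("\r#", seq_along(pi))  # mask slots out of a match pass
    pos_p <- match(r_p, ifelse(is.na(pk), sent, pk))
    # cDNA pass: entries already decided at protein level are skipped
    # for records that carry a protein key
    ck_if_prot <- ifelse(is.na(pk) & !is.na(ck), ck, sent)
    ck_if_none <- ifelse(!is.na(ck), ck, sent)
    pos_c <- ifelse(is.na(r_p), match(r_c, ck_if_none), match(r_c, ck_if_prot))

    hit_p <- !is.na(pos_p)
    hit_c <- !hit_p & !is.na(pos_c)
    matched[ri] <- hit_p | hit_c
    level[ri][hit_p] <- "protein"
    level[ri][hit_c] <- "cdna"
    panel_idx <- rep(NA_integer_, length(ri))
    panel_idx[hit_p] <- pi[pos_p[hit_p]]
    panel_idx[hit_c] <- pi[pos_c[hit_c]]
    lab <- rep(NA_character_, length(ri))
    ok <- !is.na(panel_idx)
    if (any(ok)) {
      lab[ok] <- vapply(panel$variants[pt$idx[panel_idx[ok]]],
                        function(v) v$vendor_label, character(1))
    }
    label[ri] <- lab
    # comparable at some level but no key agreed vs no shared level
    comparable <- (!is.na(r_p) & any(!is.na(pk))) |
                  (!is.na(r_c) & any(!is.na(ck)))
    reason[ri] <- ifelse(matched[ri], "",
                         ifelse(comparable, "key not in panel",
                                "no shared representation"))
  }
  out <- rec
  out$matched <- matched
  out$match_level <- level
  out$panel_label <- label
  out$reason <- reason
  structure(out, class = c("match_results", "data.frame"),
            panel_genes = panel$genes)
}

#' @export
print.match_results <- function(x, ...) {
  cat("<match_results> ", nrow(x), " records, ", sum(x$matched),
      " panel-detectable (", if (nrow(x)) format_percent(sum(x$matched),
                                                         nrow(x)) else "-",
      ")\n", sep = "")
  invisible(as.data.frame(x))
}

.pool_diagnosis <- function(d) ifelse(nzchar(d), d, "unspecified")

#' Per-gene variant-level coverage summary
#'
#' For each gene with at least one record: how many records (observed
#' mutations) there are, how many a hotspot panel would detect, and
#' the detectable percentage, plus the tier and primary-site diagnosis
#' breakdowns of those records. Genes with zero records are omitted
#' rather than reported as 0/0.
#'
#' @param results A `match_results` object from [classify()].
#' @param decimals Percent precision (0 or 1) for the rendered cells.
#' @return An object of class `gene_coverage_summary`: `genes` (gene,
#'   n_records, n_detectable, pct_detectable, pct), `by_tier` (gene,
#'   tier, n, n_detectable), `by_diagnosis` (gene, diagnosis,
#'   n_records). Stratum counts sum to the gene totals.
#' @export
variant_level_summary <- function(results, decimals = 0) {
  stopifnot(inherits(results, "match_results"))
  df <- as.data.frame(results)
  if (nrow(df) == 0L) {
    empty <- data.frame(gene = character(0), n_records = integer(0),
                        n_detectable = integer(0),
                        pct_detectable = character(0), pct = numeric(0),
                        stringsAsFactors = FALSE)
    return(structure(list(
      genes = empty,
      by_tier = data.frame(gene = character(0), tier = character(0),
                           n = integer(0), n_detectable = integer(0),
                           stringsAsFactors = FALSE),
      by_diagnosis = data.frame(gene = character(0), diagnosis = character(0),
                                n_records = integer(0),
                                stringsAsFactors = FALSE)),
      class = "gene_coverage_summary"))
  }
  genes <- unique(df$gene[order(df$gene)])
  rows <- lapply(genes, function(g) {
    sub <- df[df$gene == g, ]
    data.frame(gene = g, n_records = nrow(sub),
               n_detectable = sum(sub$matched),
               pct_detectable = format_percent(sum(sub$matched), nrow(sub),
                                               decimals),
               pct = percent_value(sum(sub$matched), nrow(sub), decimals),
               stringsAsFactors = FALSE)
  })
  tier <- factor(df$tier, levels = TIER_LEVELS)
  by_tier <- aggregate(cbind(n = rep(1L, nrow(df)), n_detectable = df$matched),
                       by = list(gene = df$gene, tier = tier), FUN = sum)
  by_tier <- by_tier[order(by_tier$gene, by_tier$tier), ]
  by_tier$tier <- as.character(by_tier$tier)
  rownames(by_tier) <- NULL
  diag <- .pool_diagnosis(df$diagnosis)
  by_diag <- aggregate(list(n_records = rep(1L, nrow(df))),
                       by = list(gene = df$gene, diagnosis = diag), FUN = sum)
  by_diag <- by_diag[order(by_diag$gene, -by_diag$n_records), ]
  rownames(by_diag) <- NULL
  structure(list(genes = do.call(rbind, rows), by_tier = by_tier,
                 by_diagnosis = by_diag),
            class = "gene_coverage_summary")
}

#' @export
print.gene_coverage_summary <- function(x, ...) {
  cat("Variant-level coverage by gene:\n")
  print(x$genes, row.names = FALSE)
  invisible(x)
}

#' Tier-stratified coverage summary
#'
#' Partitions each gene's records by clinical-significance tier
#' (AMP/ASCO/CAP 1-4, consumed as input annotations; records without
#' one form their own `"unknown"` stratum) and reports the detectable
#' count and percentage per stratum.
#'
#' @inheritParams variant_level_summary
#' @return A data.frame: gene, tier, n, n_detectable, pct_detectable,
#'   pct. Strata partition the gene's records.
#' @export
tier_stratified_summary <- function(results, decimals = 0) {
  stopifnot(inherits(results, "match_results"))
  vt <- variant_level_summary(results, decimals)$by_tier
  vt <- vt[vt$n > 0, , drop = FALSE]
  vt$pct_detectable <- format_percent(vt$n_detectable, vt$n, decimals)
  vt$pct <- percent_value(vt$n_detectable, vt$n, decimals)
  rownames(vt) <- NULL
  vt
}

#' Unique-sample-level coverage summary
#'
#' Collapses records to unique study-sample keys so a specimen with
#' several panel-detectable mutations counts once. Per sample it
#' reports whether any record matched, the matched/unmatched record
#' counts, whether the sample carries extra mutations (two or more
#' records), and whether any high-tier record is not panel-detectable.
#' Per gene it reports Idylla-positive/-negative sample totals in the
#' style of a concordance table: a sample enters a gene's row if it
#' has at least one record of that gene, and is positive if any such
#' record matched.
#'
#' @inheritParams variant_level_summary
#' @param high_tiers Tiers counted as clinically significant for the
#'   `has_extra_high_tier_undetected` flag (default Tier 1).
#' @return An object of class `sample_coverage_summary`: `samples`
#'   (one row per unique sample_key) and `by_gene` (gene, n_samples,
#'   n_positive, n_negative, pct_positive, pct_negative).
#' @export
sample_level_summary <- function(results, decimals = 0, high_tiers = "1") {
  stopifnot(inherits(results, "match_results"))
  df <- as.data.frame(results)
  if (nrow(df) == 0L) {
    samples <- data.frame(sample_key = character(0),
                          any_detectable = logical(0),
                          n_panel_matches = integer(0),
                          n_nonpanel = integer(0),
                          has_extra_mutation = logical(0),
                          has_extra_high_tier_undetected = logical(0),
                          stringsAsFactors = FALSE)
    by_gene <- data.frame(gene = character(0), n_samples = integer(0),
                          n_positive = integer(0), n_negative = integer(0),
                          pct_positive = character(0),
                          pct_negative = character(0),
                          stringsAsFactors = FALSE)
    return(structure(list(samples = samples, by_gene = by_gene),
                     class = "sample_coverage_summary"))
  }
  sk <- df$sample_key
  keys <- unique(sk)
  n_match <- vapply(split(df$matched, sk), sum, numeric(1))[keys]
  n_tot <- vapply(split(df$matched, sk), length, integer(1))[keys]
  high_undet <- vapply(split(df$tier %in% high_tiers & !df$matched, sk),
                       any, logical(1))[keys]
  samples <- data.frame(
    sample_key = keys,
    any_detectable = n_match >= 1,
    n_panel_matches = as.integer(n_match),
    n_nonpanel = as.integer(n_tot - n_match),
    has_extra_mutation = n_tot >= 2,
    has_extra_high_tier_undetected = unname(high_undet),
    row.names = NULL, stringsAsFactors = FALSE)

  genes <- sort(unique(df$gene))
  by_gene <- do.call(rbind, lapply(genes, function(g) {
    sub <- df[df$gene == g, ]
    pos_keys <- unique(sub$sample_key[sub$matched])
    all_keys <- unique(sub$sample_key)
    n_pos <- length(pos_keys); n_all <- length(all_keys)
    data.frame(gene = g, n_samples = n_all, n_positive = n_pos,
               n_negative = n_all - n_pos,
               pct_positive = format_percent(n_pos, n_all, decimals),
               pct_negative = format_percent(n_all - n_pos, n_all, decimals),
               stringsAsFactors = FALSE)
  }))
  rownames(by_gene) <- NULL
  structure(list(samples = samples, by_gene = by_gene),
            class = "sample_coverage_summary")
}

#' @export
print.sample_coverage_summary <- function(x, ...) {
  cat("Sample-level coverage (", nrow(x$samples), " unique samples):\n",
      sep = "")
  print(x$by_gene, row.names = FALSE)
  invisible(x)
}

#' Disease-specific concordance with extra-mutation analysis
#'
#' For each requested (gene, diagnosis) pair: the number of cases
#' (unique study-sample keys with at least one record of the index
#' gene carrying that diagnosis), how many are panel-positive (any
#' index-gene record matches), panel-negative, how many carry extra
#' mutations, and how many carry an extra mutation together with a
#' high-tier record that the panel would miss. Positivity is judged on
#' the index gene only, but the extra-mutation columns consider all of
#' the sample's records regardless of gene, so co-mutations in genes
#' outside the panel are counted.
#'
#' @inheritParams sample_level_summary
#' @param pairs A data.frame with columns `gene`, `diagnosis`.
#' @return A data.frame of class `disease_concordance`, one row per
#'   pair: counts, and percentage strings (blank when `n_cases` is 0).
#' @export
disease_concordance <- function(results, pairs, decimals = 0,
                                high_tiers = "1") {
  stopifnot(inherits(results, "match_results"), is.data.frame(pairs),
            all(c("gene", "diagnosis") %in% names(pairs)))
  df <- as.data.frame(results)
  sample_n_records <- table(df$sample_key)
  high_undet_by_sample <- vapply(
    split(df$tier %in% high_tiers & !df$matched, df$sample_key),
    any, logical(1))

  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- toupper(trimws(pairs$gene[i])); d <- trimws(pairs$diagnosis[i])
    idx <- df$gene == g & df$diagnosis == d
    cases <- unique(df$sample_key[idx])
    n_cases <- length(cases)
    if (n_cases == 0L) {
      return(data.frame(gene = g, diagnosis = d, n_cases = 0L,
                        n_positive = 0L, n_negative = 0L, n_extra = 0L,
                        n_extra_high_tier = 0L, pct_positive = "",
                        pct_negative = "", pct_extra = "",
                        pct_extra_high_tier = "", stringsAsFactors = FALSE))
    }
    gene_match <- vapply(split(df$matched[df$gene == g],
                               df$sample_key[df$gene == g]), any, logical(1))
    pos <- sum(gene_match[cases])
    has_extra <- as.integer(sample_n_records[cases]) >= 2L
    extra_high <- has_extra & high_undet_by_sample[cases]
    data.frame(
      gene = g, diagnosis = d, n_cases = n_cases,
      n_positive = pos, n_negative = n_cases - pos,
      n_extra = sum(has_extra), n_extra_high_tier = sum(extra_high),
      pct_positive = format_percent(pos, n_cases, decimals),
      pct_negative = format_percent(n_cases - pos, n_cases, decimals),
      pct_extra = format_percent(sum(has_extra), n_cases, decimals),
      pct_extra_high_tier = format_percent(sum(extra_high), n_cases, decimals),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("disease_concordance", "data.frame")
  out
}
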