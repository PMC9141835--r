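# Seeded synthetic-cohort generator with truth labels. Real study
# cohorts of this kind are rarely depositable (patient consent), so
# every pipeline stage is exercised against generated cohorts whose
# composition is known exactly: per-stratum detectable counts or
# fractions, a tier mix, diagnosis labels, co-occurring extra
# mutations in off-panel genes, duplicate rows, and a mix of variant
# name dialects.

DIALECTS <- c("cdna_only", "long_protein", "short_protein", "all_three")

# off-panel genes used for co-occurring "extra" mutations
EXTRA_GENES <- c("PIK3CA", "MAP2K1", "TET2", "SF3B1", "IDH1", "TP53")

#' Define one synthetic cohort stratum
#'
#' A stratum is a homogeneous block of cases sharing a gene, a
#' diagnosis label and an index-record tier. Its composition is given
#' either exactly (`detectable_count`, `n_extra`,
#' `n_extra_high_tier`) for deterministic reconstructions, or as
#' probabilities (`detectable_fraction`, `p_extra`,
#' `p_extra_high_tier`) for statistical property checks. Exactly one
#' of `detectable_count`/`detectable_fraction` must be given.
#'
#' @param gene Index gene symbol; must have panel entries when the
#'   stratum is generated.
#' @param diagnosis Diagnosis label attached to every case.
#' @param n_cases Number of cases (one index record each).
#' @param detectable_count Exact number of panel-detectable index
#'   records (first mode).
#' @param detectable_fraction Per-case probability that the index
#'   record is panel-detectable (second mode).
#' @param tier Tier of detectable index records (`"1"`..`"4"` or
#'   `"unknown"`).
#' @param nondetectable_tier Tier of non-detectable index records;
#'   defaults to `tier`.
#' @param n_extra,p_extra Cases carrying one extra (co-occurring)
#'   mutation in an off-panel gene; count or probability.
#' @param n_extra_high_tier,p_extra_high_tier Of the extra-carrying
#'   cases, how many carry a Tier-1 extra that the panel cannot
#'   detect (the rest carry a Tier-3 extra); count, or probability
#'   conditional on having an extra.
#' @param duplicate_rate Fraction of rows re-emitted as exact
#'   duplicates (removed again by reader-side deduplication).
#' @param dialect_mix Named weights over
#'   `c("cdna_only", "long_protein", "short_protein", "all_three")`
#'   controlling which name columns each record populates.
#' @param study_id Study label for the emitted rows.
#' @param label Stratum identifier used for sample naming and the
#'   per-stratum random substream; defaults to
#'   `gene/diagnosis/tier/nondetectable_tier` and must be unique
#'   within a spec list.
#' @return A `stratum_spec` list.
#' @export
stratum_spec <- function(gene, diagnosis, n_cases,
                         detectable_count = NULL, detectable_fraction = NULL,
                         tier = "1", nondetectable_tier = tier,
                         n_extra = 0L, p_extra = NULL,
                         n_extra_high_tier = 0L, p_extra_high_tier = NULL,
                         duplicate_rate = 0,
                         dialect_mix = c(all_three = 1),
                         study_id = "synthetic-study", label = NULL) {
  if (is.null(detectable_count) == is.null(detectable_fraction)) {
    ps_error("give exactly one of detectable_count / detectable_fraction",
             "panelscope_spec_error")
  }
  if (!is.null(detectable_count) && detectable_count > n_cases) {
    ps_error("detectable_count exceeds n_cases", "panelscope_spec_error")
  }
  probs <- c(detectable_fraction, p_extra, p_extra_high_tier, duplicate_rate)
  if (any(probs < 0 | probs > 1)) {
    ps_error("probabilities must lie in [0, 1]", "panelscope_spec_error")
  }
  if (!all(names(dialect_mix) %in% DIALECTS) ||
      abs(sum(dialect_mix) - 1) > 1e-9) {
    ps_error("dialect_mix must be named weights over the four dialects summing to 1",
             "panelscope_spec_error")
  }
  if (!(tier %in% TIER_LEVELS) || !(nondetectable_tier %in% TIER_LEVELS)) {
    ps_error("tier outside 1/2/3/4/unknown", "panelscope_spec_error")
  }
  label <- label %||% paste(toupper(gene), diagnosis, tier,
                            nondetectable_tier, sep = "/")
  structure(list(gene = toupper(gene), diagnosis = diagnosis,
                 label = label,
                 n_cases = as.integer(n_cases),
                 detectable_count = detectable_count,
                 detectable_fraction = detectable_fraction,
                 tier = tier, nondetectable_tier = nondetectable_tier,
                 n_extra = as.integer(n_extra), p_extra = p_extra,
                 n_extra_high_tier = as.integer(n_extra_high_tier),
                 p_extra_high_tier = p_extra_high_tier,
                 duplicate_rate = duplicate_rate,
                 dialect_mix = dialect_mix, study_id = study_id),
            class = "stratum_spec")
}

# per-stratum substream: adding a stratum must not perturb the draws
# of the others, so each stratum reseeds from a stable hash of its
# identity mixed with the global seed (kept below 2^31 - 1).
derive_seed <- function(seed, ...) {
  txt <- paste(..., collapse = "/")
  h <- 0
  for (code in utf8ToInt(txt)) h <- (h * 31 + code) %% 2147483647
  as.integer((h * 31 + (seed %% 2147483647)) %% 2147483647)
}

#' Generate a variant absent from a panel
#'
#' Draws a plausible-looking missense event (with a consistent cDNA
#' spelling) for `gene` and verifies that neither its protein nor its
#' cDNA canonical key collides with any panel entry, retrying up to
#' `max_tries` times. Used to generate truth-labelled non-detectable
#' records; uses the current RNG state.
#'
#' @param gene Gene symbol.
#' @param panel A `panel_definition`.
#' @param max_tries Attempts before giving up (only pathological
#'   panels exhaust this).
#' @param key_table Precomputed `panel_key_table(panel)`, to avoid
#'   rebuilding it across many draws.
#' @return A `variant_descriptor` carrying both representations.
#' @export
generate_nonpanel_variant <- function(gene, panel, max_tries = 100L,
                                      key_table = NULL) {
  stopifnot(inherits(panel, "panel_definition"))
  pt <- key_table %||% panel_key_table(panel)
  pk <- pt$protein_key[pt$gene == toupper(gene)]
  ck <- pt$cdna_key[pt$gene == toupper(gene)]
  aas <- setdiff(AA_ONE, c("X", "*"))
  nts <- c("A", "C", "G", "T")
  for (i in seq_len(max_tries)) {
    pos <- sample(200:1299, 1)
    ref <- sample(aas, 1)
    alt <- sample(setdiff(aas, ref), 1)
    protein <- parse_protein(sprintf("p.%s%d%s", ref, pos, alt))
    ref_nt <- sample(nts, 1)
    cdna <- parse_cdna(sprintf("c.%d%s>%s", pos * 3L - 1L, ref_nt,
                               sample(setdiff(nts, ref_nt), 1)))
    d <- variant_descriptor(gene, cdna = cdna, protein = protein)
    if (!(key_or_na(d, "protein") %in% pk) &&
        !(key_or_na(d, "cdna") %in% ck)) {
      return(d)
    }
  }
  ps_error(sprintf("could not generate an off-panel variant for %s in %d tries",
                   gene, max_tries), "panelscope_generation_error")
}

.emit_names <- function(descriptor, dialect) {
  cdna <- if (!is.null(descriptor$cdna)) format(descriptor$cdna) else ""
  long <- if (!is.null(descriptor$protein)) to_long_form(descriptor$protein) else ""
  short <- if (!is.null(descriptor$protein)) to_short_form(descriptor$protein) else ""
  # a record cannot be emitted at a level its descriptor lacks; fall
  # back to the short protein spelling (always present here)
  if (dialect == "cdna_only" && !nzchar(cdna)) dialect <- "short_protein"
  switch(dialect,
    cdna_only     = c(cdna = cdna, protein_long = "", protein_short = ""),
    long_protein  = c(cdna = "", protein_long = long, protein_short = ""),
    short_protein = c(cdna = "", protein_long = "", protein_short = short),
    all_three     = c(cdna = cdna, protein_long = long, protein_short = short))
}

#' Generate a synthetic cohort with truth labels
#'
#' Builds a cohort table from a list of [stratum_spec()]s against a
#' panel definition. Detectable index records draw their descriptor
#' uniformly from the panel's entries for the stratum's gene;
#' non-detectable records come from [generate_nonpanel_variant()]
#' (keys verified absent from the panel); extra records use off-panel
#' genes. Each record is emitted in a name dialect drawn from the
#' stratum's `dialect_mix`. A fixed seed gives byte-identical output;
#' each stratum has its own substream, so adding a stratum leaves the
#' others' draws unchanged.
#'
#' @param spec A list of `stratum_spec` objects.
#' @param panel A `panel_definition`; every stratum gene must have
#'   panel entries.
#' @param seed Integer seed.
#' @return A list with `cohort` (a `cohort_table`, duplicate rows
#'   included, as a raw export would arrive), `truth` (one label row
#'   per unique generated record: `is_panel_detectable`, `is_extra`,
#'   `tier`), and `annotations` (record-level tier/diagnosis side
#'   table for [attach_annotations()]).
#' @export
generate_cohort <- function(spec, panel, seed = 1L) {
  stopifnot(inherits(panel, "panel_definition"))
  if (inherits(spec, "stratum_spec")) spec <- list(spec)
  for (s in spec) {
    if (!inherits(s, "stratum_spec")) {
      ps_error("spec must be a list of stratum_spec objects",
               "panelscope_spec_error")
    }
    if (!(s$gene %in% panel$genes)) {
      ps_error(sprintf("stratum (%s, %s): gene %s has no panel entries",
                       s$gene, s$diagnosis, s$gene), "panelscope_spec_error")
    }
  }
  labels <- vapply(spec, function(s) s$label, character(1))
  if (anyDuplicated(labels)) {
    ps_error(sprintf("duplicate stratum label(s): %s",
                     paste(unique(labels[duplicated(labels)]), collapse = "; ")),
             "panelscope_spec_error")
  }

  key_table <- panel_key_table(panel)
  all_rows <- list(); all_truth <- list(); all_dups <- list()
  for (s in spec) {
    set.seed(derive_seed(seed, s$label))
    gene_entries <- Filter(function(v) identical(v$gene, s$gene),
                           panel$variants)
    n <- s$n_cases
    if (!is.null(s$detectable_count)) {
      detectable <- seq_len(n) <= s$detectable_count
    } else {
      detectable <- stats::runif(n) < s$detectable_fraction
    }
    if (!is.null(s$p_extra)) {
      has_extra <- stats::runif(n) < s$p_extra
      extra_high <- has_extra & (stats::runif(n) < (s$p_extra_high_tier %||% 0))
    } else {
      has_extra <- seq_len(n) <= s$n_extra
      extra_high <- seq_len(n) <= s$n_extra_high_tier
    }
    # extras sit on panel-positive cases so the extra-mutation columns
    # are decoupled from positivity (the count invariants still hold)
    slug <- gsub("[^A-Za-z0-9]+", "-", s$label)
    sid <- sprintf("%s-%04d", slug, seq_len(n))
    dialect <- if (length(s$dialect_mix) == 1L) {
      rep(names(s$dialect_mix), n)
    } else {
      sample(names(s$dialect_mix), n, replace = TRUE,
             prob = as.numeric(s$dialect_mix))
    }
    cdna <- long <- short <- character(n)
    det_idx <- which(detectable)
    if (length(det_idx)) {
      picks <- sample(length(gene_entries), length(det_idx), replace = TRUE)
      for (j in seq_along(det_idx)) {
        nm <- .emit_names(gene_entries[[picks[j]]]$descriptor,
                          dialect[det_idx[j]])
        i <- det_idx[j]
        cdna[i] <- nm[["cdna"]]; long[i] <- nm[["protein_long"]]
        short[i] <- nm[["protein_short"]]
      }
    }
    for (i in which(!detectable)) {
      nm <- .emit_names(generate_nonpanel_variant(s$gene, panel, key_table = key_table),
                        dialect[i])
      cdna[i] <- nm[["cdna"]]; long[i] <- nm[["protein_long"]]
      short[i] <- nm[["protein_short"]]
    }
    tier_i <- ifelse(detectable, s$tier, s$nondetectable_tier)
    srows <- data.frame(
      study_id = s$study_id, sample_id = sid, gene = s$gene,
      cdna = cdna, protein_long = long, protein_short = short,
      tier = tier_i, diagnosis = s$diagnosis, stringsAsFactors = FALSE)
    struth <- data.frame(
      study_id = s$study_id, sample_id = sid, gene = s$gene,
      cdna = cdna, protein_short = short,
      is_panel_detectable = detectable, is_extra = FALSE,
      tier = tier_i, stringsAsFactors = FALSE)

    ex_idx <- which(has_extra)
    if (length(ex_idx)) {
      e_cdna <- e_long <- e_short <- e_gene <- e_tier <- character(length(ex_idx))
      for (j in seq_along(ex_idx)) {
        i <- ex_idx[j]
        e_gene[j] <- EXTRA_GENES[(i - 1L) %% length(EXTRA_GENES) + 1L]
        enm <- .emit_names(generate_nonpanel_variant(e_gene[j], panel,
                                                     key_table = key_table),
                           "all_three")
        e_cdna[j] <- enm[["cdna"]]; e_long[j] <- enm[["protein_long"]]
        e_short[j] <- enm[["protein_short"]]
        e_tier[j] <- if (extra_high[i]) "1" else "3"
      }
      srows <- rbind(srows, data.frame(
        study_id = s$study_id, sample_id = sid[ex_idx], gene = e_gene,
        cdna = e_cdna, protein_long = e_long, protein_short = e_short,
        tier = e_tier, diagnosis = s$diagnosis, stringsAsFactors = FALSE))
      struth <- rbind(struth, data.frame(
        study_id = s$study_id, sample_id = sid[ex_idx], gene = e_gene,
        cdna = e_cdna, protein_short = e_short,
        is_panel_detectable = FALSE, is_extra = TRUE,
        tier = e_tier, stringsAsFactors = FALSE))
    }
    all_rows[[length(all_rows) + 1L]] <- srows
    all_truth[[length(all_truth) + 1L]] <- struth
    n_dup <- floor(s$duplicate_rate * nrow(srows))
    if (n_dup > 0) {
      all_dups[[length(all_dups) + 1L]] <-
        srows[sample(nrow(srows), n_dup, replace = FALSE), , drop = FALSE]
    }
  }

  records <- do.call(rbind, c(all_rows, all_dups))
  rownames(records) <- NULL
  truth <- do.call(rbind, all_truth)
  rownames(truth) <- NULL
  annotations <- records[!duplicated(do.call(paste,
                                             c(records[RETAINED_COLS],
                                               sep = "\r"))),
                         c("study_id", "sample_id", "gene", "protein_short",
                           "tier", "diagnosis")]
  names(annotations)[4] <- "protein"
  rownames(annotations) <- NULL
  cohort <- new_cohort_table(
    finalize_records(records),
    provenance_row("generate", nrow(records), nrow(records),
                   sprintf("%d strata, seed %d", length(spec), seed)))
  list(cohort = cohort, truth = truth, annotations = annotations)
}

#' Write / read truth labels
#'
#' Lossless TSV round-trip for the generator's truth labels.
#'
#' @param labels Truth data.frame from [generate_cohort()].
#' @param path Output path.
#' @return `path` invisibly; `read_truth()` returns the data.frame.
#' @export
write_truth <- function(labels, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(labels, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0), stringsAsFactors = FALSE)
  df$is_panel_detectable <- as.logical(df$is_panel_detectable)
  df$is_extra <- as.logical(df$is_extra)
  df
}
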