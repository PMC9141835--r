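# Panel registry: the assay's detectable-variant list, loaded from a
# TSV or JSON panel-definition file and validated through the variant
# name parsers. File schema documented in docs/panel_format.md.

#' Load an assay panel definition
#'
#' Reads a panel-definition file listing the variants an assay can
#' detect, one row per concrete change. TSV files need columns `gene`,
#' `cdna`, `protein`, `vendor_label`, `class`, `cartridge` (empty cells
#' where a representation is absent); a JSON array of objects with the
#' same field names is accepted interchangeably. Every row is parsed
#' through [parse_cdna()]/[parse_protein()], so a malformed name fails
#' the load with its row number. Row order is preserved.
#'
#' Two rows with the same gene and canonical protein key are
#' duplicates: in strict mode (default) they fail validation, otherwise
#' later duplicates are dropped with a warning.
#'
#' @param path Path to the panel file (`.tsv`/`.txt` or `.json`).
#' @param strict Fail on duplicate (gene, protein-key) rows instead of
#'   collapsing them.
#' @return An object of class `panel_definition`: fields `name`,
#'   `version`, `variants` (list of `panel_variant`), `genes`.
#' @examples
#' panel <- load_panel(system.file("extdata", "idylla_panel_synthetic.tsv",
#'                                 package = "panelscope"))
#' panel_summary(panel)
#' @export
load_panel <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    ps_error(sprintf("panel file not found: %s", path), "panelscope_io_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  } else {
    rows <- utils::read.delim(path, header = TRUE, sep = "\t",
                              colClasses = "character",
                              stringsAsFactors = FALSE,
                              na.strings = character(0),
                              check.names = FALSE)
  }
  needed <- c("gene", "cdna", "protein", "vendor_label", "class", "cartridge")
  if (nrow(rows) > 0 && !all(needed %in% names(rows))) {
    ps_error(sprintf("panel file %s lacks columns: %s", path,
                     paste(setdiff(needed, names(rows)), collapse = ", ")),
             "panelscope_format_error")
  }

  variants <- vector("list", nrow(rows))
  if (nrow(rows) > 0) {
    for (i in seq_len(nrow(rows))) {
      variants[[i]] <- tryCatch(
        panel_variant(gene = rows$gene[i], cdna = rows$cdna[i],
                      protein = rows$protein[i],
                      vendor_label = rows$vendor_label[i],
                      variant_class = rows$class[i],
                      cartridge = rows$cartridge[i]),
        panelscope_error = function(e) {
          ps_error(sprintf("panel file %s row %d: %s", path, i,
                           conditionMessage(e)),
                   "panelscope_load_error")
        })
    }
  }

  pkeys <- vapply(variants, function(v) {
    k <- key_or_na(v$descriptor, "protein")
    if (is.na(k)) paste0("cdna:", key_or_na(v$descriptor, "cdna")) else k
  }, character(1))
  dup_id <- paste(vapply(variants, function(v) v$gene, character(1)), pkeys)
  if (anyDuplicated(dup_id)) {
    dups <- unique(dup_id[duplicated(dup_id)])
    if (strict) {
      ps_error(sprintf("duplicate panel entries: %s",
                       paste(dups, collapse = "; ")),
               "panelscope_validation_error")
    }
    warning(sprintf("collapsing duplicate panel entries: %s",
                    paste(dups, collapse = "; ")))
    variants <- variants[!duplicated(dup_id)]
  }

  genes <- unique(vapply(variants, function(v) v$gene, character(1)))
  structure(list(name = basename(path),
                 version = "1",
                 variants = variants,
                 genes = genes),
            class = "panel_definition")
}

#' One panel-detectable variant
#'
#' @param gene Gene symbol; must equal the descriptor's gene.
#' @param cdna,protein Variant name strings (either may be empty).
#' @param vendor_label Assay label, e.g. `"V600E"`.
#' @param variant_class `"snv"` or `"indel"`.
#' @param cartridge Cartridge name, e.g. `"BRAF"` or `"NRAS/BRAF"`.
#' @return An object of class `panel_variant`.
#' @export
panel_variant <- function(gene, cdna = "", protein = "", vendor_label = "",
                          variant_class = c("snv", "indel"), cartridge = "") {
  variant_class <- match.arg(variant_class)
  cdna <- cdna %||% ""; protein <- protein %||% ""
  if (is.na(cdna)) cdna <- ""
  if (is.na(protein)) protein <- ""
  cdna <- trimws(cdna); protein <- trimws(protein)
  descriptor <- variant_descriptor(
    gene,
    cdna = if (nzchar(cdna)) parse_cdna(cdna) else NULL,
    protein = if (nzchar(protein)) parse_protein(protein) else NULL)
  structure(list(gene = descriptor$gene, descriptor = descriptor,
                 vendor_label = vendor_label, variant_class = variant_class,
                 cartridge = cartridge),
            class = "panel_variant")
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0L) y else x

#' @export
print.panel_definition <- function(x, ...) {
  cat("<panel_definition> ", x$name, ": ", length(x$variants),
      " variants across ", length(x$genes), " genes (",
      paste(sort(x$genes), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Per-gene panel composition
#'
#' @param panel A `panel_definition`.
#' @return A data.frame with one row per gene: `gene`, `n_variants`,
#'   `n_snv`, `n_indel`. Per-gene counts sum to the panel total.
#' @export
panel_summary <- function(panel) {
  stopifnot(inherits(panel, "panel_definition"))
  if (length(panel$variants) == 0L) {
    return(data.frame(gene = character(0), n_variants = integer(0),
                      n_snv = integer(0), n_indel = integer(0),
                      stringsAsFactors = FALSE))
  }
  gene <- vapply(panel$variants, function(v) v$gene, character(1))
  cls <- vapply(panel$variants, function(v) v$variant_class, character(1))
  genes <- unique(gene)  # file order
  data.frame(
    gene = genes,
    n_variants = vapply(genes, function(g) sum(gene == g), integer(1)),
    n_snv = vapply(genes, function(g) sum(gene == g & cls == "snv"), integer(1)),
    n_indel = vapply(genes, function(g) sum(gene == g & cls == "indel"), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Test whether a panel detects a variant
#'
#' Matches a query descriptor against the panel's entries for its
#' gene: the protein level is tried first across all entries (long and
#' short spellings canonicalize to one key), then the cDNA level for
#' entries with which no protein comparison was decisive; within a
#' level, file order wins. Descriptors whose gene has no cartridge
#' target, or that share no representation level with any panel entry
#' of their gene, do not match and the reason is recorded — a
#' cDNA-only record queried against a protein-only panel entry is
#' conservatively counted not-detectable.
#'
#' @param panel A `panel_definition`.
#' @param descriptor A `variant_descriptor`.
#' @return A list of class `panel_match` with fields `matched`
#'   (logical), `panel_variant` (the matching `panel_variant` or NULL),
#'   `match_level` (`"protein"`, `"cdna"` or NA) and `reason`.
#' @examples
#' panel <- load_panel(system.file("extdata", "idylla_panel_synthetic.tsv",
#'                                 package = "panelscope"))
#' panel_contains(panel, variant_descriptor("BRAF", protein = "p.Val600Glu"))
#' @export
panel_contains <- function(panel, descriptor) {
  stopifnot(inherits(panel, "panel_definition"),
            inherits(descriptor, "variant_descriptor"))
  if (!(descriptor$gene %in% panel$genes)) {
    return(structure(list(matched = FALSE, panel_variant = NULL,
                          match_level = NA_character_,
                          reason = "gene not on panel"),
                     class = "panel_match"))
  }
  entries <- Filter(function(v) identical(v$gene, descriptor$gene),
                    panel$variants)
  found <- function(v, level) {
    structure(list(matched = TRUE, panel_variant = v, match_level = level,
                   reason = ""), class = "panel_match")
  }
  any_comparable <- FALSE
  dp <- key_or_na(descriptor, "protein")
  if (!is.na(dp)) {
    for (v in entries) {
      vp <- key_or_na(v$descriptor, "protein")
      if (!is.na(vp)) {
        any_comparable <- TRUE
        if (identical(dp, vp)) return(found(v, "protein"))
      }
    }
  }
  dc <- key_or_na(descriptor, "cdna")
  if (!is.na(dc)) {
    for (v in entries) {
      vp <- key_or_na(v$descriptor, "protein")
      if (!is.na(dp) && !is.na(vp)) next  # protein level already decisive
      vc <- key_or_na(v$descriptor, "cdna")
      if (!is.na(vc)) {
        any_comparable <- TRUE
        if (identical(dc, vc)) return(found(v, "cdna"))
      }
    }
  }
  structure(list(matched = FALSE, panel_variant = NULL,
                 match_level = NA_character_,
                 reason = if (any_comparable) "key not in panel"
                          else "no shared representation"),
            class = "panel_match")
}

#' @export
print.panel_match <- function(x, ...) {
  if (x$matched) {
    cat("<panel_match> matched at ", x$match_level, " level: ",
        x$panel_variant$gene, " ", x$panel_variant$vendor_label, "\n", sep = "")
  } else {
    cat("<panel_match> not matched (", x$reason, ")\n", sep = "")
  }
  invisible(x)
}

# flat lookup tables used by the vectorized classifier
panel_key_table <- function(panel) {
  if (length(panel$variants) == 0L) {
    return(data.frame(idx = integer(0), gene = character(0),
                      protein_key = character(0), cdna_key = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    idx = seq_along(panel$variants),
    gene = vapply(panel$variants, function(v) v$gene, character(1)),
    protein_key = vapply(panel$variants, function(v)
      key_or_na(v$descriptor, "protein"), character(1)),
    cdna_key = vapply(panel$variants, function(v)
      key_or_na(v$descriptor, "cdna"), character(1)),
    stringsAsFactors = FALSE)
}
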