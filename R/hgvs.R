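# Variant-name parsing and normalization: cDNA and protein HGVS-style
# notation, long (3-letter) and short (1-letter) amino-acid spellings.
# Scope is deliberately the "name columns" dialect used by cBioPortal
# exports and assay package inserts: coding substitutions and simple
# indels, protein missense/nonsense/indel/frameshift events. Intronic,
# UTR, genomic (g.) and allele-level syntax are out of scope.

AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
  Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
  Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
  Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
  Ter = "*", Xaa = "X"
)

# one-letter codes legal in short forms: the 20 standard residues,
# X (unknown) and * (stop). B/J/O/U/Z are rejected as unknown codes.
AA_ONE <- unname(AA_THREE_TO_ONE)

.res3_rx <- paste0("(?:", paste(names(AA_THREE_TO_ONE), collapse = "|"), ")")
.res1_rx <- "[ACDEFGHIKLMNPQRSTVWYX*]"
.res_rx  <- paste0("(", .res3_rx, "|", .res1_rx, ")")
.resseq_rx <- paste0("((?:", .res3_rx, ")+|(?:", .res1_rx, ")+)")

ps_error <- function(message, class) {
  stop(errorCondition(message, class = c(class, "panelscope_error")))
}

.res_to_one <- function(token) {
  if (nchar(token) == 3L) unname(AA_THREE_TO_ONE[token]) else token
}

.resseq_to_one <- function(seq) {
  if (grepl(paste0("^(?:", .res3_rx, ")+$"), seq)) {
    toks <- substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
    paste(vapply(toks, .res_to_one, character(1)), collapse = "")
  } else {
    seq
  }
}

#' Parse a coding-DNA variant name
#'
#' Parses an HGVS-style coding change such as `"c.901C>G"` or
#' `"c.2235_2249del"` into a structured value. The `"c."` prefix is
#' optional and nucleotide case is normalized to uppercase, so
#' `"C.901c>g"` parses to the same value as `"c.901C>G"`.
#'
#' Supported event kinds are substitution (`>`), deletion (`del`),
#' insertion (`ins`), duplication (`dup`) and deletion-insertion
#' (`delins`) at coding positions. Intronic offsets (`c.123+1G>A`),
#' UTR positions and genomic notation are rejected.
#'
#' @param text A single variant name string.
#' @return An object of class `cdna_change` with fields `raw_text`,
#'   `start`, `end`, `kind`, `ref_allele`, `alt_allele`.
#' @examples
#' parse_cdna("c.901C>G")
#' parse_cdna("c.2235_2249del")
#' @seealso [parse_protein()], [canonical_key()]
#' @export
parse_cdna <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- trimws(text)
  if (!nzchar(raw)) ps_error("empty cDNA variant name", "panelscope_parse_error")
  body <- sub("^[cC]\\.", "", raw)
  body <- toupper(body)

  make <- function(kind, start, end, ref = "", alt = "") {
    start <- as.integer(start); end <- as.integer(end)
    if (is.na(start) || is.na(end) || start < 1L || end < start) {
      ps_error(sprintf("invalid cDNA position range in '%s'", raw),
               "panelscope_parse_error")
    }
    structure(list(raw_text = raw, start = start, end = end, kind = kind,
                   ref_allele = ref, alt_allele = alt),
              class = "cdna_change")
  }

  m <- regmatches(body, regexec("^([0-9]+)([ACGT]+)>([ACGT]+)$", body, perl = TRUE))[[1]]
  if (length(m)) return(make("substitution", m[2], m[2], m[3], m[4]))

  m <- regmatches(body, regexec("^([0-9]+)(?:_([0-9]+))?DELINS([ACGT]+)$", body, perl = TRUE))[[1]]
  if (length(m)) {
    end <- if (nzchar(m[3])) m[3] else m[2]
    return(make("delins", m[2], end, alt = m[4]))
  }
  m <- regmatches(body, regexec("^([0-9]+)(?:_([0-9]+))?DEL([ACGT]*)$", body, perl = TRUE))[[1]]
  if (length(m)) {
    end <- if (nzchar(m[3])) m[3] else m[2]
    return(make("deletion", m[2], end, ref = m[4]))
  }
  m <- regmatches(body, regexec("^([0-9]+)(?:_([0-9]+))?DUP([ACGT]*)$", body, perl = TRUE))[[1]]
  if (length(m)) {
    end <- if (nzchar(m[3])) m[3] else m[2]
    return(make("duplication", m[2], end, ref = m[4]))
  }
  m <- regmatches(body, regexec("^([0-9]+)_([0-9]+)INS([ACGT]+)$", body, perl = TRUE))[[1]]
  if (length(m)) return(make("insertion", m[2], m[3], alt = m[4]))

  ps_error(sprintf("unrecognized cDNA variant name: '%s'", raw),
           "panelscope_parse_error")
}

#' @export
format.cdna_change <- function(x, ...) {
  rng <- if (x$end == x$start) as.character(x$start) else
    paste0(x$start, "_", x$end)
  body <- switch(x$kind,
    substitution = paste0(x$start, x$ref_allele, ">", x$alt_allele),
    deletion     = paste0(rng, "del"),
    duplication  = paste0(rng, "dup"),
    insertion    = paste0(rng, "ins", x$alt_allele),
    delins       = paste0(rng, "delins", x$alt_allele)
  )
  paste0("c.", body)
}

#' @export
print.cdna_change <- function(x, ...) {
  cat("<cdna_change> ", format(x), "  [", x$kind, "]\n", sep = "")
  invisible(x)
}

.protein_make <- function(raw, kind, start_res, start_pos,
                          end_res = start_res, end_pos = start_pos,
                          new_residues = "") {
  start_pos <- as.integer(start_pos); end_pos <- as.integer(end_pos)
  if (is.na(start_pos) || is.na(end_pos) || start_pos < 1L ||
      end_pos < start_pos) {
    ps_error(sprintf("invalid residue position range in '%s'", raw),
             "panelscope_parse_error")
  }
  structure(list(raw_text = raw, start_res = start_res, start_pos = start_pos,
                 end_res = end_res, end_pos = end_pos, kind = kind,
                 new_residues = new_residues),
            class = "protein_change")
}

#' Parse a protein variant name
#'
#' Parses an HGVS-style protein change in either the long (3-letter,
#' `"p.Ala379Val"`) or short (1-letter, `"p.A379V"`) spelling into a
#' representation-independent value: both spellings of the same event
#' parse to equal objects. The `"p."` prefix and enclosing parentheses
#' (`"p.(V600E)"`) are optional on input.
#'
#' Event kinds: missense, nonsense (new residue is a stop), deletion,
#' insertion, duplication, deletion-insertion, and frameshift.
#' Frameshifts canonicalize to the affected residue plus `"fs"`; any
#' extension length (`"fs*12"`) is discarded so that package-insert
#' spellings without extensions compare equal to fully specified ones.
#'
#' @param text A single protein change string.
#' @return An object of class `protein_change`.
#' @examples
#' parse_protein("p.Ala379Val")
#' parse_protein("p.A379V")
#' parse_protein("p.Glu746_Ala750del")
#' @export
parse_protein <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- trimws(text)
  if (!nzchar(raw)) ps_error("empty protein variant name", "panelscope_parse_error")
  body <- sub("^[pP]\\.", "", raw)
  body <- sub("^\\((.*)\\)$", "\\1", body)

  rx <- function(pattern) regmatches(body, regexec(pattern, body, perl = TRUE))[[1]]

  # frameshift: residue + position (+ optional new residue) + fs (+ extension)
  m <- rx(paste0("^", .res_rx, "([0-9]+)", .res_rx, "?fs(\\*?[0-9]*|Ter[0-9]*)?$"))
  if (length(m)) {
    return(.protein_make(raw, "frameshift", .res_to_one(m[2]), m[3]))
  }
  m <- rx(paste0("^", .res_rx, "([0-9]+)(?:_", .res_rx, "([0-9]+))?delins",
                 .resseq_rx, "$"))
  if (length(m)) {
    has_end <- nzchar(m[4])
    return(.protein_make(raw, "delins", .res_to_one(m[2]), m[3],
                         if (has_end) .res_to_one(m[4]) else .res_to_one(m[2]),
                         if (has_end) m[5] else m[3],
                         new_residues = .resseq_to_one(m[6])))
  }
  m <- rx(paste0("^", .res_rx, "([0-9]+)(?:_", .res_rx, "([0-9]+))?del$"))
  if (length(m)) {
    has_end <- nzchar(m[4])
    return(.protein_make(raw, "deletion", .res_to_one(m[2]), m[3],
                         if (has_end) .res_to_one(m[4]) else .res_to_one(m[2]),
                         if (has_end) m[5] else m[3]))
  }
  m <- rx(paste0("^", .res_rx, "([0-9]+)(?:_", .res_rx, "([0-9]+))?dup$"))
  if (length(m)) {
    has_end <- nzchar(m[4])
    return(.protein_make(raw, "duplication", .res_to_one(m[2]), m[3],
                         if (has_end) .res_to_one(m[4]) else .res_to_one(m[2]),
                         if (has_end) m[5] else m[3]))
  }
  m <- rx(paste0("^", .res_rx, "([0-9]+)_", .res_rx, "([0-9]+)ins",
                 .resseq_rx, "$"))
  if (length(m)) {
    return(.protein_make(raw, "insertion", .res_to_one(m[2]), m[3],
                         .res_to_one(m[4]), m[5],
                         new_residues = .resseq_to_one(m[6])))
  }
  m <- rx(paste0("^", .res_rx, "([0-9]+)", .res_rx, "$"))
  if (length(m)) {
    new <- .res_to_one(m[4])
    kind <- if (new == "*") "nonsense" else "missense"
    return(.protein_make(raw, kind, .res_to_one(m[2]), m[3],
                         new_residues = new))
  }

  ps_error(sprintf("unrecognized protein variant name: '%s'", raw),
           "panelscope_parse_error")
}

#' Render a protein change in canonical short form
#'
#' Emits the canonical 1-letter spelling with a `"p."` prefix and no
#' parentheses: `"p.V600E"`, `"p.E746_A750del"`, `"p.A379fs"`. This is
#' the text used for protein-level canonical keys, so a change parsed
#' from a long form and the same change parsed from a short form render
#' identically.
#'
#' @param change A `protein_change` object.
#' @return A single string.
#' @examples
#' to_short_form(parse_protein("p.Val600Glu"))
#' @export
to_short_form <- function(change) {
  stopifnot(inherits(change, "protein_change"))
  if (identical(change$kind, "raw")) return(change$raw_text)
  rng <- if (change$end_pos == change$start_pos)
    paste0(change$start_res, change$start_pos)
  else
    paste0(change$start_res, change$start_pos, "_",
           change$end_res, change$end_pos)
  body <- switch(change$kind,
    missense    = paste0(change$start_res, change$start_pos, change$new_residues),
    nonsense    = paste0(change$start_res, change$start_pos, "*"),
    deletion    = paste0(rng, "del"),
    duplication = paste0(rng, "dup"),
    insertion   = paste0(rng, "ins", change$new_residues),
    delins      = paste0(rng, "delins", change$new_residues),
    frameshift  = paste0(change$start_res, change$start_pos, "fs")
  )
  paste0("p.", body)
}

AA_ONE_TO_THREE <- stats::setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

.res_to_three <- function(one) {
  paste(AA_ONE_TO_THREE[strsplit(one, "")[[1]]], collapse = "")
}

#' Render a protein change in long (3-letter) form
#'
#' The counterpart of [to_short_form()]: emits the 3-letter spelling
#' (`"p.Val600Glu"`, `"p.Glu746_Ala750del"`). Parsing the result gives
#' back an equal `protein_change`.
#'
#' @param change A `protein_change` object.
#' @return A single string.
#' @export
to_long_form <- function(change) {
  stopifnot(inherits(change, "protein_change"))
  if (identical(change$kind, "raw")) return(change$raw_text)
  s <- .res_to_three(change$start_res)
  e <- .res_to_three(change$end_res)
  rng <- if (change$end_pos == change$start_pos)
    paste0(s, change$start_pos)
  else
    paste0(s, change$start_pos, "_", e, change$end_pos)
  body <- switch(change$kind,
    missense    = paste0(s, change$start_pos, .res_to_three(change$new_residues)),
    nonsense    = paste0(s, change$start_pos, "Ter"),
    deletion    = paste0(rng, "del"),
    duplication = paste0(rng, "dup"),
    insertion   = paste0(rng, "ins", .res_to_three(change$new_residues)),
    delins      = paste0(rng, "delins", .res_to_three(change$new_residues)),
    frameshift  = paste0(s, change$start_pos, "fs")
  )
  paste0("p.", body)
}

#' @export
format.protein_change <- function(x, ...) to_short_form(x)

#' @export
print.protein_change <- function(x, ...) {
  cat("<protein_change> ", to_short_form(x), "  [", x$kind, "]\n", sep = "")
  invisible(x)
}

# non-canonical fallback: a name column we could not parse still needs a
# deterministic key so the record can flow through matching (it can only
# ever match byte-identical raw text).
raw_protein_change <- function(text) {
  structure(list(raw_text = trimws(text), start_res = NA_character_,
                 start_pos = NA_integer_, end_res = NA_character_,
                 end_pos = NA_integer_, kind = "raw", new_residues = ""),
            class = "protein_change")
}

raw_cdna_change <- function(text) {
  structure(list(raw_text = trimws(text), start = NA_integer_,
                 end = NA_integer_, kind = "raw",
                 ref_allele = "", alt_allele = ""),
            class = "cdna_change")
}

is_canonical_change <- function(x) !identical(x$kind, "raw")

#' Construct a variant descriptor
#'
#' A descriptor bundles one observed mutation's gene symbol with up to
#' two representations of the event: a coding-DNA change and/or a
#' protein change. At least one representation must be present; the
#' gene symbol is case-folded to uppercase.
#'
#' @param gene Gene symbol (e.g. `"BRAF"`).
#' @param cdna Optional `cdna_change`, or a string parsed via
#'   [parse_cdna()].
#' @param protein Optional `protein_change`, or a string parsed via
#'   [parse_protein()].
#' @return An object of class `variant_descriptor`.
#' @examples
#' variant_descriptor("BRAF", protein = "p.V600E")
#' variant_descriptor("KRAS", cdna = "c.35G>A", protein = "p.G12D")
#' @export
variant_descriptor <- function(gene, cdna = NULL, protein = NULL) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(trimws(gene)))
  if (is.character(cdna)) cdna <- parse_cdna(cdna)
  if (is.character(protein)) protein <- parse_protein(protein)
  if (is.null(cdna) && is.null(protein)) {
    ps_error("a variant descriptor needs a cDNA and/or a protein change",
             "panelscope_descriptor_error")
  }
  if (!is.null(cdna)) stopifnot(inherits(cdna, "cdna_change"))
  if (!is.null(protein)) stopifnot(inherits(protein, "protein_change"))
  structure(list(gene = toupper(trimws(gene)), cdna = cdna, protein = protein),
            class = "variant_descriptor")
}

#' @export
print.variant_descriptor <- function(x, ...) {
  reps <- c(if (!is.null(x$protein)) to_short_form(x$protein),
            if (!is.null(x$cdna)) format(x$cdna))
  cat("<variant_descriptor> ", x$gene, " ", paste(reps, collapse = " / "),
      "\n", sep = "")
  invisible(x)
}

#' Canonical key of a descriptor at a representation level
#'
#' The canonical key is the deterministic, case-canonical string that
#' all matching operates on: protein keys use the canonical short form
#' ([to_short_form()]), cDNA keys the normalized cDNA text. Two
#' descriptors of the same event at the same level always produce
#' byte-identical `key_text`.
#'
#' @param descriptor A `variant_descriptor`.
#' @param level `"protein"` or `"cdna"`.
#' @return An object of class `canonical_key` with fields `gene`,
#'   `level`, `key_text`.
#' @examples
#' canonical_key(variant_descriptor("BRAF", protein = "p.Val600Glu"), "protein")
#' @export
canonical_key <- function(descriptor, level = c("protein", "cdna")) {
  stopifnot(inherits(descriptor, "variant_descriptor"))
  level <- match.arg(level)
  rep <- switch(level, protein = descriptor$protein, cdna = descriptor$cdna)
  if (is.null(rep)) {
    ps_error(sprintf("descriptor for %s carries no %s representation",
                     descriptor$gene, level),
             "panelscope_missing_representation")
  }
  key_text <- if (level == "protein") to_short_form(rep) else {
    if (is_canonical_change(rep)) format(rep) else rep$raw_text
  }
  structure(list(gene = descriptor$gene, level = level, key_text = key_text),
            class = "canonical_key")
}

#' @export
print.canonical_key <- function(x, ...) {
  cat("<canonical_key> ", x$gene, " [", x$level, "] ", x$key_text, "\n",
      sep = "")
  invisible(x)
}

key_or_na <- function(descriptor, level) {
  rep <- switch(level, protein = descriptor$protein, cdna = descriptor$cdna)
  if (is.null(rep)) return(NA_character_)
  canonical_key(descriptor, level)$key_text
}

#' Compare two variant descriptors
#'
#' Decides whether two descriptors name the same event. Genes must be
#' equal for any match. The protein level is compared first (long and
#' short spellings canonicalize to one key, so they are a single
#' check); if neither side's protein representation is available the
#' cDNA level is compared. The verdict is `"indeterminate"` only when
#' the two descriptors share no representation level.
#'
#' @param a,b `variant_descriptor` objects.
#' @return One of `"match_protein"`, `"match_cdna"`, `"no_match"`,
#'   `"indeterminate"`. Symmetric in its arguments.
#' @examples
#' same_variant(variant_descriptor("BRAF", protein = "p.Val600Glu"),
#'              variant_descriptor("BRAF", protein = "p.V600E"))
#' @export
same_variant <- function(a, b) {
  stopifnot(inherits(a, "variant_descriptor"),
            inherits(b, "variant_descriptor"))
  if (!identical(a$gene, b$gene)) return("no_match")
  pa <- key_or_na(a, "protein"); pb <- key_or_na(b, "protein")
  if (!is.na(pa) && !is.na(pb)) {
    return(if (identical(pa, pb)) "match_protein" else "no_match")
  }
  ca <- key_or_na(a, "cdna"); cb <- key_or_na(b, "cdna")
  if (!is.na(ca) && !is.na(cb)) {
    return(if (identical(ca, cb)) "match_cdna" else "no_match")
  }
  "indeterminate"
}
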