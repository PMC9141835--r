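# shared fixtures and small oracles used across the suite

fixture_panel_path <- function() {
  system.file("extdata", "idylla_panel_synthetic.tsv", package = "panelscope")
}

fixture_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_panel(fixture_panel_path())
    cache
  }
})

default_ruleset_path <- function() {
  system.file("extdata", "default_ruleset.yaml", package = "panelscope")
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# independent 3-letter/1-letter residue table (typed out separately
# from the package's) for oracle-style conversions in tests
ORACLE_AA <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
               Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
               Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
               Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

oracle_long_to_short <- function(text) {
  # token-wise 3-to-1 substitution, keeping positions and keywords
  body <- sub("^p\\.", "", text)
  for (three in names(ORACLE_AA)) {
    body <- gsub(three, ORACLE_AA[[three]], body, fixed = TRUE)
  }
  paste0("p.", gsub("Ter", "*", body, fixed = TRUE))
}

random_missense_events <- function(n, seed = 42) {
  set.seed(seed)
  pos <- sample(1:5000, n, replace = TRUE)
  ref <- sample(names(ORACLE_AA), n, replace = TRUE)
  alt_pick <- function(r) sample(setdiff(names(ORACLE_AA), r), 1)
  alt <- vapply(ref, alt_pick, character(1))
  data.frame(long = sprintf("p.%s%d%s", ref, pos, alt),
             short = sprintf("p.%s%d%s", ORACLE_AA[ref], pos,
                             ORACLE_AA[alt]),
             stringsAsFactors = FALSE)
}

# brute-force matcher oracle: case-folded string equality of
# gene + short protein form against every panel entry
oracle_short_form_match <- function(genes, shorts, panel_genes,
                                    panel_shorts) {
  q <- toupper(paste(genes, shorts))
  p <- toupper(paste(panel_genes, panel_shorts))
  q %in% p
}

# quick cohort_table builder from a records-style data.frame
toy_cohort <- function(df) {
  base <- panelscope:::empty_records(nrow(df))
  for (col in names(df)) base[[col]] <- as.character(df[[col]])
  panelscope:::new_cohort_table(
    panelscope:::finalize_records(base),
    panelscope:::provenance_row("toy", nrow(df), nrow(df)))
}
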