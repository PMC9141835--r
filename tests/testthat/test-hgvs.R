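# Variant-name parsing, normalization and comparison

test_that("cDNA parsing handles the supported event grammar", {
  x <- parse_cdna("c.901C>G")
  expect_equal(x$kind, "substitution")
  expect_equal(x$start, 901L)
  expect_equal(x$end, 901L)
  expect_equal(x$ref_allele, "C")
  expect_equal(x$alt_allele, "G")

  # prefix and case leniency normalize to one value
  y <- parse_cdna("C.901c>g")
  expect_equal(format(y), "c.901C>G")
  expect_equal(format(y), format(x))

  d <- parse_cdna("c.2235_2249del")
  expect_equal(d$kind, "deletion")
  expect_equal(c(d$start, d$end), c(2235L, 2249L))
  expect_equal(d$alt_allele, "")

  cases <- list(
    list("c.2369C>T", "substitution", "c.2369C>T"),
    list("35G>A", "substitution", "c.35G>A"),
    list("c.2236_2253del", "deletion", "c.2236_2253del"),
    list("c.10del", "deletion", "c.10del"),
    list("c.2307_2308insGCCAGCGTG", "insertion", "c.2307_2308insGCCAGCGTG"),
    list("c.1798_1799delinsAA", "delins", "c.1798_1799delinsAA"),
    list("c.2300_2308dup", "duplication", "c.2300_2308dup"))
  for (cs in cases) {
    p <- parse_cdna(cs[[1]])
    expect_equal(p$kind, cs[[2]], info = cs[[1]])
    expect_equal(format(p), cs[[3]], info = cs[[1]])
  }
})

test_that("malformed cDNA names are rejected with the offending text", {
  for (bad in c("", "  ", "c.G>A", "c.12_5del", "p.V600E", "c.123+1G>A",
                "c.abc", "c.35G>")) {
    expect_error(parse_cdna(bad), class = "panelscope_error")
  }
  expect_error(parse_cdna("c.nonsense"), "c.nonsense")
})

test_that("cDNA format/parse round-trips are idempotent", {
  texts <- c("c.901C>G", "c.35g>a", "C.2235_2249del", "c.2307_2308insG",
             "c.1798_1799delinsAA", "c.2300dup")
  for (t in texts) {
    once <- parse_cdna(t)
    twice <- parse_cdna(format(once))
    once$raw_text <- twice$raw_text <- NULL
    expect_equal(twice, once, info = t)
  }
})

test_that("protein parsing is representation-independent", {
  long <- parse_protein("p.Ala379Val")
  short <- parse_protein("p.A379V")
  expect_equal(long$kind, "missense")
  expect_equal(long$start_res, "A")
  expect_equal(long$start_pos, 379L)
  expect_equal(long$new_residues, "V")
  long$raw_text <- short$raw_text <- NULL
  expect_equal(short, long)

  # deletion spanning E746-A750; oracle: token-wise 3-to-1 table
  del <- parse_protein("p.Glu746_Ala750del")
  expect_equal(to_short_form(del), oracle_long_to_short("p.Glu746_Ala750del"))
  expect_equal(del$kind, "deletion")
  expect_equal(c(del$start_res, del$end_res), c("E", "A"))
  expect_equal(c(del$start_pos, del$end_pos), c(746L, 750L))

  # prefix/parenthesis leniency
  expect_equal(to_short_form(parse_protein("V600E")), "p.V600E")
  expect_equal(to_short_form(parse_protein("p.(V600E)")), "p.V600E")

  # frameshift extension lengths are discarded
  for (fs in c("p.A379fs", "p.Ala379fs", "p.A379Vfs*12", "p.Ala379ValfsTer12")) {
    expect_equal(to_short_form(parse_protein(fs)), "p.A379fs", info = fs)
  }

  # other kinds, long vs short
  pairs <- list(
    c("p.Gln61Ter", "p.Q61*"),
    c("p.Asp770_Asn771insGly", "p.D770_N771insG"),
    c("p.Glu746_Ser752delinsVal", "p.E746_S752delinsV"),
    c("p.Ala767_Val769dup", "p.A767_V769dup"),
    c("p.Lys601del", "p.K601del"))
  for (p in pairs) {
    a <- parse_protein(p[1]); b <- parse_protein(p[2])
    a$raw_text <- b$raw_text <- NULL
    expect_equal(a, b, info = p[1])
  }
})

test_that("unknown residue codes and ambiguous grammar are parse errors", {
  for (bad in c("p.A999Z", "p.Zzz600Glu", "p.600V", "p.V600", "", "p.",
                "p.V600=", "c.35G>A")) {
    expect_error(parse_protein(bad), class = "panelscope_error")
  }
})

test_that("short-form rendering is canonical and a fixed point", {
  expect_equal(to_short_form(parse_protein("p.Ala379Val")), "p.A379V")
  expect_equal(to_short_form(parse_protein("p.A379V")), "p.A379V")
  expect_equal(to_short_form(parse_protein("p.Val600Glu")), "p.V600E")
  # long form is the inverse spelling
  expect_equal(to_long_form(parse_protein("p.V600E")), "p.Val600Glu")
  ev <- random_missense_events(50, seed = 7)
  for (i in seq_len(nrow(ev))) {
    expect_equal(to_long_form(parse_protein(ev$short[i])), ev$long[i])
  }
})

test_that("long and short spellings of 1000 random missense events give identical canonical keys", {
  ev <- random_missense_events(1000)
  key_of <- function(text) {
    canonical_key(variant_descriptor("BRAF", protein = text),
                  "protein")$key_text
  }
  keys_long <- vapply(ev$long, key_of, character(1), USE.NAMES = FALSE)
  keys_short <- vapply(ev$short, key_of, character(1), USE.NAMES = FALSE)
  expect_identical(keys_long, keys_short)
  expect_identical(keys_long, ev$short)  # canonical key is the short form
})

test_that("canonical keys are deterministic and fail on absent representations", {
  d <- variant_descriptor("BRAF", protein = "p.Val600Glu")
  k1 <- canonical_key(d, "protein"); k2 <- canonical_key(d, "protein")
  expect_identical(k1, k2)
  expect_equal(k1$key_text, "p.V600E")
  expect_error(canonical_key(variant_descriptor("KRAS", cdna = "c.35G>A"),
                             "protein"),
               class = "panelscope_missing_representation")
  expect_error(variant_descriptor("KRAS"), class = "panelscope_error")
})

test_that("same_variant matches across spellings and levels", {
  braf_long <- variant_descriptor("BRAF", protein = "p.Val600Glu")
  braf_short <- variant_descriptor("BRAF", protein = "p.V600E")
  expect_equal(same_variant(braf_long, braf_short), "match_protein")
  expect_equal(same_variant(braf_short,
                            variant_descriptor("NRAS", protein = "p.V600E")),
               "no_match")
  expect_equal(same_variant(variant_descriptor("KRAS", cdna = "c.35G>A"),
                            variant_descriptor("KRAS", protein = "p.G12D")),
               "indeterminate")
  expect_equal(same_variant(variant_descriptor("KRAS", cdna = "c.35G>A"),
                            variant_descriptor("KRAS", cdna = "c.35g>a")),
               "match_cdna")
  # protein level is decisive when both sides carry it
  expect_equal(same_variant(
    variant_descriptor("KRAS", cdna = "c.35G>A", protein = "p.G12D"),
    variant_descriptor("KRAS", cdna = "c.35G>A", protein = "p.G12V")),
    "no_match")
})

test_that("same_variant is symmetric over random descriptor pairs", {
  set.seed(11)
  ev <- random_missense_events(60, seed = 11)
  genes <- c("BRAF", "KRAS", "NRAS", "EGFR")
  mk <- function(i) {
    lvl <- sample(c("protein", "cdna", "both"), 1)
    g <- sample(genes, 1)
    cd <- sprintf("c.%dA>G", (i %% 300) + 1)
    switch(lvl,
      protein = variant_descriptor(g, protein = ev$short[i]),
      cdna = variant_descriptor(g, cdna = cd),
      both = variant_descriptor(g, cdna = cd, protein = ev$short[i]))
  }
  for (k in 1:100) {
    a <- mk(sample(60, 1)); b <- mk(sample(60, 1))
    expect_identical(same_variant(a, b), same_variant(b, a))
  }
})

test_that("same_variant agrees with the naive short-form string oracle", {
  ev <- random_missense_events(200, seed = 3)
  genes <- sample(c("BRAF", "KRAS"), 200, replace = TRUE)
  for (k in 1:200) {
    i <- sample(200, 1); j <- sample(200, 1)
    a <- variant_descriptor(genes[i], protein = ev$short[i])
    b <- variant_descriptor(genes[j], protein = ev$short[j])
    want <- toupper(paste(genes[i], ev$short[i])) ==
            toupper(paste(genes[j], ev$short[j]))
    expect_identical(same_variant(a, b) == "match_protein", want)
  }
})
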