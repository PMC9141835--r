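# Classification and summary surfaces

test_that("format_percent rounds half-up at the requested precision", {
  expect_equal(format_percent(123, 159, decimals = 1), "77.4%")
  expect_equal(format_percent(5, 8), "63%")        # 62.5 rounds up
  expect_equal(format_percent(1, 8, decimals = 1), "12.5%")
  expect_equal(format_percent(0, 5), "0%")
  expect_equal(format_percent(5, 5), "100%")
  expect_equal(percent_value(62, 65), 95)
  expect_error(format_percent(1, 0), class = "panelscope_percent_error")
})

test_that("classification verdicts match the membership oracle", {
  panel <- fixture_panel()
  tab <- toy_cohort(data.frame(
    study_id = "s", sample_id = c("A", "B", "C", "D"),
    gene = c("BRAF", "KRAS", "TP53", "EGFR"),
    protein_short = c("p.V600E", "p.A146T", "p.R175H", ""),
    cdna = c("", "", "", "c.9999A>T")))
  res <- classify(tab, panel)
  expect_equal(nrow(res), 4)
  expect_equal(res$matched, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$reason[3], "gene not on panel")
  expect_equal(res$reason[4], "key not in panel")
  expect_equal(res$match_level[1], "protein")

  # a panel without A146T leaves the record unmatched with its reason
  small <- load_panel(write_tsv_lines(c(
    "gene\tcdna\tprotein\tvendor_label\tclass\tcartridge",
    "KRAS\tc.35G>A\tp.G12D\tG12D\tsnv\tKRAS")))
  res2 <- classify(tab, small)
  expect_false(res2$matched[2])
  expect_equal(res2$reason[2], "key not in panel")

  # empty table -> empty result; counts always partition
  empty <- toy_cohort(data.frame(study_id = character(0),
                                 sample_id = character(0),
                                 gene = character(0)))
  expect_equal(nrow(classify(empty, panel)), 0)
})

test_that("classify agrees with panel_contains record by record", {
  panel <- fixture_panel()
  ev <- random_missense_events(80, seed = 13)
  tab <- toy_cohort(data.frame(
    study_id = "s", sample_id = sprintf("S%03d", 1:80),
    gene = sample(c(panel$genes, "TP53"), 80, replace = TRUE),
    protein_short = ev$short))
  res <- classify(tab, panel)
  for (i in seq_len(80)) {
    single <- panel_contains(panel, record_descriptor(tab, i))
    expect_identical(res$matched[i], single$matched)
    if (single$matched) {
      expect_identical(res$match_level[i], single$match_level)
    } else {
      expect_identical(res$reason[i], single$reason)
    }
  }
})

test_that("variant-level summaries report per-gene counts and percentages", {
  panel <- fixture_panel()
  spec <- list(
    stratum_spec("BRAF", "melanoma", 20, detectable_count = 15,
                 tier = "1", nondetectable_tier = "3"),
    stratum_spec("KRAS", "lung", 10, detectable_count = 0, tier = "3"))
  sim <- generate_cohort(spec, panel, seed = 4)
  res <- classify(sim$cohort, panel)
  vs <- variant_level_summary(res)
  expect_equal(vs$genes$n_records, c(20L, 10L))
  expect_equal(vs$genes$n_detectable, c(15L, 0L))
  expect_equal(vs$genes$pct_detectable, c("75%", "0%"))
  # stratum counts sum to totals
  agg_tier <- tapply(vs$by_tier$n, vs$by_tier$gene, sum)
  expect_equal(as.vector(agg_tier[vs$genes$gene]), vs$genes$n_records)
  agg_diag <- tapply(vs$by_diagnosis$n_records, vs$by_diagnosis$gene, sum)
  expect_equal(as.vector(agg_diag[vs$genes$gene]), vs$genes$n_records)

  ts <- tier_stratified_summary(res)
  expect_equal(ts$n[ts$gene == "BRAF" & ts$tier == "1"], 15L)
  expect_equal(ts$pct_detectable[ts$gene == "BRAF" & ts$tier == "1"], "100%")
  # records without tier annotations form their own stratum
  tab_untiered <- toy_cohort(data.frame(
    study_id = "s", sample_id = c("A", "B"), gene = "BRAF",
    protein_short = c("p.V600E", "p.G469A")))
  ts2 <- tier_stratified_summary(classify(tab_untiered, panel))
  expect_equal(ts2$tier, "unknown")
  expect_equal(ts2$n, 2L)
})

test_that("sample-level summaries count each specimen once", {
  panel <- fixture_panel()
  tab <- toy_cohort(data.frame(
    study_id = "s", sample_id = c("A", "A", "B", "C"),
    gene = c("BRAF", "BRAF", "BRAF", "BRAF"),
    protein_short = c("p.V600E", "p.V600K", "p.G469A", "p.V600E"),
    tier = c("1", "1", "1", "1")))
  ss <- sample_level_summary(classify(tab, panel))
  expect_equal(nrow(ss$samples), 3)
  a <- ss$samples[ss$samples$sample_key == paste("s", "A",
                                                 sep = panelscope:::SAMPLE_KEY_SEP), ]
  expect_true(a$any_detectable)
  expect_equal(a$n_panel_matches, 2L)  # two matches, one positive sample
  expect_true(a$has_extra_mutation)
  bg <- ss$by_gene
  expect_equal(bg$n_samples, 3L)
  expect_equal(bg$n_positive, 2L)
  expect_equal(bg$pct_positive, "67%")
  # invariant: any_detectable <=> n_panel_matches >= 1
  expect_equal(ss$samples$any_detectable, ss$samples$n_panel_matches >= 1)
  # empty input -> empty summary
  empty <- sample_level_summary(classify(toy_cohort(
    data.frame(study_id = character(0), sample_id = character(0),
               gene = character(0))), panel))
  expect_equal(nrow(empty$samples), 0)
})

test_that("disease concordance counts cases, positives and extras", {
  panel <- fixture_panel()
  # single case with a single matched record: 100% positive, no extras
  tab <- toy_cohort(data.frame(
    study_id = "s", sample_id = "A", gene = "BRAF",
    protein_short = "p.V600E", tier = "1",
    diagnosis = "hairy cell leukemia"))
  dc <- disease_concordance(classify(tab, panel),
                            data.frame(gene = "BRAF",
                                       diagnosis = "hairy cell leukemia"))
  expect_equal(dc$n_cases, 1L)
  expect_equal(dc$pct_positive, "100%")
  expect_equal(dc$n_extra, 0L)

  # a pair with zero cases keeps blank percentages
  dc0 <- disease_concordance(classify(tab, panel),
                             data.frame(gene = "KRAS",
                                        diagnosis = "colorectal cancer"))
  expect_equal(dc0$n_cases, 0L)
  expect_equal(dc0$pct_positive, "")

  # extras are assessed over all of the sample's records, any gene;
  # the high-tier column needs an extra AND an undetected tier-1 record
  tab2 <- toy_cohort(data.frame(
    study_id = "s", sample_id = c("A", "A", "B", "C"),
    gene = c("KRAS", "PIK3CA", "KRAS", "KRAS"),
    protein_short = c("p.G12D", "p.H1047R", "p.G12C", "p.Q99Q"),
    tier = c("1", "1", "1", "3"),
    diagnosis = "colorectal cancer"))
  dc2 <- disease_concordance(classify(tab2, panel),
                             data.frame(gene = "KRAS",
                                        diagnosis = "colorectal cancer"))
  expect_equal(dc2$n_cases, 3L)
  expect_equal(dc2$n_positive, 2L)
  expect_equal(dc2$n_extra, 1L)
  expect_equal(dc2$n_extra_high_tier, 1L)
  expect_true(dc2$n_extra_high_tier <= dc2$n_extra)
  expect_equal(dc2$n_positive + dc2$n_negative, dc2$n_cases)
})

test_that("summaries are conserved and permutation-invariant on random cohorts", {
  panel <- fixture_panel()
  for (k in 1:20) {
    spec <- list(
      stratum_spec("BRAF", "cutaneous melanoma", 15 + k,
                   detectable_fraction = 0.7, p_extra = 0.3,
                   p_extra_high_tier = 0.5, tier = "1",
                   label = sprintf("b%d", k)),
      stratum_spec("KRAS", "colorectal cancer", 10 + k,
                   detectable_fraction = 0.9, tier = "1",
                   nondetectable_tier = "3", label = sprintf("k%d", k)))
    sim <- generate_cohort(spec, panel, seed = 100 + k)
    res <- classify(sim$cohort, panel)
    vs <- variant_level_summary(res)
    # conservation: strata partition the records
    expect_equal(sum(vs$genes$n_records), nrow(res))
    expect_equal(sum(vs$by_tier$n), nrow(res))
    expect_equal(sum(vs$by_diagnosis$n_records), nrow(res))
    expect_true(all(vs$genes$n_detectable <= vs$genes$n_records))
    ss <- sample_level_summary(res)
    expect_equal(sum(ss$samples$n_panel_matches + ss$samples$n_nonpanel),
                 nrow(res))
    expect_true(all(ss$samples$n_panel_matches[ss$samples$any_detectable] >= 1))
    expect_true(all((ss$samples$n_panel_matches +
                     ss$samples$n_nonpanel)[ss$samples$has_extra_mutation] >= 2))

    # permutation invariance: shuffled records give identical summaries
    perm <- sample(nrow(sim$cohort$records))
    shuffled <- panelscope:::new_cohort_table(
      sim$cohort$records[perm, , drop = FALSE], sim$cohort$provenance)
    res_p <- classify(shuffled, panel)
    expect_equal(variant_level_summary(res_p)$genes, vs$genes)
    sp <- sample_level_summary(res_p)
    o1 <- ss$samples[order(ss$samples$sample_key), ]
    o2 <- sp$samples[order(sp$samples$sample_key), ]
    rownames(o1) <- rownames(o2) <- NULL
    expect_equal(o2, o1)
    expect_equal(sp$by_gene, ss$by_gene)
  }
})

test_that("adding a panel variant never decreases detectable counts", {
  base_lines <- c(
    "gene\tcdna\tprotein\tvendor_label\tclass\tcartridge",
    "KRAS\tc.35G>A\tp.G12D\tG12D\tsnv\tKRAS",
    "KRAS\tc.34G>T\tp.G12C\tG12C\tsnv\tKRAS")
  panel_small <- load_panel(write_tsv_lines(base_lines))
  panel_big <- load_panel(write_tsv_lines(c(
    base_lines, "KRAS\tc.436G>A\tp.A146T\tA146T\tsnv\tKRAS")))
  tab <- toy_cohort(data.frame(
    study_id = "s", sample_id = sprintf("S%d", 1:6), gene = "KRAS",
    protein_short = c("p.G12D", "p.G12C", "p.A146T", "p.A146T",
                      "p.Q61H", "p.G13D")))
  vs_small <- variant_level_summary(classify(tab, panel_small))$genes
  vs_big <- variant_level_summary(classify(tab, panel_big))$genes
  expect_true(all(vs_big$n_detectable >= vs_small$n_detectable))
  ss_small <- sample_level_summary(classify(tab, panel_small))$by_gene
  ss_big <- sample_level_summary(classify(tab, panel_big))$by_gene
  expect_true(all(ss_big$n_positive >= ss_small$n_positive))
})
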