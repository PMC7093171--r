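test_that("relative abundance and percentages follow their definitions", {
  expect_equal(relative_abundance(10, 2e6), 5)
  expect_equal(relative_abundance(0, 12345), 0)
  expect_equal(relative_abundance(247, 997000), 247 / 0.997)
  expect_error(relative_abundance(5, 0), "positive")
  expect_equal(round(type_percentage(273518, 680635), 2), 40.19)
  expect_equal(round(type_percentage(148175, 680635), 2), 21.77)
  expect_equal(type_percentage(42, 42), 100)
  expect_error(type_percentage(3, 0), "positive")
})

test_that("GC content pools locus spans and complements AT content", {
  expect_equal(gc_content(data.frame(motif = "A", length_bp = 12L)), 0)
  expect_equal(gc_content(data.frame(motif = "ACG", length_bp = 15L)),
               200 / 3)
  mixed <- data.frame(motif = c("AT", "CG"), length_bp = c(14L, 14L))
  expect_equal(gc_content(mixed), 50)
  expect_true(is.na(gc_content(data.frame(motif = character(0),
                                          length_bp = integer(0)))))
  # GC + AT = 100 on arbitrary locus sets
  set.seed(2)
  loci <- data.frame(motif = replicate(30, random_dna(sample(1:6, 1))),
                     length_bp = sample(12:60, 30, replace = TRUE))
  at <- sum((1 - vapply(strsplit(loci$motif, ""), function(b)
    mean(b %in% c("G", "C")), numeric(1))) * loci$length_bp) /
    sum(loci$length_bp) * 100
  expect_equal(gc_content(loci) + at, 100)
})

test_that("motif ranking orders by abundance with alphabetical ties", {
  loci <- data.frame(
    unit_length = 1L,
    canonical_motif = rep(c("A", "C"), c(30, 10)),
    start = 1L)
  r <- motif_ranking(loci, 1e6)
  expect_identical(r$canonical_motif, c("A", "C"))
  expect_equal(r$n_loci, c(30L, 10L))
  expect_equal(r$relative_abundance, c(30, 10))
  expect_equal(nrow(motif_ranking(loci[0, ], 1e6)), 0L)
  # tie broken lexicographically
  tie <- data.frame(unit_length = 2L,
                    canonical_motif = rep(c("AT", "AC"), each = 5),
                    start = 1L)
  expect_identical(motif_ranking(tie, 1e6)$canonical_motif, c("AC", "AT"))
})

test_that("RCN histograms are exact and conserve counts", {
  loci <- data.frame(rcn = c(7L, 7L, 9L))
  h <- rcn_distribution(loci, by = character(0))
  expect_equal(h$rcn, c(7L, 9L))
  expect_equal(h$n, c(2L, 1L))
  set.seed(30)
  big <- data.frame(unit_length = sample(1:6, 200, TRUE),
                    rcn = sample(4:30, 200, TRUE))
  h2 <- rcn_distribution(big, by = "unit_length")
  expect_equal(sum(h2$n), 200L)
  for (k in unique(big$unit_length)) {
    expect_equal(sum(h2$n[h2$unit_length == k]), sum(big$unit_length == k))
  }
})

test_that("CV of RCN uses the sample SD and is scale invariant", {
  expect_equal(cv_of_rcn(c(8, 8, 8))$cv_percent, 0)
  expect_equal(cv_of_rcn(c(8, 10, 12))$cv_percent, 20)
  expect_equal(cv_of_rcn(c(8, 10, 12), sd_type = "population")$cv_percent,
               sqrt(8 / 3) / 10 * 100)
  one <- cv_of_rcn(7)
  expect_true(is.na(one$cv_percent))
  expect_match(one$reason, "fewer than two")
  set.seed(12)
  for (i in 1:20) {
    v <- sample(4:40, sample(3:30, 1), replace = TRUE)
    s <- stats::runif(1, 0.1, 9)
    expect_equal(cv_of_rcn(v * s)$cv_percent, cv_of_rcn(v)$cv_percent)
  }
})

test_that("the per-type summary reproduces published survey arithmetic", {
  pub <- fmd_survey_table("by_type")
  total <- sum(pub$n_loci)
  expect_equal(total, 680635)
  expect_equal(round(type_percentage(pub$n_loci, total), 2),
               pub$percentage)
  expect_equal(sum(pub$percentage), 100, tolerance = 0.02)
})

test_that("summary tables are internally consistent on mined data", {
  set.seed(77)
  spec <- genome_sim_spec(n_sequences = 2, seq_length = 40000,
                          genes_per_seq = 4,
                          n_ssr = c(FIVE_UTR = 3, CDS = 3, INTRON = 15,
                                    THREE_UTR = 4, INTERGENIC = 20,
                                    TE = 5),
                          seed = 3)
  sim <- simulate_genome(spec)
  loci <- assign_region(find_perfect_ssrs(sim$sequences), sim$model)
  tabs <- build_summary_tables(loci, sim$model)
  bt <- tabs$by_type
  expect_equal(bt$n_loci[bt$type == "Total"], nrow(loci))
  expect_equal(sum(bt$n_loci[bt$type != "Total"]), nrow(loci))
  expect_equal(sum(bt$percentage[bt$type != "Total"]), 100)
  br <- tabs$by_region
  base <- br[br$region != "TE" & br$type == "Total", ]
  expect_equal(sum(base$n_loci), nrow(loci))
  # per-region per-type counts sum to the per-type totals
  for (k in c("Mono", "Di", "Tri", "Tetra", "Penta", "Hexa")) {
    expect_equal(sum(br$n_loci[br$type == k & br$region != "TE"]),
                 bt$n_loci[bt$type == k])
  }
  # empty locus set gives an all-zero but well-formed table
  empty <- build_summary_tables(assign_region(loci[0, 1:8], sim$model),
                                sim$model)
  expect_equal(sum(empty$by_type$n_loci), 0L)
  expect_equal(nrow(empty$by_type), 7L)
})
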