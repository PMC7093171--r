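gt_from <- function(calls, locus = "L1") {
  genotype_table(matrix(calls, length(calls), 1,
                        dimnames = list(paste0("i", seq_along(calls)),
                                        locus)))
}

test_that("allele frequencies and observed heterozygosity count correctly", {
  gt <- gt_from(c("A/A", "A/B"))
  expect_equal(allele_frequencies(gt, "L1"), c(A = 0.75, B = 0.25))
  expect_equal(observed_heterozygosity(gt, "L1"), 0.5)
  mono <- gt_from(c("A/A", "A/A"))
  expect_equal(allele_frequencies(mono, "L1"), c(A = 1))
  expect_equal(observed_heterozygosity(mono, "L1"), 0)
  # random tables vs a direct counting oracle
  set.seed(8)
  for (i in 1:10) {
    al <- letters[1:sample(2:5, 1)]
    calls <- paste0(sample(al, 40, TRUE), "/", sample(al, 40, TRUE))
    gt2 <- gt_from(calls)
    tab <- table(unlist(strsplit(calls, "/")))
    expect_equal(allele_frequencies(gt2, "L1"),
                 setNames(as.numeric(tab) / 80, names(tab)))
    parts <- strsplit(calls, "/")
    expect_equal(observed_heterozygosity(gt2, "L1"),
                 mean(vapply(parts, function(p) p[1] != p[2], logical(1))))
  }
  expect_error(allele_frequencies(gt_from(NA_character_), "L1"),
               "no typed")
  expect_error(allele_frequencies(gt, "nope"), "not present")
})

test_that("expected heterozygosity applies Nei's small-sample correction", {
  expect_equal(expected_heterozygosity(c(1), 10), 0)
  # {A/A, A/B}: gene diversity 0.375, times 2n/(2n-1) = 4/3
  expect_equal(expected_heterozygosity(c(0.75, 0.25), 2), 0.5)
  expect_equal(expected_heterozygosity(c(0.5, 0.5), 1e9), 0.5,
               tolerance = 1e-6)
  expect_equal(expected_heterozygosity(c(0.5, 0.5), unbiased = FALSE), 0.5)
  expect_error(expected_heterozygosity(c(0.6, 0.3), 5), "sum to 1")
})

test_that("PIC follows Botstein's formula", {
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(c(1)), 0)
  expect_equal(pic(rep(0.25, 4)), 0.703125)
  # double-sum oracle on random frequency vectors
  set.seed(4)
  for (i in 1:10) {
    p <- stats::runif(sample(2:6, 1))
    p <- p / sum(p)
    acc <- 1 - sum(p^2)
    for (a in seq_along(p)) {
      for (b in seq_along(p)) {
        if (a < b) acc <- acc - 2 * p[a]^2 * p[b]^2
      }
    }
    expect_equal(pic(p), acc)
    expect_lte(pic(p), 1 - sum(p^2))
  }
})

test_that("allelic richness matches exhaustive subsample enumeration", {
  # 2N = 8 copies with counts {5, 2, 1}
  gt <- gt_from(c("a/a", "a/a", "a/b", "b/c"))
  copies <- c(rep("a", 5), rep("b", 2), "c")
  for (g in c(2, 4, 6)) {
    brute <- mean(apply(utils::combn(8, g), 2,
                        function(ix) length(unique(copies[ix]))))
    expect_equal(allelic_richness(gt, "L1", g), brute)
  }
  expect_equal(allelic_richness(gt, "L1", 8), 3)  # k at g = 2N
  mono <- gt_from(c("a/a", "a/a"))
  expect_equal(allelic_richness(mono, "L1", 2), 1)
  # non-decreasing in g
  ar <- vapply(1:8, function(g) allelic_richness(gt, "L1", g), numeric(1))
  expect_true(all(diff(ar) > -1e-12))
  expect_error(allelic_richness(gt, "L1", 9), "between 1 and 2N")
})

test_that("the HWE exact test matches enumeration oracles", {
  expect_equal(hwe_exact_test(gt_from(rep("a/a", 6)), "L1")$p_value, 1)
  # diallelic cases vs the direct heterozygote-count oracle
  cases <- list(c(3, 1, 1), c(1, 8, 1), c(5, 0, 5), c(2, 2, 1),
                c(10, 5, 3))
  for (cs in cases) {
    calls <- c(rep("a/a", cs[1]), rep("a/b", cs[2]), rep("b/b", cs[3]))
    got <- hwe_exact_test(gt_from(calls), "L1")
    expect_equal(got$method, "enumeration")
    expect_equal(got$p_value, oracle_hwe2(cs[1], cs[2], cs[3]),
                 tolerance = 1e-12)
  }
  # Monte-Carlo approximates the enumerated P on a 3-allele locus
  set.seed(17)
  calls <- paste0(sample(c("x", "y", "z"), 25, TRUE), "/",
                  sample(c("x", "y", "z"), 25, TRUE))
  gt <- gt_from(calls)
  pe <- hwe_exact_test(gt, "L1")
  pm <- hwe_exact_test(gt, "L1", enum_limit = 1, mc_reps = 50000,
                       seed = 42)
  expect_equal(pe$method, "enumeration")
  expect_equal(pm$method, "monte-carlo")
  expect_equal(pm$p_value, pe$p_value, tolerance = 0.02)
})

test_that("statistics are invariant to individual and label permutations", {
  set.seed(23)
  calls <- paste0(sample(c("a", "b", "c"), 30, TRUE), "/",
                  sample(c("a", "b", "c"), 30, TRUE))
  gt <- gt_from(calls)
  perm <- gt_from(sample(calls))
  swapped <- gt_from(chartr("abc", "cab", calls))
  for (f in list(observed_heterozygosity,
                 function(g, l) expected_heterozygosity(
                   allele_frequencies(g, l), 30),
                 function(g, l) pic(allele_frequencies(g, l)),
                 function(g, l) allelic_richness(g, l, 10),
                 function(g, l) hwe_exact_test(g, l)$p_value)) {
    expect_equal(f(perm, "L1"), f(gt, "L1"))
    expect_equal(f(swapped, "L1"), f(gt, "L1"))
  }
})

test_that("simulated HWE genotypes recover their parameters", {
  spec <- genotype_sim_spec(n_individuals = 10000,
                            freqs = list(L1 = c(a = 0.5, b = 0.5)),
                            seed = 31)
  gt <- simulate_genotypes(spec)
  ho <- observed_heterozygosity(gt, "L1")
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(ho - 0.5), 3 * se)
  fr <- allele_frequencies(gt, "L1")
  expect_lt(abs(fr[["a"]] - 0.5), 3 * sqrt(0.5 * 0.5 / 20000))
  # full inbreeding: homozygotes only
  f1 <- simulate_genotypes(genotype_sim_spec(
    n_individuals = 200, freqs = list(L1 = c(a = 0.3, b = 0.7)),
    f = 0.999999, seed = 2))
  expect_equal(observed_heterozygosity(f1, "L1"), 0)
  # reproducibility and missing-data masking
  s <- genotype_sim_spec(n_individuals = 50,
                         freqs = list(L1 = c(a = 0.4, b = 0.6)),
                         missing_rate = 0.2, seed = 9)
  expect_identical(unclass(simulate_genotypes(s)),
                   unclass(simulate_genotypes(s)))
  expect_gt(sum(is.na(simulate_genotypes(s))), 0)
})

test_that("per-locus and panel summaries assemble correctly", {
  spec <- genotype_sim_spec(
    n_individuals = 36,
    freqs = list(A = c(x = 0.5, y = 0.5),
                 B = c(x = 0.7, y = 0.2, z = 0.1),
                 C = c(x = 1)),
    seed = 77)
  gt <- simulate_genotypes(spec)
  d <- locus_diversity(gt, mc_reps = 2000)
  expect_equal(d$locus, c("A", "B", "C"))
  expect_equal(d$N, rep(36L, 3))
  expect_true(all(d$Ho >= 0 & d$Ho <= 1))
  expect_true(all(d$PIC <= d$He + 1e-9))
  expect_equal(d$k[3], 1L)
  expect_equal(d$PIC[3], 0)
  expect_equal(d$hwe_p[3], 1)
  ps <- panel_summary(d)
  expect_equal(ps$total_alleles, sum(d$k))
  expect_equal(ps$Ho$mean, mean(d$Ho))
  one <- panel_summary(d[1, ])
  expect_equal(one$Ho$mean, d$Ho[1])
  expect_equal(one$Ho$min, one$Ho$max)
})

test_that("the published marker panel reproduces its printed aggregates", {
  pub <- fmd_survey_table("markers")
  kept <- pub[!pub$discarded, ]
  expect_equal(nrow(kept), 21L)
  ps <- panel_summary(kept)
  expect_equal(ps$total_alleles, 76)
  expect_equal(round(ps$Ho$mean, 3), 0.423)
  expect_equal(round(ps$He$mean, 3), 0.445)
  expect_equal(round(ps$Ar$mean, 3), 3.609)
  expect_equal(round(ps$PIC$mean, 3), 0.397)
  expect_equal(sum(pub$k), 83)  # including the discarded locus
})

test_that("genotype tables round-trip through TSV", {
  spec <- genotype_sim_spec(n_individuals = 12,
                            freqs = list(L1 = c(a = 0.5, b = 0.5),
                                         L2 = c(p = 0.9, q = 0.1)),
                            missing_rate = 0.1, seed = 5)
  gt <- simulate_genotypes(spec)
  f <- tempfile(fileext = ".tsv")
  write_genotypes(gt, f, header_comments = "seed: 5")
  back <- read_genotypes(f)
  expect_identical(unclass(back), unclass(gt))
  expect_error(read_genotypes({
    f2 <- tempfile(); writeLines("x\ty\n1/1\t2/2", f2); f2
  }), "id")
})
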