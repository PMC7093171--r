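test_that("a toy gene partitions into the expected UTR/CDS/intron pieces", {
  gff <- write_toy_gff(tempfile(fileext = ".gff3"))
  m <- build_region_model(gff, NULL, c(s1 = 1000))
  lens <- region_lengths(m)
  expect_equal(unname(lens[c("FIVE_UTR", "CDS", "INTRON", "THREE_UTR",
                             "INTERGENIC")]),
               c(40, 80, 120, 60, 700))
  gr <- function(x) as.data.frame(m$regions[[x]])[, c("start", "end")]
  expect_equal(gr("FIVE_UTR"), data.frame(start = 101L, end = 140L))
  expect_equal(gr("INTRON"), data.frame(start = 181L, end = 300L))
  expect_equal(gr("THREE_UTR"), data.frame(start = 341L, end = 400L))
  expect_equal(gr("CDS"),
               data.frame(start = c(141L, 301L), end = c(180L, 340L)))
})

test_that("strand flip swaps the UTR side labels", {
  plus <- build_region_model(write_toy_gff(tempfile(), "+"), NULL,
                             c(s1 = 1000))
  minus <- build_region_model(write_toy_gff(tempfile(), "-"), NULL,
                              c(s1 = 1000))
  expect_equal(as.data.frame(minus$regions$FIVE_UTR)[, c("start", "end")],
               as.data.frame(plus$regions$THREE_UTR)[, c("start", "end")])
  expect_equal(as.data.frame(minus$regions$THREE_UTR)[, c("start", "end")],
               as.data.frame(plus$regions$FIVE_UTR)[, c("start", "end")])
  expect_equal(region_lengths(minus)[["INTRON"]], 120)
})

test_that("an empty annotation leaves everything intergenic", {
  gff <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", gff)
  m <- build_region_model(gff, NULL, c(s1 = 1000))
  expect_equal(region_lengths(m)[["INTERGENIC"]], 1000)
  expect_equal(sum(region_lengths(m)[c("FIVE_UTR", "CDS", "INTRON",
                                       "THREE_UTR")]), 0)
})

test_that("the five base classes always tile the genome", {
  set.seed(11)
  for (i in 1:5) {
    spec <- genome_sim_spec(n_sequences = 2, seq_length = 30000,
                            genes_per_seq = 3,
                            n_ssr = c(FIVE_UTR = 0, CDS = 0, INTRON = 0,
                                      THREE_UTR = 0, INTERGENIC = 0,
                                      TE = 0),
                            seed = i)
    sim <- simulate_genome(spec)
    lens <- region_lengths(sim$model)
    expect_equal(sum(lens[c("FIVE_UTR", "CDS", "INTRON", "THREE_UTR",
                            "INTERGENIC")]),
                 sim$model$genome_length_bp)
  }
})

test_that("assignment uses the start coordinate and matches a point oracle", {
  gff <- write_toy_gff(tempfile(fileext = ".gff3"))
  te <- data.frame(seq_id = "s1", start = 250, end = 320)
  m <- build_region_model(gff, te, c(s1 = 1000))
  mk <- function(start, end) {
    data.frame(seq_id = "s1", start = start, end = end, unit_length = 1L,
               motif = "A", canonical_motif = "A",
               rcn = end - start + 1L, length_bp = end - start + 1L)
  }
  expect_equal(as.character(assign_region(mk(150, 165), m)$region), "CDS")
  # starts 1 bp before the gene, extends into it: counted intergenic
  expect_equal(as.character(assign_region(mk(100, 120), m)$region),
               "INTERGENIC")
  expect_true(assign_region(mk(260, 275), m)$in_te)
  expect_false(assign_region(mk(150, 165), m)$in_te)
  expect_error(assign_region(mk(10, 20) |>
                               transform(seq_id = "zz"), m), "unknown")

  # random starts vs a direct point-in-interval oracle
  set.seed(5)
  classes <- list(FIVE_UTR = c(101, 140), INTRON = c(181, 300),
                  THREE_UTR = c(341, 400))
  starts <- sample(1000, 300, replace = TRUE)
  got <- assign_region(mk(starts, pmin(starts + 10, 1000)), m)
  want <- vapply(starts, function(p) {
    if (p >= 141 && p <= 180 || p >= 301 && p <= 340) return("CDS")
    for (cl in names(classes)) {
      if (p >= classes[[cl]][1] && p <= classes[[cl]][2]) return(cl)
    }
    "INTERGENIC"
  }, character(1))
  expect_identical(as.character(got$region), want)
  expect_identical(got$in_te, starts >= 250 & starts <= 320)
})

test_that("annotation validation reports structured errors", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "s1\ttoy\tgene\t101\t200\t.\t+\t.\tID=g1",
               "s1\ttoy\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=g1",
               "s1\ttoy\texon\t90\t200\t.\t+\t.\tID=e1;Parent=t1"), gff)
  expect_error(build_region_model(gff, NULL, c(s1 = 1000)),
               "outside its gene bounds")
  gff2 <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "s9\ttoy\tgene\t101\t200\t.\t+\t.\tID=g1"), gff2)
  expect_error(build_region_model(gff2, NULL, c(s1 = 1000)), "unknown")
  expect_error(build_region_model(gff, NULL, c(s1 = 150)), "past the end")
})
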