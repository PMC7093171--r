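# Independent brute-force oracles, deliberately written as plain loops
# sharing no code with the package internals.

# divisor-check primitivity, independent of ssrmine::is_primitive
oracle_primitive <- function(m) {
  k <- nchar(m)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L) {
      unit <- substr(m, 1L, d)
      if (paste(rep(unit, k / d), collapse = "") == m) return(FALSE)
    }
  }
  TRUE
}

# exhaustive per-(start, unit_length) scan with explicit extension,
# then the documented greedy overlap resolution
oracle_mine <- function(s, thresholds = c(12L, 7L, 5L, 4L, 4L, 4L)) {
  s <- toupper(s)
  x <- utf8ToInt(s)
  n <- length(x)
  N <- utf8ToInt("N")
  cand <- list()
  for (k in 1:6) {
    eq <- if (n > k) {
      x[seq_len(n - k)] == x[seq_len(n - k) + k] &
        x[seq_len(n - k)] != N & x[seq_len(n - k) + k] != N
    } else logical(0)
    for (st in seq_len(max(0L, n - k * thresholds[k] + 1L))) {
      if (st > 1L && isTRUE(eq[st - 1L])) next  # extensible left
      j <- st
      while (j <= n - k && eq[j]) j <- j + 1L
      total <- (j - st) + k
      rcn <- total %/% k
      if (rcn < thresholds[k]) next
      motif <- substr(s, st, st + k - 1L)
      if (grepl("N", motif, fixed = TRUE)) next
      if (!oracle_primitive(motif)) next
      cand[[length(cand) + 1L]] <- data.frame(
        start = st, unit_length = k, motif = motif, rcn = rcn,
        length_bp = k * rcn, end = st + k * rcn - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(start = integer(0), unit_length = integer(0),
                      motif = character(0), rcn = integer(0),
                      length_bp = integer(0), end = integer(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$start, cand$unit_length, -cand$length_bp), ]
  keep <- logical(nrow(cand))
  last_end <- 0L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- cand$end[i]
    }
  }
  out <- cand[keep, , drop = FALSE]
  row.names(out) <- NULL
  out
}

random_dna <- function(n, gc = 0.45) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

revcomp_str <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# toy single-gene GFF3 (the worked interval-arithmetic example)
write_toy_gff <- function(path, strand = "+") {
  writeLines(c(
    "##gff-version 3",
    sprintf("s1\ttoy\tgene\t101\t400\t.\t%s\t.\tID=g1", strand),
    sprintf("s1\ttoy\tmRNA\t101\t400\t.\t%s\t.\tID=t1;Parent=g1", strand),
    sprintf("s1\ttoy\texon\t101\t180\t.\t%s\t.\tID=e1;Parent=t1", strand),
    sprintf("s1\ttoy\texon\t301\t400\t.\t%s\t.\tID=e2;Parent=t1", strand),
    sprintf("s1\ttoy\tCDS\t141\t180\t.\t%s\t0\tID=c1;Parent=t1", strand),
    sprintf("s1\ttoy\tCDS\t301\t340\t.\t%s\t0\tID=c2;Parent=t1", strand)),
    path)
  path
}

# direct 2-allele HWE exact-probabilities oracle over heterozygote counts
oracle_hwe2 <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  lp <- function(h) {
    na <- (nA - h) / 2
    nb <- (2 * n - nA - h) / 2
    if (h < 0 || na < 0 || nb < 0 || na != floor(na)) return(-Inf)
    lfactorial(n) - lfactorial(na) - lfactorial(h) - lfactorial(nb) +
      h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) -
      lfactorial(2 * n)
  }
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  ps <- vapply(hs, lp, numeric(1))
  sum(exp(ps[ps <= lp(nAB) + 1e-9]))
}
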