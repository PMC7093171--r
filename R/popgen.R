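#' Read a diploid co-dominant genotype table
#'
#' Expects a TSV with one row per individual: an `id` column followed by
#' one column per locus holding `"a/b"` allele pairs (`"NA"`, `""` or
#' `"./."` for missing). Allele labels are arbitrary strings (typically
#' fragment lengths).
#'
#' @param path TSV path.
#' @return A `genotype_table`: character matrix (individuals x loci) of
#'   `"a/b"` calls with `NA` for missing.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE, colClasses = "character")
  if (!"id" %in% names(df)) {
    stop("genotype table must have an 'id' column", call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  rownames(m) <- df$id
  genotype_table(m)
}

#' Construct a genotype table
#'
#' @param calls Character matrix of `"a/b"` calls, rows = individuals,
#'   columns = loci; `NA`, `""` or `"./."` mark missing calls.
#' @return The matrix with class `genotype_table`.
#' @export
genotype_table <- function(calls) {
  calls[calls %in% c("", "NA", "./.", "NA/NA")] <- NA_character_
  ok <- is.na(calls) | grepl("^[^/]+/[^/]+$", calls)
  if (!all(ok)) {
    stop("malformed genotype call '", calls[!ok][1],
         "' (expected 'a/b' or missing)", call. = FALSE)
  }
  structure(calls, class = c("genotype_table", class(calls)))
}

#' Write a genotype table as TSV
#'
#' @param gt A `genotype_table`.
#' @param path Output file.
#' @param header_comments Optional `#` comment lines (e.g. the seed).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path, header_comments = NULL) {
  df <- data.frame(id = rownames(gt), unclass(gt), check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_comments)) writeLines(paste0("# ", header_comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

locus_calls <- function(gt, locus) {
  if (!locus %in% colnames(gt)) {
    stop("locus '", locus, "' not present in the genotype table",
         call. = FALSE)
  }
  calls <- gt[, locus]
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0L) {
    stop("locus '", locus, "' has no typed individuals", call. = FALSE)
  }
  do.call(rbind, strsplit(calls, "/", fixed = TRUE))
}

#' Allele frequencies at one locus
#'
#' @param gt A `genotype_table`.
#' @param locus Locus (column) name.
#' @return Named numeric vector of frequencies over the 2N typed gene
#'   copies, summing to 1, sorted by allele label.
#' @export
allele_frequencies <- function(gt, locus) {
  al <- as.vector(locus_calls(gt, locus))
  tab <- table(al)
  stats::setNames(as.numeric(tab) / length(al), names(tab))
}

#' Observed heterozygosity at one locus
#'
#' Fraction of typed individuals carrying two distinct alleles.
#'
#' @inheritParams allele_frequencies
#' @return Proportion in `[0, 1]`.
#' @export
observed_heterozygosity <- function(gt, locus) {
  cc <- locus_calls(gt, locus)
  mean(cc[, 1] != cc[, 2])
}

#' Expected heterozygosity (gene diversity)
#'
#' Nei's unbiased estimator `2n/(2n-1) * (1 - sum(p^2))` by default; the
#' plain gene diversity `1 - sum(p^2)` is available since published
#' tables do not always state which convention they report.
#'
#' @param freqs Allele frequency vector summing to 1.
#' @param n Number of typed individuals (required for the unbiased
#'   form).
#' @param unbiased Apply the small-sample correction (default TRUE).
#' @return He in `[0, 1)`.
#' @export
expected_heterozygosity <- function(freqs, n = NULL, unbiased = TRUE) {
  check_freqs(freqs)
  h <- 1 - sum(freqs^2)
  if (!unbiased) return(h)
  if (is.null(n) || n < 1) {
    stop("n (typed individuals) is required for the unbiased estimator",
         call. = FALSE)
  }
  2 * n / (2 * n - 1) * h
}

check_freqs <- function(freqs) {
  if (length(freqs) == 0L) stop("empty frequency vector", call. = FALSE)
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-8) {
    stop("allele frequencies must be non-negative and sum to 1",
         call. = FALSE)
  }
  invisible(freqs)
}

#' Polymorphism information content
#'
#' Botstein's PIC: `1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param freqs Allele frequency vector summing to 1.
#' @return PIC in `[0, 1)`.
#' @examples
#' pic(c(0.5, 0.5))  # 0.375
#' @export
pic <- function(freqs) {
  check_freqs(freqs)
  p2 <- freqs^2
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - sum(p2) - (sum(p2)^2 - sum(p2^2))
}

#' Allelic richness by rarefaction
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies drawn without replacement from the 2N observed copies
#' (hypergeometric rarefaction, the FSTAT convention):
#' `sum_a [1 - C(2N - N_a, g) / C(2N, g)]`.
#'
#' @inheritParams allele_frequencies
#' @param g Rarefaction size in gene copies, `1 <= g <= 2N`.
#' @return Ar in `[1, k]`; equals the observed allele count at `g = 2N`.
#' @export
allelic_richness <- function(gt, locus, g) {
  counts <- table(as.vector(locus_calls(gt, locus)))
  ar_from_counts(as.numeric(counts), g)
}

ar_from_counts <- function(counts, g) {
  n2 <- sum(counts)
  if (g > n2 || g < 1) {
    stop("rarefaction size g must be between 1 and 2N", call. = FALSE)
  }
  sum(1 - exp(lchoose(n2 - counts, g) - lchoose(n2, g)))
}

## ---- Hardy-Weinberg exact test ------------------------------------------

## log conditional probability of a genotype array given allele counts:
## log[ N! prod(n_a!) 2^h / ((2N)! prod(n_ij!)) ]
log_array_prob <- function(geno_counts, het_mask, allele_counts) {
  n <- sum(geno_counts)
  lfactorial(n) + sum(lfactorial(allele_counts)) -
    lfactorial(2 * n) + sum(geno_counts[het_mask]) * log(2) -
    sum(lfactorial(geno_counts))
}

## genotype cell index for ordered pair (a <= b) among k alleles,
## cells enumerated (1,1),(1,2),..,(1,k),(2,2),..,(k,k)
pair_index <- function(a, b, k) {
  (a - 1) * (2 * k - a + 2) / 2 + (b - a + 1)
}

## Enumerate all genotype arrays compatible with the allele counts.
## Returns matrix of arrays (rows) or NULL when the leaf budget is hit.
enumerate_arrays <- function(allele_counts, max_arrays) {
  k <- length(allele_counts)
  cells <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  out <- list()
  overflow <- FALSE
  rec <- function(ci, rem, acc) {
    if (overflow) return()
    if (ci > nrow(cells)) {
      if (all(rem == 0)) {
        if (length(out) >= max_arrays) {
          overflow <<- TRUE
        } else {
          out[[length(out) + 1L]] <<- acc
        }
      }
      return()
    }
    a <- cells[ci, 1]; b <- cells[ci, 2]
    hi <- if (a == b) rem[a] %/% 2 else min(rem[a], rem[b])
    for (m in 0:hi) {
      rem2 <- rem
      if (a == b) {
        rem2[a] <- rem2[a] - 2L * m
      } else {
        rem2[a] <- rem2[a] - m
        rem2[b] <- rem2[b] - m
      }
      # prune: once past the last cell touching an allele its count must be 0
      if (ci == max(which(cells[, 1] == a | cells[, 2] == a)) &&
          rem2[a] != 0) next
      rec(ci + 1L, rem2, c(acc, m))
      if (overflow) return()
    }
  }
  rec(1L, allele_counts, integer(0))
  if (overflow) return(NULL)
  do.call(rbind, out)
}

#' Hardy-Weinberg exact test at one locus
#'
#' Exact conditional test: given the observed allele counts, the P value
#' is the summed probability of all genotype arrays no more probable
#' than the observed one (the exact probabilities test). The array space
#' is enumerated completely when it holds at most `enum_limit` arrays
#' (always feasible for two alleles); otherwise a Monte-Carlo estimate
#' over random pairings of the gene copies is used, with an explicit
#' seed and the add-one correction so that P is in (0, 1]. Monomorphic
#' loci return P = 1 by convention.
#'
#' @inheritParams allele_frequencies
#' @param mc_reps Monte-Carlo replicates when enumeration is infeasible.
#' @param seed Integer seed for the Monte-Carlo path.
#' @param enum_limit Largest array space enumerated exactly.
#' @return List: `p_value`, `method` (`"enumeration"` or
#'   `"monte-carlo"`), `n_typed`, `k`.
#' @export
hwe_exact_test <- function(gt, locus, mc_reps = 1e5, seed = 1L,
                           enum_limit = 20000L) {
  cc <- locus_calls(gt, locus)
  alleles <- sort(unique(as.vector(cc)))
  k <- length(alleles)
  n <- nrow(cc)
  if (k == 1L) {
    return(list(p_value = 1, method = "monomorphic", n_typed = n, k = 1L))
  }
  a <- match(cc[, 1], alleles)
  b <- match(cc[, 2], alleles)
  lo <- pmin(a, b); hi <- pmax(a, b)
  ncell <- k * (k + 1) / 2
  obs <- tabulate(pair_index(lo, hi, k), nbins = ncell)
  cells <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  het_mask <- cells[, 1] != cells[, 2]
  allele_counts <- tabulate(c(a, b), nbins = k)
  obs_lp <- log_array_prob(obs, het_mask, allele_counts)
  tol <- 1e-9
  arrays <- enumerate_arrays(allele_counts, enum_limit)
  if (!is.null(arrays)) {
    lp <- apply(arrays, 1, log_array_prob, het_mask = het_mask,
                allele_counts = allele_counts)
    p <- sum(exp(lp[lp <= obs_lp + tol]))
    # lp sums to ~1 over the full space; normalize for numeric safety
    p <- min(1, p / sum(exp(lp)))
    return(list(p_value = p, method = "enumeration", n_typed = n, k = k))
  }
  copies <- c(a, b)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  hits <- 0L
  for (r in seq_len(mc_reps)) {
    perm <- sample(copies)
    g1 <- perm[seq(1L, 2L * n, by = 2L)]
    g2 <- perm[seq(2L, 2L * n, by = 2L)]
    sim <- tabulate(pair_index(pmin(g1, g2), pmax(g1, g2), k),
                    nbins = ncell)
    if (log_array_prob(sim, het_mask, allele_counts) <= obs_lp + tol) {
      hits <- hits + 1L
    }
  }
  list(p_value = (hits + 1) / (mc_reps + 1), method = "monte-carlo",
       n_typed = n, k = k)
}

#' Per-locus diversity statistics
#'
#' Computes, for every locus of a genotype table, the typed sample size
#' N, allele count k, observed and expected heterozygosity, allelic
#' richness rarefied to `g` gene copies, PIC, and the Hardy-Weinberg
#' exact-test P value.
#'
#' @param gt A `genotype_table`.
#' @param g Rarefaction size in gene copies; default is the FSTAT
#'   convention, the minimum 2N across loci.
#' @param unbiased_he Use Nei's unbiased He (default TRUE).
#' @param hwe_alpha Significance threshold used for the `hwe_flag`
#'   column (default 0.01; flagged loci are candidates for exclusion).
#' @param mc_reps,seed,enum_limit Passed to [hwe_exact_test()].
#' @return Data frame with one row per locus: `locus`, `N`, `k`, `Ho`,
#'   `He`, `Ar`, `PIC`, `hwe_p`, `hwe_flag`.
#' @export
locus_diversity <- function(gt, g = NULL, unbiased_he = TRUE,
                            hwe_alpha = 0.01, mc_reps = 1e5, seed = 1L,
                            enum_limit = 20000L) {
  loci <- colnames(gt)
  if (length(loci) == 0L) stop("genotype table has no loci", call. = FALSE)
  n_typed <- vapply(loci, function(l) sum(!is.na(gt[, l])), integer(1))
  if (is.null(g)) g <- 2L * min(n_typed)
  rows <- lapply(seq_along(loci), function(i) {
    l <- loci[i]
    fr <- allele_frequencies(gt, l)
    hw <- hwe_exact_test(gt, l, mc_reps = mc_reps, seed = seed + i,
                         enum_limit = enum_limit)
    data.frame(locus = l, N = n_typed[[i]], k = length(fr),
               Ho = observed_heterozygosity(gt, l),
               He = expected_heterozygosity(fr, n_typed[[i]],
                                            unbiased = unbiased_he),
               Ar = allelic_richness(gt, l, min(g, 2L * n_typed[[i]])),
               PIC = pic(fr), hwe_p = hw$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$hwe_flag <- out$hwe_p < hwe_alpha
  row.names(out) <- NULL
  out
}

#' Panel-level summary of per-locus diversity
#'
#' Arithmetic means and ranges of Ho, He, Ar and PIC, and the total
#' allele count across loci.
#'
#' @param stats Data frame with columns `k`, `Ho`, `He`, `Ar`, `PIC`
#'   (e.g. from [locus_diversity()] or a published marker table).
#' @return List: `n_loci`, `total_alleles`, and per-statistic `mean`,
#'   `min`, `max`.
#' @export
panel_summary <- function(stats) {
  if (nrow(stats) == 0L) stop("empty marker panel", call. = FALSE)
  one <- function(col) list(mean = mean(stats[[col]]),
                            min = min(stats[[col]]),
                            max = max(stats[[col]]))
  list(n_loci = nrow(stats), total_alleles = sum(stats$k),
       Ho = one("Ho"), He = one("He"), Ar = one("Ar"), PIC = one("PIC"))
}
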