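#' Relative abundance of SSR loci
#'
#' Loci per megabase of the sequence class searched, the normalization
#' that makes counts comparable across regions of unequal size.
#'
#' @param n_loci Number of loci.
#' @param region_length_bp Total searched length in bp (> 0).
#' @return Loci per Mb (full precision; tables round to 2 decimals).
#' @examples
#' relative_abundance(10, 2e6)  # 5
#' @export
relative_abundance <- function(n_loci, region_length_bp) {
  if (any(region_length_bp <= 0)) {
    stop("region_length_bp must be positive", call. = FALSE)
  }
  n_loci / (region_length_bp / 1e6)
}

#' Percentage share of a repeat type
#'
#' @param n_type Count in the group.
#' @param n_total Total count (> 0).
#' @return `n_type / n_total * 100` at full precision.
#' @export
type_percentage <- function(n_type, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive", call. = FALSE)
  if (any(n_type > n_total)) stop("n_type exceeds n_total", call. = FALSE)
  n_type / n_total * 100
}

## GC fraction of a motif (equals the GC fraction of any perfect repeat
## of that motif, so locus spans need not be re-extracted).
motif_gc <- function(motif) {
  vapply(strsplit(motif, "", fixed = TRUE), function(b)
    sum(b %in% c("G", "C")) / length(b), numeric(1))
}

#' GC content of a set of SSR loci
#'
#' Percentage of G+C bases over all locus spans pooled. A perfect repeat
#' is the motif repeated, so the span GC equals the motif GC weighted by
#' locus length; no genome lookup is needed.
#'
#' @param loci SSR locus data frame (`motif`, `length_bp`).
#' @return GC percentage in 0-100, or `NA` for an empty set.
#' @examples
#' gc_content(data.frame(motif = "ACG", length_bp = 15))  # 66.67
#' @export
gc_content <- function(loci) {
  if (nrow(loci) == 0L) return(NA_real_)
  gcb <- sum(motif_gc(loci$motif) * loci$length_bp)
  gcb / sum(loci$length_bp) * 100
}

#' Rank canonical motifs by relative abundance
#'
#' Within each unit length, canonical motifs are ordered by loci per Mb
#' (descending; ties broken alphabetically), the layout of a
#' "most frequent motifs" table.
#'
#' @param loci SSR locus data frame with `canonical_motif` assigned.
#' @param region_length_bp Length of the searched sequence class in bp.
#' @param k Optional top-N cutoff per unit length.
#' @return Data frame with `unit_length`, `canonical_motif`, `n_loci`,
#'   `relative_abundance`, sorted within unit length.
#' @export
motif_ranking <- function(loci, region_length_bp, k = Inf) {
  if (nrow(loci) == 0L) {
    return(data.frame(unit_length = integer(0),
                      canonical_motif = character(0), n_loci = integer(0),
                      relative_abundance = numeric(0)))
  }
  agg <- stats::aggregate(list(n_loci = loci$start),
                          by = list(unit_length = loci$unit_length,
                                    canonical_motif = loci$canonical_motif),
                          FUN = length)
  agg$relative_abundance <- relative_abundance(agg$n_loci, region_length_bp)
  agg <- agg[order(agg$unit_length, -agg$relative_abundance,
                   agg$canonical_motif), ]
  keep <- unlist(lapply(split(seq_len(nrow(agg)), agg$unit_length),
                        function(i) utils::head(i, k)), use.names = FALSE)
  out <- agg[sort(keep), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Repeat-copy-number histogram
#'
#' Exact integer histogram of RCN values, optionally within groups.
#'
#' @param loci SSR locus data frame (`rcn`; optionally `unit_length`,
#'   `region`).
#' @param by Character vector of grouping columns present in `loci`.
#' @return Data frame with the grouping columns, `rcn` and `n`.
#' @export
rcn_distribution <- function(loci, by = intersect(c("unit_length", "region"),
                                                  names(loci))) {
  if (nrow(loci) == 0L) {
    return(data.frame(rcn = integer(0), n = integer(0)))
  }
  keys <- c(lapply(by, function(b) loci[[b]]), list(rcn = loci$rcn))
  names(keys) <- c(by, "rcn")
  agg <- stats::aggregate(list(n = loci$rcn), by = keys, FUN = length)
  agg[do.call(order, agg[c(by, "rcn")]), , drop = FALSE]
}

#' Coefficient of variation of repeat copy number
#'
#' CV = S / mean(RCN) x 100, where S is the standard deviation of the
#' RCN values of one SSR group. The sample SD (n-1 denominator) is the
#' default; the population form is available. CV is undefined (returned
#' as `NA` with a reason) for fewer than two values or zero mean.
#'
#' @param rcn Numeric vector of repeat copy numbers.
#' @param sd_type `"sample"` (n-1) or `"population"` (n).
#' @return List of class `cv_stat`: `n`, `mean_rcn`, `sd_rcn`,
#'   `cv_percent`, `reason` (`NA` unless the CV is undefined).
#' @examples
#' cv_of_rcn(c(8, 10, 12))$cv_percent  # 20
#' @export
cv_of_rcn <- function(rcn, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  n <- length(rcn)
  if (n < 2L) {
    return(structure(list(n = n, mean_rcn = if (n) mean(rcn) else NA_real_,
                          sd_rcn = NA_real_, cv_percent = NA_real_,
                          reason = "fewer than two loci"),
                     class = "cv_stat"))
  }
  m <- mean(rcn)
  if (m == 0) {
    return(structure(list(n = n, mean_rcn = 0, sd_rcn = stats::sd(rcn),
                          cv_percent = NA_real_, reason = "zero mean"),
                     class = "cv_stat"))
  }
  s <- stats::sd(rcn)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  structure(list(n = n, mean_rcn = m, sd_rcn = s,
                 cv_percent = s / m * 100, reason = NA_character_),
            class = "cv_stat")
}

#' @export
print.cv_stat <- function(x, ...) {
  if (is.na(x$cv_percent)) {
    cat("CV undefined (", x$reason, "); n =", x$n, "\n")
  } else {
    cat(sprintf("CV = %.2f%% (n = %d, mean RCN = %.2f, SD = %.2f)\n",
                x$cv_percent, x$n, x$mean_rcn, x$sd_rcn))
  }
  invisible(x)
}

type_levels <- c("Mono", "Di", "Tri", "Tetra", "Penta", "Hexa")

type_factor <- function(unit_length) {
  factor(type_levels[unit_length], levels = type_levels)
}

#' Genome-wide per-type SSR summary
#'
#' One row per repeat type (mono- to hexanucleotide) plus a Total row:
#' locus count, GC content of the pooled spans, total repeat length,
#' relative abundance per Mb of genome, and the percentage share of all
#' loci. Percentages and abundances are reported at full precision;
#' round for display.
#'
#' @param loci SSR locus data frame.
#' @param genome_length_bp Total searched genome length in bp.
#' @return Data frame shaped like a genome-survey overview table.
#' @export
summarize_by_type <- function(loci, genome_length_bp) {
  rows <- lapply(1:6, function(k) {
    sub <- loci[loci$unit_length == k, , drop = FALSE]
    data.frame(type = type_levels[k], n_loci = nrow(sub),
               gc_percent = gc_content(sub),
               total_length_bp = sum(sub$length_bp),
               relative_abundance = relative_abundance(nrow(sub),
                                                       genome_length_bp),
               percentage = if (nrow(loci)) {
                 type_percentage(nrow(sub), nrow(loci))
               } else 0,
               stringsAsFactors = FALSE)
  })
  tot <- data.frame(type = "Total", n_loci = nrow(loci),
                    gc_percent = gc_content(loci),
                    total_length_bp = sum(loci$length_bp),
                    relative_abundance = relative_abundance(nrow(loci),
                                                            genome_length_bp),
                    percentage = if (nrow(loci)) 100 else 0,
                    stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, rows), tot)
  row.names(out) <- NULL
  out
}

#' Per-region, per-type SSR summary
#'
#' Counts and relative abundance (per Mb of each region class) for every
#' repeat type in every genomic region, with per-region totals. The TE
#' overlay is tallied alongside the five disjoint base classes, so the
#' base-class counts (not including TE) sum to the genome-wide count.
#'
#' @param loci SSR locus data frame with `region`/`in_te` from
#'   [assign_region()].
#' @param model The `region_model` used for assignment.
#' @return Data frame with `region`, `type`, `n_loci`,
#'   `relative_abundance`, `gc_percent`.
#' @export
summarize_by_region <- function(loci, model) {
  base <- names(model$regions)
  groups <- c(base, "TE")
  rows <- list()
  for (rg in groups) {
    sub <- if (rg == "TE") loci[loci$in_te, , drop = FALSE]
           else loci[loci$region == rg, , drop = FALSE]
    len <- model$lengths[[rg]]
    for (k in 1:6) {
      s2 <- sub[sub$unit_length == k, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, type = type_levels[k], n_loci = nrow(s2),
        relative_abundance = if (len > 0)
          relative_abundance(nrow(s2), len) else NA_real_,
        gc_percent = gc_content(s2), stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      region = rg, type = "Total", n_loci = nrow(sub),
      relative_abundance = if (len > 0)
        relative_abundance(nrow(sub), len) else NA_real_,
      gc_percent = gc_content(sub), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$region <- factor(out$region, levels = groups)
  out$type <- factor(out$type, levels = c(type_levels, "Total"))
  row.names(out) <- NULL
  out
}

#' Build the three survey summary tables
#'
#' Convenience wrapper producing the genome-wide per-type overview, the
#' per-type motif ranking, and the per-region breakdown from one set of
#' assigned loci.
#'
#' @param loci Assigned SSR locus data frame.
#' @param model A `region_model`.
#' @param top_motifs Top-N motifs kept per unit length in the ranking.
#' @return List with elements `by_type`, `motifs`, `by_region`.
#' @export
build_summary_tables <- function(loci, model, top_motifs = 10L) {
  list(by_type = summarize_by_type(loci, model$genome_length_bp),
       motifs = motif_ranking(loci, model$genome_length_bp, top_motifs),
       by_region = summarize_by_region(loci, model))
}
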