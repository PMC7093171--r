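#' Configuration for tetranucleotide marker screening
#'
#' Screening criteria for SSR marker development: tetranucleotide unit,
#' repeat copy number inside a window (default 7-15), 200 bp of clean
#' flank on either side, and the downstream primer/product constraints
#' (primer length 18-23 bp, product 190-450 bp) recorded as metadata for
#' primer-design tools.
#'
#' @param unit_length Required unit length (default 4).
#' @param rcn_min,rcn_max Inclusive repeat-copy-number window.
#' @param flank_len Flank length in bp extracted on each side.
#' @param product_min,product_max Expected PCR product size bounds (bp),
#'   carried as metadata.
#' @param primer_min,primer_max Primer length bounds (bp), metadata.
#' @param require_unique_flanks Exact-match uniqueness check of each
#'   flank elsewhere in the genome (off by default; expensive).
#' @return List of class `screen_config`.
#' @export
screen_config <- function(unit_length = 4L, rcn_min = 7L, rcn_max = 15L,
                          flank_len = 200L, product_min = 190L,
                          product_max = 450L, primer_min = 18L,
                          primer_max = 23L,
                          require_unique_flanks = FALSE) {
  stopifnot(rcn_min <= rcn_max, product_min < product_max,
            flank_len > 0, unit_length %in% 1:6)
  structure(list(unit_length = as.integer(unit_length),
                 rcn_min = as.integer(rcn_min),
                 rcn_max = as.integer(rcn_max),
                 flank_len = as.integer(flank_len),
                 product_min = as.integer(product_min),
                 product_max = as.integer(product_max),
                 primer_min = as.integer(primer_min),
                 primer_max = as.integer(primer_max),
                 require_unique_flanks = isTRUE(require_unique_flanks)),
            class = "screen_config")
}

#' Screen SSR loci as marker candidates
#'
#' Evaluates every locus of the configured unit length against the
#' screening criteria: repeat copy number within the window, a full
#' flank available on both sides (loci too close to a sequence end are
#' rejected), no other mined SSR inside either flank, and optionally
#' exact-match flank uniqueness in the genome. Every rejected candidate
#' carries machine-readable reasons.
#'
#' @param loci SSR locus data frame from [find_perfect_ssrs()] (all unit
#'   lengths; used both as the candidate pool and to detect SSRs inside
#'   flanks).
#' @param genome Sequences as accepted by [find_perfect_ssrs()].
#' @param cfg A [screen_config()].
#' @return Data frame with the locus columns plus `left_flank`,
#'   `right_flank`, `passes` and `rejection_reasons`
#'   (semicolon-separated, empty when passing).
#' @export
screen_candidates <- function(loci, genome, cfg = screen_config()) {
  seqs <- as_seq_set(genome)
  cand <- loci[loci$unit_length == cfg$unit_length, , drop = FALSE]
  if (nrow(cand) == 0L) {
    cand$left_flank <- character(0)
    cand$right_flank <- character(0)
    cand$passes <- logical(0)
    cand$rejection_reasons <- character(0)
    return(cand)
  }
  unknown <- !(cand$seq_id %in% names(seqs))
  if (any(unknown)) {
    stop("locus seq_id '", cand$seq_id[unknown][1],
         "' absent from genome", call. = FALSE)
  }
  fl <- cfg$flank_len
  reasons <- vector("list", nrow(cand))
  left <- right <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- character(0)
    if (cand$rcn[i] < cfg$rcn_min) r <- c(r, "rcn-below-min")
    if (cand$rcn[i] > cfg$rcn_max) r <- c(r, "rcn-above-max")
    s <- seqs[[cand$seq_id[i]]]
    if (cand$start[i] - fl < 1L || cand$end[i] + fl > nchar(s)) {
      r <- c(r, "insufficient-flank")
    } else {
      left[i] <- substr(s, cand$start[i] - fl, cand$start[i] - 1L)
      right[i] <- substr(s, cand$end[i] + 1L, cand$end[i] + fl)
      other <- loci[loci$seq_id == cand$seq_id[i] &
                      !(loci$start == cand$start[i] &
                          loci$end == cand$end[i]), , drop = FALSE]
      hit <- other$end >= cand$start[i] - fl &
             other$start <= cand$end[i] + fl
      if (any(hit)) r <- c(r, "ssr-in-flank")
      if (cfg$require_unique_flanks &&
          (!flank_unique(left[i], seqs, cand$seq_id[i],
                         cand$start[i] - fl) ||
           !flank_unique(right[i], seqs, cand$seq_id[i],
                         cand$end[i] + 1L))) {
        r <- c(r, "non-unique-flank")
      }
    }
    reasons[[i]] <- r
  }
  cand$left_flank <- left
  cand$right_flank <- right
  cand$passes <- lengths(reasons) == 0L
  cand$rejection_reasons <- vapply(reasons, paste, character(1),
                                   collapse = ";")
  row.names(cand) <- NULL
  cand
}

## TRUE when `flank` occurs exactly once in the genome (at its own site).
flank_unique <- function(flank, seqs, own_seq, own_start) {
  n <- 0L
  for (nm in names(seqs)) {
    hits <- gregexpr(flank, seqs[[nm]], fixed = TRUE)[[1]]
    if (hits[1] != -1L) n <- n + length(hits)
    if (n > 1L) return(FALSE)
  }
  n == 1L
}

#' Export screened marker candidates
#'
#' Writes a FASTA of each candidate's locus plus flanks (records named
#' `seq_id:start-end`) and a TSV of the metadata including pass/fail and
#' rejection reasons. Only candidates with extractable flanks appear in
#' the FASTA; all appear in the TSV.
#'
#' @param candidates Output of [screen_candidates()].
#' @param fasta_path,tsv_path Output paths.
#' @param passing_only Restrict the FASTA to passing candidates
#'   (default TRUE).
#' @return Invisible list of the two paths.
#' @export
export_candidates <- function(candidates, fasta_path, tsv_path,
                              passing_only = TRUE) {
  sel <- if (passing_only) candidates[candidates$passes, , drop = FALSE]
         else candidates[candidates$left_flank != "", , drop = FALSE]
  recs <- Biostrings::DNAStringSet(paste0(
    sel$left_flank, strrep(sel$motif, sel$rcn), sel$right_flank))
  names(recs) <- sprintf("%s:%d-%d", sel$seq_id, sel$start, sel$end)
  Biostrings::writeXStringSet(recs, fasta_path)
  meta <- candidates[, setdiff(names(candidates),
                               c("left_flank", "right_flank"))]
  utils::write.table(meta, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fasta_path, tsv = tsv_path))
}
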