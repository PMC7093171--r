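#' Minimum repeat-copy-number thresholds for SSR mining
#'
#' Minimum number of complete unit copies a perfect repeat must reach to
#' be reported, one threshold per unit length 1-6. The defaults
#' (12, 7, 5, 4, 4, 4) are the widely used "systemic" criteria of
#' genome-scale SSR surveys; all are overridable.
#'
#' @param mono,di,tri,tetra,penta,hexa Integer minima (each >= 2).
#' @return Named integer vector of length 6 with class
#'   `"mining_thresholds"`.
#' @examples
#' mining_thresholds()            # the defaults
#' mining_thresholds(di = 6)      # relax dinucleotides
#' @export
mining_thresholds <- function(mono = 12L, di = 7L, tri = 5L,
                              tetra = 4L, penta = 4L, hexa = 4L) {
  v <- as.integer(c(mono, di, tri, tetra, penta, hexa))
  if (anyNA(v) || any(v < 2L)) {
    stop("all minimum repeat copy numbers must be integers >= 2",
         call. = FALSE)
  }
  names(v) <- as.character(1:6)
  structure(v, class = "mining_thresholds")
}

## Normalise sequence input to a named character vector of uppercase DNA.
## Accepts a character vector, a Biostrings::DNAStringSet, or a FASTA path.
as_seq_set <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) {
    out <- as.character(seqs)
  } else if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs) &&
             !grepl("^[ACGTNacgtn]*$", seqs)) {
    ss <- Biostrings::readDNAStringSet(seqs)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
  } else if (is.character(seqs)) {
    out <- seqs
  } else {
    stop("sequences must be a character vector, DNAStringSet or FASTA path",
         call. = FALSE)
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    names(out) <- paste0("seq", seq_along(out))
  }
  toupper(out)
}

## Integer-encode one sequence; error with position on invalid characters.
encode_seq <- function(s, seq_id) {
  x <- utf8ToInt(s)
  # A=65 C=67 G=71 T=84 N=78
  ok <- x %in% c(65L, 67L, 71L, 84L, 78L)
  if (!all(ok)) {
    p <- which(!ok)[1]
    stop(sprintf("invalid character '%s' at position %d of sequence '%s'",
                 substr(s, p, p), p, seq_id), call. = FALSE)
  }
  x
}

empty_ssr_frame <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             unit_length = integer(0), motif = character(0),
             canonical_motif = character(0), rcn = integer(0),
             length_bp = integer(0), stringsAsFactors = FALSE)
}

## Candidate maximal perfect runs of period k in one encoded sequence.
## Exactly one left-maximal phase start exists per maximal period-k region;
## regions whose leading k-mer is non-primitive belong to a smaller period
## and are skipped here.
runs_for_period <- function(x, valid, k, min_rcn, s) {
  n <- length(x)
  if (n < k * min_rcn) return(NULL)
  eq <- x[seq_len(n - k)] == x[seq_len(n - k) + k] &
        valid[seq_len(n - k)] & valid[seq_len(n - k) + k]
  r <- rle(eq)
  len <- r$lengths
  ends <- cumsum(len)
  starts <- ends - len + 1L
  keep <- r$values & (len + k) >= k * min_rcn
  if (!any(keep)) return(NULL)
  a <- starts[keep]
  total <- len[keep] + k
  rcn <- total %/% k
  motif <- substring(s, a, a + k - 1L)
  prim <- is_primitive(motif)
  if (!any(prim)) return(NULL)
  data.frame(start = a[prim], unit_length = k, motif = motif[prim],
             rcn = rcn[prim], stringsAsFactors = FALSE)
}

mine_one <- function(s, seq_id, thresholds) {
  x <- encode_seq(s, seq_id)
  valid <- x != 78L  # N is a hard terminator
  cand <- do.call(rbind, lapply(1:6, function(k) {
    runs_for_period(x, valid, k, thresholds[[k]], s)
  }))
  if (is.null(cand) || nrow(cand) == 0L) return(empty_ssr_frame())
  cand$length_bp <- cand$unit_length * cand$rcn
  cand$end <- cand$start + cand$length_bp - 1L
  # greedy overlap resolution: earlier start, then smaller unit, then
  # longer run; each base belongs to at most one locus
  cand <- cand[order(cand$start, cand$unit_length, -cand$length_bp), ]
  last_end <- 0L
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- cand$end[i]
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(seq_id = seq_id, start = cand$start, end = cand$end,
             unit_length = cand$unit_length, motif = cand$motif,
             canonical_motif = canonical_motif(cand$motif),
             rcn = cand$rcn, length_bp = cand$length_bp,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mine perfect microsatellites from nucleotide sequences
#'
#' Scans each sequence for maximal perfect tandem repeats with unit
#' lengths 1-6 bp. A reported locus cannot be extended by one unit-phase
#' base on either side, is described by its smallest primitive unit,
#' has at least the configured number of complete copies, and trailing
#' partial units are truncated. `N` terminates runs; lowercase
#' (soft-masked) bases are treated as ordinary bases. Overlaps between
#' candidate loci of different unit lengths are resolved greedily
#' left-to-right (earlier start, then smaller unit, then longer run), so
#' no two reported loci share a base.
#'
#' @param seqs Named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or the path to a (multi-)FASTA file.
#' @param thresholds A [mining_thresholds()] object.
#' @return A data frame with one row per locus and columns `seq_id`,
#'   `start`, `end` (1-based inclusive), `unit_length`, `motif` (unit as
#'   read on the forward strand), `canonical_motif`, `rcn` (complete
#'   copies) and `length_bp`, sorted by (`seq_id`, `start`).
#' @examples
#' find_perfect_ssrs(c(chr1 = paste0("GGC", strrep("A", 12), "CGG")))
#' @export
find_perfect_ssrs <- function(seqs, thresholds = mining_thresholds()) {
  if (!inherits(thresholds, "mining_thresholds")) {
    thresholds <- do.call(mining_thresholds, as.list(thresholds))
  }
  ss <- as_seq_set(seqs)
  out <- do.call(rbind, lapply(seq_along(ss), function(i) {
    mine_one(ss[[i]], names(ss)[i], thresholds)
  }))
  if (is.null(out)) out <- empty_ssr_frame()
  out[order(out$seq_id, out$start), , drop = FALSE]
}

#' Write mined loci as TSV
#'
#' @param loci SSR locus data frame from [find_perfect_ssrs()].
#' @param path Output file.
#' @param header_comments Optional character vector written as leading
#'   `#` comment lines (e.g. the run seed or configuration hash).
#' @return `path`, invisibly.
#' @export
write_ssr_tsv <- function(loci, path, header_comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_comments)) {
    writeLines(paste0("# ", header_comments), con)
  }
  utils::write.table(loci, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a mined-locus TSV back into a data frame
#'
#' @param path TSV written by [write_ssr_tsv()].
#' @return SSR locus data frame.
#' @export
read_ssr_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Export mined loci as GFF3 microsatellite features
#'
#' @param loci SSR locus data frame.
#' @param path Output GFF3 file.
#' @return `path`, invisibly.
#' @export
ssr_to_gff3 <- function(loci, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tssrmine\tmicrosatellite\t%d\t%d\t.\t+\t.\tID=ssr%d;motif=%s;canonical_motif=%s;rcn=%d",
                     loci$seq_id, loci$start, loci$end, seq_len(nrow(loci)),
                     loci$motif, loci$canonical_motif, loci$rcn))
  writeLines(lines, path)
  invisible(path)
}
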