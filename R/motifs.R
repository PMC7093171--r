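#' Reverse complement of a DNA motif
#'
#' Base-pairing complement of the reversed string, for plain character
#' motifs (A/C/G/T only).
#'
#' @param motif Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp_motif("GT")   # "AC"
#' @export
revcomp_motif <- function(motif) {
  check_dna(motif)
  vapply(motif, function(m) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(m, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

check_dna <- function(motif) {
  bad <- grepl("[^ACGT]", motif)
  if (any(bad)) {
    stop("invalid alphabet: motif must contain only A/C/G/T, got '",
         motif[bad][1], "'", call. = FALSE)
  }
  invisible(motif)
}

rotations <- function(m) {
  k <- nchar(m)
  if (k == 1L) return(m)
  d <- paste0(m, m)
  vapply(seq_len(k), function(i) substr(d, i, i + k - 1L), character(1))
}

#' Test whether a motif is primitive
#'
#' A motif is primitive when it is not a whole-number repetition of a
#' shorter unit (e.g. "ACAC" is (AC)x2, not primitive). Only primitive
#' motifs are valid repeat units: a poly-A run must be reported as unit
#' "A", never as "AA".
#'
#' @param motif Character vector of DNA strings (A/C/G/T).
#' @return Logical vector.
#' @examples
#' is_primitive(c("ACAC", "AAT"))  # FALSE TRUE
#' @export
is_primitive <- function(motif) {
  check_dna(motif)
  vapply(motif, function(m) {
    k <- nchar(m)
    if (k == 1L) return(TRUE)
    for (d in seq_len(k - 1L)) {
      if (k %% d == 0L &&
          m == strrep(substr(m, 1L, d), k %/% d)) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

#' Canonical representative of a repeat-motif class
#'
#' Repeat units that are circular permutations and/or reverse complements
#' of each other describe the same microsatellite and are grouped as one
#' type. The class representative is the lexicographically smallest string
#' among all rotations of the motif and all rotations of its reverse
#' complement, so e.g. "GT", "TG", "CA" and "AC" all map to "AC".
#'
#' @param motif Character vector of primitive DNA motifs, 1-6 bp.
#' @return Character vector of canonical motifs, same length.
#' @examples
#' canonical_motif(c("GT", "CGA", "TTC"))  # "AC" "ACG" "AAG"
#' @export
canonical_motif <- function(motif) {
  check_dna(motif)
  if (any(nchar(motif) < 1L | nchar(motif) > 6L)) {
    stop("motif length must be 1-6 bp", call. = FALSE)
  }
  if (!all(is_primitive(motif))) {
    stop("invalid motif: not primitive", call. = FALSE)
  }
  vapply(motif, function(m) {
    min(c(rotations(m), rotations(revcomp_motif(m))))
  }, character(1), USE.NAMES = FALSE)
}

#' Enumerate canonical motif classes of a given unit length
#'
#' Brute-force enumeration of all primitive k-mers, grouped by
#' [canonical_motif()]. There are 2, 4, 10, 33, 102 and 350 classes for
#' unit lengths 1 through 6.
#'
#' @param unit_length Integer in 1..6.
#' @return Sorted character vector of class representatives.
#' @export
canonical_classes <- function(unit_length) {
  if (length(unit_length) != 1L || is.na(unit_length) ||
      unit_length < 1 || unit_length > 6) {
    stop("unit_length must be a single integer in 1..6", call. = FALSE)
  }
  k <- as.integer(unit_length)
  kmers <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                       stringsAsFactors = FALSE))
  kmers <- kmers[is_primitive(kmers)]
  sort(unique(canonical_motif(kmers)))
}

#' Number of canonical motif classes for a unit length
#'
#' @inheritParams canonical_classes
#' @return Integer count of classes.
#' @export
count_canonical_classes <- function(unit_length) {
  length(canonical_classes(unit_length))
}
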