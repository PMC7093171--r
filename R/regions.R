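#' Build a disjoint genomic region partition from annotation
#'
#' Partitions every base of the genome into exactly one of five classes
#' (5'UTR, CDS, intron, 3'UTR, intergenic) from a GFF3 gene annotation,
#' with transposable elements carried as a separate overlay that may
#' overlap any base class. Introns are the gaps between consecutive exons
#' of a transcript; UTRs are exonic bases outside the CDS, sided by
#' strand (upstream of the CDS is 5' on `+`, 3' on `-`); when transcripts
#' of one gene disagree the longest transcript (largest summed exon
#' length) defines the structure; overlapping features from different
#' genes are resolved with precedence CDS > 5'UTR > 3'UTR > intron.
#' All remaining bases are intergenic.
#'
#' @param gff Path to a GFF3 file, or a `GRanges` as returned by
#'   `rtracklayer::import` (with `type`, `ID`, `Parent` metadata).
#' @param te_track Optional transposable-element intervals: a BED path
#'   (0-based half-open, converted on read), a `GRanges`, or a data frame
#'   with columns `seq_id`, `start`, `end` (1-based inclusive).
#' @param seq_lengths Named vector of sequence lengths (bp).
#' @return A `region_model` object: list with `regions` (named list of
#'   disjoint `GRanges` for FIVE_UTR, CDS, INTRON, THREE_UTR, INTERGENIC),
#'   `te` (`GRanges` overlay), `lengths` (merged total bp per class,
#'   including TE), `genome_length_bp` and `seq_lengths`.
#' @export
build_region_model <- function(gff, te_track = NULL, seq_lengths) {
  if (is.null(names(seq_lengths)) || any(seq_lengths < 1)) {
    stop("seq_lengths must be a named vector of positive lengths",
         call. = FALSE)
  }
  g <- if (is.character(gff)) rtracklayer::import(gff, format = "gff3")
       else gff
  if (length(g)) {
    bad <- !(as.character(GenomicRanges::seqnames(g)) %in%
               names(seq_lengths))
    if (any(bad)) {
      stop("annotation references unknown seq_id '",
           as.character(GenomicRanges::seqnames(g))[bad][1], "'",
           call. = FALSE)
    }
    over <- GenomicRanges::end(g) >
      seq_lengths[as.character(GenomicRanges::seqnames(g))]
    if (any(over)) {
      stop("annotation feature extends past the end of sequence '",
           as.character(GenomicRanges::seqnames(g))[over][1], "'",
           call. = FALSE)
    }
  }
  parts <- partition_from_annotation(g, seq_lengths)
  genome <- GenomicRanges::GRanges(
    names(seq_lengths),
    IRanges::IRanges(1L, as.integer(seq_lengths)))
  genic <- Reduce(function(a, b) GenomicRanges::union(a, b, ignore.strand = TRUE),
                  parts)
  intergenic <- GenomicRanges::setdiff(genome, genic, ignore.strand = TRUE)
  regions <- c(parts, list(INTERGENIC = intergenic))
  te <- normalize_te(te_track, seq_lengths)
  lens <- vapply(regions, function(x)
    sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(x, ignore.strand = TRUE)))),
    numeric(1))
  lens <- c(lens, TE = sum(as.numeric(
    GenomicRanges::width(GenomicRanges::reduce(te, ignore.strand = TRUE)))))
  structure(list(regions = regions, te = te, lengths = lens,
                 genome_length_bp = sum(as.numeric(seq_lengths)),
                 seq_lengths = seq_lengths),
            class = "region_model")
}

## CDS/UTR/intron GRanges (strand-stripped, reduced, mutually disjoint)
## from the parsed annotation.
partition_from_annotation <- function(g, seq_lengths) {
  empty <- GenomicRanges::GRanges()
  out <- list(FIVE_UTR = empty, CDS = empty, INTRON = empty,
              THREE_UTR = empty)
  if (length(g) == 0L) return(out)
  type <- as.character(g$type)
  first_parent <- function(x) {
    vapply(as.list(x$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
  }
  tx <- g[type %in% c("mRNA", "transcript")]
  exons <- g[type == "exon"]
  cds <- g[type == "CDS"]
  if (length(exons) == 0L) return(out)
  exon_parent <- first_parent(exons)
  cds_parent <- if (length(cds)) first_parent(cds) else character(0)
  if (length(tx)) {
    tx_gene <- first_parent(tx)
    tx_ids <- as.character(tx$ID)
  } else {
    # exons parented directly on genes: one implicit transcript per gene
    tx_ids <- unique(exon_parent)
    tx_gene <- tx_ids
  }
  # longest transcript (summed exon width) represents each gene
  exon_w <- tapply(GenomicRanges::width(exons), exon_parent, sum)
  keep_tx <- unlist(lapply(split(tx_ids, tx_gene), function(ids) {
    w <- exon_w[ids]
    w[is.na(w)] <- 0
    ids[which.max(w)]
  }), use.names = FALSE)
  genes <- g[type == "gene"]
  if (length(genes)) {
    gene_span <- stats::setNames(
      paste0(GenomicRanges::seqnames(genes), ":",
             GenomicRanges::start(genes), "-", GenomicRanges::end(genes)),
      as.character(genes$ID))
    for (i in seq_along(exons)) {
      gid <- tx_gene[match(exon_parent[i], tx_ids)]
      if (!is.na(gid) && gid %in% as.character(genes$ID)) {
        gr <- genes[match(gid, as.character(genes$ID))]
        if (GenomicRanges::start(exons[i]) < GenomicRanges::start(gr) ||
            GenomicRanges::end(exons[i]) > GenomicRanges::end(gr)) {
          stop("exon at ", as.character(GenomicRanges::seqnames(exons[i])),
               ":", GenomicRanges::start(exons[i]),
               " lies outside its gene bounds", call. = FALSE)
        }
      }
    }
  }
  five <- cds_all <- intron <- three <- GenomicRanges::GRanges()
  for (t in keep_tx) {
    ex <- GenomicRanges::reduce(exons[exon_parent == t])
    if (length(ex) == 0L) next
    cd <- GenomicRanges::reduce(cds[cds_parent == t])
    span <- range(ex)
    intr <- GenomicRanges::setdiff(span, ex, ignore.strand = TRUE)
    intron <- c(intron, unstrand(intr))
    if (length(cd) == 0L) next
    cds_all <- c(cds_all, unstrand(cd))
    utr <- GenomicRanges::setdiff(ex, cd, ignore.strand = TRUE)
    if (length(utr)) {
      minus <- as.character(GenomicRanges::strand(
        tx_strand(g, exons, exon_parent, t))) == "-"
      left <- GenomicRanges::end(utr) < min(GenomicRanges::start(cd))
      if (minus) {
        five <- c(five, unstrand(utr[!left]))
        three <- c(three, unstrand(utr[left]))
      } else {
        five <- c(five, unstrand(utr[left]))
        three <- c(three, unstrand(utr[!left]))
      }
    }
  }
  cds_all <- GenomicRanges::reduce(cds_all)
  five <- GenomicRanges::setdiff(GenomicRanges::reduce(five), cds_all,
                                 ignore.strand = TRUE)
  three <- GenomicRanges::reduce(three)
  three <- GenomicRanges::setdiff(
    three, GenomicRanges::union(cds_all, five, ignore.strand = TRUE),
    ignore.strand = TRUE)
  genic_hi <- Reduce(function(a, b)
    GenomicRanges::union(a, b, ignore.strand = TRUE),
    list(cds_all, five, three))
  intron <- GenomicRanges::setdiff(GenomicRanges::reduce(intron), genic_hi,
                                   ignore.strand = TRUE)
  list(FIVE_UTR = five, CDS = cds_all, INTRON = intron, THREE_UTR = three)
}

unstrand <- function(x) {
  GenomicRanges::strand(x) <- "*"
  x
}

tx_strand <- function(g, exons, exon_parent, t) {
  exons[exon_parent == t][1]
}

normalize_te <- function(te_track, seq_lengths) {
  if (is.null(te_track)) return(GenomicRanges::GRanges())
  if (is.character(te_track)) {
    te <- rtracklayer::import(te_track)  # BED: 0-based half-open on disk
  } else if (is.data.frame(te_track)) {
    te <- GenomicRanges::GRanges(
      te_track$seq_id,
      IRanges::IRanges(te_track$start, te_track$end))
  } else {
    te <- te_track
  }
  bad <- !(as.character(GenomicRanges::seqnames(te)) %in% names(seq_lengths))
  if (any(bad)) {
    stop("TE track references unknown seq_id '",
         as.character(GenomicRanges::seqnames(te))[bad][1], "'",
         call. = FALSE)
  }
  unstrand(GenomicRanges::reduce(te, ignore.strand = TRUE))
}

#' @export
print.region_model <- function(x, ...) {
  cat("Genomic region model:", x$genome_length_bp, "bp on",
      length(x$seq_lengths), "sequence(s)\n")
  for (nm in names(x$lengths)) {
    cat(sprintf("  %-10s %12.0f bp\n", nm, x$lengths[[nm]]))
  }
  invisible(x)
}

#' Per-class merged region lengths
#'
#' @param model A `region_model`.
#' @return Named numeric vector of total bp per class (five base classes
#'   plus `TE`).
#' @export
region_lengths <- function(model) model$lengths

#' Assign SSR loci to genomic regions
#'
#' Each locus gets the base-class label of the interval containing its
#' start coordinate (boundary-spanning loci are therefore counted once),
#' plus a logical TE flag set when the start lies inside a
#' transposable-element interval.
#'
#' @param loci SSR locus data frame from [find_perfect_ssrs()].
#' @param model A `region_model` from [build_region_model()].
#' @return `loci` with added columns `region` (factor with the five base
#'   classes) and `in_te` (logical).
#' @export
assign_region <- function(loci, model) {
  classes <- names(model$regions)
  if (nrow(loci) == 0L) {
    loci$region <- factor(character(0), levels = classes)
    loci$in_te <- logical(0)
    return(loci)
  }
  unknown <- !(loci$seq_id %in% names(model$seq_lengths))
  if (any(unknown)) {
    stop("locus on unknown seq_id '", loci$seq_id[unknown][1], "'",
         call. = FALSE)
  }
  pts <- GenomicRanges::GRanges(loci$seq_id,
                                IRanges::IRanges(loci$start, loci$start))
  lab <- rep(NA_character_, nrow(loci))
  for (cl in classes) {
    hit <- IRanges::overlapsAny(pts, model$regions[[cl]],
                                ignore.strand = TRUE)
    lab[hit] <- cl
  }
  stopifnot(!anyNA(lab))  # the five classes tile the genome
  loci$region <- factor(lab, levels = classes)
  loci$in_te <- IRanges::overlapsAny(pts, model$te, ignore.strand = TRUE)
  loci
}
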