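#' Specification for a synthetic annotated genome with planted SSRs
#'
#' Describes a multi-sequence genome: i.i.d. background at a given GC
#' fraction, protein-coding genes (5'UTR / multi-exon CDS / introns /
#' 3'UTR), random transposable-element intervals overlaid on any region,
#' and perfect SSRs planted into chosen region classes with controlled
#' motif and repeat-copy-number distributions. Defaults give a compact
#' mammalian-like test genome: 4 sequences of 150 kb, GC 0.42, 8 genes
#' per sequence, ~20% TE cover, and 500 planted loci distributed with
#' the intron/intergenic bias seen in real genome surveys.
#'
#' @param n_sequences Number of sequences.
#' @param seq_length Length of each sequence (bp; recycled).
#' @param gc Background GC fraction.
#' @param genes_per_seq Genes per sequence.
#' @param exons_per_gene Range (min, max) of exon counts per gene.
#' @param cds_exon_len,intron_len,utr5_len,utr3_len Mean lengths (bp) of
#'   CDS exons, introns and UTRs (exponential-ish jitter applied).
#' @param te_per_seq Number of TE intervals per sequence.
#' @param te_len Range (min, max) of TE interval lengths.
#' @param n_ssr Named integer vector of planted locus counts per target
#'   class (`FIVE_UTR`, `CDS`, `INTRON`, `THREE_UTR`, `INTERGENIC`,
#'   `TE`); `TE` plants are placed inside TE intervals (their base class
#'   is whatever lies underneath).
#' @param unit_weights Sampling weights for unit lengths 1-6.
#' @param rcn_extra Mean number of copies above the mining minimum
#'   (geometric).
#' @param thresholds [mining_thresholds()] the planted loci must meet.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List of class `genome_sim_spec`.
#' @export
genome_sim_spec <- function(n_sequences = 4L, seq_length = 150000L,
                            gc = 0.42, genes_per_seq = 8L,
                            exons_per_gene = c(2L, 5L),
                            cds_exon_len = 160L, intron_len = 1200L,
                            utr5_len = 150L, utr3_len = 300L,
                            te_per_seq = 25L, te_len = c(200L, 2000L),
                            n_ssr = c(FIVE_UTR = 30L, CDS = 30L,
                                      INTRON = 150L, THREE_UTR = 40L,
                                      INTERGENIC = 200L, TE = 50L),
                            unit_weights = c(0.35, 0.25, 0.18, 0.12,
                                             0.08, 0.02),
                            rcn_extra = 3,
                            thresholds = mining_thresholds(),
                            seed = 1L) {
  stopifnot(gc > 0, gc < 1, n_sequences >= 1, all(seq_length > 1000))
  structure(as.list(environment()), class = "genome_sim_spec")
}

sample_base <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

## Break every mined run in `s` (a character vector of single bases) by
## substituting its middle base, avoiding positions in `protect`.
scrub_runs <- function(s, thresholds, max_iter = 60L) {
  for (it in seq_len(max_iter)) {
    loci <- mine_one(paste(s, collapse = ""), "x", thresholds)
    if (nrow(loci) == 0L) return(s)
    for (i in seq_len(nrow(loci))) {
      pos <- loci$start[i] + loci$length_bp[i] %/% 2L
      s[pos] <- sample(setdiff(c("A", "C", "G", "T"), s[pos]), 1)
    }
  }
  stop("failed to scrub accidental repeats from the background",
       call. = FALSE)
}

#' Simulate an annotated genome with planted perfect SSRs
#'
#' Generates FASTA sequences, a GFF3 gene annotation, a TE BED track and
#' a truth table of every planted SSR. The background is sampled i.i.d.
#' at the requested GC and scrubbed of accidental threshold-passing
#' repeats by single-base substitutions, then loci are planted with at
#' least two clean spacer bases between plants, entirely inside an
#' interval of their target region class. After planting the generator
#' re-mines each sequence and repairs any discrepancy (an accidental run
#' created by planting, or a plant extended by its flank) so that mining
#' at the spec thresholds returns exactly the truth table.
#'
#' @param spec A [genome_sim_spec()].
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `annotation.gff3`, `te.bed` and `truth.tsv` (seed echoed in the
#'   TSV/GFF headers).
#' @return Invisible list: `sequences` (named character), `gff`
#'   (`GRanges`), `te` (data frame, 1-based), `truth` (data frame:
#'   locus columns plus `region`, `in_te`), `model` (the
#'   `region_model`), `paths` (when written).
#' @export
simulate_genome <- function(spec = genome_sim_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  set.seed(spec$seed)
  lens <- rep_len(as.integer(spec$seq_length), spec$n_sequences)
  names(lens) <- sprintf("scaf%02d", seq_len(spec$n_sequences))
  ann <- list()
  te_rows <- list()
  for (si in seq_along(lens)) {
    layout <- gene_layout(names(lens)[si], lens[[si]], spec)
    ann[[si]] <- layout
    te_rows[[si]] <- sample_te(names(lens)[si], lens[[si]], spec)
  }
  gff_df <- do.call(rbind, ann)
  te_df <- do.call(rbind, te_rows)
  gff <- gff_granges(gff_df)
  model <- build_region_model(gff, te_df, lens)
  seqs <- lapply(lens, function(L) scrub_runs(sample_base(L, spec$gc),
                                              spec$thresholds))
  names(seqs) <- names(lens)
  planted <- plant_ssrs(seqs, model, spec)
  seqs <- planted$seqs
  truth <- planted$truth
  # repair pass: mining must reproduce the truth table exactly
  for (nm in names(seqs)) {
    protect <- unlist(lapply(which(truth$seq_id == nm), function(i)
      seq(truth$start[i], truth$end[i])), use.names = FALSE)
    for (it in 1:60) {
      mined <- mine_one(paste(seqs[[nm]], collapse = ""), nm,
                        spec$thresholds)
      tt <- truth[truth$seq_id == nm, , drop = FALSE]
      ok <- nrow(mined) == nrow(tt) &&
        all(mined$start == tt$start & mined$end == tt$end &
              mined$motif == tt$motif)
      if (ok) break
      extra <- mined[!(mined$start %in% tt$start &
                         mined$end %in% tt$end), , drop = FALSE]
      s <- seqs[[nm]]
      fixed <- FALSE
      for (i in seq_len(nrow(extra))) {
        span <- setdiff(seq(extra$start[i], extra$end[i]), protect)
        if (length(span)) {
          pos <- span[ceiling(length(span) / 2)]
          s[pos] <- sample(setdiff(c("A", "C", "G", "T"), s[pos]), 1)
          fixed <- TRUE
        }
      }
      if (!fixed) stop("could not reconcile planted truth with mining",
                       call. = FALSE)
      seqs[[nm]] <- s
    }
  }
  sequences <- vapply(seqs, paste, character(1), collapse = "")
  out <- list(sequences = sequences, gff = gff, te = te_df, truth = truth,
              model = model, seed = spec$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out_dir, "genome.fa")
    ss <- Biostrings::DNAStringSet(sequences)
    Biostrings::writeXStringSet(ss, fa)
    gff_path <- file.path(out_dir, "annotation.gff3")
    write_gff3(gff_df, gff_path, seed = spec$seed)
    bed <- file.path(out_dir, "te.bed")
    writeLines(sprintf("%s\t%d\t%d\tTE%d", te_df$seq_id,
                       te_df$start - 1L, te_df$end,
                       seq_len(nrow(te_df))), bed)
    truth_path <- file.path(out_dir, "truth.tsv")
    write_ssr_tsv(truth, truth_path,
                  header_comments = paste("seed:", spec$seed))
    out$paths <- c(fasta = fa, gff = gff_path, te = bed,
                   truth = truth_path)
  }
  invisible(out)
}

## lay out non-overlapping genes with UTR/exon/intron structure;
## returns a data frame of GFF3 rows
gene_layout <- function(seq_id, L, spec) {
  rows <- list()
  cursor <- 2000L
  for (gi in seq_len(spec$genes_per_seq)) {
    n_ex <- sample(seq(spec$exons_per_gene[1], spec$exons_per_gene[2]), 1)
    u5 <- pmax(40L, as.integer(stats::rexp(1, 1 / spec$utr5_len)))
    u3 <- pmax(60L, as.integer(stats::rexp(1, 1 / spec$utr3_len)))
    ex_len <- pmax(60L, as.integer(stats::rexp(n_ex, 1 / spec$cds_exon_len)))
    in_len <- if (n_ex > 1)
      pmax(200L, as.integer(stats::rexp(n_ex - 1, 1 / spec$intron_len)))
    else integer(0)
    glen <- u5 + u3 + sum(ex_len) + sum(in_len)
    gstart <- cursor + sample(1500:4000, 1)
    gend <- gstart + glen - 1L
    if (gend > L - 2000L) break
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("%s.g%d", seq_id, gi)
    tid <- paste0(gid, ".t1")
    # genomic exon coordinates: first exon carries the genomically-left
    # UTR, last exon the right one; strand decides which is 5'
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    pos <- gstart
    cds <- list()
    for (e in seq_len(n_ex)) {
      lead <- if (e == 1) u5 else 0L
      tail <- if (e == n_ex) u3 else 0L
      ex_start[e] <- pos
      ex_end[e] <- pos + lead + ex_len[e] + tail - 1L
      cds[[e]] <- c(pos + lead, pos + lead + ex_len[e] - 1L)
      pos <- ex_end[e] + if (e < n_ex) in_len[e] else 0L
      pos <- pos + 1L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = seq_id,
      type = c("gene", "mRNA", rep("exon", n_ex), rep("CDS", n_ex)),
      start = c(gstart, gstart, ex_start, vapply(cds, `[`, 1, i = 1)),
      end = c(gend, gend, ex_end, vapply(cds, `[`, 1, i = 2)),
      strand = strand,
      id = c(gid, tid, paste0(tid, ".e", seq_len(n_ex)),
             paste0(tid, ".c", seq_len(n_ex))),
      parent = c(NA, gid, rep(tid, 2 * n_ex)),
      stringsAsFactors = FALSE)
    cursor <- gend
  }
  do.call(rbind, rows)
}

sample_te <- function(seq_id, L, spec) {
  w <- sample(seq(spec$te_len[1], spec$te_len[2]), spec$te_per_seq,
              replace = TRUE)
  s <- sample.int(L - max(w) - 1L, spec$te_per_seq)
  data.frame(seq_id = seq_id, start = s, end = s + w - 1L,
             stringsAsFactors = FALSE)
}

gff_granges <- function(df) {
  gr <- GenomicRanges::GRanges(df$seq_id,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$type <- df$type
  gr$ID <- df$id
  gr$Parent <- IRanges::CharacterList(lapply(df$parent, function(p)
    if (is.na(p)) character(0) else p))
  gr
}

write_gff3 <- function(df, path, seed) {
  attrs <- ifelse(is.na(df$parent), sprintf("ID=%s", df$id),
                  sprintf("ID=%s;Parent=%s", df$id, df$parent))
  lines <- c("##gff-version 3", paste0("# seed: ", seed),
             sprintf("%s\tssrmine_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     df$seq_id, df$type, df$start, df$end, df$strand,
                     attrs))
  writeLines(lines, path)
  invisible(path)
}

## plant loci into region-class intervals; >=2 spacer bases between
## plants; returns updated base vectors and the truth table
plant_ssrs <- function(seqs, model, spec) {
  taken <- lapply(seqs, function(s) logical(length(s)))
  truth <- list()
  classes <- names(spec$n_ssr)
  class_pool <- canonical_class_pool()
  for (cl in classes) {
    target <- spec$n_ssr[[cl]]
    if (target == 0L) next
    iv <- if (cl == "TE") model$te else model$regions[[cl]]
    iv_df <- data.frame(seq_id = as.character(GenomicRanges::seqnames(iv)),
                        start = GenomicRanges::start(iv),
                        end = GenomicRanges::end(iv),
                        stringsAsFactors = FALSE)
    planted <- 0L
    guard <- 0L
    while (planted < target) {
      guard <- guard + 1L
      if (guard > target * 400L) {
        stop("spec infeasible: cannot place ", target,
             " loci in region class ", cl, call. = FALSE)
      }
      k <- sample(1:6, 1, prob = spec$unit_weights)
      motif <- sample(class_pool[[k]], 1)
      rcn <- spec$thresholds[[k]] + stats::rgeom(1, 1 / (1 + spec$rcn_extra))
      len <- k * rcn
      w <- iv_df$end - iv_df$start + 1L
      ok_iv <- which(w >= len + 4L)
      if (length(ok_iv) == 0L) next
      row <- iv_df[ok_iv[sample.int(length(ok_iv), 1)], ]
      start <- row$start + 2L +
        sample.int(row$end - row$start + 1L - len - 4L + 1L, 1) - 1L
      end <- start + len - 1L
      guard_lo <- max(1L, start - 2L)
      guard_hi <- min(length(taken[[row$seq_id]]), end + 2L)
      if (any(taken[[row$seq_id]][guard_lo:guard_hi])) next
      seqs[[row$seq_id]][start:end] <-
        strsplit(strrep(motif, rcn), "", fixed = TRUE)[[1]]
      taken[[row$seq_id]][guard_lo:guard_hi] <- TRUE
      truth[[length(truth) + 1L]] <- data.frame(
        seq_id = row$seq_id, start = start, end = end,
        unit_length = k, motif = motif,
        canonical_motif = canonical_motif(motif), rcn = rcn,
        length_bp = len, target_class = cl, stringsAsFactors = FALSE)
      planted <- planted + 1L
    }
  }
  if (length(truth) == 0L) {
    tt <- empty_ssr_frame()
    tt$target_class <- character(0)
    return(list(seqs = seqs, truth = assign_region(tt, model)))
  }
  tt <- do.call(rbind, truth)
  tt <- tt[order(tt$seq_id, tt$start), , drop = FALSE]
  row.names(tt) <- NULL
  tt <- assign_region(tt, model)
  list(seqs = seqs, truth = tt)
}

## canonical class representatives per unit length, cached
.class_pool <- new.env(parent = emptyenv())
canonical_class_pool <- function() {
  if (is.null(.class_pool$pool)) {
    .class_pool$pool <- lapply(1:6, canonical_classes)
  }
  .class_pool$pool
}

#' Specification for simulated diploid genotype tables
#'
#' @param n_individuals Sample size (default 36, a typical captive-
#'   population genotyping design).
#' @param freqs Named list: one allele-frequency vector per locus (each
#'   summing to 1).
#' @param f Inbreeding coefficient in `[0, 1)`; 0 is Hardy-Weinberg
#'   equilibrium.
#' @param missing_rate Fraction of calls masked as missing.
#' @param seed Integer seed.
#' @return List of class `genotype_sim_spec`.
#' @export
genotype_sim_spec <- function(n_individuals = 36L,
                              freqs = list(L1 = c(a180 = 0.5, a184 = 0.3,
                                                  a188 = 0.2)),
                              f = 0, missing_rate = 0, seed = 1L) {
  stopifnot(f >= 0, f < 1, missing_rate >= 0, missing_rate < 1,
            n_individuals >= 1)
  for (p in freqs) {
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      stop("allele frequencies must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  structure(list(n_individuals = as.integer(n_individuals), freqs = freqs,
                 f = f, missing_rate = missing_rate, seed = as.integer(seed)),
            class = "genotype_sim_spec")
}

#' Simulate genotypes under (possibly inbred) Hardy-Weinberg sampling
#'
#' Draws each individual's genotype at each locus with
#' `P(het i,j) = 2 p_i p_j (1 - F)` and
#' `P(hom i) = p_i^2 + F p_i (1 - p_i)`, then masks calls missing at the
#' configured rate. `F = 0` is exact HWE; `F = 1` would be fully inbred
#' (all homozygotes).
#'
#' @param spec A [genotype_sim_spec()].
#' @return A `genotype_table` (individuals x loci).
#' @export
simulate_genotypes <- function(spec = genotype_sim_spec()) {
  stopifnot(inherits(spec, "genotype_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_individuals
  loci <- names(spec$freqs)
  if (is.null(loci)) loci <- paste0("L", seq_along(spec$freqs))
  m <- matrix(NA_character_, n, length(loci),
              dimnames = list(sprintf("ind%03d", seq_len(n)), loci))
  for (j in seq_along(spec$freqs)) {
    p <- spec$freqs[[j]]
    al <- names(p)
    if (is.null(al)) al <- paste0("a", seq_along(p))
    k <- length(p)
    gen <- expand.grid(i = seq_len(k), j = seq_len(k))
    gen <- gen[gen$i <= gen$j, ]
    prob <- ifelse(gen$i == gen$j,
                   p[gen$i]^2 + spec$f * p[gen$i] * (1 - p[gen$i]),
                   2 * p[gen$i] * p[gen$j] * (1 - spec$f))
    pick <- sample.int(nrow(gen), n, replace = TRUE, prob = prob)
    m[, j] <- paste0(al[gen$i[pick]], "/", al[gen$j[pick]])
    if (spec$missing_rate > 0) {
      m[stats::runif(n) < spec$missing_rate, j] <- NA_character_
    }
  }
  genotype_table(m)
}
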