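#' Pipeline configuration
#'
#' One object carrying every stage's options with documented defaults:
#' mining thresholds, region assignment rules, statistics conventions,
#' the marker screen, and the popgen settings. Serializable to JSON; the
#' MD5 hash of the serialized form is echoed into every report header so
#' mixed-configuration comparisons are detectable.
#'
#' @param thresholds A [mining_thresholds()].
#' @param screen A [screen_config()].
#' @param sd_type SD convention for CV (`"sample"` or `"population"`).
#' @param top_motifs Motifs kept per unit length in the ranking table.
#' @param unbiased_he,hwe_alpha,mc_reps,enum_limit,rarefaction_g,seed
#'   Popgen options; `rarefaction_g = NULL` means the minimum 2N across
#'   loci.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(thresholds = mining_thresholds(),
                            screen = screen_config(),
                            sd_type = "sample", top_motifs = 10L,
                            unbiased_he = TRUE, hwe_alpha = 0.01,
                            mc_reps = 1e5, enum_limit = 20000L,
                            rarefaction_g = NULL, seed = 1L) {
  structure(list(thresholds = thresholds, screen = screen,
                 sd_type = sd_type, top_motifs = as.integer(top_motifs),
                 unbiased_he = isTRUE(unbiased_he), hwe_alpha = hwe_alpha,
                 mc_reps = mc_reps, enum_limit = as.integer(enum_limit),
                 rarefaction_g = rarefaction_g, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_rec(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

unclass_rec <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_rec)
  else if (is.null(x)) x
  else unclass(x)
}

#' Run the full SSR characterization pipeline
#'
#' Mines perfect SSRs from a genome, builds the genomic region partition
#' from the annotation, assigns loci to regions, computes the three
#' survey summary tables plus per-group RCN coefficients of variation,
#' and screens tetranucleotide marker candidates. When `out_dir` is
#' given, writes TSV reports (`loci.tsv`, `by_type.tsv`, `motifs.tsv`,
#' `by_region.tsv`, `cv.tsv`, `candidates.tsv`, `candidates.fa`) and a
#' `run_log.txt` with package version, seed and configuration hash; each
#' TSV header echoes the config hash.
#'
#' @param fasta Genome sequences (path, character vector or
#'   `DNAStringSet`).
#' @param gff GFF3 annotation path or `GRanges`.
#' @param te_track Optional TE track (BED path, data frame or
#'   `GRanges`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List: `loci` (assigned), `model`, `tables`
#'   (`by_type`/`motifs`/`by_region`), `cv` (per type x region),
#'   `candidates`, `config_hash`.
#' @export
run_ssr_pipeline <- function(fasta, gff, te_track = NULL,
                             config = pipeline_config(), out_dir = NULL) {
  seqs <- as_seq_set(fasta)
  seq_lengths <- nchar(seqs)
  loci <- find_perfect_ssrs(seqs, config$thresholds)
  model <- build_region_model(gff, te_track, seq_lengths)
  loci <- assign_region(loci, model)
  tables <- build_summary_tables(loci, model, config$top_motifs)
  cv <- cv_table(loci, config$sd_type)
  candidates <- screen_candidates(loci, seqs, config$screen)
  hash <- config_hash(config)
  out <- list(loci = loci, model = model, tables = tables, cv = cv,
              candidates = candidates, config_hash = hash)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- c(paste("config:", hash), paste("seed:", config$seed))
    write_ssr_tsv(loci, file.path(out_dir, "loci.tsv"), hdr)
    for (nm in names(tables)) {
      write_ssr_tsv(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                    hdr)
    }
    write_ssr_tsv(cv, file.path(out_dir, "cv.tsv"), hdr)
    export_candidates(candidates, file.path(out_dir, "candidates.fa"),
                      file.path(out_dir, "candidates.tsv"))
    writeLines(c(paste("ssrmine version:",
                       as.character(utils::packageVersion("ssrmine"))),
                 paste("seed:", config$seed), paste("config hash:", hash),
                 paste("loci:", nrow(loci)),
                 paste("genome bp:", model$genome_length_bp)),
               file.path(out_dir, "run_log.txt"))
  }
  out
}

## CV of RCN per repeat type within each region class (plus genome-wide)
cv_table <- function(loci, sd_type = "sample") {
  groups <- c("Genome", levels(loci$region))
  rows <- list()
  for (g in groups) {
    sub <- if (g == "Genome") loci else loci[loci$region == g, , drop = FALSE]
    for (k in 1:6) {
      rcn <- sub$rcn[sub$unit_length == k]
      cv <- cv_of_rcn(rcn, sd_type)
      rows[[length(rows) + 1L]] <- data.frame(
        region = g, type = type_levels[k], n = cv$n,
        mean_rcn = cv$mean_rcn, sd_rcn = cv$sd_rcn,
        cv_percent = cv$cv_percent, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Run the genotype-panel diversity analysis
#'
#' Reads (or takes) a genotype table, computes per-locus diversity
#' statistics and the panel summary, and flags loci deviating from
#' Hardy-Weinberg equilibrium at the configured alpha (such loci are
#' the conventional candidates for exclusion from a marker panel).
#'
#' @param genotypes A `genotype_table` or TSV path for
#'   [read_genotypes()].
#' @param config A [pipeline_config()].
#' @param out Optional TSV output path (per-locus rows; the panel means
#'   go into the header comments together with the config hash).
#' @return List: `per_locus` data frame, `panel` summary list,
#'   `config_hash`.
#' @export
run_popgen <- function(genotypes, config = pipeline_config(), out = NULL) {
  gt <- if (is.character(genotypes) && !is.matrix(genotypes)) {
    read_genotypes(genotypes)
  } else genotypes
  per_locus <- locus_diversity(gt, g = config$rarefaction_g,
                               unbiased_he = config$unbiased_he,
                               hwe_alpha = config$hwe_alpha,
                               mc_reps = config$mc_reps,
                               seed = config$seed,
                               enum_limit = config$enum_limit)
  panel <- panel_summary(per_locus)
  hash <- config_hash(config)
  if (!is.null(out)) {
    hdr <- c(paste("config:", hash),
             sprintf("panel: loci=%d alleles=%d mean_Ho=%.3f mean_He=%.3f mean_Ar=%.3f mean_PIC=%.3f",
                     panel$n_loci, panel$total_alleles, panel$Ho$mean,
                     panel$He$mean, panel$Ar$mean, panel$PIC$mean))
    write_ssr_tsv(per_locus, out, hdr)
  }
  list(per_locus = per_locus, panel = panel, config_hash = hash)
}

#' Published forest musk deer SSR survey tables
#'
#' Reference tabulations from a published genome-wide SSR survey of the
#' forest musk deer (*Moschus berezovskii*) genome, shipped as plain
#' text: `"by_type"` (genome-wide per-type counts, GC, lengths,
#' abundance), `"by_region"` (per-type locus counts in six genomic
#' region classes) and `"markers"` (the 21-locus diversity panel plus
#' the one locus discarded for HWE deviation). These serve as worked
#' examples and as fixtures for checking the summary builders against
#' independently published arithmetic.
#'
#' @param which One of `"by_type"`, `"by_region"`, `"markers"`.
#' @return Data frame.
#' @export
fmd_survey_table <- function(which = c("by_type", "by_region", "markers")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0("fmd_", which, ".tsv"),
                   package = "ssrmine")
  utils::read.table(f, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
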