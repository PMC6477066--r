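#' Simulation configuration for a recessive-mutant F2 mapping study
#'
#' Bundles every knob of the synthetic-data module into a validated list.
#' The defaults emulate the study conditions of a gamma-ray tomato mutant
#' mapped in an F2 cross: a monogenic recessive 2-bp deletion, a 20-plant
#' mutant sequencing bulk at ~30x depth, a SolCAP-like array with 1956
#' informative markers out of 7600, an F2 of 186 plants, and three-replicate
#' ovary RNA-seq with one planted >10-fold up-regulated gene.
#'
#' The simulated genome is deliberately smaller than a real tomato genome
#' (three 8-Mb chromosomes) while the genetic map density (1 cM / 750 kb) and
#' the marker count are kept at study scale, so recombination-limited
#' quantities -- cosegregation interval sizes of a few Mbp with ~45 mutant
#' plants -- behave as in the real cross.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param gene_density Protein-coding genes per bp (default 1.03e-4, i.e.
#'   267 genes per 2.6 Mbp). Ignored when `n_genes` is given.
#' @param n_genes Optional fixed total gene count (apportioned to
#'   chromosomes by length); when `NULL` per-chromosome counts are Poisson
#'   with mean `gene_density * length`.
#' @param cds_codon_range Range (min, max) of CDS lengths in codons,
#'   sampled uniformly per gene. The CDS excludes the stop codon.
#' @param causal_chrom Chromosome carrying the causal gene.
#' @param causal_type Causal variant type, `"deletion"` (default) or `"snp"`.
#' @param causal_size Deletion length in bp (default 2, a frameshift).
#' @param mutagen_rate Mutagen-induced variant rate per bp, homozygous in the
#'   mutant parent (default 3e-6, gamma-ray scale).
#' @param indel_fraction Fraction of background variants that are 1-3 bp
#'   indels rather than SNPs.
#' @param intracultivar_rate Rate per bp of pre-existing intra-cultivar
#'   variants segregating independently of the cross (default 5e-5); their
#'   carrier frequency is drawn from U(0.5, 1) so the class includes
#'   near-fixed cultivar-vs-reference differences.
#' @param f2_size Number of F2 individuals (default 186).
#' @param bulk_size Number of mutant-phenotype plants pooled for sequencing
#'   (default 20).
#' @param depth_mean Mean per-variant sequencing depth of the bulk, Poisson
#'   distributed (default 30).
#' @param seq_error Per-read probability that the observed allele is flipped
#'   (default 0.005).
#' @param cm_per_bp Genetic map density in centimorgans per bp under the
#'   Haldane model (default 1 cM / 750 kb, tomato-like).
#' @param marker_n_total,marker_n_informative Size of the array marker panel
#'   and how many of its markers distinguish the two parents.
#' @param genotype_error,genotype_missing Per-call array genotyping error and
#'   missingness rates (defaults 0).
#' @param rnaseq_replicates RNA-seq replicates per group (default 3).
#' @param rnaseq_dispersion Negative-binomial dispersion of replicate counts
#'   (default 0.005; each replicate is a pool of 15-17 ovaries, which damps
#'   biological variability).
#' @param rnaseq_planted_up,rnaseq_planted_down Numbers of planted up- and
#'   down-regulated genes (defaults 13 and 12).
#' @param rnaseq_fc Fold change of ordinary planted genes (default 4).
#' @param rnaseq_fc_max Fold change of the single strongest planted gene
#'   (default 16, emulating a GA20ox1-like >10-fold response).
#' @param seed Integer seed giving byte-identical outputs on re-run.
#'
#' @return A list of class `fg_config`.
#' @examples
#' cfg <- sim_config(chrom_lengths = c(chr1 = 5e5), f2_size = 20)
#' cfg$bulk_size
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 8e6, chr2 = 8e6, chr3 = 8e6),
                       gene_density = 1.03e-4,
                       n_genes = NULL,
                       cds_codon_range = c(150L, 650L),
                       causal_chrom = "chr2",
                       causal_type = c("deletion", "snp"),
                       causal_size = 2L,
                       mutagen_rate = 3e-6,
                       indel_fraction = 0.1,
                       intracultivar_rate = 5e-5,
                       f2_size = 186L,
                       bulk_size = 20L,
                       depth_mean = 30,
                       seq_error = 0.005,
                       cm_per_bp = 1 / 750e3,
                       marker_n_total = 7600L,
                       marker_n_informative = 1956L,
                       genotype_error = 0,
                       genotype_missing = 0,
                       rnaseq_replicates = 3L,
                       rnaseq_dispersion = 0.005,
                       rnaseq_planted_up = 13L,
                       rnaseq_planted_down = 12L,
                       rnaseq_fc = 4,
                       rnaseq_fc_max = 16,
                       seed = 1L) {
  causal_type <- match.arg(causal_type)
  cfg <- list(
    chrom_lengths = chrom_lengths, gene_density = gene_density,
    n_genes = n_genes, cds_codon_range = as.integer(cds_codon_range),
    causal_chrom = causal_chrom, causal_type = causal_type,
    causal_size = as.integer(causal_size),
    mutagen_rate = mutagen_rate, indel_fraction = indel_fraction,
    intracultivar_rate = intracultivar_rate,
    f2_size = as.integer(f2_size), bulk_size = as.integer(bulk_size),
    depth_mean = depth_mean, seq_error = seq_error, cm_per_bp = cm_per_bp,
    marker_n_total = as.integer(marker_n_total),
    marker_n_informative = as.integer(marker_n_informative),
    genotype_error = genotype_error, genotype_missing = genotype_missing,
    rnaseq_replicates = as.integer(rnaseq_replicates),
    rnaseq_dispersion = rnaseq_dispersion,
    rnaseq_planted_up = as.integer(rnaseq_planted_up),
    rnaseq_planted_down = as.integer(rnaseq_planted_down),
    rnaseq_fc = rnaseq_fc, rnaseq_fc_max = rnaseq_fc_max,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "fg_config")
}

validate_config <- function(cfg) {
  if (length(cfg$chrom_lengths) < 1 || is.null(names(cfg$chrom_lengths)) ||
      anyNA(cfg$chrom_lengths) || any(cfg$chrom_lengths < 1)) {
    abort("`chrom_lengths` must be a named vector of positive lengths.")
  }
  rates <- c(mutagen_rate = cfg$mutagen_rate,
             intracultivar_rate = cfg$intracultivar_rate,
             seq_error = cfg$seq_error,
             genotype_error = cfg$genotype_error,
             genotype_missing = cfg$genotype_missing,
             indel_fraction = cfg$indel_fraction)
  bad <- rates < 0 | rates > 1
  if (any(bad)) {
    abort(paste0("rates must lie in [0, 1]: ",
                 paste(names(rates)[bad], collapse = ", ")))
  }
  counts <- c(cfg$f2_size, cfg$bulk_size, cfg$marker_n_total,
              cfg$marker_n_informative, cfg$rnaseq_replicates,
              cfg$rnaseq_planted_up, cfg$rnaseq_planted_down)
  if (any(counts < 0)) abort("counts must be >= 0")
  if (cfg$marker_n_informative > cfg$marker_n_total) {
    abort("`marker_n_informative` cannot exceed `marker_n_total`")
  }
  if (cfg$depth_mean < 0) abort("`depth_mean` must be >= 0")
  if (cfg$rnaseq_dispersion <= 0) abort("`rnaseq_dispersion` must be > 0")
  if (!cfg$causal_chrom %in% names(cfg$chrom_lengths)) {
    abort("`causal_chrom` is not one of `chrom_lengths`")
  }
  if (cfg$cm_per_bp < 0) abort("`cm_per_bp` must be >= 0")
  if (cfg$causal_size < 1) abort("`causal_size` must be >= 1")
  invisible(cfg)
}

#' @export
print.fg_config <- function(x, ...) {
  cat("<fg_config>\n")
  cat("  genome: ", length(x$chrom_lengths), " chromosome(s), ",
      format(sum(x$chrom_lengths), big.mark = ","), " bp\n", sep = "")
  cat("  F2 size ", x$f2_size, ", bulk ", x$bulk_size,
      ", depth mean ", x$depth_mean, "\n", sep = "")
  cat("  markers ", x$marker_n_informative, "/", x$marker_n_total,
      " informative; seed ", x$seed, "\n", sep = "")
  invisible(x)
}
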