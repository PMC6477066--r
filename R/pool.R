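#' Pool a bulk of F2 plants and draw per-variant allele read counts
#'
#' Emulates bulked-segregant sequencing: equal DNA contribution per plant,
#' per-variant depth Poisson with mean `depth_mean`, and mutant-allele read
#' counts binomial with success probability equal to the bulk mutant-allele
#' frequency perturbed by a symmetric sequencing-error flip
#' (`p = f(1-e) + (1-f)e`). For causal and mutagen variants the bulk allele
#' frequency follows from the parental origin of each pooled haplotype at the
#' variant position; intra-cultivar variants are carried per haplotype with
#' probability `cultivar_freq`, independent of the cross.
#'
#' @param population An `f2_population`.
#' @param variants Variant tibble from [plant_variants()].
#' @param bulk Individual ids to pool; default all mutant-phenotype plants.
#' @param depth_mean Mean sequencing depth per variant (Poisson).
#' @param error_rate Per-read allele-flip probability.
#' @return Tibble: variant columns plus `true_af` (bulk allele frequency),
#'   `mut_reads`, `wt_reads`, `depth`.
#' @examples
#' set.seed(1)
#' cfg <- sim_config(chrom_lengths = c(chr1 = 6e4), causal_chrom = "chr1",
#'                   mutagen_rate = 0, intracultivar_rate = 0, f2_size = 30)
#' ref <- build_reference(cfg)
#' vars <- plant_variants(ref$sequence, ref$genes, cfg)
#' pop <- simulate_f2(cfg, vars)
#' pool_and_sequence(pop, vars, depth_mean = 25, error_rate = 0)
#' @export
pool_and_sequence <- function(population, variants, bulk = NULL,
                              depth_mean = 30, error_rate = 0.005) {
  if (is.null(bulk)) {
    bulk <- population$phenotypes$individual[
      population$phenotypes$phenotype == "mutant"]
  }
  if (length(bulk) == 0) abort("bulk is empty")
  if (depth_mean < 0) abort("`depth_mean` must be >= 0")
  nb <- length(bulk)
  nv <- nrow(variants)
  f <- numeric(nv)

  linked <- variants$origin %in% c("causal", "mutagen")
  for (cn in unique(variants$chrom[linked])) {
    sel <- which(linked & variants$chrom == cn)
    oc <- origin_counts(population$segments, cn, variants$pos[sel])
    rows <- match(bulk, oc$individual)
    cnt <- oc$counts[rows, , drop = FALSE]
    f[sel] <- colSums(cnt) / (2 * nb)
  }
  icv <- which(variants$origin == "intra_cultivar")
  if (length(icv)) {
    f[icv] <- rbinom(length(icv), 2L * nb, variants$cultivar_freq[icv]) / (2 * nb)
  }

  depth <- rpois(nv, depth_mean)
  p_eff <- f * (1 - error_rate) + (1 - f) * error_rate
  mut_reads <- rbinom(nv, depth, p_eff)
  variants |>
    mutate(true_af = f, mut_reads = mut_reads,
           wt_reads = depth - mut_reads, depth = depth)
}
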