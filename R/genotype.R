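#' Simulate an array marker panel and the two parental genotype profiles
#'
#' Places `config$marker_n_total` markers uniformly over the genome and
#' simulates the genotype calls of the two parents on that panel: at
#' `config$marker_n_informative` markers the parents carry distinct
#' homozygous calls (AA in the mutant parent, BB in the other parent); the
#' remaining markers are monomorphic, heterozygous, or missing in a parent
#' and therefore uninformative for mapping.
#'
#' @param config An [sim_config()] object.
#' @return List with `panel` (tibble `marker_id`, `chrom`, `pos`),
#'   `parent_a` and `parent_b` (tibbles `marker_id`, `call`); parent A is
#'   the mutant parent.
#' @export
make_marker_panel <- function(config) {
  lens <- config$chrom_lengths
  total <- config$marker_n_total
  chrom <- sample(names(lens), total, replace = TRUE, prob = lens / sum(lens))
  pos <- integer(total)
  for (cn in unique(chrom)) {
    i <- chrom == cn
    pos[i] <- sort(sample.int(lens[[cn]], sum(i)))
  }
  ord <- order(chrom, pos)
  panel <- tibble(marker_id = sprintf("mk%05d", seq_len(total)),
                  chrom = chrom[ord], pos = pos[ord])

  informative <- sort(sample.int(total, config$marker_n_informative))
  call_a <- call_b <- rep("AA", total)
  other <- setdiff(seq_len(total), informative)
  # uninformative markers: monomorphic, het, or missing in a parent
  kind <- sample(c("mono", "het", "missing"), length(other),
                 replace = TRUE, prob = c(0.8, 0.1, 0.1))
  call_b[informative] <- "BB"
  call_a[other][kind == "het"] <- "AB"
  call_b[other][kind == "missing"] <- "missing"
  list(panel = panel,
       parent_a = tibble(marker_id = panel$marker_id, call = call_a),
       parent_b = tibble(marker_id = panel$marker_id, call = call_b))
}

#' Genotype an F2 population on a marker panel
#'
#' Calls each individual at each marker from the parental origin of its two
#' haplotypes: AA when both haplotypes are mutant-parent, BB when both are
#' from the other parent, AB otherwise. Genotyping errors (a call replaced by
#' a random different call) and missingness are applied independently per
#' call at the given rates.
#'
#' @param population An `f2_population` from [simulate_f2()].
#' @param panel Marker tibble with `marker_id`, `chrom`, `pos`.
#' @param error_rate,missing_rate Per-call rates in \[0, 1\].
#' @return Long genotype tibble: `individual`, `phenotype`, `marker_id`,
#'   `chrom`, `pos`, `call` (AA/AB/BB/missing).
#' @export
genotype_array <- function(population, panel, error_rate = 0,
                           missing_rate = 0) {
  if (error_rate < 0 || error_rate > 1 || missing_rate < 0 || missing_rate > 1)
    abort("rates must lie in [0, 1]")
  bad <- !panel$chrom %in% names(population$chrom_lengths) |
    panel$pos < 1 |
    panel$pos > unlist(population$chrom_lengths[panel$chrom])
  if (any(bad)) {
    abort(sprintf("%d marker(s) fall outside the simulated chromosomes",
                  sum(bad)))
  }

  out <- vector("list", length(unique(panel$chrom)))
  chroms <- unique(panel$chrom)
  for (k in seq_along(chroms)) {
    pm <- panel[panel$chrom == chroms[k], ]
    oc <- origin_counts(population$segments, chroms[k], pm$pos)
    calls <- matrix(c("BB", "AB", "AA")[oc$counts + 1L],
                    nrow = nrow(oc$counts))
    out[[k]] <- tibble(
      individual = rep(oc$individual, times = nrow(pm)),
      marker_id = rep(pm$marker_id, each = length(oc$individual)),
      chrom = chroms[k],
      pos = rep(pm$pos, each = length(oc$individual)),
      call = as.vector(calls)
    )
  }
  geno <- bind_rows(out)

  n <- nrow(geno)
  if (error_rate > 0) {
    flip <- which(runif(n) < error_rate)
    if (length(flip)) {
      geno$call[flip] <- vapply(geno$call[flip], function(cc) {
        sample(setdiff(c("AA", "AB", "BB"), cc), 1L)
      }, character(1))
    }
  }
  if (missing_rate > 0) {
    geno$call[runif(n) < missing_rate] <- "missing"
  }

  geno |>
    left_join(population$phenotypes, by = "individual") |>
    select("individual", "phenotype", "marker_id", "chrom", "pos", "call") |>
    arrange(.data$individual, .data$chrom, .data$pos)
}
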