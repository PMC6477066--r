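#' Simulate a two-group RNA-seq count matrix with planted fold changes
#'
#' Draws negative-binomial counts for WT and mutant ovary pools
#' (`config$rnaseq_replicates` per group, dispersion
#' `config$rnaseq_dispersion`). Baseline means are log-normal; among genes
#' with baseline mean >= 100, `rnaseq_planted_up` genes are up-regulated in
#' the mutant (one at `rnaseq_fc_max`-fold, emulating a GA20ox1-like
#' >10-fold response, the rest at `rnaseq_fc`-fold) and
#' `rnaseq_planted_down` genes are down-regulated at 1/`rnaseq_fc`. The true
#' planted effect is recorded per gene in `true_log2fc`.
#'
#' @param config An [sim_config()] object.
#' @param genes Optional gene-model tibble; when given, gene ids and
#'   transcript lengths (summed exon widths) come from the models, otherwise
#'   `n_genes` synthetic genes with lengths U(500, 3000) are used.
#' @param n_genes Number of genes when `genes` is `NULL` (default 2000).
#' @return Long count tibble: `gene_id`, `gene_length`, `sample_id`,
#'   `group` (WT/mutant), `count`, `true_log2fc`.
#' @examples
#' set.seed(1)
#' counts <- simulate_rnaseq_counts(sim_config(), n_genes = 50)
#' dplyr::count(counts, group)
#' @export
simulate_rnaseq_counts <- function(config, genes = NULL, n_genes = 2000L) {
  if (config$rnaseq_dispersion <= 0) abort("dispersion must be > 0")
  reps <- config$rnaseq_replicates
  if (reps < 2) abort("need >= 2 replicates per group")

  if (!is.null(genes) && nrow(genes) > 0) {
    gl <- genes |>
      filter(.data$type == "exon") |>
      group_by(.data$gene_id) |>
      summarise(gene_length = sum(.data$end - .data$start + 1L),
                .groups = "drop")
  } else {
    gl <- tibble(gene_id = sprintf("gene%05d", seq_len(n_genes)),
                 gene_length = sample(500:3000, n_genes, replace = TRUE))
  }
  ng <- nrow(gl)

  base_mean <- rlnorm(ng, meanlog = log(80), sdlog = 1.5)
  lfc <- rep(0, ng)
  eligible <- which(base_mean >= 100)
  n_up <- min(config$rnaseq_planted_up, length(eligible))
  up <- if (n_up > 0) sample(eligible, n_up) else integer(0)
  remaining <- setdiff(eligible, up)
  n_dn <- min(config$rnaseq_planted_down, length(remaining))
  dn <- if (n_dn > 0) sample(remaining, n_dn) else integer(0)
  if (n_up < config$rnaseq_planted_up || n_dn < config$rnaseq_planted_down) {
    warn("fewer eligible genes (baseline mean >= 100) than planted effects requested")
  }
  if (length(up)) {
    lfc[up] <- log2(config$rnaseq_fc)
    lfc[up[1]] <- log2(config$rnaseq_fc_max)
  }
  if (length(dn)) lfc[dn] <- -log2(config$rnaseq_fc)

  samples <- tibble(
    sample_id = c(sprintf("WT_%d", seq_len(reps)),
                  sprintf("mutant_%d", seq_len(reps))),
    group = rep(c("WT", "mutant"), each = reps)
  )
  size <- 1 / config$rnaseq_dispersion
  out <- vector("list", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    mu <- if (samples$group[s] == "mutant") base_mean * 2^lfc else base_mean
    out[[s]] <- tibble(gene_id = gl$gene_id, gene_length = gl$gene_length,
                       sample_id = samples$sample_id[s],
                       group = samples$group[s],
                       count = rnbinom(ng, mu = mu, size = size),
                       true_log2fc = lfc)
  }
  bind_rows(out)
}
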