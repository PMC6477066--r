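#' @export
print.fg_run <- function(x, ...) {
  cat("<fg_run> seed", x$seed, "\n")
  s <- x$segregation
  cat(sprintf("  segregation: %d WT / %d mutant, chi-square %.2f (%s at 0.05)\n",
              s$n_wt, s$n_mutant, s$statistic,
              if (s$significant) "significant" else "ns"))
  if (nrow(x$interval)) {
    cat(sprintf("  interval: %s:%d-%d (%.1f Mbp, %d genes)\n",
                x$interval$chrom, x$interval$left, x$interval$right,
                interval_length_mbp(x$interval), nrow(x$interval_genes)))
  } else {
    cat("  interval: none found\n")
  }
  nc <- if (is.null(x$candidates)) 0L else nrow(x$candidates)
  cat(sprintf("  candidates after filters: %d variant(s) in %d gene(s)\n",
              nc, if (nc) length(unique(x$candidates$gene_id)) else 0L))
  cat(sprintf("  causal gene %s; top-ranked %s (%srecovered)\n",
              x$causal_gene, x$top_gene %||% "none",
              if (x$recovered_top) "" else "NOT "))
  if (!is.null(x$de)) {
    cat(sprintf("  RNA-seq DE: %d up, %d down\n", x$de$n_up, x$de$n_down))
  }
  invisible(x)
}

#' Tidy the ranked candidate table of a pipeline run
#'
#' @param x An `fg_run` object.
#' @param ... Unused.
#' @return Tibble of ranked candidate variants with effect annotations and,
#'   when the confirmation stage ran, cosegregation results.
#' @export
tidy.fg_run <- function(x, ...) {
  if (is.null(x$candidates)) {
    return(tibble(gene_id = character(), chrom = character(),
                  pos = integer(), effect = character()))
  }
  as_tibble(x$candidates)
}

#' One-row summary of a pipeline run
#'
#' @param x An `fg_run` object.
#' @param ... Unused.
#' @return One-row tibble: seed, segregation statistic, interval size and
#'   gene count, candidate counts, recovery flags, DE counts.
#' @export
glance.fg_run <- function(x, ...) {
  tibble(
    seed = x$seed,
    chi_square = x$segregation$statistic,
    segregation_ns = !x$segregation$significant,
    interval_mbp = if (nrow(x$interval)) interval_length_mbp(x$interval) else NA_real_,
    interval_contains_causal = if (nrow(x$interval)) {
      x$interval$chrom == x$causal_variant$chrom &&
        x$causal_variant$pos >= x$interval$left &&
        x$causal_variant$pos <= x$interval$right
    } else NA,
    n_interval_genes = nrow(x$interval_genes),
    n_candidate_variants = if (is.null(x$candidates)) 0L else nrow(x$candidates),
    n_candidate_genes = if (is.null(x$candidates)) 0L else
      length(unique(x$candidates$gene_id)),
    top_gene = x$top_gene,
    causal_gene = x$causal_gene,
    recovered_top = x$recovered_top,
    recovered_any = x$recovered_any,
    n_de_up = if (is.null(x$de)) NA_integer_ else x$de$n_up,
    n_de_down = if (is.null(x$de)) NA_integer_ else x$de$n_down
  )
}

#' Plot SNP/Indel indices along the genome
#'
#' Manhattan-style plot of per-variant SNP/Indel indices, with the depth and
#' index thresholds and (optionally) the candidate interval and causal locus
#' marked.
#'
#' @param records Output of [compute_snp_index()].
#' @param interval Optional one-row interval tibble to shade.
#' @param causal Optional list/tibble with `chrom` and `pos` of the true
#'   locus.
#' @param min_index Index threshold line (default 0.9).
#' @return A ggplot object.
#' @export
plot_snp_index <- function(records, interval = NULL, causal = NULL,
                           min_index = 0.9) {
  dat <- records |> filter(.data$defined)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos / 1e6, y = .data$index)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$origin), alpha = 0.7) +
    ggplot2::geom_hline(yintercept = min_index, linetype = "dashed") +
    ggplot2::facet_wrap(~chrom, nrow = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mbp)", y = "SNP/Indel index",
                  colour = "origin") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
  if (!is.null(interval) && nrow(interval)) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(interval) |> mutate(chrom = .data$chrom),
      ggplot2::aes(xmin = .data$left / 1e6, xmax = .data$right / 1e6),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue",
      inherit.aes = FALSE)
  }
  if (!is.null(causal)) {
    p <- p + ggplot2::geom_vline(
      data = tibble(chrom = causal$chrom, pos = causal$pos),
      ggplot2::aes(xintercept = .data$pos / 1e6),
      colour = "red", linetype = "dotted")
  }
  p
}

#' Autoplot method for pipeline runs
#'
#' @param object An `fg_run` object.
#' @param ... Passed to [plot_snp_index()].
#' @return A ggplot object.
#' @export
autoplot.fg_run <- function(object, ...) {
  plot_snp_index(object$snp_records,
                 interval = if (nrow(object$interval)) object$interval else NULL,
                 causal = object$causal_variant, ...)
}

#' Volcano plot of a differential-expression result
#'
#' @param de DE result tibble from [differential_test()].
#' @param lfc,q_threshold Thresholds to draw (defaults 1 and 0.05).
#' @return A ggplot object.
#' @export
plot_de_volcano <- function(de, lfc = 1, q_threshold = 0.05) {
  dat <- de |> filter(!is.na(.data$q_value))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2fc,
                                    y = -log10(.data$q_value),
                                    colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-lfc, lfc), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(q_threshold), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "steelblue",
                                            unchanged = "grey60")) +
    ggplot2::labs(x = "log2 fold change (mutant / WT)",
                  y = "-log10 q value") +
    ggplot2::theme_bw()
}
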