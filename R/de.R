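#' Reads per kilobase of transcript per million mapped reads
#'
#' RPKM = count / (gene length in kb x library size in millions), computed
#' per sample with the library size taken as that sample's total mapped
#' count.
#'
#' @param data Long count tibble with columns `gene_id`, `gene_length`,
#'   `sample_id`, `group`, `count`.
#' @return The input with an added `rpkm` column.
#' @examples
#' d <- tibble::tibble(gene_id = "g1", gene_length = 1000,
#'                     sample_id = "s1", group = "WT", count = 10)
#' compute_rpkm(dplyr::mutate(d, count = 1e6))$rpkm
#' @export
compute_rpkm <- function(data) {
  need <- c("gene_id", "gene_length", "sample_id", "count")
  if (!all(need %in% names(data))) {
    abort(paste("`data` must have columns", paste(need, collapse = ", ")))
  }
  if (any(data$gene_length <= 0)) abort("gene lengths must be > 0")
  out <- as_tibble(data) |>
    group_by(.data$sample_id) |>
    mutate(lib_size = sum(.data$count)) |>
    ungroup()
  if (any(out$lib_size == 0)) abort("zero library size")
  out |>
    mutate(rpkm = .data$count / ((.data$gene_length / 1e3) *
                                   (.data$lib_size / 1e6))) |>
    select(-"lib_size")
}

#' Filter to expressed genes
#'
#' A gene is considered expressed when its mean RPKM across replicates is at
#' least `threshold` in at least one group (either-group rule; a gene
#' expressed only in the mutant is still testable).
#'
#' @param data RPKM tibble from [compute_rpkm()].
#' @param threshold Mean-RPKM cutoff (default 1).
#' @return The rows of `data` belonging to expressed genes.
#' @export
filter_expressed <- function(data, threshold = 1) {
  if (!"rpkm" %in% names(data)) abort("run `compute_rpkm()` first")
  keep <- data |>
    group_by(.data$gene_id, .data$group) |>
    summarise(m = mean(.data$rpkm), .groups = "drop_last") |>
    summarise(expressed = any(.data$m >= threshold), .groups = "drop") |>
    filter(.data$expressed)
  data |> filter(.data$gene_id %in% keep$gene_id)
}

#' Per-gene two-group differential expression test on RPKM
#'
#' Two-sample t-test on log2(RPKM + pseudocount) per gene, multiplicity
#' adjustment across the tested (expressed) genes (Benjamini-Hochberg q
#' values by default; Bonferroni available), and log2 fold ratio of group
#' mean RPKM (mutant vs WT, pseudocount-stabilised). Calls: `up` when
#' log2FC >= `lfc` and q < `q_threshold`, `down` when log2FC <= -`lfc` and
#' q < `q_threshold`, otherwise `unchanged`; genes present in `data` but not
#' in the expressed set are reported as `not_expressed` and excluded from
#' the adjustment. Genes with zero within-group variance in both groups have
#' an undefined p value and are flagged in `note`.
#'
#' @param data RPKM tibble (all genes, from [compute_rpkm()]).
#' @param expressed Optional tibble of expressed-gene rows (from
#'   [filter_expressed()]); default tests every gene in `data`.
#' @param lfc Absolute log2-fold-change call threshold (default 1).
#' @param q_threshold q-value call threshold (default 0.05).
#' @param pseudocount Added to RPKM before log2 and to group means before
#'   the ratio (default 1).
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @param test `"student"` (default) or `"welch"`. With only three
#'   replicates per group Welch's Satterthwaite degrees of freedom collapse
#'   toward 2, which places a floor on attainable p values and starves the
#'   multiplicity adjustment of power, so the pooled-variance test is the
#'   default.
#' @param ref_group Name of the reference group (default `"WT"`); the fold
#'   change is the other group over this one.
#' @return Tibble with one row per gene: `gene_id`, `mean_rpkm_ref`,
#'   `mean_rpkm_alt`, `log2fc`, `p_value`, `q_value`, `call`, `note`.
#' @export
differential_test <- function(data, expressed = NULL, lfc = 1,
                              q_threshold = 0.05, pseudocount = 1,
                              adjust = c("BH", "bonferroni"),
                              test = c("student", "welch"),
                              ref_group = "WT") {
  adjust <- match.arg(adjust)
  test <- match.arg(test)
  if (!"rpkm" %in% names(data)) abort("run `compute_rpkm()` first")
  groups <- unique(data$group)
  if (length(groups) != 2 || !ref_group %in% groups) {
    abort("`data` must contain exactly two groups including `ref_group`")
  }
  alt_group <- setdiff(groups, ref_group)
  reps <- data |> distinct(.data$group, .data$sample_id) |> count(.data$group)
  if (any(reps$n < 2)) abort("need >= 2 replicates per group")

  tested_ids <- if (is.null(expressed)) unique(data$gene_id) else
    unique(expressed$gene_id)

  wide <- data |>
    filter(.data$gene_id %in% tested_ids) |>
    select("gene_id", "sample_id", "rpkm") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "rpkm")
  m <- as.matrix(wide[, -1])
  sample_groups <- data |>
    distinct(.data$sample_id, .data$group)
  grp <- sample_groups$group[match(colnames(m), sample_groups$sample_id)]
  lx <- log2(m + pseudocount)
  ref_cols <- grp == ref_group

  p <- vapply(seq_len(nrow(lx)), function(i) {
    x <- lx[i, ref_cols]; y <- lx[i, !ref_cols]
    tryCatch(t.test(y, x, var.equal = test == "student")$p.value,
             error = function(e) NA_real_)
  }, numeric(1))

  mean_ref <- rowMeans(m[, ref_cols, drop = FALSE])
  mean_alt <- rowMeans(m[, !ref_cols, drop = FALSE])
  log2fc <- log2((mean_alt + pseudocount) / (mean_ref + pseudocount))
  q <- p.adjust(p, method = adjust)

  call <- dplyr::case_when(
    !is.na(q) & log2fc >= lfc & q < q_threshold ~ "up",
    !is.na(q) & log2fc <= -lfc & q < q_threshold ~ "down",
    .default = "unchanged"
  )
  res <- tibble(gene_id = wide$gene_id,
                mean_rpkm_ref = mean_ref, mean_rpkm_alt = mean_alt,
                log2fc = log2fc, p_value = p, q_value = q, call = call,
                note = ifelse(is.na(p), "zero_variance", NA_character_))

  skipped <- setdiff(unique(data$gene_id), tested_ids)
  if (length(skipped)) {
    res <- bind_rows(res, tibble(
      gene_id = skipped, mean_rpkm_ref = NA_real_, mean_rpkm_alt = NA_real_,
      log2fc = NA_real_, p_value = NA_real_, q_value = NA_real_,
      call = "not_expressed", note = NA_character_))
  }
  res |> arrange(.data$gene_id)
}

#' Overlap differential-expression calls with an external gene list
#'
#' Compares the up/down calls of a DE result with a reference list of
#' direction-annotated genes (for instance genes responding to a hormone
#' treatment) and tallies concordant, discordant, and absent genes.
#'
#' @param de DE result tibble from [differential_test()].
#' @param reference Tibble with `gene_id` and `direction` (`"up"`/`"down"`).
#' @return Tibble with `category` (`up_up`, `down_down`, `discordant`,
#'   `absent`), `n`, and `genes` (list column).
#' @export
overlap_with_list <- function(de, reference) {
  called <- de |> filter(.data$call %in% c("up", "down"))
  j <- left_join(called, reference, by = "gene_id")
  up_up <- j$gene_id[!is.na(j$direction) & j$call == "up" & j$direction == "up"]
  dn_dn <- j$gene_id[!is.na(j$direction) & j$call == "down" & j$direction == "down"]
  disc <- j$gene_id[!is.na(j$direction) & j$call != j$direction]
  absent <- j$gene_id[is.na(j$direction)]
  tibble(category = c("up_up", "down_down", "discordant", "absent"),
         n = c(length(up_up), length(dn_dn), length(disc), length(absent)),
         genes = list(up_up, dn_dn, disc, absent))
}
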