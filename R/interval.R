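#' Retain markers that distinguish the two parents
#'
#' A marker is informative for F2 mapping only when the two parents carry
#' distinct homozygous calls; heterozygous or missing parental calls are
#' discarded.
#'
#' @param parent_a,parent_b Tibbles with `marker_id` and `call`
#'   (AA/AB/BB/missing).
#' @param panel Marker tibble (`marker_id`, `chrom`, `pos`).
#' @return The informative subset of `panel` (possibly empty, with a
#'   warning).
#' @export
select_informative_markers <- function(parent_a, parent_b, panel) {
  calls <- inner_join(parent_a, parent_b, by = "marker_id",
                      suffix = c("_a", "_b"))
  hom <- c("AA", "BB")
  keep <- calls$call_a %in% hom & calls$call_b %in% hom &
    calls$call_a != calls$call_b
  ids <- calls$marker_id[keep]
  out <- panel |> filter(.data$marker_id %in% ids)
  if (nrow(out) == 0) warn("no informative markers: parents are indistinguishable on this panel")
  out
}

#' Map the candidate interval cosegregating with the mutant phenotype
#'
#' Finds, among mutant-phenotype individuals only, the maximal run of
#' consecutive markers at which every individual is homozygous for the
#' mutant-parent allele (AA). Missing calls are ignored as uninformative;
#' a heterozygous call in a mutant-phenotype individual breaks cosegregation
#' at that marker (such individuals are listed in the `het_individuals`
#' attribute as a phenotyping-error diagnostic). The interval's flanks are
#' the first non-cosegregating markers on each side -- the outer bound that
#' is guaranteed to contain the causal locus -- or the chromosome ends. Ties
#' between runs with equally many cosegregating markers are broken by longest
#' physical span, then lowest chromosome/position.
#'
#' @param genotypes Long genotype tibble from [genotype_array()] (columns
#'   `individual`, `phenotype`, `marker_id`, `chrom`, `pos`, `call`).
#' @param panel Marker tibble (`marker_id`, `chrom`, `pos`).
#' @param chrom_lengths Optional named vector; used for flank positions when
#'   a run touches a panel end (otherwise the run-edge marker position is
#'   used).
#' @return One-row tibble: `chrom`, `left`, `right`, `left_marker`,
#'   `right_marker`, `n_markers`, `span_bp`; zero rows (with a warning and a
#'   `diagnostics` attribute) when no marker cosegregates.
#' @export
map_cosegregating_interval <- function(genotypes, panel,
                                       chrom_lengths = NULL) {
  mut <- genotypes |> filter(.data$phenotype == "mutant")
  if (nrow(mut) == 0) abort("no mutant-phenotype individuals in the table")

  per_marker <- mut |>
    group_by(.data$marker_id) |>
    summarise(n_break = sum(.data$call %in% c("AB", "BB")), .groups = "drop")
  het_tbl <- mut |>
    filter(.data$call == "AB") |>
    count(.data$individual, name = "n_het_markers")

  pan <- panel |>
    arrange(.data$chrom, .data$pos) |>
    left_join(per_marker, by = "marker_id") |>
    mutate(coseg = is.na(.data$n_break) | .data$n_break == 0)

  runs <- list()
  for (cn in unique(pan$chrom)) {
    pc <- pan[pan$chrom == cn, ]
    r <- rle(pc$coseg)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    tr <- which(r$values)
    for (k in tr) {
      i1 <- starts[k]; i2 <- ends[k]
      runs[[length(runs) + 1L]] <- tibble(
        chrom = cn, i1 = i1, i2 = i2, n_markers = i2 - i1 + 1L,
        span_bp = pc$pos[i2] - pc$pos[i1],
        run_left = pc$pos[i1],
        left = if (i1 > 1) pc$pos[i1 - 1L]
               else if (!is.null(chrom_lengths)) 1L else pc$pos[i1],
        right = if (i2 < nrow(pc)) pc$pos[i2 + 1L]
                else if (!is.null(chrom_lengths)) as.integer(chrom_lengths[[cn]])
                else pc$pos[i2],
        left_marker = if (i1 > 1) pc$marker_id[i1 - 1L] else NA_character_,
        right_marker = if (i2 < nrow(pc)) pc$marker_id[i2 + 1L] else NA_character_
      )
    }
  }
  if (length(runs) == 0) {
    warn("no marker cosegregates with the mutant phenotype")
    out <- tibble(chrom = character(), left = integer(), right = integer(),
                  left_marker = character(), right_marker = character(),
                  n_markers = integer(), span_bp = integer())
    attr(out, "diagnostics") <- pan |>
      arrange(.data$n_break) |>
      head(5) |>
      select("marker_id", "chrom", "pos", "n_break")
    attr(out, "het_individuals") <- het_tbl
    return(out)
  }
  best <- bind_rows(runs) |>
    arrange(desc(.data$n_markers), desc(.data$span_bp),
            .data$chrom, .data$run_left) |>
    slice(1) |>
    select("chrom", "left", "right", "left_marker", "right_marker",
           "n_markers", "span_bp")
  attr(best, "het_individuals") <- het_tbl
  best
}

#' Narrow a candidate interval with an additional genotyped marker
#'
#' When an extra marker inside the interval fails to cosegregate (some
#' mutant-phenotype individual is not AA), it replaces the flank on its side
#' and shrinks the interval; a marker that cosegregates in every mutant
#' leaves the interval unchanged. A single failing marker does not by itself
#' reveal which side of the causal locus it lies on, so `side = "auto"`
#' replaces the nearer flank (the usual situation when markers are picked to
#' split a flank-heavy region); pass `"left"` or `"right"` when recombinant
#' haplotypes have been inspected.
#'
#' @param interval One-row interval tibble from
#'   [map_cosegregating_interval()].
#' @param extra_genotypes Tibble of calls at one marker: `individual`,
#'   `marker_id`, `chrom`, `pos`, `call`, and optionally `phenotype` (when
#'   present only mutant rows are used).
#' @param side `"auto"`, `"left"`, or `"right"`.
#' @return The updated interval tibble.
#' @export
narrow_interval <- function(interval, extra_genotypes,
                            side = c("auto", "left", "right")) {
  side <- match.arg(side)
  if (nrow(interval) != 1) abort("`interval` must have exactly one row")
  pos <- unique(extra_genotypes$pos)
  mk <- unique(extra_genotypes$marker_id)
  cn <- unique(extra_genotypes$chrom)
  if (length(pos) != 1 || length(mk) != 1) {
    abort("`extra_genotypes` must describe a single marker")
  }
  if (cn != interval$chrom || pos <= interval$left || pos >= interval$right) {
    abort(sprintf("marker %s at %s:%d lies outside the interval (%d-%d)",
                  mk, cn, pos, interval$left, interval$right))
  }
  gg <- extra_genotypes
  if ("phenotype" %in% names(gg)) gg <- gg[gg$phenotype == "mutant", ]
  fails <- any(gg$call %in% c("AB", "BB"))
  if (!fails) return(interval)

  if (side == "auto") {
    side <- if (pos - interval$left <= interval$right - pos) "left" else "right"
  }
  if (side == "left") {
    interval$left <- pos
    interval$left_marker <- mk
  } else {
    interval$right <- pos
    interval$right_marker <- mk
  }
  interval$span_bp <- interval$right - interval$left
  interval
}

#' Interval length in Mbp
#'
#' @param interval One-row interval tibble (columns `left`, `right`).
#' @param digits Decimal places (default 1, matching how mapping intervals
#'   are conventionally reported).
#' @return Length in Mbp, rounded.
#' @examples
#' iv <- tibble::tibble(chrom = "chr4", left = 57939715, right = 60553996)
#' interval_length_mbp(iv)
#' @export
interval_length_mbp <- function(interval, digits = 1) {
  if (nrow(interval) < 1) abort("empty interval")
  if (any(interval$left >= interval$right)) abort("interval left must be < right")
  round((interval$right - interval$left) / 1e6, digits)
}

#' Genes overlapping a candidate interval
#'
#' Closed-interval, any-overlap rule: a gene is counted when its genomic
#' span intersects `[left, right]` at one or more bases, so a gene abutting a
#' flank is included and the causal gene can never be dropped by a boundary
#' convention.
#'
#' @param genes Gene-model feature tibble.
#' @param interval One-row interval tibble.
#' @return Tibble of overlapping genes (`gene_id`, `chrom`, `strand`,
#'   `start`, `end`).
#' @export
genes_in_interval <- function(genes, interval) {
  if (nrow(interval) != 1) abort("`interval` must have exactly one row")
  gene_spans(genes) |>
    filter(.data$chrom == interval$chrom,
           .data$end >= interval$left,
           .data$start <= interval$right)
}
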