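#' Compute the SNP/Indel index of pooled allele counts
#'
#' The SNP/Indel index of a variant is the proportion of bulk reads carrying
#' the mutant allele: `mut_reads / (mut_reads + wt_reads)`. At a locus
#' homozygous in every pooled plant the index is ~1; at loci unlinked to the
#' selected phenotype it fluctuates around 0.5 in an F2 bulk. Zero-depth
#' records are flagged undefined (`index = NA`), never divided.
#'
#' @param data Tibble with integer columns `mut_reads` and `wt_reads`
#'   (e.g. from [pool_and_sequence()] or [read_pooled_vcf()]).
#' @return The input with added `depth`, `index`, and `defined` columns.
#' @examples
#' compute_snp_index(tibble::tibble(mut_reads = c(10, 5, 0),
#'                                  wt_reads = c(0, 5, 0)))
#' @export
compute_snp_index <- function(data) {
  if (!all(c("mut_reads", "wt_reads") %in% names(data))) {
    abort("`data` must have columns `mut_reads` and `wt_reads`")
  }
  if (any(data$mut_reads < 0 | data$wt_reads < 0, na.rm = TRUE)) {
    abort("read counts must be >= 0")
  }
  as_tibble(data) |>
    mutate(depth = .data$mut_reads + .data$wt_reads,
           defined = .data$depth > 0,
           index = ifelse(.data$depth > 0, .data$mut_reads / .data$depth,
                          NA_real_))
}

#' Subtract intra-cultivar background variants
#'
#' Removes records whose variant identity -- the exact
#' (chrom, pos, ref, alt) key after left-anchoring -- matches a variant in
#' the background set (e.g. variants segregating among wild-type individuals
#' of the parental cultivar, discovered from WT resequencing).
#' Position-only near-matches with a different allele are retained with a
#' warning, so distinct overlapping indels are never silently discarded.
#' The operation is idempotent.
#'
#' @param records Variant record tibble (columns `chrom`, `pos`, `ref`,
#'   `alt`, ...).
#' @param background Background variant tibble with the same key columns.
#' @return `records` minus the exact matches.
#' @export
subtract_intracultivar <- function(records, background) {
  if (is.null(background) || nrow(background) == 0) return(records)
  key <- c("chrom", "pos", "ref", "alt")
  out <- anti_join(records, background |> select(all_of(key)), by = key)
  near <- semi_join(out, background |> select("chrom", "pos"),
                    by = c("chrom", "pos"))
  if (nrow(near) > 0) {
    warn(sprintf(
      "%d record(s) share a position with a background variant but differ in allele; retained",
      nrow(near)))
  }
  out
}

#' Filter candidate variants by depth, index, and candidate interval
#'
#' Retains records with reliable read support (`depth >= min_depth`,
#' default 10), a high SNP/Indel index consistent with homozygosity in the
#' bulk (`index >= min_index`, default 0.9 -- tolerant of sequencing error at
#' the depth floor), and, when an interval is supplied, a position inside
#' it. The three filters are tallied separately in the `filter_log`
#' attribute.
#'
#' @param records Output of [compute_snp_index()].
#' @param min_depth Minimum total depth (default 10).
#' @param min_index Minimum SNP/Indel index (default 0.9).
#' @param interval Optional one-row interval tibble; only records on its
#'   chromosome between its flanks pass.
#' @return The surviving records, with a `filter_log` attribute (tibble of
#'   per-filter counts).
#' @export
filter_candidates <- function(records, min_depth = 10, min_index = 0.9,
                              interval = NULL) {
  if (min_depth < 0) abort("`min_depth` must be >= 0")
  if (min_index < 0 || min_index > 1) abort("`min_index` must lie in [0, 1]")
  rec <- records |>
    mutate(passes_depth = .data$depth >= min_depth,
           passes_index = .data$defined & .data$index >= min_index,
           in_interval = if (is.null(interval)) TRUE else
             .data$chrom == interval$chrom &
             .data$pos >= interval$left & .data$pos <= interval$right)
  log <- tibble(
    filter = c("input", "depth", "index", "interval", "retained"),
    n = c(nrow(rec), sum(rec$passes_depth), sum(rec$passes_index),
          sum(rec$in_interval),
          sum(rec$passes_depth & rec$passes_index & rec$in_interval))
  )
  out <- rec |> filter(.data$passes_depth & .data$passes_index & .data$in_interval)
  attr(out, "filter_log") <- log
  out
}

#' Assign candidate variants to genes by CDS overlap
#'
#' A variant is assigned to a gene iff its reference span overlaps a CDS
#' interval of that gene (the coding-region rule: intronic and intergenic
#' variants are assigned to no gene). Many variants may map to one gene;
#' genes are de-duplicated and their variants nested.
#'
#' @param records Variant record tibble (`chrom`, `pos`, `ref`, ...).
#' @param genes Gene-model feature tibble.
#' @return Nested tibble: `gene_id`, `chrom`, `n_variants`, `variants`
#'   (list column of the records hitting each gene).
#' @export
variants_to_genes <- function(records, genes) {
  if (nrow(records) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  n_variants = integer(), variants = list()))
  }
  cds <- genes |>
    filter(.data$type == "CDS") |>
    select("gene_id", "chrom", cds_start = "start", cds_end = "end")
  rec <- records |>
    mutate(span_start = .data$pos,
           span_end = .data$pos + nchar(.data$ref) - 1L)
  hits <- inner_join(
    rec, cds,
    by = join_by(chrom, overlaps(span_start, span_end, cds_start, cds_end))
  ) |>
    distinct(.data$gene_id, .data$chrom, .data$pos, .data$ref, .data$alt,
             .keep_all = TRUE) |>
    select(-"cds_start", -"cds_end", -"span_start", -"span_end")
  hits |>
    tidyr::nest(variants = -"gene_id") |>
    mutate(chrom = map_chr(.data$variants, ~ .x$chrom[1]),
           n_variants = map_int(.data$variants, nrow)) |>
    select("gene_id", "chrom", "n_variants", "variants")
}
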