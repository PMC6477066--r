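#' @noRd
variant_cols <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), class = character(), origin = character(),
         cultivar_freq = double())
}

# One random SNP/indel at a given position, VCF left-anchored. `seq_raw` is
# the chromosome as a raw vector (substr on multi-Mb native strings is slow
# in multibyte locales).
#' @noRd
random_variant <- function(seq_raw, pos, indel_fraction) {
  L <- length(seq_raw)
  base_at <- function(a, b) rawToChar(seq_raw[a:b])
  if (runif(1) >= indel_fraction) {
    ref <- base_at(pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    return(list(pos = pos, ref = ref, alt = alt, class = "snp"))
  }
  k <- sample(1:3, 1L)
  anchor <- base_at(pos, pos)
  if (runif(1) < 0.5 || pos + k > L) {
    list(pos = pos, ref = anchor, alt = paste0(anchor, random_dna(k)),
         class = "insertion")
  } else {
    list(pos = pos, ref = base_at(pos, pos + k), alt = anchor,
         class = "deletion")
  }
}

#' @noRd
random_variant_set <- function(reference, rate, indel_fraction, origin) {
  lens <- nchar(reference)
  n <- rpois(1, rate * sum(lens))
  if (n == 0) return(variant_cols())
  chrom <- sample(names(reference), n, replace = TRUE,
                  prob = lens / sum(lens))
  raws <- lapply(reference, charToRaw)
  pos <- ref <- alt <- cls <- vector("list", n)
  for (i in seq_len(n)) {
    L <- lens[[chrom[i]]]
    p <- sample.int(L - 5L, 1L) + 1L
    v <- random_variant(raws[[chrom[i]]], p, indel_fraction)
    pos[[i]] <- v$pos; ref[[i]] <- v$ref; alt[[i]] <- v$alt; cls[[i]] <- v$class
  }
  tibble(chrom = chrom, pos = as.integer(unlist(pos)), ref = unlist(ref),
         alt = unlist(alt), class = unlist(cls), origin = origin,
         cultivar_freq = NA_real_)
}

# First CDS chunk in transcription order for one gene.
#' @noRd
first_cds_chunk <- function(genes, gene_id) {
  cds <- genes |> filter(.data$gene_id == !!gene_id, .data$type == "CDS")
  if (cds$strand[1] == "+") cds[which.min(cds$start), ] else cds[which.max(cds$end), ]
}

#' Plant the causal, mutagen-induced, and intra-cultivar variants
#'
#' Creates the three origin classes of variants the mapping pipeline must
#' disentangle: exactly one causal variant (by default a 2-bp frameshift
#' deletion in the first exon of the causal gene), mutagen-induced background
#' variants homozygous in the mutant parent, and intra-cultivar variants
#' segregating among wild-type individuals independently of the cross (their
#' per-haplotype carrier frequency, drawn from U(0.5, 1), is stored in
#' `cultivar_freq`). Indels are VCF left-anchored with one reference base.
#'
#' @param reference Named character vector of chromosome sequences.
#' @param genes Gene-model feature tibble.
#' @param config An [sim_config()] object.
#' @param causal_gene Optional gene id to mutate; default is the gene nearest
#'   the midpoint of `config$causal_chrom`.
#' @return Tibble of variants with columns `chrom`, `pos`, `ref`, `alt`,
#'   `class`, `origin`, `cultivar_freq`; the causal row has
#'   `origin == "causal"`.
#' @examples
#' set.seed(1)
#' cfg <- sim_config(chrom_lengths = c(chr1 = 6e4), causal_chrom = "chr1",
#'                   mutagen_rate = 0, intracultivar_rate = 0)
#' ref <- build_reference(cfg)
#' plant_variants(ref$sequence, ref$genes, cfg)
#' @export
plant_variants <- function(reference, genes, config, causal_gene = NULL) {
  spans <- gene_spans(genes) |> filter(.data$chrom == config$causal_chrom)
  if (nrow(spans) == 0) {
    abort(sprintf("no gene on causal chromosome %s to mutate",
                  config$causal_chrom))
  }
  if (is.null(causal_gene)) {
    mid <- config$chrom_lengths[[config$causal_chrom]] / 2
    causal_gene <- spans$gene_id[which.min(abs((spans$start + spans$end) / 2 - mid))]
  } else if (!causal_gene %in% spans$gene_id) {
    abort("`causal_gene` is not a gene on the causal chromosome")
  }

  chunk <- first_cds_chunk(genes, causal_gene)
  seqc <- reference[[chunk$chrom]]
  chunk_len <- chunk$end - chunk$start + 1L
  if (config$causal_type == "deletion") {
    k <- config$causal_size
    if (chunk_len < k + 4L) abort("causal deletion does not fit in first exon CDS")
    # CDS-coordinate offset of the first deleted base (skip the start codon)
    d <- sample(seq(4L, chunk_len - k), 1L)
    if (chunk$strand == "+") {
      a <- chunk$start + d - 1L
    } else {
      a <- chunk$end - d - k + 2L
    }
    b <- a + k - 1L
    p <- a - 1L
    causal <- tibble(chrom = chunk$chrom, pos = p,
                     ref = substr(seqc, p, b), alt = substr(seqc, p, p),
                     class = "deletion", origin = "causal",
                     cultivar_freq = NA_real_)
  } else {
    d <- sample(seq(4L, chunk_len), 1L)
    p <- if (chunk$strand == "+") chunk$start + d - 1L else chunk$end - d + 1L
    ref_b <- substr(seqc, p, p)
    causal <- tibble(chrom = chunk$chrom, pos = p, ref = ref_b,
                     alt = sample(setdiff(c("A", "C", "G", "T"), ref_b), 1L),
                     class = "snp", origin = "causal",
                     cultivar_freq = NA_real_)
  }

  mut <- random_variant_set(reference, config$mutagen_rate,
                            config$indel_fraction, "mutagen")
  icv <- random_variant_set(reference, config$intracultivar_rate,
                            config$indel_fraction, "intra_cultivar")
  if (nrow(icv)) icv$cultivar_freq <- runif(nrow(icv), 0.5, 1)

  out <- bind_rows(causal, mut, icv)
  # drop background variants colliding with the causal site or each other
  causal_span <- seq(causal$pos, causal$pos + nchar(causal$ref) - 1L)
  out <- out |>
    filter(.data$origin == "causal" |
             !(.data$chrom == causal$chrom & .data$pos %in% causal_span)) |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
    arrange(.data$chrom, .data$pos)
  attr(out, "causal_gene") <- causal_gene
  out
}
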