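#' Write and read the reference sequence as FASTA
#'
#' @param reference Named character vector of chromosome sequences.
#' @param path Output file.
#' @return `path`, invisibly (writer); named character vector (reader).
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference), path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write and read gene models as GFF3
#'
#' Gene rows carry an `ID` attribute; exon and CDS rows carry `Parent`.
#' Coordinates are 1-based inclusive throughout.
#'
#' @param genes Gene-model feature tibble.
#' @param path Output file.
#' @return `path`, invisibly (writer); feature tibble (reader).
#' @export
write_gene_models_gff3 <- function(genes, path) {
  # GFF3 phase of each CDS interval: bases of the first complete codon,
  # from the cumulative CDS length 5' of it in transcription order
  phase <- rep(NA_integer_, nrow(genes))
  is_cds <- genes$type == "CDS"
  for (g in unique(genes$gene_id[is_cds])) {
    idx <- which(is_cds & genes$gene_id == g)
    ord <- if (genes$strand[idx[1]] == "+") order(genes$start[idx]) else
      order(-genes$end[idx])
    widths <- (genes$end - genes$start + 1L)[idx][ord]
    before <- cumsum(c(0L, widths[-length(widths)]))
    phase[idx[ord]] <- (3L - before %% 3L) %% 3L
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand,
    type = genes$type,
    source = "fgmap",
    phase = phase,
    ID = ifelse(genes$type == "gene", genes$gene_id, NA_character_),
    Parent = ifelse(genes$type == "gene", NA_character_, genes$gene_id)
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_models_gff3
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  parent <- vapply(df$Parent, function(p) {
    if (length(p)) as.character(p)[1] else NA_character_
  }, character(1))
  tibble(
    gene_id = ifelse(df$type == "gene", as.character(df$ID), parent),
    chrom = as.character(df$seqnames),
    strand = as.character(df$strand),
    type = as.character(df$type),
    start = df$start, end = df$end
  ) |>
    filter(.data$type %in% c("gene", "exon", "CDS")) |>
    arrange(.data$chrom, .data$start, .data$gene_id)
}

#' Write a variant set as VCF, read pooled allele counts from VCF
#'
#' The writer stores the origin label in `INFO/ORIGIN` and, when the
#' variants carry pooled read counts, an AD-style `FORMAT` field
#' (`wt_reads,mut_reads` -- reference then alternate depth) for a single
#' `bulk` sample. The reader recovers the per-allele depths from AD.
#' `vcfR` writes gzip-compressed VCF when `path` ends in `.gz`.
#'
#' @param variants Variant tibble (optionally with `mut_reads`/`wt_reads`).
#' @param path Output file (`.vcf` or `.vcf.gz`).
#' @return `path`, invisibly (writer); tibble with `chrom`, `pos`, `ref`,
#'   `alt`, `origin`, `wt_reads`, `mut_reads` (reader).
#' @importClassesFrom vcfR vcfR
#' @export
write_variants_vcf <- function(variants, path) {
  meta <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"Variant origin class\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">"
  )
  info <- if ("origin" %in% names(variants)) {
    paste0("ORIGIN=", variants$origin)
  } else rep(".", nrow(variants))
  fix <- cbind(
    CHROM = variants$chrom, POS = as.character(variants$pos),
    ID = rep(".", nrow(variants)), REF = variants$ref, ALT = variants$alt,
    QUAL = rep(".", nrow(variants)), FILTER = rep(".", nrow(variants)),
    INFO = info
  )
  has_counts <- all(c("mut_reads", "wt_reads") %in% names(variants))
  gt <- if (has_counts) {
    cbind(FORMAT = rep("AD", nrow(variants)),
          bulk = paste(variants$wt_reads, variants$mut_reads, sep = ","))
  } else {
    matrix(character(0), nrow = nrow(variants), ncol = 0)
  }
  v <- new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' @rdname write_variants_vcf
#' @export
read_pooled_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  origin <- sub("^.*ORIGIN=([^;]+).*$", "\\1", fix$INFO)
  origin[!grepl("ORIGIN=", fix$INFO)] <- NA_character_
  out <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, origin = origin
  )
  if (ncol(v@gt) >= 2) {
    ad <- vcfR::extract.gt(v, element = "AD")[, 1]
    parts <- strsplit(ad, ",", fixed = TRUE)
    out$wt_reads <- as.integer(vapply(parts, `[`, character(1), 1))
    out$mut_reads <- as.integer(vapply(parts, `[`, character(1), 2))
  }
  out
}

#' Write and read a genotype table as TSV
#'
#' Wide layout: one row per individual, a `phenotype` column, then one
#' column per marker with calls in AA/AB/BB/missing.
#'
#' @param genotypes Long genotype tibble from [genotype_array()].
#' @param path Output file.
#' @param panel Marker tibble (`marker_id`, `chrom`, `pos`) used to restore
#'   marker coordinates when reading.
#' @return `path`, invisibly (writer); long genotype tibble (reader).
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  wide <- genotypes |>
    select("individual", "phenotype", "marker_id", "call") |>
    tidyr::pivot_wider(names_from = "marker_id", values_from = "call")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path, panel) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  wide |>
    tidyr::pivot_longer(-c("individual", "phenotype"),
                        names_to = "marker_id", values_to = "call") |>
    inner_join(panel, by = "marker_id") |>
    select("individual", "phenotype", "marker_id", "chrom", "pos", "call") |>
    arrange(.data$individual, .data$chrom, .data$pos)
}

#' Write and read an RNA-seq count matrix as TSV
#'
#' Wide layout: `gene_id`, `gene_length`, then one column per sample named
#' `<group>_<replicate>`; the group of each sample is recovered from the
#' prefix before the final underscore.
#'
#' @param counts Long count tibble from [simulate_rnaseq_counts()].
#' @param path Output file.
#' @return `path`, invisibly (writer); long count tibble (reader).
#' @export
write_counts_tsv <- function(counts, path) {
  wide <- counts |>
    select("gene_id", "gene_length", "sample_id", "count") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  wide |>
    tidyr::pivot_longer(-c("gene_id", "gene_length"),
                        names_to = "sample_id", values_to = "count") |>
    mutate(group = sub("_[0-9]+$", "", .data$sample_id)) |>
    select("gene_id", "gene_length", "sample_id", "group", "count")
}
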