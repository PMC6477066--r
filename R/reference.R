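#' @noRd
random_dna <- function(n) {
  if (n <= 0) return("")
  rawToChar(sample(charToRaw("ACGT"), n, replace = TRUE))
}

#' @noRd
nonstop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# Stop-free coding sequence of n_codons codons starting with ATG.
#' @noRd
stop_free_cds <- function(n_codons) {
  stopifnot(n_codons >= 1)
  if (n_codons == 1) return("ATG")
  paste0("ATG",
         paste(sample(nonstop_codons(), n_codons - 1L, replace = TRUE),
               collapse = ""))
}

#' @noRd
revcomp <- function(x) {
  rawToChar(rev(charToRaw(chartr("ACGTacgt", "TGCAtgca", x))))
}

# Draw the transcription-order anatomy of one gene: UTRs, CDS chunks,
# introns, and the stop codon right after the CDS 3' end. Plain vectors --
# this runs once per simulated gene.
#' @noRd
gene_anatomy <- function(cds_codon_range) {
  n_codons <- sample(seq(cds_codon_range[1], cds_codon_range[2]), 1L)
  cds_len <- 3L * n_codons
  n_exons <- sample(1:3, 1L)
  if (n_exons == 1L) {
    chunk_lens <- cds_len
  } else {
    repeat {
      cuts <- sort(sample(seq(60L, cds_len - 60L), n_exons - 1L))
      chunk_lens <- diff(c(0L, cuts, cds_len))
      if (all(chunk_lens >= 60L)) break
    }
  }
  introns <- if (n_exons > 1L) sample(80:800, n_exons - 1L, replace = TRUE) else integer(0)
  utr5 <- sample(0:150, 1L)
  utr3 <- sample(60:200, 1L)

  types <- character(0); lens <- integer(0)
  if (utr5 > 0) { types <- "utr5"; lens <- utr5 }
  for (i in seq_len(n_exons)) {
    types <- c(types, "cds"); lens <- c(lens, chunk_lens[i])
    if (i < n_exons) { types <- c(types, "intron"); lens <- c(lens, introns[i]) }
  }
  types <- c(types, "stop", "utr3")
  lens <- c(lens, 3L, utr3)
  tend <- cumsum(lens)
  list(n_codons = n_codons, cds_len = cds_len, type = types,
       t_start = tend - lens + 1L, t_end = tend, total = sum(lens))
}

# Map transcription-order segments onto the genome for a gene whose span is
# [gstart, gstart + total - 1]. On "-" the transcript runs right-to-left.
# Returns genomic start/end vectors aligned with anatomy$type.
#' @noRd
place_anatomy <- function(anatomy, gstart, strand) {
  if (strand == "+") {
    list(start = gstart + anatomy$t_start - 1L,
         end = gstart + anatomy$t_end - 1L)
  } else {
    list(start = gstart + anatomy$total - anatomy$t_end,
         end = gstart + anatomy$total - anatomy$t_start)
  }
}

# Exons = maximal runs of transcription-adjacent non-intron segments.
#' @noRd
exon_intervals <- function(type, start, end) {
  is_intron <- type == "intron"
  grp <- cumsum(is_intron)[!is_intron]
  s <- start[!is_intron]; e <- end[!is_intron]
  ex_start <- as.integer(tapply(s, grp, min))
  ex_end <- as.integer(tapply(e, grp, max))
  o <- order(ex_start)
  list(start = ex_start[o], end = ex_end[o])
}

#' Simulate a reference sequence with non-overlapping gene models
#'
#' Generates one random chromosome sequence per entry of
#' `config$chrom_lengths` and populates it with non-overlapping
#' protein-coding gene models. Each gene has 1-3 exons, a CDS whose length is
#' divisible by 3 and excludes the stop codon, an optional 5' UTR, and a 3'
#' UTR beginning with the stop codon. CDS regions are written into the
#' sequence as stop-free open reading frames (first codon ATG) so that wild
#' type models always translate cleanly; a TAA stop codon is written
#' immediately 3' of the CDS end.
#'
#' @param config An [sim_config()] object.
#' @return A list with `sequence` (named character vector of chromosome
#'   sequences) and `genes` (tibble of features with columns `gene_id`,
#'   `chrom`, `strand`, `type` in gene/exon/CDS, `start`, `end`; 1-based
#'   inclusive coordinates, GFF3 convention).
#' @examples
#' set.seed(1)
#' ref <- build_reference(sim_config(chrom_lengths = c(chr1 = 6e4),
#'                                   causal_chrom = "chr1"))
#' dplyr::count(ref$genes, type)
#' @export
build_reference <- function(config) {
  validate_config(config)
  chroms <- names(config$chrom_lengths)
  lens <- config$chrom_lengths
  if (!is.null(config$n_genes)) {
    n_per <- round(config$n_genes * lens / sum(lens))
    # keep the fixed total exact despite rounding
    n_per[1] <- config$n_genes - sum(n_per[-1])
  } else {
    n_per <- rpois(length(lens), config$gene_density * lens)
  }

  seqs <- vector("list", length(chroms))
  names(seqs) <- chroms
  feats <- vector("list", length(chroms))
  gene_offset <- 0L
  empty <- tibble(gene_id = character(), chrom = character(),
                  strand = character(), type = character(),
                  start = integer(), end = integer())

  for (ci in seq_along(chroms)) {
    L <- as.integer(lens[[ci]])
    n <- n_per[[ci]]
    base <- sample(charToRaw("ACGT"), L, replace = TRUE)
    f_gene <- f_type <- f_strand <- vector("list", n)
    f_start <- f_end <- vector("list", n)
    wr_start <- wr_content <- vector("list", n)
    if (n > 0) {
      anatomies <- replicate(n, gene_anatomy(config$cds_codon_range),
                             simplify = FALSE)
      totals <- map_int(anatomies, "total")
      slack <- L - sum(totals) - (n + 1L)
      if (slack < 0) {
        abort(sprintf(
          "requested %d genes (%d bp) do not fit in chromosome %s (%d bp)",
          n, sum(totals), chroms[ci], L))
      }
      gaps <- as.vector(stats::rmultinom(1, slack, rep(1, n + 1L))) + 1L
      gstarts <- cumsum(c(0L, totals[-n])) + cumsum(gaps[seq_len(n)]) + 1L
      strands <- sample(c("+", "-"), n, replace = TRUE)

      for (gi in seq_len(n)) {
        an <- anatomies[[gi]]
        pl <- place_anatomy(an, gstarts[gi], strands[gi])

        cds_seq <- stop_free_cds(an$n_codons)
        is_cds <- an$type == "cds"
        cds_start <- pl$start[is_cds]; cds_end <- pl$end[is_cds]
        ts <- an$t_start[is_cds]
        o <- order(ts)
        widths <- (cds_end - cds_start + 1L)[o]
        offs <- cumsum(c(0L, widths[-length(widths)]))
        chunks <- substring(cds_seq, offs + 1L, offs + widths)
        if (strands[gi] == "-") chunks <- vapply(chunks, revcomp, character(1))
        stp <- which(an$type == "stop")
        wr_start[[gi]] <- c(cds_start[o], pl$start[stp])
        wr_content[[gi]] <- c(chunks,
                              if (strands[gi] == "-") "TTA" else "TAA")

        ex <- exon_intervals(an$type, pl$start, pl$end)
        n_ex <- length(ex$start); n_cds <- length(cds_start)
        f_gene[[gi]] <- rep(sprintf("gene%05d", gene_offset + gi),
                            1L + n_ex + n_cds)
        f_strand[[gi]] <- rep(strands[gi], 1L + n_ex + n_cds)
        f_type[[gi]] <- c("gene", rep("exon", n_ex), rep("CDS", n_cds))
        f_start[[gi]] <- c(min(pl$start), ex$start, sort(cds_start))
        f_end[[gi]] <- c(max(pl$end), ex$end, sort(cds_end))
      }
      # single vectorised write: repeated subassignment would copy the
      # chromosome once per gene
      starts <- unlist(wr_start)
      contents <- unlist(wr_content)
      idx <- sequence(nchar(contents), from = starts)
      base[idx] <- charToRaw(paste(contents, collapse = ""))
    }
    seqs[[ci]] <- rawToChar(base)
    feats[[ci]] <- if (n > 0) {
      tibble(gene_id = unlist(f_gene), chrom = chroms[ci],
             strand = unlist(f_strand), type = unlist(f_type),
             start = as.integer(unlist(f_start)),
             end = as.integer(unlist(f_end)))
    } else empty
    gene_offset <- gene_offset + n
  }

  genes <- bind_rows(feats) |> arrange(.data$chrom, .data$start, .data$gene_id)
  list(sequence = unlist(seqs), genes = genes)
}

#' Genomic span of each gene model
#'
#' @param genes Gene-model feature tibble from [build_reference()].
#' @return Tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`.
#' @export
gene_spans <- function(genes) {
  genes |>
    filter(.data$type == "gene") |>
    select("gene_id", "chrom", "strand", "start", "end")
}
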