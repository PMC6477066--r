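# Splice genomic intervals into a transcription-order sequence: extract
# ascending intervals, concatenate, reverse-complement on "-".
#' @noRd
splice_seq <- function(seq, intervals, strand) {
  if (nrow(intervals) == 0) return("")
  iv <- intervals[order(intervals$start), ]
  s <- paste(substring(seq, iv$start, iv$end), collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' @noRd
translate_str <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(x, 1, 3L * n)),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

#' Translate the coding sequence of a gene model
#'
#' Extracts the CDS intervals (transcription order, reverse-complemented on
#' the minus strand), concatenates them, and translates with the standard
#' genetic code. Under the convention used throughout this package the CDS
#' excludes the stop codon, so a 2871-bp CDS yields a 957-residue protein.
#' An internal stop codon in a supposed wild-type model triggers a
#' validation warning.
#'
#' @param genes Gene-model feature tibble.
#' @param reference Named character vector of chromosome sequences.
#' @param gene_id Gene to translate.
#' @return The protein sequence (single character string, no stop).
#' @examples
#' ex <- truncation_example()
#' nchar(translate_cds(ex$genes, ex$reference, ex$gene_id))
#' @export
translate_cds <- function(genes, reference, gene_id) {
  feats <- genes[genes$gene_id == gene_id & genes$type == "CDS", ]
  if (nrow(feats) == 0) abort(sprintf("no CDS for gene %s", gene_id))
  cds_len <- sum(feats$end - feats$start + 1L)
  if (cds_len %% 3L != 0L) {
    abort(sprintf("CDS length %d of %s is not divisible by 3", cds_len, gene_id))
  }
  seq <- reference[[feats$chrom[1]]]
  prot <- translate_str(splice_seq(seq, feats, feats$strand[1]))
  if (grepl("*", prot, fixed = TRUE)) {
    warn(sprintf("internal stop codon in CDS of %s", gene_id))
  }
  prot
}

#' Apply a variant to a sequence and return the coordinate shift map
#'
#' Substitutions replace bases in place; insertions and deletions shift all
#' downstream coordinates by `nchar(alt) - nchar(ref)`. The returned `lift`
#' function maps reference coordinates onto the mutated sequence (positions
#' inside a deleted run collapse onto the anchor base), so gene-model
#' intervals can be lifted across the edit.
#'
#' @param reference Named character vector of chromosome sequences.
#' @param variant One-row tibble with `chrom`, `pos`, `ref`, `alt`
#'   (left-anchored, 1-based).
#' @return List with `sequence` (the mutated named vector), `delta` (net
#'   length change), and `lift` (function mapping old to new coordinates).
#' @export
apply_variant <- function(reference, variant) {
  if (nrow(variant) != 1) abort("`variant` must have exactly one row")
  seq <- reference[[variant$chrom]]
  if (is.null(seq)) abort(sprintf("chromosome %s not in reference", variant$chrom))
  ref_end <- variant$pos + nchar(variant$ref) - 1L
  observed <- substr(seq, variant$pos, ref_end)
  if (observed != variant$ref) {
    abort(sprintf(
      "reference allele mismatch at %s:%d: expected %s, sequence has %s (wrong genome build?)",
      variant$chrom, variant$pos, variant$ref, observed))
  }
  mutated <- paste0(substr(seq, 1L, variant$pos - 1L), variant$alt,
                    substr(seq, ref_end + 1L, nchar(seq)))
  delta <- nchar(variant$alt) - nchar(variant$ref)
  anchor <- variant$pos
  lift <- function(p) {
    ifelse(p <= anchor, p,
           ifelse(p > ref_end, p + delta, anchor))
  }
  reference[[variant$chrom]] <- mutated
  list(sequence = reference, delta = delta, lift = lift)
}

# Transcript sequence downstream of the CDS 3' end (stop codon + 3' UTR),
# in transcription order -- the region scanned when a frameshift removes the
# native stop.
#' @noRd
downstream_of_cds <- function(seq, exons, cds, strand) {
  if (strand == "+") {
    cds_end <- max(cds$end)
    dn <- exons |>
      mutate(start = pmax(.data$start, cds_end + 1L)) |>
      filter(.data$start <= .data$end)
  } else {
    cds_end <- min(cds$start)
    dn <- exons |>
      mutate(end = pmin(.data$end, cds_end - 1L)) |>
      filter(.data$start <= .data$end)
  }
  splice_seq(seq, dn, strand)
}

# The genomic span whose bases a variant changes. SNP/MNP: the substituted
# bases; deletion: the deleted run (after the anchor base); insertion: the
# two bases flanking the insertion point.
#' @noRd
changed_span <- function(variant) {
  nr <- nchar(variant$ref); na <- nchar(variant$alt)
  if (nr == na) {
    c(variant$pos, variant$pos + nr - 1L)
  } else if (nr > na) {
    c(variant$pos + 1L, variant$pos + nr - 1L)
  } else {
    c(variant$pos, variant$pos + 1L)
  }
}

#' @noRd
overlaps_any <- function(span, intervals) {
  any(intervals$end >= span[1] & intervals$start <= span[2])
}

#' Classify the effect of variants on gene models
#'
#' Each variant is classified against the gene whose span contains it:
#' non-genic positions are intergenic, non-exonic gene positions intronic,
#' exonic non-coding positions UTR. Coding SNPs are called
#' synonymous/missense/nonsense by protein comparison. Coding indels are
#' in-frame when the net length change is divisible by 3 and frameshifts
#' otherwise; for frameshift and nonsense calls the mutated CDS is
#' re-translated -- scanning past the annotated CDS end into the downstream
#' transcript when the native stop is lost -- to locate the first stop
#' codon, reported as a 1-based codon position in the mutated reading frame
#' together with the truncated protein length (stop position minus one).
#' A frameshift is only called a truncation when that first stop falls at or
#' before the wild-type protein length; when the shifted frame reaches no
#' stop until then (or until the transcript end) the effect is
#' `stop_lost_extension` and the extended/scanned length is reported.
#' In-frame indels are checked for premature stops against the shifted
#' expected length (wild-type length plus the net codon change).
#'
#' If protein `domains` are supplied, domains lying entirely beyond the
#' truncation point are reported as lost and domains interrupted by it as
#' truncated.
#'
#' @param variants Variant tibble (`chrom`, `pos`, `ref`, `alt`, one row per
#'   variant; extra columns are preserved).
#' @param genes Gene-model feature tibble.
#' @param reference Named character vector of chromosome sequences.
#' @param domains Optional tibble of protein domains: `domain`, `start_aa`,
#'   `end_aa` (1-based residue coordinates of the wild-type protein).
#' @return Tibble with one row per variant: input key columns plus
#'   `gene_id`, `effect`, `wt_protein_aa`, `stop_codon_pos`,
#'   `truncated_protein_aa`, `domains_lost`, `domains_truncated`.
#' @examples
#' ex <- truncation_example()
#' classify_effect(ex$variant, ex$genes, ex$reference, domains = ex$domains)
#' @export
classify_effect <- function(variants, genes, reference, domains = NULL) {
  spans <- gene_spans(genes)
  out <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    out[[i]] <- classify_one(variants[i, ], genes, spans, reference, domains)
  }
  bind_rows(out)
}

#' @noRd
classify_one <- function(variant, genes, spans, reference, domains) {
  base_cols <- variant |> select(any_of(c("chrom", "pos", "ref", "alt",
                                          "class", "origin")))
  res <- function(gene_id, effect, wt_aa = NA_integer_, stop_pos = NA_integer_,
                  trunc_aa = NA_integer_, lost = NA_character_,
                  truncated = NA_character_) {
    bind_cols(base_cols,
              tibble(gene_id = gene_id, effect = effect,
                     wt_protein_aa = as.integer(wt_aa),
                     stop_codon_pos = as.integer(stop_pos),
                     truncated_protein_aa = as.integer(trunc_aa),
                     domains_lost = lost, domains_truncated = truncated))
  }

  span <- changed_span(variant)
  hit <- spans |>
    filter(.data$chrom == variant$chrom, .data$end >= span[1],
           .data$start <= span[2])
  if (nrow(hit) == 0) return(res(NA_character_, "intergenic"))
  gene <- hit[1, ]
  feats <- genes[genes$gene_id == gene$gene_id, ]
  exons <- feats[feats$type == "exon", ]
  cds <- feats[feats$type == "CDS", ]
  strand <- gene$strand

  in_cds <- overlaps_any(span, cds)
  nr <- nchar(variant$ref); na <- nchar(variant$alt)
  is_indel <- nr != na
  # an insertion only disrupts the CDS when its insertion point is internal
  if (is_indel && na > nr) {
    in_cds <- any(cds$start <= variant$pos & cds$end > variant$pos)
  }
  if (!in_cds) {
    eff <- if (overlaps_any(span, exons)) "UTR" else "intronic"
    return(res(gene$gene_id, eff))
  }

  # window around the gene (extended to cover the variant's reference span)
  L <- nchar(reference[[variant$chrom]])
  ws <- max(1L, min(gene$start, variant$pos) - 1L)
  we <- min(L, max(gene$end, variant$pos + nr - 1L))
  local_seq <- substr(reference[[variant$chrom]], ws, we)
  loc <- function(tbl) tbl |> mutate(start = .data$start - ws + 1L,
                                     end = .data$end - ws + 1L)
  lexons <- loc(exons); lcds <- loc(cds)
  lvar <- variant
  lvar$pos <- variant$pos - ws + 1L

  wt_cds_seq <- splice_seq(local_seq, lcds, strand)
  wt_prot <- translate_str(wt_cds_seq)
  wt_aa <- nchar(wt_prot)

  applied <- apply_variant(setNames(list(local_seq), variant$chrom)[variant$chrom],
                           lvar)
  mseq <- applied$sequence[[variant$chrom]]
  lift_iv <- function(tbl) {
    tbl |>
      mutate(start = applied$lift(.data$start), end = applied$lift(.data$end)) |>
      filter(.data$start <= .data$end)
  }
  mexons <- lift_iv(lexons); mcds <- lift_iv(lcds)
  mut_cds_seq <- splice_seq(mseq, mcds, strand)
  mut_scan <- paste0(mut_cds_seq, downstream_of_cds(mseq, mexons, mcds, strand))
  prot_scan <- translate_str(mut_scan)
  stop_at <- regexpr("*", prot_scan, fixed = TRUE)[1]
  stop_found <- stop_at > 0
  mut_prot <- if (stop_found) substr(prot_scan, 1L, stop_at - 1L) else prot_scan

  finish_domains <- function(trunc_aa) {
    if (is.null(domains) || is.na(trunc_aa)) {
      return(list(lost = NA_character_, truncated = NA_character_))
    }
    lost <- domains$domain[domains$start_aa > trunc_aa]
    part <- domains$domain[domains$start_aa <= trunc_aa &
                             domains$end_aa > trunc_aa]
    list(lost = if (length(lost)) paste(lost, collapse = ",") else NA_character_,
         truncated = if (length(part)) paste(part, collapse = ",") else NA_character_)
  }

  if (!is_indel) {
    if (identical(mut_prot, wt_prot) && stop_found && stop_at == wt_aa + 1L) {
      return(res(gene$gene_id, "synonymous", wt_aa))
    }
    if (stop_found && stop_at <= wt_aa) {
      dm <- finish_domains(stop_at - 1L)
      return(res(gene$gene_id, "nonsense", wt_aa, stop_at, stop_at - 1L,
                 dm$lost, dm$truncated))
    }
    return(res(gene$gene_id, "missense", wt_aa))
  }

  delta <- na - nr
  if (delta %% 3L == 0L) {
    # premature relative to the shifted expected length, not the WT length
    expected_aa <- wt_aa + delta %/% 3L
    stop_pos <- if (stop_found && stop_at <= expected_aa) stop_at else NA_integer_
    trunc <- if (!is.na(stop_pos)) stop_pos - 1L else NA_integer_
    dm <- finish_domains(trunc)
    return(res(gene$gene_id, "in_frame_indel", wt_aa, stop_pos, trunc,
               dm$lost, dm$truncated))
  }
  if (stop_found && stop_at <= wt_aa) {
    dm <- finish_domains(stop_at - 1L)
    return(res(gene$gene_id, "frameshift", wt_aa, stop_at, stop_at - 1L,
               dm$lost, dm$truncated))
  }
  # the shifted frame reaches no stop at or before the WT length: the
  # protein is extended, not truncated
  res(gene$gene_id, "stop_lost_extension", wt_aa,
      stop_pos = if (stop_found) stop_at else NA_integer_,
      trunc_aa = if (stop_found) stop_at - 1L else nchar(prot_scan))
}

#' Construct the worked truncation example
#'
#' Builds a synthetic plus-strand two-exon gene whose stop-free CDS spans
#' `3 * n_codons` bp (2871 bp and 957 aa by default) together with a 2-bp
#' deletion in the first exon engineered so that the first stop codon of the
#' frameshifted reading frame falls at codon `stop_codon` (494 by default,
#' i.e. a truncated protein of 493 residues), and a single transmembrane
#' domain at residues 505-524 that the truncation removes. The construction
#' is deterministic: the CDS is ATG followed by GCT repeats, with TAA written
#' at the frame-shifted position of codon `stop_codon`; the deletion removes
#' CDS bases 4-5 so the mutated frame reads TGC (Cys) until the planted
#' stop.
#'
#' @param n_codons Wild-type protein length in codons (default 957).
#' @param stop_codon 1-based codon position of the first stop in the mutated
#'   frame (default 494; must lie in `[3, n_codons - 1]`).
#' @return List with `reference`, `genes`, `variant`, `domains`, `gene_id`.
#' @examples
#' ex <- truncation_example()
#' classify_effect(ex$variant, ex$genes, ex$reference, domains = ex$domains)
#' @export
truncation_example <- function(n_codons = 957L, stop_codon = 494L) {
  n_codons <- as.integer(n_codons); stop_codon <- as.integer(stop_codon)
  if (stop_codon < 3L || stop_codon > n_codons - 1L) {
    abort("`stop_codon` must lie in [3, n_codons - 1]")
  }
  cds_len <- 3L * n_codons
  cds <- paste0("ATG", strrep("GCT", n_codons - 1L))
  # plant TAA at mutated-frame codon `stop_codon`, i.e. CDS bases
  # 3s..3s+2 of the wild type (the wild-type frame stays stop-free: codon s
  # remains GCT, codon s+1 becomes AAT)
  s3 <- 3L * stop_codon
  cds <- paste0(substr(cds, 1L, s3 - 1L), "TAA",
                substr(cds, s3 + 3L, cds_len))
  stopifnot(nchar(cds) == cds_len)

  pad5 <- 100L
  exon1_cds <- min(1800L, cds_len - 3L)   # CDS bases in exon 1
  intron_len <- 200L
  utr3 <- 117L
  chrom <- "chr4"

  e1_start <- pad5 + 1L
  e1_end <- pad5 + exon1_cds
  e2_start <- e1_end + intron_len + 1L
  e2_cds_end <- e2_start + (cds_len - exon1_cds) - 1L
  e2_end <- e2_cds_end + 3L + utr3
  total <- e2_end + 100L

  seq <- random_dna(total)
  write_at <- function(seq, start, content) {
    paste0(substr(seq, 1L, start - 1L), content,
           substr(seq, start + nchar(content), nchar(seq)))
  }
  seq <- write_at(seq, e1_start, substr(cds, 1L, exon1_cds))
  seq <- write_at(seq, e2_start, substr(cds, exon1_cds + 1L, cds_len))
  seq <- write_at(seq, e2_cds_end + 1L, "TAA")

  genes <- tibble(
    gene_id = "geneX", chrom = chrom, strand = "+",
    type = c("gene", "exon", "exon", "CDS", "CDS"),
    start = c(e1_start, e1_start, e2_start, e1_start, e2_start),
    end = c(e2_end, e1_end, e2_end, e1_end, e2_cds_end)
  )
  # 2-bp deletion of CDS bases 4-5 (genomic e1_start+3 .. e1_start+4),
  # VCF-anchored on the preceding base
  p <- e1_start + 2L
  variant <- tibble(chrom = chrom, pos = p,
                    ref = substr(seq, p, p + 2L), alt = substr(seq, p, p),
                    class = "deletion", origin = "causal")
  domains <- tibble(domain = "transmembrane", start_aa = 505L, end_aa = 524L)
  list(reference = setNames(seq, chrom), genes = genes, variant = variant,
       domains = domains, gene_id = "geneX")
}
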