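# Independent oracles. These deliberately avoid the package's own helpers:
# reverse-complement via chartr + rev, translation via seqinr, splicing by a
# plain substr loop over the full chromosome (no windowing), so they share
# nothing with the implementation path they check.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

oracle_translate <- function(x) {
  if (nchar(x) < 3) return("")
  paste(seqinr::translate(strsplit(tolower(x), "")[[1]]), collapse = "")
}

oracle_splice <- function(seq, iv, strand) {
  iv <- iv[order(iv$start), ]
  s <- ""
  for (i in seq_len(nrow(iv))) {
    s <- paste0(s, substr(seq, iv$start[i], iv$end[i]))
  }
  if (strand == "-") oracle_revcomp(s) else s
}

# Full-genome re-translation oracle for variant effect calls. Applies the
# variant to the whole chromosome, lifts the gene model, re-splices and
# re-translates the mutated coding sequence (scanning into the downstream
# transcript), and classifies from the protein comparison.
oracle_classify <- function(variant, genes, reference) {
  nores <- function(effect) list(effect = effect,
                                 stop_codon_pos = NA_integer_,
                                 truncated_protein_aa = NA_integer_)
  chrom_seq <- reference[[variant$chrom]]
  nr <- nchar(variant$ref); na_ <- nchar(variant$alt)
  span <- if (nr == na_) c(variant$pos, variant$pos + nr - 1L) else
    if (nr > na_) c(variant$pos + 1L, variant$pos + nr - 1L) else
      c(variant$pos, variant$pos + 1L)

  gs <- genes[genes$type == "gene" & genes$chrom == variant$chrom, ]
  hit <- gs[gs$end >= span[1] & gs$start <= span[2], ]
  if (nrow(hit) == 0) return(nores("intergenic"))
  g <- hit[1, ]
  feats <- genes[genes$gene_id == g$gene_id, ]
  ex <- feats[feats$type == "exon", ]
  cds <- feats[feats$type == "CDS", ]

  in_cds <- any(cds$end >= span[1] & cds$start <= span[2])
  if (na_ > nr) in_cds <- any(cds$start <= variant$pos & cds$end > variant$pos)
  if (!in_cds) {
    return(nores(if (any(ex$end >= span[1] & ex$start <= span[2])) "UTR"
                 else "intronic"))
  }

  stopifnot(substr(chrom_seq, variant$pos, variant$pos + nr - 1L) == variant$ref)
  mut_seq <- paste0(substr(chrom_seq, 1, variant$pos - 1L), variant$alt,
                    substr(chrom_seq, variant$pos + nr, nchar(chrom_seq)))
  delta <- na_ - nr
  lift <- function(p) {
    ifelse(p <= variant$pos, p,
           ifelse(p > variant$pos + nr - 1L, p + delta, variant$pos))
  }
  lift_iv <- function(iv) {
    iv$start <- lift(iv$start); iv$end <- lift(iv$end)
    iv[iv$start <= iv$end, ]
  }

  wt_prot <- oracle_translate(oracle_splice(chrom_seq, cds, g$strand))
  wt_aa <- nchar(wt_prot)
  mcds <- lift_iv(cds); mex <- lift_iv(ex)
  if (g$strand == "+") {
    ce <- max(mcds$end)
    dn <- mex; dn$start <- pmax(dn$start, ce + 1L)
  } else {
    cs <- min(mcds$start)
    dn <- mex; dn$end <- pmin(dn$end, cs - 1L)
  }
  dn <- dn[dn$start <= dn$end, ]
  scan <- paste0(oracle_splice(mut_seq, mcds, g$strand),
                 oracle_splice(mut_seq, dn, g$strand))
  aa <- strsplit(oracle_translate(scan), "")[[1]]
  stop_at <- which(aa == "*")[1]
  stop_found <- !is.na(stop_at)
  mut_prot <- if (stop_found) paste(aa[seq_len(stop_at - 1L)], collapse = "")
    else paste(aa, collapse = "")

  if (nr == na_) {
    if (identical(mut_prot, wt_prot) && stop_found && stop_at == wt_aa + 1L) {
      return(nores("synonymous"))
    }
    if (stop_found && stop_at <= wt_aa) {
      return(list(effect = "nonsense", stop_codon_pos = stop_at,
                  truncated_protein_aa = stop_at - 1L))
    }
    return(nores("missense"))
  }
  if (delta %% 3L == 0L) {
    sp <- if (stop_found && stop_at <= wt_aa + delta %/% 3L) stop_at else NA_integer_
    return(list(effect = "in_frame_indel", stop_codon_pos = sp,
                truncated_protein_aa = if (is.na(sp)) NA_integer_ else sp - 1L))
  }
  if (stop_found && stop_at <= wt_aa) {
    return(list(effect = "frameshift", stop_codon_pos = stop_at,
                truncated_protein_aa = stop_at - 1L))
  }
  list(effect = "stop_lost_extension",
       stop_codon_pos = if (stop_found) stop_at else NA_integer_,
       truncated_protein_aa = if (stop_found) stop_at - 1L else length(aa))
}

# Random variant in or around a gene of a simulated reference, for
# oracle-equivalence sweeps.
random_test_variant <- function(reference, genes) {
  spans <- gene_spans(genes)
  g <- spans[sample.int(nrow(spans), 1L), ]
  L <- nchar(reference[[g$chrom]])
  pos <- sample(seq(max(2L, g$start - 200L), min(L - 6L, g$end + 200L)), 1L)
  seq_raw <- charToRaw(reference[[g$chrom]])
  kind <- sample(c("snp", "del", "ins"), 1L, prob = c(0.5, 0.3, 0.2))
  if (kind == "snp") {
    ref <- rawToChar(seq_raw[pos])
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  } else if (kind == "del") {
    k <- sample(1:4, 1L)
    ref <- rawToChar(seq_raw[pos:(pos + k)])
    alt <- rawToChar(seq_raw[pos])
  } else {
    k <- sample(1:4, 1L)
    ref <- rawToChar(seq_raw[pos])
    alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                             collapse = ""))
  }
  tibble::tibble(chrom = g$chrom, pos = pos, ref = ref, alt = alt)
}
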