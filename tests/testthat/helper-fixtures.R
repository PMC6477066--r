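# Small study configurations used across tests: same structure as the
# defaults, scaled down so a single test runs in well under a second.

tiny_config <- function(...) {
  defaults <- list(
    chrom_lengths = c(chr1 = 6e4, chr2 = 6e4),
    causal_chrom = "chr1",
    cds_codon_range = c(80L, 200L),
    mutagen_rate = 0, intracultivar_rate = 0,
    f2_size = 30L, bulk_size = 10L,
    marker_n_total = 60L, marker_n_informative = 30L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# A one-individual population homozygous for a given parental origin
# genome-wide, for boundary-case genotype tests.
uniform_population <- function(origin, chrom_lengths = c(chr1 = 6e4)) {
  seg <- purrr::map(names(chrom_lengths), function(cn) {
    tibble::tibble(individual = 1L, chrom = cn, hap = rep(1:2),
                   start = 1L, end = as.integer(chrom_lengths[[cn]]),
                   origin = origin)
  }) |> purrr::list_rbind()
  structure(list(segments = seg,
                 phenotypes = tibble::tibble(individual = 1L,
                                             phenotype = if (origin == "M") "mutant" else "WT"),
                 causal = list(chrom = names(chrom_lengths)[1], pos = 1L),
                 chrom_lengths = chrom_lengths),
            class = "f2_population")
}

# Hand-written genotype table: markers mk01..mk<n> at positions 1e5 * i on
# one chromosome; `calls` is a named list individual -> character vector of
# calls (length n).
toy_genotypes <- function(calls, phenotypes, n_markers, chrom = "chr1") {
  pos <- as.integer(1e5 * seq_len(n_markers))
  ids <- sprintf("mk%02d", seq_len(n_markers))
  purrr::imap(calls, function(cc, ind) {
    tibble::tibble(individual = as.integer(ind),
                   phenotype = phenotypes[[ind]],
                   marker_id = ids, chrom = chrom, pos = pos, call = cc)
  }) |> purrr::list_rbind()
}

toy_panel <- function(n_markers, chrom = "chr1") {
  tibble::tibble(marker_id = sprintf("mk%02d", seq_len(n_markers)),
                 chrom = chrom, pos = as.integer(1e5 * seq_len(n_markers)))
}
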