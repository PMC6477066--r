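# Effect-severity ranking used to prioritise candidates: truncating
# mutations first, then missense, then everything else.
#' @noRd
effect_severity <- function(effect) {
  dplyr::case_match(effect,
    c("frameshift", "nonsense", "stop_lost_extension") ~ 1L,
    "missense" ~ 2L,
    "in_frame_indel" ~ 3L,
    "synonymous" ~ 4L,
    .default = 5L
  )
}

# Simulate an independent confirmation cohort and genotype each candidate
# variant in it: n_mut mutant-phenotype and n_wt WT-phenotype plants
# (emulating the linkage-analysis populations). A candidate cosegregates
# perfectly when all mutants are homozygous for it and no WT plant is.
#' @noRd
confirm_cosegregation <- function(config, variants, candidates,
                                  n_mut = 83L, n_wt = 80L) {
  mut_ids <- integer(0); wt_ids <- integer(0)
  pops <- list()
  batch <- 1L
  while (length(mut_ids) < n_mut || length(wt_ids) < n_wt) {
    pop <- simulate_f2(config, variants, n = 200L)
    ph <- pop$phenotypes
    pops[[batch]] <- pop
    mut_ids <- c(mut_ids, ph$individual[ph$phenotype == "mutant"] +
                   (batch - 1L) * 1e6)
    wt_ids <- c(wt_ids, ph$individual[ph$phenotype == "WT"] +
                  (batch - 1L) * 1e6)
    batch <- batch + 1L
  }
  mut_ids <- mut_ids[seq_len(n_mut)]
  wt_ids <- wt_ids[seq_len(n_wt)]

  geno_counts <- function(cand_chrom, cand_pos, cand) {
    # mutant-parent haplotype dose per cohort individual at the variant
    doses <- numeric(0); ids <- numeric(0)
    for (b in seq_along(pops)) {
      if (cand$origin %in% c("causal", "mutagen")) {
        oc <- origin_counts(pops[[b]]$segments, cand_chrom, cand_pos)
        doses <- c(doses, oc$counts[, 1])
        ids <- c(ids, oc$individual + (b - 1L) * 1e6)
      } else {
        n <- nrow(pops[[b]]$phenotypes)
        fcv <- if (is.null(cand$cultivar_freq) || is.na(cand$cultivar_freq))
          0.5 else cand$cultivar_freq
        doses <- c(doses, rbinom(n, 2L, fcv))
        ids <- c(ids, pops[[b]]$phenotypes$individual + (b - 1L) * 1e6)
      }
    }
    doses[match(c(mut_ids, wt_ids), ids)]
  }

  out <- candidates
  out$discordant <- NA_integer_
  out$cosegregates <- NA
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    dose <- geno_counts(cand$chrom, cand$pos, cand)
    dose_mut <- dose[seq_len(n_mut)]
    dose_wt <- dose[n_mut + seq_len(n_wt)]
    disc <- sum(dose_mut != 2L) + sum(dose_wt == 2L)
    out$discordant[i] <- disc
    out$cosegregates[i] <- disc == 0L
  }
  out
}

#' Run the full mutant-identification pipeline on simulated data
#'
#' Executes the entire analysis chain on data generated under `config`:
#' simulate reference/gene models/variants/F2 population, test phenotype
#' segregation against 3:1, select informative array markers and map the
#' cosegregating candidate interval from the mutant-phenotype plants,
#' sequence a pooled mutant bulk and compute SNP/Indel indices, subtract
#' intra-cultivar background variants, filter by depth/index/interval,
#' assign surviving variants to genes by CDS overlap, classify their
#' protein-level effects, rank candidates by effect severity and an
#' independent-cohort cosegregation check (83 mutant + 80 WT plants), and
#' finally run the ovary RNA-seq differential-expression stage. The report
#' records whether the planted causal gene was recovered.
#'
#' @param config An [sim_config()] object.
#' @param seed Integer seed; default `config$seed`. Identical seeds give
#'   byte-identical reports.
#' @param min_depth,min_index Candidate filters (defaults 10 and 0.9).
#' @param confirm Run the cosegregation-confirmation stage (default TRUE).
#' @param rnaseq Run the RNA-seq DE stage (default TRUE).
#' @return An object of class `fg_run`; see [glance.fg_run()] and
#'   [tidy.fg_run()].
#' @examples
#' \donttest{
#' cfg <- sim_config(chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
#'                   causal_chrom = "chr1", f2_size = 60,
#'                   marker_n_total = 400, marker_n_informative = 150)
#' run <- run_pipeline(cfg, seed = 7)
#' glance(run)
#' }
#' @export
run_pipeline <- function(config, seed = config$seed, min_depth = 10,
                         min_index = 0.9, confirm = TRUE, rnaseq = TRUE) {
  validate_config(config)
  set.seed(seed)
  log_rows <- list()
  note <- function(stage, n_in, n_out) {
    log_rows[[length(log_rows) + 1L]] <<- tibble(
      stage = stage, n_in = as.integer(n_in), n_out = as.integer(n_out))
  }

  ref <- build_reference(config)
  note("build_reference", length(config$chrom_lengths),
       nrow(gene_spans(ref$genes)))
  variants <- plant_variants(ref$sequence, ref$genes, config)
  causal_variant <- variants[variants$origin == "causal", ]
  causal_gene <- attr(variants, "causal_gene")
  note("plant_variants", NA, nrow(variants))

  pop <- simulate_f2(config, variants)
  n_mutant <- sum(pop$phenotypes$phenotype == "mutant")
  note("simulate_f2", config$f2_size, n_mutant)
  segregation <- chi_square_segregation(
    tibble(n_wt = config$f2_size - n_mutant, n_mutant = n_mutant))

  mk <- make_marker_panel(config)
  inf_panel <- select_informative_markers(mk$parent_a, mk$parent_b, mk$panel)
  note("select_informative_markers", nrow(mk$panel), nrow(inf_panel))
  genotypes <- genotype_array(pop, inf_panel, config$genotype_error,
                              config$genotype_missing)
  interval <- map_cosegregating_interval(genotypes, inf_panel,
                                         config$chrom_lengths)
  interval_genes <- if (nrow(interval)) genes_in_interval(ref$genes, interval)
    else gene_spans(ref$genes)[0, ]
  note("map_cosegregating_interval", nrow(inf_panel), nrow(interval_genes))

  mutant_ids <- pop$phenotypes$individual[pop$phenotypes$phenotype == "mutant"]
  bulk <- sample(mutant_ids, min(config$bulk_size, length(mutant_ids)))
  pooled <- pool_and_sequence(pop, variants, bulk = bulk,
                              depth_mean = config$depth_mean,
                              error_rate = config$seq_error)
  records <- compute_snp_index(pooled)
  note("compute_snp_index", nrow(pooled), sum(records$defined))
  background <- variants |> filter(.data$origin == "intra_cultivar")
  records_sub <- subtract_intracultivar(records, background)
  note("subtract_intracultivar", nrow(records), nrow(records_sub))
  filtered <- filter_candidates(records_sub, min_depth = min_depth,
                                min_index = min_index,
                                interval = if (nrow(interval)) interval else NULL)
  note("filter_candidates", nrow(records_sub), nrow(filtered))

  gene_hits <- variants_to_genes(filtered, ref$genes)
  cand_variants <- if (nrow(gene_hits)) {
    gene_hits |> select("variants") |> tidyr::unnest("variants")
  } else filtered[0, ]
  note("variants_to_genes", nrow(filtered), nrow(gene_hits))

  effects <- if (nrow(cand_variants)) {
    classify_effect(cand_variants |>
                      select("chrom", "pos", "ref", "alt",
                             any_of(c("class", "origin"))),
                    ref$genes, ref$sequence) |>
      left_join(cand_variants |>
                  select("chrom", "pos", "index", "depth",
                         any_of("cultivar_freq")),
                by = c("chrom", "pos"))
  } else NULL

  candidates <- NULL
  if (!is.null(effects)) {
    candidates <- effects |> mutate(severity = effect_severity(.data$effect))
    if (confirm) {
      candidates <- confirm_cosegregation(config, variants, candidates)
      candidates <- candidates |>
        arrange(.data$severity, .data$discordant, desc(.data$index),
                desc(.data$depth), .data$chrom, .data$pos)
    } else {
      candidates <- candidates |>
        arrange(.data$severity, desc(.data$index), desc(.data$depth),
                .data$chrom, .data$pos)
    }
    note("rank_candidates", nrow(candidates), nrow(candidates))
  }

  top_gene <- if (!is.null(candidates) && nrow(candidates)) {
    candidates$gene_id[1]
  } else NA_character_
  recovered_any <- !is.null(candidates) && causal_gene %in% candidates$gene_id
  recovered_top <- identical(top_gene, causal_gene)

  de <- NULL
  if (rnaseq) {
    counts <- simulate_rnaseq_counts(config, genes = ref$genes)
    rpkm <- compute_rpkm(counts)
    expressed <- filter_expressed(rpkm)
    de_res <- differential_test(rpkm, expressed)
    truth <- counts |> distinct(.data$gene_id, .data$true_log2fc)
    de <- list(result = left_join(de_res, truth, by = "gene_id"),
               n_up = sum(de_res$call == "up"),
               n_down = sum(de_res$call == "down"))
    note("differential_test", length(unique(counts$gene_id)),
         de$n_up + de$n_down)
  }

  structure(list(
    seed = as.integer(seed), config = config,
    segregation = segregation,
    n_informative_markers = nrow(inf_panel),
    interval = interval,
    interval_genes = interval_genes,
    snp_records = records_sub,
    filter_log = attr(filtered, "filter_log"),
    candidates = candidates,
    causal_gene = causal_gene,
    causal_variant = causal_variant,
    top_gene = top_gene,
    recovered_top = recovered_top,
    recovered_any = recovered_any,
    de = de,
    genotypes = genotypes,
    stage_log = bind_rows(log_rows)
  ), class = "fg_run")
}

#' Write a pipeline run report to disk
#'
#' Serialises the run as a JSON summary plus TSV tables of the stage
#' outputs (SNP records, ranked candidates, interval, DE results,
#' genotypes), so any stage can be re-examined or re-run in isolation.
#'
#' @param run An `fg_run` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summary <- list(
    seed = run$seed,
    segregation = as.list(run$segregation[1, ]),
    n_informative_markers = run$n_informative_markers,
    interval = if (nrow(run$interval)) as.list(run$interval[1, ]) else NULL,
    interval_length_mbp = if (nrow(run$interval))
      interval_length_mbp(run$interval) else NULL,
    n_interval_genes = nrow(run$interval_genes),
    filter_log = run$filter_log,
    causal_gene = run$causal_gene,
    top_gene = run$top_gene,
    recovered_top = run$recovered_top,
    recovered_any = run$recovered_any,
    n_de_up = run$de$n_up, n_de_down = run$de$n_down,
    stage_log = run$stage_log
  )
  jsonlite::write_json(summary, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  readr::write_tsv(run$snp_records, file.path(dir, "snp_records.tsv"))
  if (!is.null(run$candidates)) {
    readr::write_tsv(run$candidates, file.path(dir, "candidates.tsv"))
  }
  if (nrow(run$interval)) {
    readr::write_tsv(run$interval, file.path(dir, "interval.tsv"))
  }
  if (!is.null(run$de)) {
    readr::write_tsv(run$de$result, file.path(dir, "differential_expression.tsv"))
  }
  write_genotypes_tsv(run$genotypes, file.path(dir, "genotypes.tsv"))
  invisible(dir)
}
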