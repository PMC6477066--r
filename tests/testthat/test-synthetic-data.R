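test_that("a zero-gene config yields an empty model set and a full-length sequence", {
  cfg <- tiny_config(gene_density = 0)
  withr::local_seed(1)
  ref <- build_reference(cfg)
  expect_equal(nrow(ref$genes), 0L)
  expect_equal(unname(nchar(ref$sequence)), unname(as.integer(cfg$chrom_lengths)))
})

test_that("gene counts follow the configured density (Poisson) or fixed total", {
  cfg <- sim_config(chrom_lengths = c(chr4 = 2.6e6), causal_chrom = "chr4")
  withr::local_seed(7)
  ref <- build_reference(cfg)
  n <- nrow(gene_spans(ref$genes))
  mu <- cfg$gene_density * 2.6e6  # 267.8 at study density
  expect_lt(abs(n - mu), 4 * sqrt(mu))

  cfg_fixed <- sim_config(chrom_lengths = c(chr4 = 2.6e6), causal_chrom = "chr4",
                          n_genes = 267L)
  ref_fixed <- build_reference(cfg_fixed)
  expect_equal(nrow(gene_spans(ref_fixed$genes)), 267L)
})

test_that("simulated gene models are structurally valid and translate cleanly", {
  withr::local_seed(3)
  ref <- build_reference(tiny_config())
  cds_len <- ref$genes |>
    dplyr::filter(type == "CDS") |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(len = sum(end - start + 1))
  expect_true(all(cds_len$len %% 3 == 0))

  spans <- gene_spans(ref$genes)
  by_chr <- split(spans, spans$chrom)
  for (s in by_chr) {
    s <- s[order(s$start), ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] > s$end[-nrow(s)]))
  }

  # CDS contained in exons, and wild-type translation is stop-free
  for (g in utils::head(spans$gene_id, 5)) {
    feats <- ref$genes[ref$genes$gene_id == g, ]
    cds <- feats[feats$type == "CDS", ]
    ex <- feats[feats$type == "exon", ]
    for (i in seq_len(nrow(cds))) {
      expect_true(any(ex$start <= cds$start[i] & ex$end >= cds$end[i]))
    }
    expect_no_warning(prot <- translate_cds(ref$genes, ref$sequence, g))
    expect_false(grepl("*", prot, fixed = TRUE))
  }
})

test_that("the same seed reproduces reference and variants byte-identically", {
  cfg <- tiny_config(mutagen_rate = 1e-4, intracultivar_rate = 1e-4)
  gen <- function() {
    set.seed(99)
    ref <- build_reference(cfg)
    vars <- plant_variants(ref$sequence, ref$genes, cfg)
    list(ref = ref, vars = vars)
  }
  a <- gen(); b <- gen()
  expect_identical(a$ref$sequence, b$ref$sequence)
  expect_identical(a$ref$genes, b$ref$genes)
  expect_identical(a$vars, b$vars)
})

test_that("background variant counts follow the Poisson rate and rate zero leaves only the causal variant", {
  withr::local_seed(11)
  cfg0 <- tiny_config()
  ref <- build_reference(cfg0)
  vars0 <- plant_variants(ref$sequence, ref$genes, cfg0)
  expect_equal(nrow(vars0), 1L)
  expect_equal(vars0$origin, "causal")

  cfg <- tiny_config(mutagen_rate = 2e-3)  # mean 240 over 120 kb
  vars <- plant_variants(ref$sequence, ref$genes, cfg)
  n_mut <- sum(vars$origin == "mutagen")
  mu <- 2e-3 * sum(cfg$chrom_lengths)
  expect_lt(abs(n_mut - mu), 4 * sqrt(mu))
})

test_that("the causal 2-bp deletion is left-anchored with one reference base", {
  withr::local_seed(2)
  cfg <- tiny_config()
  ref <- build_reference(cfg)
  vars <- plant_variants(ref$sequence, ref$genes, cfg)
  causal <- vars[vars$origin == "causal", ]
  expect_equal(nchar(causal$ref), 3L)
  expect_equal(nchar(causal$alt), 1L)
  expect_equal(causal$class, "deletion")
  # anchor convention: alt is the first reference base, and the ref allele
  # matches the genome
  expect_equal(substr(causal$ref, 1, 1), causal$alt)
  expect_equal(substr(ref$sequence[[causal$chrom]], causal$pos,
                      causal$pos + 2L), causal$ref)
})

test_that("F2 haplotype segments tile each chromosome without gaps or overlaps", {
  withr::local_seed(5)
  cfg <- tiny_config(cm_per_bp = 1 / 5e3)  # high map density to force crossovers
  ref <- build_reference(cfg)
  vars <- plant_variants(ref$sequence, ref$genes, cfg)
  pop <- simulate_f2(cfg, vars, n = 20)
  seg <- pop$segments
  for (key in split(seg, paste(seg$individual, seg$chrom, seg$hap))) {
    key <- key[order(key$start), ]
    expect_equal(key$start[1], 1L)
    expect_equal(key$end[nrow(key)],
                 as.integer(cfg$chrom_lengths[[key$chrom[1]]]))
    if (nrow(key) > 1) {
      expect_equal(key$start[-1], key$end[-nrow(key)] + 1L)
      # consecutive segments alternate parental origin
      expect_true(all(key$origin[-1] != key$origin[-nrow(key)]))
    }
  }
})

test_that("zero recombination gives single-parent haplotypes", {
  withr::local_seed(5)
  cfg <- tiny_config(cm_per_bp = 0)
  ref <- build_reference(cfg)
  vars <- plant_variants(ref$sequence, ref$genes, cfg)
  pop <- simulate_f2(cfg, vars, n = 15)
  n_seg <- pop$segments |>
    dplyr::count(individual, chrom, hap)
  expect_true(all(n_seg$n == 1L))
})

test_that("the mutant phenotype fraction converges to 1/4 and mutants are homozygous at the locus", {
  withr::local_seed(8)
  cfg <- tiny_config(chrom_lengths = c(chr1 = 1e4), f2_size = 20000L)
  ref <- build_reference(sim_config(chrom_lengths = c(chr1 = 1e4),
                                    causal_chrom = "chr1", n_genes = 1L,
                                    cds_codon_range = c(80L, 150L)))
  vars <- plant_variants(ref$sequence, ref$genes, cfg)
  pop <- simulate_f2(cfg, vars)
  frac <- mean(pop$phenotypes$phenotype == "mutant")
  se <- sqrt(0.25 * 0.75 / 20000)
  expect_lt(abs(frac - 0.25), 4 * se)

  # definitional invariant of the recessive model
  oc <- fgmap:::origin_counts(pop$segments, pop$causal$chrom, pop$causal$pos)
  mut <- pop$phenotypes$individual[pop$phenotypes$phenotype == "mutant"]
  expect_true(all(oc$counts[match(mut, oc$individual), 1] == 2L))
})

test_that("genotype calls reflect parental origin, with error and missing rates applied", {
  pop_m <- uniform_population("M")
  panel <- tibble::tibble(marker_id = c("a", "b"), chrom = "chr1",
                          pos = c(100L, 5000L))
  g <- genotype_array(pop_m, panel)
  expect_true(all(g$call == "AA"))

  g_w <- genotype_array(uniform_population("W"), panel)
  expect_true(all(g_w$call == "BB"))

  withr::local_seed(1)
  g_missing <- genotype_array(pop_m, panel, missing_rate = 1)
  expect_true(all(g_missing$call == "missing"))

  off <- tibble::tibble(marker_id = "x", chrom = "chr1", pos = 999999L)
  expect_error(genotype_array(pop_m, off), "outside")
})

test_that("at the marker nearest the causal locus all mutant plants call AA", {
  withr::local_seed(13)
  cfg <- tiny_config(f2_size = 60L)
  ref <- build_reference(cfg)
  vars <- plant_variants(ref$sequence, ref$genes, cfg)
  pop <- simulate_f2(cfg, vars)
  panel <- make_marker_panel(cfg)$panel
  on_chr <- panel[panel$chrom == pop$causal$chrom, ]
  nearest <- on_chr[which.min(abs(on_chr$pos - pop$causal$pos)), ]
  geno <- genotype_array(pop, nearest)
  expect_true(all(geno$call[geno$phenotype == "mutant"] == "AA"))
})

test_that("pooled sequencing has index 1 at the causal variant and flags zero depth", {
  withr::local_seed(21)
  cfg <- tiny_config(f2_size = 60L)
  ref <- build_reference(cfg)
  vars <- plant_variants(ref$sequence, ref$genes, cfg)
  pop <- simulate_f2(cfg, vars)
  pooled <- pool_and_sequence(pop, vars, depth_mean = 15, error_rate = 0)
  rec <- compute_snp_index(pooled)
  causal <- rec[rec$origin == "causal", ]
  expect_true(causal$defined)
  expect_equal(causal$index, 1)

  zero <- pool_and_sequence(pop, vars, depth_mean = 0, error_rate = 0)
  zrec <- compute_snp_index(zero)
  expect_false(any(zrec$defined))
  expect_true(all(is.na(zrec$index)))

  expect_error(pool_and_sequence(pop, vars, bulk = integer(0)), "empty")
})

test_that("RNA-seq counts: no planted effects means equal group means; planted 16-fold shows up; seeds reproduce", {
  cfg0 <- sim_config(rnaseq_planted_up = 0L, rnaseq_planted_down = 0L)
  withr::local_seed(31)
  counts <- simulate_rnaseq_counts(cfg0, n_genes = 400)
  expect_true(all(counts$true_log2fc == 0))
  m <- counts |>
    dplyr::group_by(group) |>
    dplyr::summarise(m = mean(count))
  expect_lt(abs(log2(m$m[1] / m$m[2])), 0.1)

  # a 16-fold planted gene at baseline >= 100: empirical log2 ratio near 4
  cfg <- sim_config(rnaseq_planted_up = 1L, rnaseq_planted_down = 0L)
  ratios <- purrr::map_dbl(1:20, function(s) {
    set.seed(1000 + s)
    cc <- simulate_rnaseq_counts(cfg, n_genes = 300)
    top <- cc[cc$true_log2fc == max(cc$true_log2fc), ]
    g <- top |>
      dplyr::group_by(group) |>
      dplyr::summarise(m = mean(count))
    log2(g$m[g$group == "mutant"] / g$m[g$group == "WT"])
  })
  expect_true(all(abs(ratios - 4) < 1))

  gen <- function() { set.seed(77); simulate_rnaseq_counts(cfg, n_genes = 100) }
  expect_identical(gen(), gen())

  bad <- cfg; bad$rnaseq_dispersion <- 0
  expect_error(simulate_rnaseq_counts(bad), "dispersion")
})
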