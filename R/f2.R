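# Haplotype segments of one gamete under the Haldane model: crossover count
# Poisson with mean = map length in Morgans, breakpoints uniform, no
# interference.
#' @noRd
gamete_segments <- function(L, morgans) {
  k <- rpois(1, morgans)
  k <- min(k, L - 1L)
  breaks <- if (k > 0) sort(sample.int(L - 1L, k)) else integer(0)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, as.integer(L))
  first <- sample(c("M", "W"), 1L)
  origins <- rep(c(first, setdiff(c("M", "W"), first)),
                 length.out = length(starts))
  list(start = starts, end = ends, origin = origins)
}

#' Simulate an F2 population segregating a monogenic recessive mutation
#'
#' Each F2 individual is formed from two independent F1 gametes; each gamete
#' is a mosaic of mutant-parent (`"M"`) and wild-type-parent (`"W"`) segments
#' produced by Haldane-model recombination (Poisson crossovers, no
#' interference, map density `config$cm_per_bp`). The phenotype is mutant iff
#' both haplotypes carry mutant-parent origin at the causal position, so the
#' expected mutant fraction is 1/4.
#'
#' @param config An [sim_config()] object.
#' @param variants Variant tibble from [plant_variants()] (the row with
#'   `origin == "causal"` defines the phenotype locus).
#' @param n Population size (default `config$f2_size`).
#' @return An object of class `f2_population`: a list with `segments`
#'   (tibble: `individual`, `chrom`, `hap`, `start`, `end`, `origin`),
#'   `phenotypes` (tibble: `individual`, `phenotype` in WT/mutant),
#'   `causal` (list with `chrom`, `pos`), and `chrom_lengths`.
#' @examples
#' set.seed(1)
#' cfg <- sim_config(chrom_lengths = c(chr1 = 6e4), causal_chrom = "chr1",
#'                   mutagen_rate = 0, intracultivar_rate = 0, f2_size = 8)
#' ref <- build_reference(cfg)
#' vars <- plant_variants(ref$sequence, ref$genes, cfg)
#' pop <- simulate_f2(cfg, vars)
#' pop$phenotypes
#' @export
simulate_f2 <- function(config, variants, n = config$f2_size) {
  if (n < 1) abort("population size must be >= 1")
  causal <- variants[variants$origin == "causal", ]
  if (nrow(causal) != 1) abort("`variants` must contain exactly one causal row")
  lens <- config$chrom_lengths
  morgans <- lens * config$cm_per_bp / 100

  acc <- vector("list", n * length(lens) * 2L)
  idx <- 1L
  for (ind in seq_len(n)) {
    for (ci in seq_along(lens)) {
      for (hap in 1:2) {
        g <- gamete_segments(lens[[ci]], morgans[[ci]])
        acc[[idx]] <- list(individual = rep(ind, length(g$start)),
                           chrom = rep(names(lens)[ci], length(g$start)),
                           hap = rep(hap, length(g$start)),
                           start = g$start, end = g$end, origin = g$origin)
        idx <- idx + 1L
      }
    }
  }
  segments <- tibble(
    individual = unlist(lapply(acc, `[[`, "individual")),
    chrom = unlist(lapply(acc, `[[`, "chrom")),
    hap = unlist(lapply(acc, `[[`, "hap")),
    start = unlist(lapply(acc, `[[`, "start")),
    end = unlist(lapply(acc, `[[`, "end")),
    origin = unlist(lapply(acc, `[[`, "origin"))
  )

  oc <- origin_counts(segments, causal$chrom, causal$pos)
  pheno <- tibble(individual = oc$individual,
                  phenotype = ifelse(oc$counts[, 1] == 2L, "mutant", "WT")) |>
    arrange(.data$individual)

  structure(list(segments = segments,
                 phenotypes = pheno,
                 causal = list(chrom = causal$chrom, pos = causal$pos),
                 chrom_lengths = lens),
            class = "f2_population")
}

# Number of mutant-parent haplotypes (0/1/2) per individual at each position
# on one chromosome. Returns list(individual = ids, counts = matrix
# [individual x position]).
#' @noRd
origin_counts <- function(segments, chrom, positions) {
  seg <- segments[segments$chrom == chrom, ]
  positions <- as.integer(positions)
  ids <- sort(unique(seg$individual))
  counts <- matrix(0L, nrow = length(ids), ncol = length(positions))
  row_of <- match(seg$individual, ids)
  pieces <- split(seq_len(nrow(seg)),
                  paste(row_of, seg$hap, sep = "_"))
  for (rows in pieces) {
    rows <- rows[order(seg$start[rows])]
    j <- findInterval(positions, seg$start[rows])
    is_m <- seg$origin[rows][j] == "M"
    r <- row_of[rows[1]]
    counts[r, ] <- counts[r, ] + as.integer(is_m)
  }
  list(individual = ids, counts = counts)
}

#' @export
print.f2_population <- function(x, ...) {
  n <- nrow(x$phenotypes)
  nm <- sum(x$phenotypes$phenotype == "mutant")
  cat("<f2_population> ", n, " individuals (", nm, " mutant, ",
      n - nm, " WT); causal locus ", x$causal$chrom, ":",
      x$causal$pos, "\n", sep = "")
  invisible(x)
}
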