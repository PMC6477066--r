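#' Chi-square goodness-of-fit test of phenotype segregation
#'
#' Tests observed WT/mutant phenotype counts against a Mendelian expectation
#' (3:1 by default, the F2 ratio of a monogenic recessive trait) with the
#' Pearson statistic and no continuity correction, so the statistic equals
#' the classical hand computation for two phenotype classes (df = 1).
#'
#' @param data Data frame with one row per cross and integer columns `n_wt`
#'   and `n_mutant`.
#' @param ratio Expected WT:mutant ratio, length-2 positive numeric
#'   (default `c(3, 1)`).
#' @param alpha Significance level for the verdict column (default 0.05).
#' @return The input tibble with added columns `n_total`, `statistic`, `df`,
#'   `p_value`, and `significant`.
#' @examples
#' crosses <- tibble::tibble(cross = c("MT", "AC"),
#'                           n_wt = c(76, 143), n_mutant = c(33, 43))
#' chi_square_segregation(crosses)
#' @export
chi_square_segregation <- function(data, ratio = c(3, 1), alpha = 0.05) {
  if (!all(c("n_wt", "n_mutant") %in% names(data))) {
    abort("`data` must have columns `n_wt` and `n_mutant`")
  }
  if (length(ratio) != 2 || any(ratio <= 0)) {
    abort("`ratio` must be two positive numbers (WT:mutant)")
  }
  if (any(data$n_wt < 0 | data$n_mutant < 0)) abort("counts must be >= 0")
  total <- data$n_wt + data$n_mutant
  if (any(total == 0)) abort("total count is 0: nothing to test")

  p <- ratio / sum(ratio)
  res <- purrr::map2(data$n_wt, data$n_mutant, function(w, m) {
    ct <- suppressWarnings(chisq.test(c(w, m), p = p, correct = FALSE))
    tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
           p_value = unname(ct$p.value))
  }) |> list_rbind()

  as_tibble(data) |>
    mutate(n_total = total,
           statistic = res$statistic,
           df = as.integer(res$df),
           p_value = res$p_value,
           significant = res$p_value < alpha)
}
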