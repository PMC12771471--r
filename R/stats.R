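#' Brunner-Munzel test for two independent samples
#'
#' Nonparametric test of the relative effect
#' `p = P(X < Y) + 0.5 P(X = Y)` for continuous or tied data with possibly
#' unequal variances. Uses pooled midranks; the variance is estimated from
#' the within-group variances of (pooled minus internal) ranks, the
#' statistic is referred to a t distribution with Satterthwaite-type
#' degrees of freedom, and the two-sided p-value is returned. Under
#' stochastic equality of the groups the relative effect is 0.5.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @return A list of class `"bm_test"`: `p_hat` (relative effect estimate),
#'   `statistic`, `df`, `p_value`, `n_x`, `n_y`.
#' @export
brunner_munzel <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("both samples need at least 2 observations")
  pooled <- c(x, y)
  if (length(unique(pooled)) < 2)
    stop("all pooled values are tied; the relative effect is degenerate")
  r <- rank(pooled)                 # midranks
  r1 <- rank(x); r2 <- rank(y)      # internal midranks
  m1 <- mean(r[seq_len(n1)]); m2 <- mean(r[n1 + seq_len(n2)])
  p_hat <- (m2 - (n2 + 1) / 2) / n1
  v1 <- sum((r[seq_len(n1)] - r1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r[n1 + seq_len(n2)] - r2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  denom <- sqrt(n1 * v1 + n2 * v2)
  N <- n1 + n2
  if (denom < 1e-12) {
    warning("complete separation: rank variance is zero; ",
            "p-value taken as 0")
    stat <- sign(m2 - m1) * Inf
    return(structure(list(p_hat = p_hat, statistic = stat, df = NA_real_,
                          p_value = 0, n_x = n1, n_y = n2),
                     class = "bm_test"))
  }
  stat <- n1 * n2 * (m2 - m1) / N / denom
  df <- denom^4 / ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(stat), df)
  structure(list(p_hat = p_hat, statistic = stat, df = df, p_value = p,
                 n_x = n1, n_y = n2), class = "bm_test")
}

#' Holm step-down adjustment of p-values
#'
#' Family-wise error-rate control: sorted ascending, the i-th smallest
#' p-value is multiplied by (k - i + 1), running maxima are enforced, and
#' values are capped at 1.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  p.adjust(p_values, method = "holm")
}

#' Fisher's exact test with Monte Carlo p-values for large tables
#'
#' For 2 x 2 tables the exact two-sided hypergeometric rule is used; for
#' larger tables the p-value is estimated by Monte Carlo simulation
#' conditional on the margins with `monte_carlo_B` replicates, as
#' `p = (1 + #{simulated tables at least as extreme}) / (B + 1)`.
#'
#' @param table matrix of non-negative integer counts.
#' @param monte_carlo_B number of Monte Carlo replicates for tables larger
#'   than 2 x 2 (default 10000).
#' @param seed integer seed for the Monte Carlo draw (recorded in the
#'   output); NULL uses the current RNG stream.
#' @return A list of class `"fisher_result"`: `p_value`, `method`, `B`
#'   (NA for exact), `seed`.
#' @export
fisher_exact <- function(table, monte_carlo_B = 10000, seed = NULL) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0), all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("a table margin is zero; no association is testable (p = 1)")
    return(structure(list(p_value = 1, method = "degenerate", B = NA,
                          seed = seed), class = "fisher_result"))
  }
  if (all(dim(table) == c(2, 2))) {
    p <- fisher.test(table)$p.value
    return(structure(list(p_value = p, method = "exact", B = NA, seed = seed),
                     class = "fisher_result"))
  }
  p <- with_seed(seed,
    fisher.test(table, simulate.p.value = TRUE, B = monte_carlo_B)$p.value)
  structure(list(p_value = p, method = "monte_carlo", B = monte_carlo_B,
                 seed = seed), class = "fisher_result")
}

#' Ordinal / categorical phenotype scores
#'
#' Container for the two categorical traits scored alongside spot areas:
#' frons melanization (ordinal 0 = none, 1 = below the compound eyes,
#' 2 = extending above their lower edge) and hypopygium morphology
#' (normal / abnormal relative to the individual's sex).
#'
#' @param trait `"frons_melanization"` or `"hypopygium"`.
#' @param values vector of scores (`0:2` for frons; `"normal"`/`"abnormal"`
#'   for hypopygium).
#' @param group parallel vector of group labels (e.g. treatment x sex).
#' @return A list of class `"categorical_score"` with a `table()` of
#'   group x value counts ready for [fisher_exact()].
#' @export
categorical_score <- function(trait = c("frons_melanization", "hypopygium"),
                              values, group) {
  trait <- match.arg(trait)
  stopifnot(length(values) == length(group))
  if (trait == "frons_melanization" && !all(values %in% 0:2))
    stop("frons melanization scores must be 0, 1 or 2")
  if (trait == "hypopygium" && !all(values %in% c("normal", "abnormal")))
    stop("hypopygium scores must be 'normal' or 'abnormal'")
  structure(list(trait = trait, values = values, group = group,
                 table = table(group, values)),
            class = "categorical_score")
}

significance_stars <- function(p) {
  ifelse(p < 0.005, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Per-spot Brunner-Munzel battery with Holm correction
#'
#' For each requested comparison of two groups, runs the Brunner-Munzel
#' test on normalized spot areas separately for each spot 1..10, adjusts
#' the ten p-values by the Holm method (the multiple-testing family is the
#' ten spots within one comparison panel), and assigns significance stars
#' at 0.05 / 0.01 / 0.005.
#'
#' @param records data.frame of spot-area records: `individual_id`, `sex`,
#'   `treatment`, `spot_index`, `normalized_area`.
#' @param comparisons list of length-2 character vectors of group labels;
#'   group labels are `"<treatment>:<sex>"` (e.g. `"GFP_RNAi:F"`).
#' @param n_spots spots per panel (default 10).
#' @return data.frame with columns `comparison`, `spot_index`, `p_hat`,
#'   `statistic`, `df`, `p_value`, `p_holm`, `stars`; exactly `n_spots`
#'   rows per retained comparison.
#' @export
run_dimorphism_battery <- function(records, comparisons, n_spots = 10) {
  records$group <- paste(records$treatment, records$sex, sep = ":")
  out <- list()
  for (cmp in comparisons) {
    g1 <- records[records$group == cmp[1], ]
    g2 <- records[records$group == cmp[2], ]
    n1 <- length(unique(g1$individual_id))
    n2 <- length(unique(g2$individual_id))
    if (n1 < 2 || n2 < 2) {
      warning("comparison ", paste(cmp, collapse = " vs "),
              " skipped: a group has fewer than 2 individuals")
      next
    }
    res <- lapply(seq_len(n_spots), function(k) {
      b <- brunner_munzel(g1$normalized_area[g1$spot_index == k],
                          g2$normalized_area[g2$spot_index == k])
      data.frame(comparison = paste(cmp, collapse = " vs "), spot_index = k,
                 p_hat = b$p_hat, statistic = b$statistic, df = b$df,
                 p_value = b$p_value)
    })
    res <- do.call(rbind, res)
    res$p_holm <- holm_adjust(res$p_value)
    res$stars <- significance_stars(res$p_holm)
    out[[length(out) + 1]] <- res
  }
  if (length(out) == 0) return(invisible(NULL))
  do.call(rbind, out)
}
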