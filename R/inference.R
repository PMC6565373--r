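new_comparison <- function(probability, alpha, n_comparisons, resolution_n,
                           label = NA_character_, mode = "all-pairs") {
  alpha_adj <- alpha / n_comparisons
  direction <- if (probability > 1 - alpha_adj / 2) "greater"
  else if (probability < alpha_adj / 2) "lesser"
  else "none"
  structure(list(
    probability = probability,
    probability_label = format_probability(probability, resolution_n),
    alpha = alpha, n_comparisons = n_comparisons,
    significant = direction != "none", direction = direction,
    resolution_n = resolution_n, label = label, mode = mode),
    class = "hb_comparison")
}

#' @export
print.hb_comparison <- function(x, ...) {
  cat(sprintf("<hb_comparison> %s: %s (alpha = %g%s) -> %s\n",
              if (is.na(x$label)) "P(first >= second)" else x$label,
              x$probability_label, x$alpha,
              if (x$n_comparisons > 1)
                sprintf(", Bonferroni m = %d", x$n_comparisons) else "",
              if (x$significant) paste0("significant (", x$direction, ")")
              else "not significant"))
  invisible(x)
}

#' Render a bootstrap probability with its resolution bound
#'
#' A probability of exactly 0 or 1 from `N` resamples is only resolved to
#' `1/N`, so it is rendered as `p < 1/N` or `p > 1 - 1/N` (the numeric field
#' keeps the raw 0 or 1).
#'
#' @param p Probability in `[0, 1]`.
#' @param n Resampling resolution (number of resamples behind `p`).
#' @return A string.
#' @export
format_probability <- function(p, n) {
  if (!is.null(n) && is.finite(n) && n > 0) {
    if (p == 0) return(paste("p <", format(1 / n)))
    if (p == 1) return(paste("p >", format(1 - 1 / n)))
  }
  sprintf("p = %.4g", p)
}

resampled_of <- function(x) {
  if (inherits(x, "hb_boot")) x$resampled_means
  else if (is.numeric(x) && length(x) >= 1L) as.numeric(x)
  else stop("expected an hb_boot object or a numeric vector of resampled means")
}

#' Posterior probability of a group mean exceeding a constant
#'
#' The proportion of the population of bootstrapped means greater than or
#' equal to `c` -- a direct probability reported in lieu of a p-value. A
#' proportion below `alpha/2` means the group lies significantly below the
#' constant; above `1 - alpha/2`, significantly above (two-way test).
#'
#' @param x An `hb_boot` or numeric vector of resampled means.
#' @param c The constant, semitones.
#' @param alpha Two-way significance level.
#' @param n_comparisons Bonferroni correction count.
#' @param label Optional label for reports.
#' @return An object of class `hb_comparison`.
#' @export
prob_ge_constant <- function(x, c = 0, alpha = 0.05, n_comparisons = 1L,
                             label = NA_character_) {
  r <- resampled_of(x)
  new_comparison(mean(r >= c), alpha, n_comparisons, length(r), label,
                 mode = "vs-constant")
}

#' Posterior probability of one group exceeding another
#'
#' Treats the two resampled-mean populations as independent and computes the
#' volume of their joint distribution on one side of the unity line,
#' including the line itself: `P(a >= b) = (1 / (Na * Nb)) * sum_ij 1[a_i >=
#' b_j]`. Computed exactly by sorting `b` and binary-searching every `a_i`
#' (no subsampling of pairs). A `paired` mode compares index-by-index
#' instead, kept for sensitivity analysis; all-pairs is the default and the
#' mode is recorded in the result.
#'
#' @param a,b `hb_boot` objects or numeric vectors of resampled means.
#' @inheritParams prob_ge_constant
#' @param mode `"all-pairs"` (default) or `"paired"`.
#' @return An object of class `hb_comparison`.
#' @export
prob_group_ge <- function(a, b, alpha = 0.05, n_comparisons = 1L,
                          label = NA_character_,
                          mode = c("all-pairs", "paired")) {
  mode <- match.arg(mode)
  av <- resampled_of(a)
  bv <- resampled_of(b)
  if (mode == "all-pairs") {
    p <- sum(findInterval(av, sort(bv))) / (length(av) * length(bv))
    res_n <- min(length(av), length(bv))
  } else {
    if (length(av) != length(bv))
      stop("paired mode requires populations of equal length")
    p <- mean(av >= bv)
    res_n <- length(av)
  }
  new_comparison(p, alpha, n_comparisons, res_n, label, mode)
}

#' Two-way significance decision for a bootstrap probability
#'
#' A probability is significant at level `alpha` (two-way) when it falls
#' below `alpha_adj / 2` or above `1 - alpha_adj / 2`, with `alpha_adj =
#' alpha / n_comparisons` (Bonferroni correction across `n_comparisons`
#' tests). Direction is `greater` above the upper threshold, `lesser` below
#' the lower one, `none` otherwise.
#'
#' @param probability Probability in `[0, 1]` (or an `hb_comparison` to
#'   re-decide under a different correction).
#' @inheritParams prob_ge_constant
#' @param resolution_n Resampling resolution behind the probability, for
#'   rendering.
#' @return An object of class `hb_comparison`.
#' @export
decide <- function(probability, alpha = 0.05, n_comparisons = 1L,
                   resolution_n = NULL, label = NA_character_) {
  if (inherits(probability, "hb_comparison")) {
    cmp <- probability
    return(new_comparison(cmp$probability, alpha, n_comparisons,
                          cmp$resolution_n, cmp$label, cmp$mode))
  }
  if (!is.finite(probability) || probability < 0 || probability > 1)
    stop("probability must lie in [0, 1]")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (n_comparisons < 1L) stop("n_comparisons must be >= 1")
  new_comparison(probability, alpha, n_comparisons, resolution_n, label,
                 mode = "decision")
}

#' Tabulate a set of comparisons
#'
#' Flattens `hb_comparison` objects into one row each: probability, rendered
#' bound, thresholds and decision. `NULL` entries (comparisons that do not
#' make sense for a cell) become rows of `NA`s, keeping table layouts
#' explicit about untested cells.
#'
#' @param comparisons A named list of `hb_comparison` objects (or `NULL`s).
#' @return A data.table.
#' @export
comparison_table <- function(comparisons) {
  rbindlist(lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    if (is.null(cmp))
      return(data.table(comparison = nm, probability = NA_real_,
                        rendered = NA_character_, alpha = NA_real_,
                        n_comparisons = NA_integer_, lower = NA_real_,
                        upper = NA_real_, significant = NA,
                        direction = NA_character_, mode = NA_character_))
    a <- cmp$alpha / cmp$n_comparisons
    data.table(comparison = nm, probability = cmp$probability,
               rendered = cmp$probability_label, alpha = cmp$alpha,
               n_comparisons = as.integer(cmp$n_comparisons),
               lower = a / 2, upper = 1 - a / 2,
               significant = cmp$significant, direction = cmp$direction,
               mode = cmp$mode)
  }))
}
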