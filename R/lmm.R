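#' Assemble a semitone response table for the mixed model
#'
#' Stacks one or more pitch datasets, converts each record in the analysis
#' window to semitones against its own syllable baseline, and attaches the
#' numeric shift-condition covariate (e.g. -1 / 0 / +1 for shift direction,
#' or 0/1 for pooled shift vs no shift).
#'
#' @param datasets A list of [pitch_dataset()] objects (bird ids must be
#'   unique across datasets, as the generator guarantees).
#' @param conditions Numeric vector, one condition value per dataset.
#' @param epoch,days Analysis window (default: end of shift, days 12--14).
#' @param aggregate `"iteration"` (default; one row per rendition) or
#'   `"day"` (per-syllable daily means).
#' @return A data.table with columns `bird_id`, `syllable_id`, `st`, `x`.
#' @export
pitch_lmm_data <- function(datasets, conditions, epoch = "shift", days = NULL,
                           aggregate = c("iteration", "day")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(datasets) == length(conditions))
  rbindlist(lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    if (is.null(days)) days <- end_of_shift_days(d)
    w <- semitone_records(d, epoch, days)
    if (aggregate == "day")
      w <- w[, .(st = mean(st)), by = .(bird_id, syllable_id, day)]
    w[, .(bird_id, syllable_id, st, x = conditions[i])]
  }))
}

#' Nested random-intercept linear mixed model on pitch change
#'
#' The frequentist cross-check on the bootstrap inference: a linear mixed
#' model of per-iteration semitone pitch change with a fixed slope on the
#' shift condition and random intercepts for bird and for syllable nested
#' within bird,
#'
#'   st_ijk = beta0 + beta1 * x_ij + c_k(bird) + b_jk(syllable in bird) + eps_ij
#'
#' fitted by REML via `lme4::lmer`. The fixed-effect p-value uses the
#' large-sample normal approximation of the t-statistic. Singular fits
#' (variance components estimated at zero) are flagged, not hidden.
#'
#' @param data A table from [pitch_lmm_data()], or anything with columns
#'   `bird_id`, `syllable_id`, `st`, `x`.
#' @return An object of class `pitch_lmm`: `beta0`, `beta1`, `se_fixed`,
#'   `t_fixed`, `p_fixed`, `sd_bird`, `sd_syllable`, `residual_sd`,
#'   `bird_intercepts`, `syllable_intercepts`, `singular`, `converged` (with
#'   any `convergence_messages` recorded verbatim), `n_obs`, and the
#'   underlying `fit`.
#' @export
fit_pitch_lmm <- function(data) {
  data <- as.data.table(data)
  stopifnot(all(c("bird_id", "syllable_id", "st", "x") %in% names(data)))
  if (length(unique(data$x)) < 2L)
    stop("condition covariate is constant: no contrast to estimate")
  conv_msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(st ~ x + (1 | bird_id) + (1 | bird_id:syllable_id),
               data = data, REML = TRUE),
    warning = function(w) {
      # convergence chatter becomes a recorded diagnostic, not console noise
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        conv_msgs <<- c(conv_msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    })
  co <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_of <- function(grp) {
    i <- match(grp, vc$grp)
    if (is.na(i)) 0 else vc$sdcor[i]
  }
  re <- lme4::ranef(fit)
  structure(list(
    beta0 = unname(co["(Intercept)", "Estimate"]),
    beta1 = unname(co["x", "Estimate"]),
    se_fixed = unname(co["x", "Std. Error"]),
    t_fixed = unname(co["x", "t value"]),
    p_fixed = 2 * pnorm(-abs(unname(co["x", "t value"]))),
    sd_bird = sd_of("bird_id"),
    sd_syllable = sd_of("bird_id:syllable_id"),
    residual_sd = sd_of("Residual"),
    bird_intercepts = setNames(re$bird_id[[1]], rownames(re$bird_id)),
    syllable_intercepts = setNames(re$`bird_id:syllable_id`[[1]],
                                   rownames(re$`bird_id:syllable_id`)),
    singular = lme4::isSingular(fit),
    converged = length(conv_msgs) == 0L,
    convergence_messages = conv_msgs,
    n_obs = nrow(data),
    fit = fit), class = "pitch_lmm")
}

#' @export
print.pitch_lmm <- function(x, ...) {
  cat(sprintf(paste0(
    "<pitch_lmm> st ~ condition + (1|bird) + (1|bird:syllable), n = %d\n",
    "  beta1 = %.4f st (SE %.4f), t = %.2f, p = %.3g%s\n",
    "  sd: bird %.3f, syllable-in-bird %.3f, residual %.3f\n"),
    x$n_obs, x$beta1, x$se_fixed, x$t_fixed, x$p_fixed,
    paste0(if (x$singular) " [singular fit]" else "",
           if (!x$converged) " [convergence warning]" else ""),
    x$sd_bird, x$sd_syllable, x$residual_sd))
  invisible(x)
}

#' Serialize a mixed-model fit summary
#'
#' @param x A `pitch_lmm`.
#' @param path JSON path.
#' @export
write_lmm_json <- function(x, path) {
  stopifnot(inherits(x, "pitch_lmm"))
  jsonlite::write_json(
    list(beta0 = x$beta0, beta1 = x$beta1, se_fixed = x$se_fixed,
         t_fixed = x$t_fixed, p_fixed = x$p_fixed, sd_bird = x$sd_bird,
         sd_syllable = x$sd_syllable, residual_sd = x$residual_sd,
         singular = x$singular, converged = x$converged,
         convergence_messages = x$convergence_messages, n_obs = x$n_obs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
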