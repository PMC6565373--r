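#' Ground truth for the synthetic optical-density section generator
#'
#' Emulates per-section OD-ratio tables from TH-stained histology: each bird
#' contributes `sections_per_bird` sections whose Area-X/striatum OD ratio is
#' drawn from a Normal family -- saline-injected birds around `saline_mean`,
#' lesioned birds around a lower mean. The lesioned mean can be given directly
#' or solved numerically so that the lesioned population's mass below the
#' saline 5th percentile equals `target_below_threshold_fraction`.
#'
#' @param n_saline_birds,n_lesion_birds Bird counts (defaults: the study's
#'   4 saline and 16 lesioned birds).
#' @param sections_per_bird Sections contributed by each bird.
#' @param saline_mean,saline_sd Normal parameters of the saline OD ratios.
#' @param lesion_sd Spread of the lesioned OD ratios.
#' @param lesion_mean Lesioned mean; ignored when a target fraction is given.
#' @param target_below_threshold_fraction Desired fraction of lesioned
#'   sections below the saline 5th percentile, in (0, 1).
#' @param striatum_mean,striatum_sd Normal parameters of the reference
#'   striatum OD (arbitrary units); `od_areax` is realized as
#'   `ratio * od_striatum` so the ratio is exact.
#' @param lesion_bird_ids Optional character vector of bird ids for the
#'   lesioned birds (length `n_lesion_birds`), to link sections to behavioral
#'   birds.
#' @param seed RNG seed.
#' @return An object of class `od_generator_truth`.
#' @export
od_generator_truth <- function(n_saline_birds = 4L, n_lesion_birds = 16L,
                               sections_per_bird = 30L,
                               saline_mean = 1.4, saline_sd = 0.1,
                               lesion_sd = saline_sd, lesion_mean = NULL,
                               target_below_threshold_fraction = NULL,
                               striatum_mean = 1.0, striatum_sd = 0.05,
                               lesion_bird_ids = NULL, seed = 1L) {
  if (sections_per_bird < 1L) stop("sections_per_bird must be >= 1")
  if (saline_sd <= 0 || lesion_sd <= 0) stop("scale parameters must be > 0")
  tgt <- target_below_threshold_fraction
  if (!is.null(tgt)) {
    if (!is.finite(tgt) || tgt <= 0 || tgt >= 1)
      stop("target_below_threshold_fraction must lie strictly in (0, 1) ",
           "for a continuous OD-ratio family")
    q5 <- qnorm(0.05, saline_mean, saline_sd)
    lesion_mean <- uniroot(function(m) pnorm(q5, m, lesion_sd) - tgt,
                           interval = saline_mean + c(-50, 50) * saline_sd,
                           tol = 1e-10)$root
  } else if (is.null(lesion_mean)) {
    lesion_mean <- saline_mean
  }
  if (!is.null(lesion_bird_ids) && length(lesion_bird_ids) != n_lesion_birds)
    stop("lesion_bird_ids must have length n_lesion_birds")
  structure(list(
    n_saline_birds = as.integer(n_saline_birds),
    n_lesion_birds = as.integer(n_lesion_birds),
    sections_per_bird = as.integer(sections_per_bird),
    saline_mean = saline_mean, saline_sd = saline_sd,
    lesion_mean = lesion_mean, lesion_sd = lesion_sd,
    target_below_threshold_fraction = tgt,
    striatum_mean = striatum_mean, striatum_sd = striatum_sd,
    lesion_bird_ids = lesion_bird_ids, seed = as.integer(seed)),
    class = "od_generator_truth")
}

#' Generate synthetic per-section optical densities
#'
#' @param truth An [od_generator_truth()].
#' @return A data.table with columns `bird_id`, `group` (saline/lesioned),
#'   `section_index`, `od_areax`, `od_striatum`.
#' @export
generate_od_sections <- function(truth) {
  stopifnot(inherits(truth, "od_generator_truth"))
  set.seed(truth$seed)
  one_group <- function(n_birds, ids, group, mean, sd) {
    ns <- truth$sections_per_bird
    rbindlist(lapply(seq_len(n_birds), function(b) {
      ratio <- rnorm(ns, mean, sd)
      striat <- pmax(rnorm(ns, truth$striatum_mean, truth$striatum_sd), 1e-6)
      data.table(bird_id = ids[b], group = group,
                 section_index = seq_len(ns),
                 od_areax = ratio * striat, od_striatum = striat)
    }))
  }
  sal <- one_group(truth$n_saline_birds,
                   sprintf("saline_b%02d", seq_len(truth$n_saline_birds)),
                   "saline", truth$saline_mean, truth$saline_sd)
  ids <- truth$lesion_bird_ids
  if (is.null(ids)) ids <- sprintf("lesioned_b%02d", seq_len(truth$n_lesion_birds))
  les <- one_group(truth$n_lesion_birds, ids, "lesioned",
                   truth$lesion_mean, truth$lesion_sd)
  rbind(sal, les)
}

#' Read / write per-section OD tables
#'
#' CSV with header `bird_id,group,section_index,od_areax,od_striatum`.
#'
#' @param path File path.
#' @return `read_od_csv()` a data.table; `write_od_csv()` the path, invisibly.
#' @export
read_od_csv <- function(path) {
  fread(path, colClasses = list(character = c("bird_id", "group")))
}

#' @rdname read_od_csv
#' @param x An OD section table.
#' @export
write_od_csv <- function(x, path) {
  fwrite(x, path)
  invisible(path)
}
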