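# Approximate macro-category mix of the ipsilateral region ontology,
# proportional to a published region listing; rescaled to any region count.
CATEGORY_MIX <- c(
  "Isocortex" = 45, "Olfactory areas" = 7, "Hippocampal formation" = 7,
  "Claustrum + amygdala" = 7, "Striatum + pallidum" = 18, "Thalamus" = 38,
  "Hypothalamus" = 21, "Midbrain + pons" = 54, "Medulla" = 38,
  "Cerebellum" = 3, "Fiber tracts" = 1
)

#' Default settings for the synthetic cohort generator
#'
#' The defaults emulate the study conditions the analysis was designed for:
#' a 28-mouse cohort (14 control, 14 chronically sleep-restricted; 14 males
#' of whom 8 controls, 14 females of whom 6 controls), 293 ipsilateral
#' regions spread over 11 macro-categories, log-normally distributed
#' baseline projection fractions (median 0.002, 1.0 decades of log10 spread,
#' so a realistic share of regions falls below the 0.1\% reliability
#' threshold), total projection fraction scaling with injection volume to
#' the power 0.216, and injection-centroid distances drawn from
#' Normal(826, 140^2) (medial--lateral, from the midline),
#' Normal(1771, 262^2) (anterior--posterior, from the anterior commissure)
#' and Normal(636, 60^2) (depth from the pia), in micrometres, truncated at
#' zero. Injection volumes are log-normal in arbitrary units (the analysis
#' only uses their ratios). Multiplicative log-normal noise with
#' \code{noise_sd = 0.1} matches the subtle, heterogeneous regime the
#' analysis targets.
#'
#' @param n_control,n_csr animals per condition.
#' @param n_regions number of ipsilateral regions.
#' @param baseline_median,baseline_log10_sd median and log10-scale SD of the
#'   per-region baseline projection fraction \code{b_j}.
#' @param exponent true power-law exponent \code{n} of the total projection
#'   fraction vs injection volume relation.
#' @param injvol_meanlog,injvol_sdlog log-normal parameters of injection
#'   volume (arbitrary cohort-consistent units).
#' @param centroid_mean,centroid_sd length-3 vectors (ML, AP, DV), µm.
#' @param slope_sd length-3 vector: SDs of the per-region covariate slopes
#'   (per µm of centred ML/AP/DV distance).
#' @param condition_scheme \code{"null"} (no group effect),
#'   \code{"homogeneous"} (every region shifted by \code{effect_size}), or
#'   \code{"heterogeneous"} (a sparse subset of regions carries signed
#'   effects of magnitude \code{effect_size}, biased positive).
#' @param effect_size per-region condition effect magnitude (fractional
#'   shift of the mean between conditions; the GLM's \code{kc}).
#' @param prop_affected,prop_positive heterogeneous scheme: fraction of
#'   regions affected, and fraction of affected regions with positive sign.
#' @param noise_sd SD of the multiplicative log-scale noise.
#' @param hemisphere,volume_unit carried into the cohort table.
#' @return a named list of generator settings.
#' @export
synth_config <- function(n_control = 14, n_csr = 14,
                         n_regions = 293,
                         baseline_median = 0.002, baseline_log10_sd = 1.0,
                         exponent = 0.216,
                         injvol_meanlog = log(0.15), injvol_sdlog = 0.35,
                         centroid_mean = c(826, 1771, 636),
                         centroid_sd = c(140, 262, 60),
                         slope_sd = c(4e-4, 2e-4, 8e-4),
                         condition_scheme = c("heterogeneous", "null", "homogeneous"),
                         effect_size = 0.08,
                         prop_affected = 0.25, prop_positive = 0.8,
                         noise_sd = 0.1,
                         hemisphere = "ipsilateral",
                         volume_unit = "arbitrary") {
  condition_scheme <- match.arg(condition_scheme)
  cfg <- list(n_control = n_control, n_csr = n_csr, n_regions = n_regions,
              baseline_median = baseline_median,
              baseline_log10_sd = baseline_log10_sd,
              exponent = exponent,
              injvol_meanlog = injvol_meanlog, injvol_sdlog = injvol_sdlog,
              centroid_mean = centroid_mean, centroid_sd = centroid_sd,
              slope_sd = slope_sd,
              condition_scheme = condition_scheme,
              effect_size = effect_size,
              prop_affected = prop_affected, prop_positive = prop_positive,
              noise_sd = noise_sd,
              hemisphere = hemisphere, volume_unit = volume_unit)
  class(cfg) <- "synth_config"
  cfg
}

rtruncnorm_pos <- function(n, mean, sd) {
  # normal truncated at 0 by resampling; distances are physical, >= 0
  x <- stats::rnorm(n, mean, sd)
  while (any(x < 0)) {
    bad <- x < 0
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

synthetic_regions <- function(n_regions) {
  counts <- round(CATEGORY_MIX / sum(CATEGORY_MIX) * n_regions)
  # fix rounding drift on the largest category
  counts[which.max(counts)] <- counts[which.max(counts)] + (n_regions - sum(counts))
  categories <- rep(names(counts), counts)
  data.frame(
    region_id = seq_len(n_regions),
    abbreviation = sprintf("R%03d", seq_len(n_regions)),
    name = sprintf("Synthetic region %03d", seq_len(n_regions)),
    category = categories,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a raw-stage cohort from the generative model
#' \deqn{PF_{ij} = \mathrm{clip}_{[0,1]}\big( b_j\, V_i^{\,n}\,
#'   (1 + s_{x,j}\tilde x_i + s_{y,j}\tilde y_i + s_{z,j}\tilde z_i
#'      + k_{c,j} c_i)\, e^{\sigma \varepsilon_{ij}} \big)}
#' with \eqn{\varepsilon_{ij}} standard normal and centred covariates
#' \eqn{\tilde x_i = x_i - \bar x} (and likewise AP, DV) — the same centring
#' the downstream GLM applies, so with \eqn{\sigma = 0} the GLM on the
#' unit-mean normalized table is exactly correctly specified and recovers
#' every \eqn{k_{c,j}}. Effects enter multiplicatively on the baseline so
#' that unit-mean normalization divides them by \eqn{b_j V_i^n} cleanly.
#'
#' The generator refuses configurations whose systematic part goes
#' non-positive (slopes too large) and configurations under which clipping
#' at 1 touches 1\% or more of the entries, rather than letting clipping
#' distort the generative truth silently.
#'
#' @param config a \code{\link{synth_config}}.
#' @param seed integer seed; identical (config, seed) gives a bit-identical
#'   cohort and truth.
#' @return list with elements \code{cohort} (a raw-stage
#'   \code{cohort_table}) and \code{truth} (class \code{synthetic_truth}:
#'   exponent, prefactor \code{A = sum(b_j)}, baselines, slopes, true
#'   per-region condition effects, noise SD, seed).
#' @export
generate_cohort <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, {
    n_a <- config$n_control + config$n_csr
    p <- config$n_regions

    regions <- synthetic_regions(p)

    condition <- c(rep(1, config$n_control), rep(-1, config$n_csr))
    sex <- assign_sexes(config$n_control, config$n_csr)
    injvol <- stats::rlnorm(n_a, config$injvol_meanlog, config$injvol_sdlog)
    ml <- rtruncnorm_pos(n_a, config$centroid_mean[1], config$centroid_sd[1])
    ap <- rtruncnorm_pos(n_a, config$centroid_mean[2], config$centroid_sd[2])
    dv <- rtruncnorm_pos(n_a, config$centroid_mean[3], config$centroid_sd[3])

    animals <- data.frame(
      animal_id = sprintf("A%02d", seq_len(n_a)),
      condition = condition, sex = sex,
      injection_volume = injvol,
      ml_um = ml, ap_um = ap, dv_um = dv,
      stringsAsFactors = FALSE)

    b <- config$baseline_median *
      10 ^ stats::rnorm(p, 0, config$baseline_log10_sd)
    sx <- stats::rnorm(p, 0, config$slope_sd[1])
    sy <- stats::rnorm(p, 0, config$slope_sd[2])
    sz <- stats::rnorm(p, 0, config$slope_sd[3])
    kc <- switch(config$condition_scheme,
      null = rep(0, p),
      homogeneous = rep(config$effect_size, p),
      heterogeneous = {
        k <- rep(0, p)
        hit <- stats::runif(p) < config$prop_affected
        sgn <- ifelse(stats::runif(p) < config$prop_positive, 1, -1)
        k[hit] <- config$effect_size * sgn[hit]
        k
      })

    xt <- ml - mean(ml); yt <- ap - mean(ap); zt <- dv - mean(dv)
    systematic <- 1 + outer(xt, sx) + outer(yt, sy) + outer(zt, sz) +
      outer(condition, kc)
    if (any(systematic <= 0))
      stop("generator settings imply a non-positive mean factor for ",
           sum(systematic <= 0), " animal-region combination(s); reduce ",
           "slope_sd and/or effect_size")

    noise <- if (config$noise_sd > 0)
      exp(config$noise_sd * matrix(stats::rnorm(n_a * p), n_a, p))
    else matrix(1, n_a, p)

    pf <- sweep(systematic * noise, 2, b, `*`) * injvol ^ config$exponent
    clipped <- pf > 1
    if (mean(clipped) >= 0.01)
      stop("clipping at 1 would affect ", sprintf("%.1f%%", 100 * mean(clipped)),
           " of entries (>= 1%); the generator refuses rather than distort ",
           "the generative truth")
    pf[clipped] <- 1
    dimnames(pf) <- list(animals$animal_id, regions$abbreviation)

    cohort <- cohort_table(pf, animals, regions,
                           hemisphere = config$hemisphere, stage = "raw",
                           volume_unit = config$volume_unit)
    truth <- structure(
      list(exponent = config$exponent, prefactor = sum(b),
           baseline = stats::setNames(b, regions$abbreviation),
           slopes = data.frame(abbreviation = regions$abbreviation,
                               sx = sx, sy = sy, sz = sz,
                               stringsAsFactors = FALSE),
           kc = stats::setNames(kc, regions$abbreviation),
           noise_sd = config$noise_sd,
           clipped_fraction = mean(clipped),
           clipped_regions = regions$abbreviation[colSums(clipped) > 0],
           seed = seed, config = config),
      class = "synthetic_truth")
    list(cohort = cohort, truth = truth)
  })
}

assign_sexes <- function(n_control, n_csr) {
  # mirror the study's sex balance as closely as the group sizes allow:
  # a bit over half the controls male, the complement in the CSR group
  m_ctrl <- round(n_control * 8 / 14)
  m_csr <- max(0L, min(n_csr, round((n_control + n_csr) / 2) - m_ctrl))
  c(rep(c("M", "F"), c(m_ctrl, n_control - m_ctrl)),
    rep(c("M", "F"), c(m_csr, n_csr - m_csr)))
}

#' Generate an ensemble of null cohorts
#'
#' Cohorts are drawn with the condition effect switched off
#' (\code{condition_scheme = "null"}), for type-I-error calibration of the
#' bootstrap test and the classifier. Per-cohort seeds are derived
#' deterministically from the master seed.
#'
#' Occasionally a derived seed draws a baseline configuration the generator
#' refuses (clipping would reach 1\% of entries); such seeds are skipped
#' deterministically and the next derived seed is used, so the ensemble
#' always contains \code{n_cohorts} valid cohorts. Skipped seeds are
#' recorded in attribute \code{"skipped_seeds"}.
#'
#' @param config a \code{\link{synth_config}}; its condition scheme is
#'   forced to \code{"null"}.
#' @param n_cohorts number of independent cohorts (>= 1).
#' @param seed master seed.
#' @return list of \code{generate_cohort()} results, with the derived seeds
#'   attached as attribute \code{"seeds"}.
#' @export
make_null_ensemble <- function(config = synth_config(), n_cohorts, seed = 1L) {
  stopifnot(n_cohorts >= 1)
  config$condition_scheme <- "null"
  pool <- derive_seeds(seed, 2L * n_cohorts + 10L)
  out <- vector("list", n_cohorts)
  used <- integer(n_cohorts)
  skipped <- integer(0)
  i <- 0L
  for (s in pool) {
    if (i == n_cohorts) break
    g <- tryCatch(generate_cohort(config, s), error = function(e) e)
    if (inherits(g, "error")) { skipped <- c(skipped, s); next }
    i <- i + 1L
    out[[i]] <- g
    used[i] <- s
  }
  if (i < n_cohorts)
    stop("could not generate ", n_cohorts, " valid null cohorts from the ",
         "derived seed pool; the generator refused ", length(skipped),
         " of them — the configuration is too close to its validity limits")
  attr(out, "seeds") <- used
  attr(out, "skipped_seeds") <- skipped
  out
}
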