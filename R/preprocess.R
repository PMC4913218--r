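#' Remove regions with unreliably weak signal
#'
#' A region is retained iff its mean projection fraction across animals is
#' at least \code{min_mean_pf} (default 0.1\%): regions below the threshold
#' carry signal too weak to be reliable across mice. The boundary value is
#' retained (removal is for means strictly below the threshold).
#'
#' @param cohort a raw-stage \code{cohort_table}.
#' @param min_mean_pf retention threshold on the column mean.
#' @return list with \code{cohort} (stage \code{"thresholded"}, retained
#'   values unchanged) and \code{removed} (abbreviations of dropped regions,
#'   in ontology order).
#' @export
threshold_regions <- function(cohort, min_mean_pf = 0.001) {
  require_stage(cohort, "raw")
  cm <- colMeans(cohort$values)
  keep <- cm >= min_mean_pf
  if (!any(keep))
    stop("thresholding at ", min_mean_pf, " would remove every region")
  out <- cohort
  out$values <- cohort$values[, keep, drop = FALSE]
  out$regions <- cohort$regions[keep, , drop = FALSE]
  rownames(out$regions) <- NULL
  out$stage <- "thresholded"
  validate_cohort(out)
  list(cohort = out, removed = cohort$regions$abbreviation[!keep])
}

#' Fit the injection-volume power law
#'
#' Dividing projection fractions directly by injection volume
#' over-corrects; instead the total projection fraction per animal is
#' modelled as \eqn{\sum_j PF_{ij} = A\, V_i^{\,n}} (the additive constant
#' is identically zero: no injection, no fluorescence). Taking logs,
#' \eqn{\log \sum PF = n \log V + \log A}, and \eqn{(n, A)} come from an
#' ordinary least-squares fit; natural logs are used (the base cancels in
#' \eqn{n}).
#'
#' @param cohort a thresholded \code{cohort_table}; sums run over the
#'   retained regions only.
#' @param exclude optional character vector of region abbreviations to
#'   leave out of the per-animal sum (e.g. the injected region itself).
#' @return an object of class \code{power_law_fit}: \code{exponent} (n),
#'   \code{prefactor} (A > 0), \code{intercept} (0 by construction of the
#'   model), \code{r_squared} of the log-log fit.
#' @export
fit_volume_exponent <- function(cohort, exclude = NULL) {
  require_stage(cohort, "thresholded")
  if (nrow(cohort$values) < 3L)
    stop("need at least 3 animals to fit the power law")
  cols <- colnames(cohort$values)
  if (!is.null(exclude)) {
    unknown <- setdiff(exclude, cols)
    if (length(unknown) > 0L)
      stop("exclude names unknown region(s): ", paste(unknown, collapse = ", "))
    cols <- setdiff(cols, exclude)
  }
  s <- rowSums(cohort$values[, cols, drop = FALSE])
  if (any(s == 0))
    stop("animal(s) with zero total projection fraction (log undefined): ",
         paste(rownames(cohort$values)[s == 0], collapse = ", "))
  lv <- log(cohort$animals$injection_volume)
  if (stats::var(lv) == 0)
    stop("injection volumes are all equal; the exponent is unidentifiable")
  fit <- stats::lm(log(s) ~ lv)
  tss <- sum((log(s) - mean(log(s))) ^ 2)
  rss <- sum(stats::residuals(fit) ^ 2)
  structure(
    list(exponent = unname(stats::coef(fit)[2L]),
         prefactor = exp(unname(stats::coef(fit)[1L])),
         intercept = 0,
         # a constant response is fit exactly by the intercept
         r_squared = if (tss == 0) 1 else 1 - rss / tss),
    class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> sum(PF) = A * InjVol^n : n = %.4g, A = %.4g (R^2 = %.3f)\n",
              x$exponent, x$prefactor, x$r_squared))
  invisible(x)
}

#' Normalize projection fractions by injection volume
#'
#' Divides every animal's projection fractions by \eqn{V_i^{\,n}}. After
#' this step values are no longer guaranteed to be at most 1.
#'
#' @param cohort a thresholded \code{cohort_table}.
#' @param n power-law exponent (finite; typically from
#'   \code{\link{fit_volume_exponent}}).
#' @return the cohort at stage \code{"volume_normalized"}.
#' @export
normalize_by_volume <- function(cohort, n) {
  require_stage(cohort, "thresholded")
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n))
  v <- cohort$animals$injection_volume
  if (any(v <= 0)) stop("non-positive injection volume")
  out <- cohort
  out$values <- cohort$values / (v ^ n)
  out$stage <- "volume_normalized"
  validate_cohort(out)
  out
}

#' Scale every region to unit mean across animals
#'
#' Region columns are divided by their mean over animals so regions with
#' very different absolute projection strengths become comparable in the
#' per-region GLM. Idempotent.
#'
#' @param cohort a volume-normalized \code{cohort_table}.
#' @return the cohort at stage \code{"unit_mean"}; every column mean is 1
#'   to within 1e-12.
#' @export
unit_mean_normalize <- function(cohort) {
  if (identical(cohort$stage, "unit_mean")) return(cohort)
  require_stage(cohort, "volume_normalized")
  cm <- colMeans(cohort$values)
  if (any(cm <= 0))
    stop("zero-mean region column(s) cannot be scaled to unit mean: ",
         paste(colnames(cohort$values)[cm <= 0], collapse = ", "))
  out <- cohort
  out$values <- sweep(cohort$values, 2, cm, `/`)
  out$stage <- "unit_mean"
  validate_cohort(out)
  out
}

#' Injection-placement diagnostic correlations
#'
#' Quantifies how strongly the brain-wide projection pattern depends on
#' where the injection landed. The animal with the most extreme distance on
#' the chosen axis is the reference; every animal's region profile is
#' correlated (Pearson) against the reference's, so the reference itself
#' scores exactly 1. With \code{normalize = TRUE} region columns are first
#' scaled to unit mean to remove between-injection strength differences
#' (this is what makes negative correlations possible).
#'
#' @param cohort a \code{cohort_table} (any stage).
#' @param axis \code{"ML"}, \code{"AP"} or \code{"DV"}.
#' @param normalize scale columns to unit mean first.
#' @return data frame: animal_id, distance on the chosen axis, Pearson r
#'   against the reference; attribute \code{"reference"} names the
#'   reference animal. A tie on distance is broken by file order.
#' @export
injection_distance_correlations <- function(cohort,
                                            axis = c("ML", "AP", "DV"),
                                            normalize = TRUE) {
  validate_cohort(cohort)
  axis <- match.arg(axis)
  if (nrow(cohort$values) < 2L) stop("need at least 2 animals")
  dist_col <- c(ML = "ml_um", AP = "ap_um", DV = "dv_um")[[axis]]
  d <- cohort$animals[[dist_col]]
  v <- cohort$values
  if (normalize) {
    cm <- colMeans(v)
    if (any(cm <= 0))
      stop("zero-mean region column(s) prevent unit-mean scaling: ",
           paste(colnames(v)[cm <= 0], collapse = ", "))
    v <- sweep(v, 2, cm, `/`)
  }
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance projection vector for animal(s): ",
         paste(rownames(v)[sds == 0], collapse = ", "))
  ref <- which.max(d)  # which.max takes the first maximum: deterministic tie-break
  r <- as.vector(stats::cor(t(v), v[ref, ]))
  out <- data.frame(animal_id = cohort$animals$animal_id,
                    distance_um = d, pearson_r = r,
                    stringsAsFactors = FALSE)
  attr(out, "reference") <- cohort$animals$animal_id[ref]
  out
}
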