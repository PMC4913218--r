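# Shared-design multi-response OLS: one QR of the design serves every
# region column. Returns coefficients (p_design x n_regions) and residual
# variance per region.
fit_shared_design <- function(X, Y) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop("rank-deficient design matrix (rank ", qrx$rank, " < ", ncol(X),
         " columns); cannot fit the per-region GLM")
  coefs <- qr.coef(qrx, Y)
  resid <- Y - X %*% coefs
  df <- nrow(X) - ncol(X)
  rv <- if (df > 0) colSums(resid ^ 2) / df else rep(NA_real_, ncol(Y))
  list(coefficients = coefs, resid_var = rv)
}

glm_design <- function(animals, include_condition, centers = NULL) {
  if (is.null(centers))
    centers <- c(ml = mean(animals$ml_um), ap = mean(animals$ap_um),
                 dv = mean(animals$dv_um))
  X <- cbind(intercept = 1,
             kx = animals$ml_um - centers[["ml"]],
             ky = animals$ap_um - centers[["ap"]],
             kz = animals$dv_um - centers[["dv"]])
  if (include_condition) X <- cbind(X, kc = animals$condition)
  list(X = X, centers = centers)
}

#' Per-region general linear model
#'
#' For every retained region \eqn{j}, fits
#' \deqn{PF_{ij} = \beta_j + k_{x,j}\tilde x_i + k_{y,j}\tilde y_i
#'   + k_{z,j}\tilde z_i + k_{c,j} c_i}
#' where \eqn{\tilde x, \tilde y, \tilde z} are the injection-centroid
#' distances centred to mean zero over the fitted animals and \eqn{c_i} is
#' +1 for controls, -1 for sleep-restricted animals. Under the Gaussian
#' identity-link likelihood implied by the linear equation, maximum
#' likelihood is ordinary least squares; all regions share one design
#' matrix, so one QR decomposition fits every region at once (numerically
#' identical to region-by-region \code{lm}). A positive \eqn{k_{c,j}} means
#' controls have the higher normalized projection fraction in region j.
#'
#' @param cohort a \code{cohort_table} at stage \code{"unit_mean"}.
#' @param include_condition model the condition term (requires at least 6
#'   animals and both conditions present).
#' @return a \code{glm_fit_table}: data frame with one row per region
#'   (\code{region}, \code{beta}, \code{kx}, \code{ky}, \code{kz},
#'   \code{kc} when modelled, \code{resid_var}); the covariate centres used
#'   are attached as attribute \code{"centers"}.
#' @export
fit_region_glm <- function(cohort, include_condition = TRUE) {
  require_stage(cohort, "unit_mean")
  n <- nrow(cohort$values)
  p_design <- if (include_condition) 5L else 4L
  if (n < p_design + 1L)
    stop("need at least ", p_design + 1L, " animals to fit ", p_design,
         " parameters per region")
  des <- glm_design(cohort$animals, include_condition)
  fit <- fit_shared_design(des$X, cohort$values)
  co <- t(fit$coefficients)
  out <- data.frame(region = colnames(cohort$values),
                    beta = co[, "intercept"],
                    kx = co[, "kx"], ky = co[, "ky"], kz = co[, "kz"],
                    stringsAsFactors = FALSE)
  if (include_condition) out$kc <- co[, "kc"]
  out$resid_var <- fit$resid_var
  rownames(out) <- NULL
  structure(out, centers = des$centers,
            include_condition = include_condition,
            class = c("glm_fit_table", "data.frame"))
}

#' Mean condition coefficient
#'
#' The unweighted arithmetic mean of the per-region condition coefficients
#' \eqn{k_{c,j}} over all retained regions — the scalar summary whose sign
#' the bootstrap test examines.
#'
#' @param fit a \code{glm_fit_table} fitted with the condition term.
#' @return the mean condition coefficient (a single number).
#' @export
mean_condition_effect <- function(fit) {
  stopifnot(inherits(fit, "glm_fit_table"))
  if (is.null(fit$kc))
    stop("fit has no condition coefficient (fitted with include_condition = FALSE)")
  mean(fit$kc)
}

#' Remove the injection-geometry signal from the feature matrix
#'
#' Fits the condition-free GLM (\eqn{\beta_j + k_x \tilde x + k_y \tilde y +
#' k_z \tilde z}) on a training subset of animals and subtracts the fitted
#' covariate contribution from every animal's row — including animals
#' outside the subset, using the subset's centring constants — so that, as
#' far as the model can tell, only condition (and noise) remains in the
#' features. Fitting on the training subset only keeps held-out animals
#' from leaking into cross-validated classifiers; passing all animals
#' reproduces the fit-on-everyone variant.
#'
#' @param cohort a \code{cohort_table} at stage \code{"unit_mean"}.
#' @param fit_animals animal ids (character) or row indices to fit on;
#'   default all animals.
#' @return numeric matrix (all animals x regions) of residual features
#'   \eqn{PF_{ij} - k_{x,j}\tilde x_i - k_{y,j}\tilde y_i - k_{z,j}\tilde z_i}.
#' @export
residualize_covariates <- function(cohort, fit_animals = NULL) {
  require_stage(cohort, "unit_mean")
  all_ids <- cohort$animals$animal_id
  idx <- if (is.null(fit_animals)) seq_along(all_ids)
         else if (is.character(fit_animals)) {
           unknown <- setdiff(fit_animals, all_ids)
           if (length(unknown) > 0L)
             stop("unknown animal id(s) in fit_animals: ",
                  paste(unknown, collapse = ", "))
           match(fit_animals, all_ids)
         } else as.integer(fit_animals)
  if (length(idx) < 5L)
    stop("need at least 5 animals in fit_animals for the rank-4 design")

  train <- cohort$animals[idx, , drop = FALSE]
  des_train <- glm_design(train, include_condition = FALSE)
  fit <- fit_shared_design(des_train$X, cohort$values[idx, , drop = FALSE])

  des_all <- glm_design(cohort$animals, include_condition = FALSE,
                        centers = des_train$centers)
  covar_part <- des_all$X[, c("kx", "ky", "kz"), drop = FALSE] %*%
    fit$coefficients[c("kx", "ky", "kz"), , drop = FALSE]
  cohort$values - covar_part
}
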