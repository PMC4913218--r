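# Weighted least-squares decision stump: best single-feature threshold
# minimizing weighted SSE of the working response. Deterministic: candidate
# splits at midpoints between distinct sorted values; ties broken towards
# the first feature, then the earlier split. Sort orders of the training
# matrix are computed once (presort_features) and reused across boosting
# rounds; the split search itself is vectorized over all features.
presort_features <- function(X) {
  n <- nrow(X)
  ord <- apply(X, 2, order, method = "radix")
  xs <- matrix(X[cbind(as.vector(ord), rep(seq_len(ncol(X)), each = n))],
               n, ncol(X))
  # a split is allowed only between strictly distinct neighbouring values
  valid <- xs[-n, , drop = FALSE] < xs[-1L, , drop = FALSE]
  list(X = X, ord = ord, xs = xs, valid = valid, n = n, p = ncol(X))
}

fit_stump <- function(ps, z, w) {
  n <- ps$n
  total_w <- sum(w)
  total_wz <- sum(w * z)
  base_sse_part <- -total_wz ^ 2 / total_w  # SSE minus constant sum(w z^2)
  W <- matrix(w[ps$ord], n, ps$p)
  WZ <- matrix((w * z)[ps$ord], n, ps$p)
  cw <- apply(W, 2, cumsum)[-n, , drop = FALSE]
  cwz <- apply(WZ, 2, cumsum)[-n, , drop = FALSE]
  sse_part <- -(cwz ^ 2 / cw + (total_wz - cwz) ^ 2 / (total_w - cw))
  sse_part[!ps$valid] <- Inf
  j <- which.min(sse_part)  # column-major: first feature, then earlier split
  if (length(j) == 0L || sse_part[j] >= base_sse_part - 1e-12)
    return(list(feature = 0L, split = NA_real_,
                left = total_wz / total_w, right = total_wz / total_w))
  v <- (j - 1L) %% (n - 1L) + 1L
  f <- (j - 1L) %/% (n - 1L) + 1L
  list(feature = f, split = (ps$xs[v, f] + ps$xs[v + 1L, f]) / 2,
       left = cwz[j] / cw[j],
       right = (total_wz - cwz[j]) / (total_w - cw[j]))
}

predict_stump <- function(stump, X) {
  if (stump$feature == 0L) return(rep(stump$left, nrow(X)))
  ifelse(X[, stump$feature] <= stump$split, stump$left, stump$right)
}

#' Train a logit-boost tree ensemble
#'
#' Stagewise additive logistic regression: at each round, Newton weights
#' \eqn{w_i = p_i(1 - p_i)} and working responses
#' \eqn{z_i = (y^*_i - p_i) / w_i} (with \eqn{y^* \in \{0, 1\}}) are formed
#' from the current class probabilities, a regression tree of the given
#' depth is fitted to \eqn{z} by weighted least squares, and half its
#' prediction is added to the score \eqn{F}; probabilities update as
#' \eqn{p = 1 / (1 + e^{-2F})}. This minimizes the binomial deviance.
#' Working responses are clamped to \eqn{[-4, 4]} and weights floored at
#' \eqn{2\times 10^{-8}}, the customary numerical safeguards. Depth-1
#' stumps use an exact internal search; deeper trees use weighted
#' recursive-partitioning regression. Training is fully deterministic.
#'
#' @param X numeric matrix, samples x features.
#' @param y labels in \{-1, +1\} (+1 control, -1 sleep-restricted, matching
#'   the GLM coding); both classes must be present.
#' @param rounds boosting rounds (>= 1).
#' @param depth base-learner tree depth (1 = stumps).
#' @return a \code{logitboost_model}; predict with
#'   \code{\link{predict.logitboost_model}}.
#' @export
train_boosted_trees <- function(X, y, rounds = 100L, depth = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y), rounds >= 1L, depth >= 1L)
  if (!all(y %in% c(-1, 1))) stop("labels must be coded -1 / +1")
  if (length(unique(y)) < 2L)
    stop("both classes must be present in the training labels")
  n <- nrow(X)
  ystar <- (y + 1) / 2
  Fscore <- rep(0, n)
  p <- rep(0.5, n)
  learners <- vector("list", rounds)
  colnames(X) <- colnames(X) %||% sprintf("f%d", seq_len(ncol(X)))
  ps <- if (depth == 1L) presort_features(X) else NULL
  for (m in seq_len(rounds)) {
    w <- pmax(p * (1 - p), 2e-8)
    z <- pmin(pmax((ystar - p) / w, -4), 4)
    if (depth == 1L) {
      learner <- fit_stump(ps, z, w)
      fhat <- predict_stump(learner, X)
    } else {
      df <- data.frame(z = z, X, check.names = FALSE)
      learner <- rpart::rpart(
        z ~ ., data = df, weights = w, method = "anova",
        control = rpart::rpart.control(maxdepth = depth, cp = 0,
                                       minsplit = 2, minbucket = 1,
                                       xval = 0, maxcompete = 0,
                                       maxsurrogate = 0))
      fhat <- unname(stats::predict(learner, df))
    }
    learners[[m]] <- learner
    Fscore <- Fscore + 0.5 * fhat
    p <- 1 / (1 + exp(-2 * Fscore))
  }
  structure(list(learners = learners, depth = depth, rounds = rounds,
                 majority = if (sum(y == 1) >= sum(y == -1)) 1 else -1,
                 features = colnames(X)),
            class = "logitboost_model")
}

#' Predict with a logit-boost ensemble
#'
#' @param object a \code{logitboost_model}.
#' @param newdata numeric matrix with the training feature columns.
#' @param type \code{"class"} for -1/+1 labels (an exactly zero additive
#'   score falls back to the majority training class), \code{"score"} for
#'   the additive score F.
#' @param ... unused.
#' @return numeric vector of labels or scores.
#' @export
predict.logitboost_model <- function(object, newdata, type = c("class", "score"),
                                     ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(newdata))
  if (is.null(colnames(newdata))) colnames(newdata) <- object$features
  newdata <- newdata[, object$features, drop = FALSE]
  Fscore <- rep(0, nrow(newdata))
  for (learner in object$learners) {
    fhat <- if (object$depth == 1L) predict_stump(learner, newdata)
    else unname(stats::predict(learner,
                               as.data.frame(newdata, check.names = FALSE)))
    Fscore <- Fscore + 0.5 * fhat
  }
  if (type == "score") return(Fscore)
  out <- sign(Fscore)
  out[out == 0] <- object$majority
  out
}

#' Exact binomial tail probability for a classification error count
#'
#' The chance probability of making at most \code{errors} mistakes out of
#' \code{n} coin-flip classifications:
#' \eqn{P(X \le E)}, \eqn{X \sim \mathrm{Binomial}(n, \mathrm{chance})},
#' computed by exact summation of the probability mass function on the log
#' scale (no normal approximation).
#'
#' @param errors observed number of errors (0..n).
#' @param n number of attempts.
#' @param chance per-attempt error probability under the null (default
#'   0.5).
#' @return the exact cumulative probability.
#' @export
binomial_significance <- function(errors, n, chance = 0.5) {
  stopifnot(length(errors) == 1L, length(n) == 1L,
            errors == round(errors), n == round(n))
  if (errors < 0 || errors > n) stop("errors must lie in 0..n")
  if (chance <= 0 || chance >= 1) stop("chance must lie strictly in (0, 1)")
  k <- 0:errors
  sum(exp(lchoose(n, k) + k * log(chance) + (n - k) * log1p(-chance)))
}

#' Leave-one-out classification of animals
#'
#' Each animal in turn is held out; the injection-geometry signal is
#' removed by \code{\link{residualize_covariates}} fitted on the remaining
#' animals only (no leakage; set \code{residualize_once = TRUE} for the
#' fit-on-everyone variant), features are optionally compacted by summing
#' regions within each cluster of a partition scale, a logit-boost
#' ensemble is trained on the remaining animals, and the held-out animal
#' is classified. Performance is the ability to classify all animals this
#' way; its chance significance is the exact binomial tail probability of
#' the error count at probability one half.
#'
#' @param cohort a \code{cohort_table} at stage \code{"unit_mean"} with at
#'   least 4 animals and both conditions represented at least twice.
#' @param hierarchy optional \code{partition_hierarchy} from
#'   \code{\link{markov_stability_scan}}; \code{NULL} classifies the raw
#'   residualized regions.
#' @param rounds,depth boosting hyperparameters (defaults 100 stump
#'   rounds).
#' @param scale_policy with a hierarchy: \code{"inner"} picks the scale by
#'   nested leave-one-out within each training fold (default, unbiased);
#'   \code{"fixed"} uses scale \code{fixed_scale}; \code{"per-scale"}
#'   reports every scale's accuracy and takes the best as the headline (an
#'   optimistic reading, flagged in the report).
#' @param fixed_scale scale index for \code{scale_policy = "fixed"}.
#' @param residualize_once fit the covariate residualization once on all
#'   animals instead of per fold.
#' @return a \code{classification_report}: per-animal table (true and
#'   predicted labels, scale used), \code{errors}, \code{n_animals},
#'   \code{accuracy}, \code{accuracy_pct} (nearest integer percent),
#'   \code{binomial_p}, and with a hierarchy a \code{per_scale} accuracy
#'   table.
#' @export
loocv_classify <- function(cohort, hierarchy = NULL, rounds = 100L,
                           depth = 1L,
                           scale_policy = c("inner", "fixed", "per-scale"),
                           fixed_scale = NULL, residualize_once = FALSE) {
  require_stage(cohort, "unit_mean")
  scale_policy <- match.arg(scale_policy)
  n <- nrow(cohort$values)
  y <- cohort$animals$condition
  if (n < 4L || min(table(y)) < 2L)
    stop("need at least 4 animals with both conditions represented at least twice")
  if (is.null(hierarchy)) scale_policy <- "fixed"
  scales <- if (is.null(hierarchy)) list(NULL) else hierarchy
  if (scale_policy == "fixed" && !is.null(hierarchy)) {
    if (is.null(fixed_scale)) stop("scale_policy='fixed' needs fixed_scale")
    scales <- hierarchy[fixed_scale]
  }

  feats_once <- if (residualize_once) residualize_covariates(cohort) else NULL

  fold_features <- function(holdout) {
    base <- if (residualize_once) feats_once
            else residualize_covariates(cohort, fit_animals = setdiff(seq_len(n), holdout))
    lapply(scales, function(sc) {
      if (is.null(sc)) base else merge_by_partition(base, sc$labels)
    })
  }

  predict_fold <- function(feats, holdout) {
    tr <- setdiff(seq_len(n), holdout)
    if (length(unique(y[tr])) < 2L)
      stop("training fold for animal '", cohort$animals$animal_id[holdout],
           "' contains a single class")
    model <- train_boosted_trees(feats[tr, , drop = FALSE], y[tr],
                                 rounds = rounds, depth = depth)
    predict(model, feats[holdout, , drop = FALSE])
  }

  per_scale_pred <- matrix(NA_real_, n, length(scales))
  for (a in seq_len(n)) {
    fl <- fold_features(a)
    for (s in seq_along(scales))
      per_scale_pred[a, s] <- predict_fold(fl[[s]], a)
  }
  per_scale_err <- colSums(per_scale_pred != y)

  if (scale_policy == "inner" && length(scales) > 1L) {
    # nested LOO within each training fold to pick that fold's scale
    chosen <- integer(n)
    pred <- numeric(n)
    for (a in seq_len(n)) {
      tr <- setdiff(seq_len(n), a)
      inner_err <- numeric(length(scales))
      fl_outer <- fold_features(a)
      for (b in tr) {
        fl <- fold_features(c(a, b))  # residualize without both held-out animals
        for (s in seq_along(scales)) {
          trin <- setdiff(tr, b)
          if (length(unique(y[trin])) < 2L) next
          m <- train_boosted_trees(fl[[s]][trin, , drop = FALSE], y[trin],
                                   rounds = rounds, depth = depth)
          if (predict(m, fl[[s]][b, , drop = FALSE]) != y[b])
            inner_err[s] <- inner_err[s] + 1
        }
      }
      chosen[a] <- which.min(inner_err)  # first minimum: deterministic
      pred[a] <- predict_fold(fl_outer[[chosen[a]]], a)
    }
    scale_used <- chosen
  } else if (scale_policy == "per-scale") {
    best_s <- which.min(per_scale_err)
    pred <- per_scale_pred[, best_s]
    scale_used <- rep(best_s, n)
  } else {
    pred <- per_scale_pred[, 1L]
    scale_used <- rep(if (is.null(hierarchy)) NA_integer_
                      else if (is.null(fixed_scale)) 1L else fixed_scale, n)
  }

  E <- sum(pred != y)
  report <- structure(
    list(predictions = data.frame(
           animal_id = cohort$animals$animal_id,
           true = y, predicted = pred, scale = scale_used,
           stringsAsFactors = FALSE),
         errors = E, n_animals = n,
         accuracy = (n - E) / n,
         accuracy_pct = round(100 * (n - E) / n),
         binomial_p = binomial_significance(E, n, 0.5),
         scale_policy = if (is.null(hierarchy)) "none" else scale_policy,
         rounds = rounds, depth = depth),
    class = "classification_report")
  if (!is.null(hierarchy)) {
    report$per_scale <- data.frame(
      scale = seq_along(scales),
      time = vapply(scales, function(s) s$time, numeric(1)),
      n_clusters = vapply(scales, function(s) s$n_clusters, numeric(1)),
      errors = per_scale_err,
      accuracy = (n - per_scale_err) / n)
  }
  report
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(paste0("<classification_report> %d animals, %d errors: ",
                     "accuracy %.3f (%d%%), binomial p = %.4g\n"),
              x$n_animals, x$errors, x$accuracy, x$accuracy_pct,
              x$binomial_p))
  cat("  scale policy:", x$scale_policy, "\n")
  invisible(x)
}
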