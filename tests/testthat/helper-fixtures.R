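# Builders for small hand-made cohorts and independent numerical oracles.

toy_regions <- function(p, categories = "Isocortex") {
  data.frame(region_id = seq_len(p),
             abbreviation = sprintf("RG%02d", seq_len(p)),
             name = sprintf("Region %d", seq_len(p)),
             category = rep(categories, length.out = p),
             stringsAsFactors = FALSE)
}

# fixed irregular centroid values (recycled): realistic spreads, and no
# affine relation between the three axes, so GLM designs stay full rank
ML_BASE <- c(712, 845, 780, 921, 698, 803, 888, 756, 934, 819, 771, 902, 741, 866)
AP_BASE <- c(1523, 1888, 1610, 1745, 1950, 1581, 1696, 1832, 1570, 1915, 1655, 1780, 1990, 1540)
DV_BASE <- c(598, 663, 612, 641, 588, 672, 605, 650, 627, 591, 668, 619, 645, 600)

toy_animals <- function(n,
                        condition = rep(c(1, -1), length.out = n),
                        sex = rep(c("M", "F"), length.out = n),
                        injection_volume = seq(1, 2, length.out = n),
                        ml_um = rep(ML_BASE, length.out = n),
                        ap_um = rep(AP_BASE, length.out = n),
                        dv_um = rep(DV_BASE, length.out = n)) {
  data.frame(animal_id = sprintf("A%02d", seq_len(n)),
             condition = condition, sex = sex,
             injection_volume = injection_volume,
             ml_um = ml_um, ap_um = ap_um, dv_um = dv_um,
             stringsAsFactors = FALSE)
}

toy_cohort <- function(values, stage = "raw", animals = NULL, regions = NULL,
                       ...) {
  values <- as.matrix(values)
  if (is.null(animals)) animals <- toy_animals(nrow(values), ...)
  if (is.null(regions)) regions <- toy_regions(ncol(values))
  rownames(values) <- animals$animal_id
  colnames(values) <- regions$abbreviation
  cohort_table(values, animals, regions, stage = stage)
}

# canonical preprocessing chain used all over the tests
prep_chain <- function(cohort, n = NULL) {
  thr <- threshold_regions(cohort)
  if (is.null(n)) n <- fit_volume_exponent(thr$cohort)$exponent
  unit_mean_normalize(normalize_by_volume(thr$cohort, n))
}

# --- independent oracles -------------------------------------------------

# textbook Pearson correlation (no stats::cor)
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx) ^ 2) * sum((y - my) ^ 2))
}

# all set partitions of n elements as restricted growth strings
enum_partitions <- function(n) {
  out <- list()
  rec <- function(labs, mx) {
    if (length(labs) == n) { out[[length(out) + 1L]] <<- labs; return() }
    for (v in seq_len(mx + 1L)) rec(c(labs, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# Markov stability quality matrix by an independent route: truncated
# series for the matrix exponential with scaling and squaring, applied to
# the random-walk Laplacian directly (the package uses a symmetrized
# eigendecomposition instead).
oracle_stability_matrix <- function(W, t) {
  d <- rowSums(W)
  stopifnot(all(d > 0))
  n <- nrow(W)
  L <- diag(n) - W / d
  s <- max(0L, ceiling(log2(max(t * max(abs(L)), 1))) + 4L)
  A <- -t * L / 2 ^ s
  E <- diag(n); term <- diag(n)
  for (k in 1:30) {
    term <- term %*% A / k
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  pi_ <- d / sum(d)
  diag(pi_) %*% E - outer(pi_, pi_)
}

oracle_partition_score <- function(M, labels) {
  sum(vapply(split(seq_along(labels), labels),
             function(idx) sum(M[idx, idx]), numeric(1)))
}

# random small test graph with weights in [0, 1]
random_toy_graph <- function(n, p_edge = 0.6) {
  W <- matrix(0, n, n)
  m <- n * (n - 1) / 2
  w <- ifelse(stats::runif(m) < p_edge, round(stats::runif(m), 2), 0)
  W[upper.tri(W)] <- w
  W <- W + t(W)
  # ensure no zero-degree node so the oracle's random-walk matrix exists
  for (i in which(rowSums(W) == 0)) {
    j <- if (i == 1L) 2L else 1L
    W[i, j] <- W[j, i] <- 0.5
  }
  as_correlation_graph(W)
}
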