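#' Region-region correlation graph
#'
#' Pearson correlations between region columns, computed across animals,
#' thresholded at zero (negative correlations dropped — a positive-only
#' similarity graph) and with the diagonal zeroed.
#'
#' @param features numeric matrix, animals x regions, at least 3 rows.
#' @return a \code{correlation_graph}: node names and the symmetric
#'   non-negative weight matrix with zero diagonal.
#' @export
region_correlation_graph <- function(features) {
  stopifnot(is.matrix(features), is.numeric(features))
  if (nrow(features) < 3L) stop("need at least 3 animals")
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("V%d", seq_len(ncol(features)))
  sds <- apply(features, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region column(s): ",
         paste(colnames(features)[sds == 0], collapse = ", "))
  W <- stats::cor(features)
  W[W < 0] <- 0
  W[W > 1] <- 1  # guard rounding just above 1
  diag(W) <- 0
  structure(list(nodes = colnames(features), W = W),
            class = "correlation_graph")
}

#' Make a correlation graph from an explicit weight matrix
#'
#' For toy and test graphs. Checks symmetry, the \code{[0, 1]} weight range
#' and the zero diagonal.
#'
#' @param W symmetric non-negative matrix, entries in \code{[0, 1]}, zero
#'   diagonal.
#' @param nodes optional node names.
#' @return a \code{correlation_graph}.
#' @export
as_correlation_graph <- function(W, nodes = NULL) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (any(!is.finite(W))) stop("non-finite weights")
  if (max(abs(W - t(W))) > 1e-12) stop("weight matrix must be symmetric")
  if (any(W < 0) || any(W > 1)) stop("weights must lie in [0, 1]")
  if (any(diag(W) != 0)) stop("diagonal must be zero")
  if (is.null(nodes)) nodes <- if (!is.null(rownames(W))) rownames(W)
                               else sprintf("n%d", seq_len(nrow(W)))
  dimnames(W) <- list(nodes, nodes)
  structure(list(nodes = nodes, W = W), class = "correlation_graph")
}

# Quality matrix of continuous-time Markov stability at time t, for the
# positive-degree nodes of the graph:
#   M(t) = Pi expm(-t L_rw) - pi pi',  L_rw = I - D^{-1} W,  pi = d / sum(d).
# Computed exactly through the eigendecomposition of the symmetrized
# Laplacian L_sym = D^{-1/2}(D - W)D^{-1/2}:
#   Pi expm(-t L_rw) = (1/sum d) D^{1/2} V exp(-t Lambda) V' D^{1/2},
# which is symmetric. The eigendecomposition is t-independent, so one
# factorization serves a whole time grid.
stability_eigen <- function(W) {
  d <- rowSums(W)
  active <- which(d > 0)
  if (length(active) == 0L)
    stop("graph has no edges; stability is undefined")
  Wa <- W[active, active, drop = FALSE]
  da <- d[active]
  isq <- 1 / sqrt(da)
  Lsym <- diag(length(active)) - (isq * Wa) * rep(isq, each = length(active))
  eig <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  list(values = eig$values, vectors = eig$vectors,
       d = da, total = sum(d), active = active, n = nrow(W))
}

stability_quality_matrix <- function(se, t) {
  E <- se$vectors %*% (exp(-t * se$values) * t(se$vectors))
  sq <- sqrt(se$d)
  M_active <- (sq * E * rep(sq, each = length(sq))) / se$total -
    tcrossprod(se$d / se$total)
  M_active <- (M_active + t(M_active)) / 2
  # zero-degree nodes contribute nothing and are permanent singletons
  M <- matrix(0, se$n, se$n)
  M[se$active, se$active] <- M_active
  M
}

#' Markov stability of a given partition
#'
#' The stability of a partition at Markov time \code{t} is the summed
#' autocovariance of a continuous-time random walk over the within-cluster
#' blocks:
#' \deqn{r(t, H) = \sum_{C} \sum_{i, j \in C}
#'   \big[ (\Pi e^{-tL})_{ij} - \pi_i \pi_j \big]}
#' with \eqn{L = I - D^{-1}W} the random-walk Laplacian and
#' \eqn{\pi = d / \sum d} the degree-proportional stationary distribution.
#' The all-in-one-cluster partition scores exactly 0 at every time.
#'
#' @param graph a \code{correlation_graph}.
#' @param labels integer cluster label per node.
#' @param t Markov time (> 0).
#' @return the stability score.
#' @export
partition_stability <- function(graph, labels, t) {
  stopifnot(inherits(graph, "correlation_graph"),
            length(labels) == length(graph$nodes), t > 0)
  M <- stability_quality_matrix(stability_eigen(graph$W), t)
  sum(vapply(split(seq_along(labels), labels),
             function(idx) sum(M[idx, idx]), numeric(1)))
}

# One Louvain-style greedy maximization of sum_{same cluster} B_ij on a
# dense symmetric quality matrix: local node moves to the best-gaining
# cluster, then aggregation, repeated until no move improves. Diagonal
# terms ride along with their node and cancel out of every gain.
louvain_dense <- function(B, order_nodes) {
  n <- nrow(B)
  labels <- seq_len(n)

  move_pass <- function(B, labels, ord) {
    improved <- FALSE
    repeat {
      moved_any <- FALSE
      for (i in ord) {
        li <- labels[i]
        totals <- rowsum_vec(B[i, ], labels)       # sum of B[i, j] per cluster
        stay <- totals[[as.character(li)]] - B[i, i]
        gains <- vapply(totals, identity, numeric(1)) - stay
        gains[[as.character(li)]] <- 0
        best <- names(gains)[which.max(gains)]
        if (gains[[best]] > 1e-13 && best != as.character(li)) {
          labels[i] <- as.integer(best)
          moved_any <- TRUE
          improved <- TRUE
        }
      }
      if (!moved_any) break
    }
    list(labels = labels, improved = improved)
  }

  # multilevel loop
  node_of <- seq_len(n)  # current supernode of each original node
  Bcur <- B
  repeat {
    ncur <- nrow(Bcur)
    ord <- order_nodes(ncur)
    res <- move_pass(Bcur, seq_len(ncur), ord)
    labs <- canonical_labels(res$labels)
    if (!res$improved || max(labs) == ncur) {
      node_of <- labs[node_of]
      break
    }
    node_of <- labs[node_of]
    # aggregate
    ind <- matrix(0, ncur, max(labs))
    ind[cbind(seq_len(ncur), labs)] <- 1
    Bcur <- t(ind) %*% Bcur %*% ind
    if (nrow(Bcur) == 1L) break
  }
  canonical_labels(node_of)
}

rowsum_vec <- function(x, groups) {
  s <- rowsum(x, groups)
  stats::setNames(as.list(s[, 1L]), rownames(s))
}

# Relabel clusters 1, 2, ... in order of first appearance.
canonical_labels <- function(labels) {
  u <- unique(labels)
  match(labels, u)
}

partition_score_matrix <- function(M, labels) {
  sum(vapply(split(seq_along(labels), labels),
             function(idx) sum(M[idx, idx]), numeric(1)))
}

#' Multiscale community detection by Markov stability
#'
#' Scans a grid of Markov times; at each time the partition maximizing
#' continuous-time Markov stability (see
#' \code{\link{partition_stability}}) is sought by Louvain-style greedy
#' optimization restarted from \code{n_restarts} random node orders. Small
#' times resolve fine partitions (all singletons in the limit), large times
#' coarse ones. The matrix exponential is computed exactly from one
#' eigendecomposition of the symmetrized Laplacian, reused across the whole
#' time grid. Ties between equally stable partitions are broken towards
#' fewer clusters, then lexicographically smaller canonical labels.
#' Zero-degree nodes remain singletons at every scale. Disconnected graphs
#' are handled blockwise by the same algebra.
#'
#' @param graph a \code{correlation_graph}.
#' @param times ascending grid of Markov times; default 20 points
#'   log-spaced on \code{[1e-2, 1e2]}.
#' @param n_restarts random restarts of the greedy optimizer per time.
#' @param seed integer seed; the scan is deterministic given
#'   (graph, times, n_restarts, seed).
#' @return a \code{partition_hierarchy}: list of scales, each with
#'   \code{time}, \code{labels} (named integer vector over all nodes),
#'   \code{n_clusters}, \code{stability}.
#' @export
markov_stability_scan <- function(graph,
                                  times = 10 ^ seq(-2, 2, length.out = 20),
                                  n_restarts = 20L, seed = 1L) {
  stopifnot(inherits(graph, "correlation_graph"))
  if (length(times) == 0L || any(times <= 0)) stop("times must be positive")
  if (is.unsorted(times)) stop("times must be sorted ascending")
  se <- stability_eigen(graph$W)
  n <- length(graph$nodes)

  scales <- with_seed(seed, lapply(times, function(t) {
    M <- stability_quality_matrix(se, t)
    best <- NULL
    for (r in seq_len(n_restarts)) {
      perm <- sample.int(n)
      labs <- louvain_dense(M, function(m) {
        if (m == n) perm else sample.int(m)
      })
      cand <- list(labels = labs,
                   score = partition_score_matrix(M, labs),
                   k = max(labs))
      if (is.null(best) || better_partition(cand, best)) best <- cand
    }
    # zero-degree nodes forced to their own singleton clusters
    if (length(se$active) < n) {
      iso <- setdiff(seq_len(n), se$active)
      labs <- best$labels
      labs[iso] <- max(labs) + seq_along(iso)
      best$labels <- canonical_labels(labs)
      best$k <- max(best$labels)
      best$score <- partition_score_matrix(M, best$labels)
    }
    list(time = t,
         labels = stats::setNames(best$labels, graph$nodes),
         n_clusters = best$k,
         stability = best$score)
  }))
  structure(scales, class = "partition_hierarchy")
}

better_partition <- function(cand, best, tol = 1e-12) {
  if (cand$score > best$score + tol) return(TRUE)
  if (cand$score < best$score - tol) return(FALSE)
  if (cand$k != best$k) return(cand$k < best$k)
  # lexicographic canonical labels
  d <- cand$labels - best$labels
  nz <- which(d != 0)
  length(nz) > 0L && d[nz[1L]] < 0
}

#' @export
print.partition_hierarchy <- function(x, ...) {
  cat("<partition_hierarchy> ", length(x), " scales\n", sep = "")
  for (s in x)
    cat(sprintf("  t = %-10.4g clusters = %-4d stability = %.6g\n",
                s$time, s$n_clusters, s$stability))
  invisible(x)
}

#' Merge feature columns by a partition
#'
#' Each output column is the per-animal sum of the input columns assigned
#' to that cluster, so the total per-animal projection is conserved
#' exactly.
#'
#' @param features numeric matrix, animals x regions, with column names.
#' @param partition named integer vector mapping every feature column to a
#'   cluster id (e.g. one scale's \code{labels} from
#'   \code{\link{markov_stability_scan}}).
#' @return animals x clusters matrix; columns named
#'   \code{cluster<k>} in ascending cluster id.
#' @export
merge_by_partition <- function(features, partition) {
  stopifnot(is.matrix(features))
  if (is.null(names(partition)))
    stop("partition must be named by region")
  unknown <- setdiff(names(partition), colnames(features))
  if (length(unknown) > 0L)
    stop("partition labels unknown region(s): ", paste(unknown, collapse = ", "))
  uncovered <- setdiff(colnames(features), names(partition))
  if (length(uncovered) > 0L)
    stop("partition does not cover region(s): ",
         paste(uncovered, collapse = ", "))
  lab <- partition[colnames(features)]
  ids <- sort(unique(lab))
  ind <- matrix(0, ncol(features), length(ids))
  ind[cbind(seq_along(lab), match(lab, ids))] <- 1
  out <- features %*% ind
  colnames(out) <- paste0("cluster", ids)
  rownames(out) <- rownames(features)
  out
}
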