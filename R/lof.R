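#' Local Outlier Factor scoring
#'
#' A from-scratch Local Outlier Factor (LOF) implementation built on exact
#' (full pairwise) neighbor search. LOF compares the local density of a
#' point with the local densities of its k-distance neighbors: scores near 1
#' indicate a point embedded in a region of comparable density, scores well
#' above 1 indicate an outlier. Two modes are provided:
#'
#' * *fit mode* — each reference point is scored against the other
#'   references (leave-self-out), used for threshold calibration and for
#'   symmetry diagnostics;
#' * *novelty mode* — external query points are scored against a fixed
#'   reference population and never join it, which is how embedded test
#'   B-scans are classified against the normal-image reference set.
#'
#' Ties: the k-distance neighborhood contains every reference at distance
#' `<=` the k-distance, so its size can exceed `k`. Duplicates: when all
#' reachability distances from a point are zero its local reachability
#' density is the `+Inf` sentinel, with ratio conventions `Inf/Inf = 1` and
#' `finite/Inf = 0`.
#'
#' @name lof
NULL

#' LOF parameters
#'
#' @param k neighborhood size (default 20); must be smaller than the
#'   reference set.
#' @param threshold decision threshold `tau` for the NORMAL/AMD call:
#'   `"auto"` calibrates it as the `quantile` of fit-mode (leave-self-out)
#'   LOF scores of the reference set; a positive number fixes it.
#' @param quantile calibration quantile used when `threshold = "auto"`.
#' @param metric `"euclidean"` (default) or `"cosine"`. On the alpha-sphere
#'   that embedding features live on, the two induce the same neighbor
#'   ranking.
#' @return a `lof_params` list.
#' @export
lof_params <- function(k = 20, threshold = "auto", quantile = 0.99,
                       metric = c("euclidean", "cosine")) {
  assert_positive_int(k, "k")
  metric <- match.arg(metric)
  if (is.character(threshold)) {
    if (!identical(threshold, "auto")) abort('`threshold` must be "auto" or a positive number')
  } else if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    abort('`threshold` must be "auto" or a positive number')
  }
  if (quantile <= 0 || quantile > 1) abort("`quantile` must lie in (0, 1]")
  structure(list(k = as.integer(k), threshold = threshold,
                 quantile = quantile, metric = metric),
            class = "lof_params")
}

as_ref_matrix <- function(refs) {
  m <- as.matrix(refs)
  if (!is.numeric(m) || any(!is.finite(m))) {
    abort("reference set must be a finite numeric matrix")
  }
  m
}

dist_fun <- function(metric) {
  switch(metric,
    euclidean = function(q, refs) sqrt(colSums((t(refs) - q)^2)),
    cosine = function(q, refs) {
      qn <- sqrt(sum(q^2)); rn <- sqrt(rowSums(refs^2))
      1 - as.vector(refs %*% q) / (qn * rn)
    })
}

# Pairwise reference distances; diagonal set to Inf so a point is never its
# own neighbor.
ref_dist_matrix <- function(refs, metric = "euclidean") {
  n <- nrow(refs)
  df <- dist_fun(metric)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) D[i, ] <- df(refs[i, ], refs)
  D[D < 0] <- 0
  diag(D) <- Inf
  D
}

#' k-distance of a query point
#'
#' Distance from `o` to its k-th nearest neighbor among the reference
#' points. The query is never its own candidate neighbor.
#'
#' @param o numeric query vector.
#' @param refs reference matrix (rows are points).
#' @param k neighborhood size, `k < nrow(refs)` in fit mode and
#'   `k <= nrow(refs)` for an external query.
#' @param metric distance metric.
#' @return the k-distance, a single number.
#' @export
#' @examples
#' refs <- cbind(c(1, 2, 3))
#' k_distance(0, refs, k = 2) # 2
k_distance <- function(o, refs, k, metric = "euclidean") {
  refs <- as_ref_matrix(refs)
  if (k > nrow(refs)) {
    abort(sprintf("k = %d but only %d candidate neighbors are available", k, nrow(refs)))
  }
  d <- sort(dist_fun(metric)(as.numeric(o), refs))
  d[k]
}

#' k-distance neighborhood
#'
#' Indices of all reference points at distance `<=` the k-distance of `o`;
#' size is at least `k`, strictly larger only under distance ties.
#'
#' @inheritParams k_distance
#' @return integer vector of reference row indices.
#' @export
k_neighborhood <- function(o, refs, k, metric = "euclidean") {
  refs <- as_ref_matrix(refs)
  d <- dist_fun(metric)(as.numeric(o), refs)
  kd <- k_distance(o, refs, k, metric)
  which(d <= kd)
}

#' Reachability distance of p with respect to o
#'
#' `max(k_distance(o), d(p, o))`: the true distance, floored at o's
#' k-distance so that the density estimate around dense points is smoothed.
#' Asymmetric in general.
#'
#' @param p,o numeric vectors; `o` should be a reference point.
#' @inheritParams k_distance
#' @return a single number, `>= d(p, o)`.
#' @export
reach_dist <- function(p, o, refs, k, metric = "euclidean") {
  refs <- as_ref_matrix(refs)
  df <- dist_fun(metric)
  d_po <- df(as.numeric(p), matrix(as.numeric(o), nrow = 1))
  # o's own k-distance is leave-self-out: drop one exact copy of o from the
  # candidate neighbors if present
  d_o <- df(as.numeric(o), refs)
  self <- which(d_o == 0)
  cand <- if (length(self) > 0) refs[-self[1], , drop = FALSE] else refs
  max(k_distance(o, cand, k, metric), d_po)
}

# Internal core: all LOF quantities for the reference set (fit mode) from a
# precomputed distance matrix with Inf diagonal.
lof_fit_core <- function(D, k) {
  n <- nrow(D)
  if (k >= n) abort(sprintf("k = %d requires a reference set of more than k points (n = %d)", k, n))
  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    kdist[i] <- sort(d)[k]
    nbrs[[i]] <- which(d <= kdist[i])
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    rd <- pmax(kdist[nbrs[[i]]], D[i, nbrs[[i]]])
    m <- mean(rd)
    lrd[i] <- if (m == 0) Inf else 1 / m
  }
  lof <- numeric(n)
  for (i in seq_len(n)) {
    r <- lrd[nbrs[[i]]] / lrd[i]
    r[is.infinite(lrd[nbrs[[i]]]) & is.infinite(lrd[i])] <- 1
    lof[i] <- mean(r)
  }
  list(kdist = kdist, neighborhoods = nbrs, lrd = lrd, lof = lof)
}

#' Local reachability density
#'
#' Inverse of the mean reachability distance from `p` to its k-distance
#' neighborhood. Returns `Inf` when all reachability distances are zero
#' (`p` duplicated at least `k` times among the references).
#'
#' @inheritParams k_distance
#' @param p numeric query vector (scored in novelty mode: `p` does not join
#'   the references).
#' @return a positive number or `Inf`.
#' @export
lrd <- function(p, refs, k, metric = "euclidean") {
  refs <- as_ref_matrix(refs)
  fit <- lof_fit_core(ref_dist_matrix(refs, metric), k)
  d <- dist_fun(metric)(as.numeric(p), refs)
  d[d < 0] <- 0
  kd <- sort(d)[k]
  nb <- which(d <= kd)
  m <- mean(pmax(fit$kdist[nb], d[nb]))
  if (m == 0) Inf else 1 / m
}

#' LOF score of a query point (novelty mode)
#'
#' Mean over `p`'s k-distance neighborhood of the ratio of each neighbor's
#' local reachability density to `p`'s own.
#'
#' @inheritParams lrd
#' @return a positive number; about 1 for inliers, well above 1 for
#'   outliers.
#' @export
#' @examples
#' square <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
#' lof_score(c(5, 5), square, k = 2) # about 6.154
lof_score <- function(p, refs, k, metric = "euclidean") {
  score_queries(matrix(as.numeric(p), nrow = 1), refs,
                lof_params(k = k, threshold = 1.5, metric = metric))$lof_score
}

#' Fit-mode LOF scores of a reference set
#'
#' Scores every reference point against the others (leave-self-out). Used
#' for threshold calibration and for symmetry diagnostics.
#'
#' @param refs reference matrix.
#' @param k neighborhood size (`k < nrow(refs)`).
#' @param metric distance metric.
#' @return tibble with `row`, `lof_score`, `lrd`, `k_distance`.
#' @export
lof_fit <- function(refs, k = 20, metric = "euclidean") {
  refs <- as_ref_matrix(refs)
  fit <- lof_fit_core(ref_dist_matrix(refs, metric), k)
  tibble(row = seq_len(nrow(refs)), lof_score = fit$lof,
         lrd = fit$lrd, k_distance = fit$kdist)
}

#' Calibrate the LOF decision threshold
#'
#' The threshold `tau` is the `quantile` of the fit-mode LOF scores of the
#' reference set: a query scoring above what all but the most extreme
#' references score is called abnormal.
#'
#' @inheritParams lof_fit
#' @param quantile calibration quantile.
#' @return the threshold, a single number.
#' @export
calibrate_threshold <- function(refs, k = 20, quantile = 0.99,
                                metric = "euclidean") {
  scores <- lof_fit(refs, k, metric)$lof_score
  finite <- scores[is.finite(scores)]
  if (length(finite) == 0) abort("all reference LOF scores are degenerate")
  unname(stats::quantile(finite, quantile))
}

#' Score query points against a reference set (novelty mode)
#'
#' Each query is scored independently against the fixed reference set
#' (queries never join the references and never see each other), so the
#' batch result is independent of query order. Decisions are `AMD` when the
#' LOF score strictly exceeds the threshold, `NORMAL` otherwise.
#'
#' @param queries numeric matrix of query points (rows), same number of
#'   columns as `refs`.
#' @param refs reference matrix.
#' @param params a [lof_params()].
#' @return tibble with one row per query: `query`, `lof_score`, `decision`,
#'   `neighborhood_size`, plus the threshold used as attribute
#'   `"threshold"`.
#' @export
score_queries <- function(queries, refs, params = lof_params()) {
  refs <- as_ref_matrix(refs)
  queries <- as.matrix(queries)
  if (nrow(queries) == 0) {
    out <- tibble(query = integer(), lof_score = numeric(),
                  decision = character(), neighborhood_size = integer())
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  if (ncol(queries) != ncol(refs)) {
    abort(sprintf("query dimension (%d) does not match reference dimension (%d)",
                  ncol(queries), ncol(refs)))
  }
  k <- params$k
  if (k > nrow(refs)) {
    abort(sprintf("k = %d but the reference set has only %d points", k, nrow(refs)))
  }
  fit <- lof_fit_core(ref_dist_matrix(refs, params$metric), k)
  tau <- if (identical(params$threshold, "auto")) {
    calibrate_threshold(refs, k, params$quantile, params$metric)
  } else params$threshold
  df <- dist_fun(params$metric)
  n_q <- nrow(queries)
  scores <- numeric(n_q); nsize <- integer(n_q)
  for (i in seq_len(n_q)) {
    d <- df(queries[i, ], refs)
    d[d < 0] <- 0
    kd <- sort(d)[k]
    nb <- which(d <= kd)
    m <- mean(pmax(fit$kdist[nb], d[nb]))
    lrd_q <- if (m == 0) Inf else 1 / m
    r <- fit$lrd[nb] / lrd_q
    r[is.infinite(fit$lrd[nb]) & is.infinite(lrd_q)] <- 1
    scores[i] <- mean(r)
    nsize[i] <- length(nb)
  }
  out <- tibble(query = seq_len(n_q), lof_score = scores,
                decision = ifelse(scores > tau, "AMD", "NORMAL"),
                neighborhood_size = nsize)
  attr(out, "threshold") <- tau
  out
}
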