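# Independent brute-force oracles, written naively (explicit loops, no code
# shared with the package implementation).

euclid <- function(a, b) sqrt(sum((a - b)^2))

# Every LOF intermediate for the reference set, fit mode (leave-self-out),
# by exhaustive enumeration.
oracle_lof_fit <- function(refs, k) {
  n <- nrow(refs)
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) D[i, j] <- euclid(refs[i, ], refs[j, ])
  kdist <- numeric(n); nbrs <- vector("list", n)
  for (i in 1:n) {
    others <- setdiff(1:n, i)
    ds <- sort(D[i, others])
    kdist[i] <- ds[k]
    nbrs[[i]] <- others[D[i, others] <= kdist[i]]
  }
  lrd <- numeric(n)
  for (i in 1:n) {
    tot <- 0
    for (o in nbrs[[i]]) tot <- tot + max(kdist[o], D[i, o])
    m <- tot / length(nbrs[[i]])
    lrd[i] <- if (m == 0) Inf else 1 / m
  }
  lof <- numeric(n)
  for (i in 1:n) {
    s <- 0
    for (o in nbrs[[i]]) {
      r <- if (is.infinite(lrd[o]) && is.infinite(lrd[i])) 1 else lrd[o] / lrd[i]
      s <- s + r
    }
    lof[i] <- s / length(nbrs[[i]])
  }
  list(kdist = kdist, nbrs = nbrs, lrd = lrd, lof = lof)
}

# Novelty-mode LOF of one external query against the reference set.
oracle_lof_query <- function(q, refs, k) {
  n <- nrow(refs)
  fit <- oracle_lof_fit(refs, k)
  d <- numeric(n)
  for (j in 1:n) d[j] <- euclid(q, refs[j, ])
  kd <- sort(d)[k]
  nb <- which(d <= kd)
  tot <- 0
  for (o in nb) tot <- tot + max(fit$kdist[o], d[o])
  m <- tot / length(nb)
  lrd_q <- if (m == 0) Inf else 1 / m
  s <- 0
  for (o in nb) {
    s <- s + if (is.infinite(fit$lrd[o]) && is.infinite(lrd_q)) 1
             else fit$lrd[o] / lrd_q
  }
  list(kdist = kd, nbrs = nb, lrd = lrd_q, lof = s / length(nb))
}

# AUC by all-pairs comparison, half credit for ties.
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == "AMD"]; neg <- scores[truth == "NORMAL"]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Mean absolute difference induced by the multiplicative speckle model,
# simulated directly on a noiseless image.
oracle_speckle_mad <- function(noiseless, sd, seed) {
  set.seed(seed)
  noisy <- pmin(pmax(noiseless * pmax(0, 1 + rnorm(length(noiseless), sd = sd)), 0), 1)
  mean(abs(noisy - noiseless))
}

# Small helper: an easy, quickly generated labeled image set. Lesion
# geometry scales with the canvas so small test canvases stay valid.
make_easy_set <- function(n_normal, n_dry, n_wet, seed, side = 224) {
  sc <- side / 224
  cfg <- synth_config(height = side, width = side, speckle_sd = 0.02,
                      layer_contrast = 0.5,
                      drusen_count = if (side < 150) 2 else 3,
                      drusen_amplitude = max(3, round(14 * sc)),
                      drusen_width = max(3, round(8 * sc)),
                      fluid_depth = max(5, round(30 * sc)),
                      fluid_width = max(20, round(90 * sc)),
                      tilt_jitter = 6 * sc, seed = seed)
  generate_dataset(cfg, n_normal, n_dry, n_wet, seed = seed)
}
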