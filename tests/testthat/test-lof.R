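unit_square <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))

test_that("k-distance and neighborhood match geometry on hand-solved cases", {
  line <- cbind(c(1, 2, 3))
  expect_equal(k_distance(0, line, k = 2), 2)

  # corner query against the other three corners: ties at distance 1
  refs <- unit_square[-1, ]
  expect_equal(k_distance(unit_square[1, ], refs, k = 2), 1)
  nb <- k_neighborhood(unit_square[1, ], refs, k = 2)
  expect_setequal(nb, c(1, 2))          # the two adjacent corners
  expect_false(3 %in% nb)               # diagonal corner excluded

  # query equidistant to 3 refs: tie inclusion makes |N| = 3 with k = 2
  tri <- rbind(c(1, 0), c(-1, 0), c(0, 1))
  expect_length(k_neighborhood(c(0, 0), tri, k = 2), 3)

  expect_error(k_distance(0, line, k = 5), "available")
})

test_that("reachability distance takes the max of true distance and the neighbor's k-distance", {
  refs <- unit_square
  # far query: true distance dominates
  expect_equal(reach_dist(c(5, 5), c(1, 1), refs, k = 2),
               sqrt(32))
  # near query: smoothing branch returns the k-distance
  expect_equal(reach_dist(c(1.1, 1), c(1, 1), refs, k = 2), 1)
})

test_that("square-corner symmetry gives LOF exactly 1 and the planted query its hand-derived score", {
  fit <- lof_fit(unit_square, k = 2)
  expect_equal(fit$lof_score, rep(1, 4))
  expect_equal(fit$lrd, rep(1, 4))

  expect_equal(lrd(c(5, 5), unit_square, k = 2),
               3 / (sqrt(32) + sqrt(41) + sqrt(41)))
  expect_equal(lof_score(c(5, 5), unit_square, k = 2),
               (sqrt(32) + sqrt(41) + sqrt(41)) / 3)
})

test_that("every intermediate matches the exhaustive oracle on random instances, fit and novelty modes", {
  set.seed(42)
  for (trial in 1:60) {
    n <- sample(8:60, 1); d <- sample(1:5, 1); k <- sample(1:min(10, n - 1), 1)
    refs <- matrix(rnorm(n * d), n, d)
    if (trial %% 4 == 0) {
      # inject duplicates and exact ties
      refs[2, ] <- refs[1, ]
      refs[3, ] <- refs[1, ]
    }
    or <- oracle_lof_fit(refs, k)
    fit <- lof_fit(refs, k)
    expect_equal(fit$k_distance, or$kdist, tolerance = 1e-9)
    expect_equal(fit$lrd, or$lrd, tolerance = 1e-9)
    expect_equal(fit$lof_score, or$lof, tolerance = 1e-9)

    q <- rnorm(d) * 2
    oq <- oracle_lof_query(q, refs, k)
    res <- score_queries(matrix(q, 1), refs, lof_params(k = k, threshold = 1.5))
    expect_equal(res$lof_score, oq$lof, tolerance = 1e-9)
    expect_equal(res$neighborhood_size, length(oq$nbrs))
    expect_equal(lrd(q, refs, k), oq$lrd, tolerance = 1e-9)
    expect_equal(k_distance(q, refs, k), oq$kdist, tolerance = 1e-9)
    expect_setequal(k_neighborhood(q, refs, k), oq$nbrs)
  }
})

test_that("duplicate-heavy inputs hit the +Inf lrd sentinel without breaking scores", {
  refs <- rbind(matrix(1, 4, 2), matrix(rnorm(10), 5, 2))
  expect_equal(lrd(c(1, 1), refs, k = 3), Inf)
  fit <- lof_fit(refs, k = 3)
  expect_equal(fit$lof_score[1:4], rep(1, 4))   # Inf/Inf := 1 among duplicates
  # points whose neighborhoods touch the duplicate cluster may score Inf
  # (neighbor lrd Inf over finite own lrd) but never NaN
  expect_false(any(is.nan(fit$lof_score)))
  expect_equal(fit$lof_score, oracle_lof_fit(refs, 3)$lof)
})

test_that("LOF is invariant under rigid motions and equals 1 on transitive point sets", {
  set.seed(7)
  for (trial in 1:10) {
    n <- 40; d <- 3; k <- 5
    refs <- matrix(rnorm(n * d), n, d)
    q <- matrix(rnorm(3 * d), 3, d)
    R <- qr.Q(qr(matrix(rnorm(d * d), d)))
    t0 <- rnorm(d)
    move <- function(m) sweep(m %*% R, 2, t0, `+`)
    p <- lof_params(k = k, threshold = 1.5)
    expect_equal(score_queries(move(q), move(refs), p)$lof_score,
                 score_queries(q, refs, p)$lof_score, tolerance = 1e-9)
  }
  # regular polygon and hypercube corners: transitive isometry group
  hexagon <- t(vapply(0:5, function(i) {
    c(cos(i * pi / 3), sin(i * pi / 3))
  }, numeric(2)))
  expect_equal(lof_fit(hexagon, k = 2)$lof_score, rep(1, 6), tolerance = 1e-9)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(lof_fit(cube, k = 3)$lof_score, rep(1, 8), tolerance = 1e-9)
})

test_that("moving a query radially away from a cluster never decreases its LOF", {
  set.seed(11)
  refs <- matrix(rnorm(60 * 2, sd = 0.5), 60, 2)
  dir <- c(1, 1) / sqrt(2)
  radius_start <- max(sqrt(rowSums(refs^2))) + k_distance(c(0, 0), refs, 5)
  radii <- radius_start + seq(0, 20, by = 0.5)
  scores <- vapply(radii, function(r) lof_score(r * dir, refs, k = 5),
                   numeric(1))
  expect_true(all(diff(scores) >= -1e-12))
})

test_that("a planted far outlier earns the maximum fit-mode LOF", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    refs <- rbind(matrix(rnorm(100 * 2), 100, 2), c(50, 50))
    fit <- lof_fit(refs, k = 5)
    hits <- hits + (which.max(fit$lof_score) == 101)
  }
  expect_gte(hits, 20 * 0.99)
})

test_that("cosine and euclidean metrics rank neighbors identically on the alpha-sphere", {
  set.seed(13)
  refs <- l2_norm_scale(matrix(rnorm(50 * 8), 50, 8), alpha = 5)
  q <- l2_norm_scale(rnorm(8), alpha = 5)
  for (k in c(3, 7)) {
    expect_setequal(k_neighborhood(q, refs, k, metric = "euclidean"),
                    k_neighborhood(q, refs, k, metric = "cosine"))
  }
})

test_that("batch scoring is order-independent and enforces its contracts", {
  set.seed(3)
  refs <- matrix(rnorm(80), 40, 2)
  q <- matrix(rnorm(12), 6, 2)
  p <- lof_params(k = 5, threshold = 1.5)
  fwd <- score_queries(q, refs, p)
  perm <- c(4, 1, 6, 2, 5, 3)
  rev <- score_queries(q[perm, ], refs, p)
  expect_equal(rev$lof_score, fwd$lof_score[perm])
  expect_equal(rev$decision, fwd$decision[perm])

  # on-manifold query scores ~1 -> NORMAL; far query -> AMD
  dense <- matrix(runif(200 * 2), 200, 2)
  res <- score_queries(rbind(dense[1, ], c(5, 5)), dense, lof_params(k = 10, threshold = 1.5))
  expect_identical(res$decision, c("NORMAL", "AMD"))

  expect_error(score_queries(matrix(1, 1, 3), refs, p), "dimension")
  empty <- score_queries(matrix(numeric(0), 0, 2), refs, p)
  expect_equal(nrow(empty), 0)
})

test_that("novelty-mode scores agree with scikit-learn's LOF on random instances", {
  set.seed(99)
  refs <- matrix(rnorm(60 * 3), 60, 3)
  q <- matrix(rnorm(10 * 3), 10, 3)
  k <- 7
  ours <- score_queries(q, refs, lof_params(k = k, threshold = 1.5))$lof_score

  tmp <- tempfile(fileext = ".json")
  out <- tempfile(fileext = ".json")
  jsonlite::write_json(list(refs = refs, q = q, k = k), tmp, digits = NA,
                       auto_unbox = TRUE)
  code <- sprintf(paste(
    "import json, numpy as np",
    "from sklearn.neighbors import LocalOutlierFactor",
    "d = json.load(open('%s'))",
    "m = LocalOutlierFactor(n_neighbors=d['k'], novelty=True).fit(np.array(d['refs']))",
    "json.dump(list(-m.score_samples(np.array(d['q']))), open('%s', 'w'))",
    sep = "; "), tmp, out)
  status <- system2("python", c("-c", shQuote(code)))
  expect_identical(status, 0L)
  theirs <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-6)
})
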