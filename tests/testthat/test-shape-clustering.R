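test_that("z-normalization centres, scales and is idempotent", {
  z <- znormalize(c(1, 2, 3, 4))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(znormalize(z), z)
  expect_equal(znormalize(c(5, 5, 5, 5)), rep(0, 4))
  m <- znormalize(rbind(c(1, 2, 3, 4), c(2, 2, 2, 2)))
  expect_equal(m[2, ], rep(0, 4))
  expect_equal(apply(m[1, , drop = FALSE], 1, sd), c(1))
  expect_error(znormalize(3), "length >= 2")
})

test_that("shape-based distance matches brute-force shift enumeration", {
  set.seed(31)
  for (i in 1:40) {
    x <- sample(-5:9, 4, replace = TRUE)
    y <- sample(-5:9, 4, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(sbd(x, y), sbd_brute(x, y), tolerance = 1e-12)
  }
  # longer series too
  for (i in 1:10) {
    x <- rnorm(9); y <- rnorm(9)
    expect_equal(sbd(x, y), sbd_brute(x, y), tolerance = 1e-12)
  }
})

test_that("shape-based distance has metric-like shape properties", {
  set.seed(32)
  for (i in 1:20) {
    x <- rnorm(4); y <- rnorm(4)
    expect_equal(sbd(x, x), 0, tolerance = 1e-12)
    # invariance to positive affine transforms
    expect_equal(sbd(x, 2.5 * x + 7), 0, tolerance = 1e-12)
    expect_equal(sbd(x, y), sbd(y, x))
    d <- sbd(x, y)
    expect_gte(d, -1e-12); expect_lte(d, 2)
  }
  expect_error(sbd(1:4, 1:5), "lengths differ")
  # a shapeless (constant) series sits at distance 1
  expect_equal(sbd(c(3, 3, 3, 3), c(1, 2, 3, 4)), 1)
})

test_that("shape extraction returns the member shape for trivial clusters", {
  x <- c(1, 4, 2, 0)
  cen <- shape_extract_centroid(matrix(x, 1))
  expect_equal(sbd(cen, x), 0, tolerance = 1e-10)
  same <- matrix(rep(x, 5), 5, byrow = TRUE)
  cen2 <- shape_extract_centroid(same)
  expect_equal(sbd(cen2, x), 0, tolerance = 1e-10)
  expect_equal(mean(cen2), 0, tolerance = 1e-12)
  expect_error(shape_extract_centroid(matrix(numeric(0), 0, 4)), "empty")
})

test_that("shape extraction maximizes summed squared NCC over candidates", {
  # numeric oracle: among unit-shape candidates, nothing beats the
  # centroid on the summed squared aligned normalized cross-correlation
  # (the functional the principal-eigenvector construction maximizes)
  set.seed(33)
  members <- rbind(c(0, 2, 3, 1), c(0.2, 1.8, 3.3, 0.9), c(-1, 2, 4, 1),
                   c(0, -2, -3, -1))   # includes a mirrored series
  cen <- shape_extract_centroid(members)
  a <- znormalize(members)
  score <- function(v) {
    zv <- znormalize(v)
    nv <- sqrt(sum(zv^2))
    if (nv == 0) return(0)
    sum(apply(a, 1, function(m)
      (sum(m * zv) / (sqrt(sum(m^2)) * nv))^2))
  }
  s_cen <- score(cen)
  for (i in 1:300) expect_lte(score(rnorm(4)), s_cen + 1e-9)
})

test_that("k-Shape recovers planted clusters and is seed-deterministic", {
  spec <- trait_series_spec(list(proto_rise, proto_peak_mid,
                                 proto_zigzag),
                            members_per_cluster = 30, noise_sd = 0.3,
                            seed = 7)
  tm <- generate_trait_matrix(spec)
  fit <- kshape_cluster(tm$series, 3, seed = 2)
  expect_equal(mclust::adjustedRandIndex(fit$cluster, tm$true_labels), 1.0)
  # determinism
  fit2 <- kshape_cluster(tm$series, 3, seed = 2)
  expect_identical(fit$cluster, fit2$cluster)
  expect_equal(fit$centroids, fit2$centroids)
  # every row assigned to a non-empty cluster within range
  expect_true(all(fit$cluster >= 1 & fit$cluster <= 3))
  expect_true(all(tabulate(fit$cluster, 3) > 0))
  expect_error(kshape_cluster(tm$series, 100), "exceeds")
})

test_that("k equal to the row count isolates every series at objective zero", {
  set.seed(13)
  m <- matrix(rnorm(24), 6, 4)
  fit <- kshape_cluster(m, 6, seed = 1)
  expect_equal(sort(unique(fit$cluster)), 1:6)
  expect_equal(fit$objective, 0, tolerance = 1e-9)
})

test_that("accepted within-cluster objective never increases across sweeps", {
  # the monotone safeguard guarantees a non-increasing objective trace
  # whatever the noise level or initialization
  for (seed in 1:6) {
    spec <- trait_series_spec(list(proto_rise, proto_peak_mid,
                                   proto_zigzag, proto_peak_early),
                              members_per_cluster = 12, noise_sd = 1.2,
                              seed = 16 + seed)
    tm <- generate_trait_matrix(spec)
    fit <- kshape_cluster(tm$series, 4, seed = seed)
    expect_true(all(diff(fit$trace) <= 1e-9))
    # reported objective is the last accepted sweep (modulo the rare
    # empty-cluster repair, which can only move single rows)
    expect_gte(fit$objective, min(fit$trace) - 1e-9)
    expect_lte(fit$iterations, 100)
  }
})

test_that("validity indices behave at their limits and match hand arithmetic", {
  tight <- rbind(c(0, 10, 6, 2), c(0.01, 10, 6, 2), c(0, 10.01, 6, 2),
                 c(1, 2, 3, 4), c(1.01, 2, 3, 4), c(1, 2.01, 3, 4))
  fit <- kshape_cluster(tight, 2, seed = 1)
  expect_equal(mclust::adjustedRandIndex(fit$cluster, rep(1:2, each = 3)), 1)
  expect_lt(davies_bouldin(tight, fit), 0.05)
  expect_gt(dunn_index(tight, fit), 10)

  # duplicated points across clusters force the Dunn index to zero
  dup <- rbind(c(0, 10, 6, 2), c(1, 2, 3, 4))
  series <- rbind(dup, dup)
  res <- structure(list(k = 2, cluster = c(1, 1, 2, 2),
                        centroids = znormalize(dup)), class = "kshape")
  expect_equal(dunn_index(series, res), 0)

  # hand computation on a 6-point 2-cluster toy set
  toy <- rbind(c(0, 1, 2, 3), c(0, 1.2, 1.9, 3.1), c(0.1, 0.9, 2.1, 2.9),
               c(5, 1, 4, 0), c(5.2, 0.8, 4.1, 0.2), c(4.9, 1.1, 3.8, 0))
  lab <- rep(1:2, each = 3)
  cen <- rbind(shape_extract_centroid(toy[1:3, ]),
               shape_extract_centroid(toy[4:6, ]))
  res2 <- structure(list(k = 2, cluster = lab, centroids = cen),
                    class = "kshape")
  s1 <- mean(sapply(1:3, function(i) sbd(toy[i, ], cen[1, ])))
  s2 <- mean(sapply(4:6, function(i) sbd(toy[i, ], cen[2, ])))
  m12 <- sbd(cen[1, ], cen[2, ])
  expect_equal(davies_bouldin(toy, res2), (s1 + s2) / m12,
               tolerance = 1e-10)
  dm <- outer(1:6, 1:6, Vectorize(function(i, j) sbd(toy[i, ], toy[j, ])))
  inter <- min(dm[1:3, 4:6])
  intra <- max(dm[1:3, 1:3], dm[4:6, 4:6])
  expect_equal(dunn_index(toy, res2), inter / intra, tolerance = 1e-10)
})

test_that("cluster-number selection scans k and returns a full CVI table", {
  spec <- trait_series_spec(list(proto_rise, proto_peak_mid,
                                   proto_zigzag, proto_peak_early),
                            members_per_cluster = 15, noise_sd = 0.3,
                            seed = 21)
  tm <- generate_trait_matrix(spec)
  sel <- select_cluster_number(tm$series, k_max = 8, seed = 3)
  expect_equal(nrow(sel$table), 7)      # k = 2..8
  expect_equal(sel$k_opt, 4)
  # identical duplicate rows forming 2 groups -> k* = 2
  two <- rbind(matrix(rep(c(0, 10, 6, 2), 6), 6, byrow = TRUE),
               matrix(rep(c(1, 2, 3, 4), 6), 6, byrow = TRUE)) +
    matrix(rnorm(48, 0, 0.01), 12, 4)
  sel2 <- select_cluster_number(two, k_max = 5, seed = 1)
  expect_equal(sel2$k_opt, 2)
  # k_max above the row count is truncated with a warning
  expect_warning(sel3 <- select_cluster_number(two, k_max = 40, seed = 1),
                 "truncated")
  expect_equal(max(sel3$table$k), 12)
})
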