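test_that("Moran's I on a 2x2 checkerboard with rook weights is -1", {
  r <- morans_i(c(1, 0, 0, 1), c(0, 1, 0, 1), c(0, 0, 1, 1),
                scheme = "rook")
  expect_equal(r$statistic, -1)
  expect_lt(r$z_score, 0)
})

test_that("Moran's I equals the brute-force double-sum oracle", {
  set.seed(11)
  for (n in c(6, 12, 25)) {
    x <- stats::runif(n, 0, 15)
    y <- stats::runif(n, 0, 20)
    v <- stats::rnorm(n)
    w <- spatial_weights(x, y)
    r <- morans_i(v, x, y)
    expect_equal(r$statistic, oracle_moran(v, w), tolerance = 1e-10)
  }
})

test_that("Moran's I and its randomization sd match an independent
           implementation under row-standardised weights", {
  skip_if_not_installed("ape")
  set.seed(12)
  x <- stats::runif(20)
  y <- stats::runif(20)
  v <- stats::rnorm(20)
  w <- 1 / as.matrix(stats::dist(cbind(x, y)))
  diag(w) <- 0
  ref <- ape::Moran.I(v, w) # ape row-standardises internally
  mine <- morans_i(v, x, y, weights = w / rowSums(w))
  expect_equal(mine$statistic, ref$observed, tolerance = 1e-12)
  expect_equal(mine$sd, ref$sd, tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("Moran's I is invariant to shifting and positive scaling", {
  set.seed(13)
  x <- stats::runif(15)
  y <- stats::runif(15)
  v <- stats::rnorm(15)
  base <- morans_i(v, x, y)
  shifted <- morans_i(v + 100, x, y)
  scaled <- morans_i(v * 3.7, x, y)
  expect_equal(shifted$statistic, base$statistic, tolerance = 1e-10)
  expect_equal(scaled$statistic, base$statistic, tolerance = 1e-10)
  expect_equal(scaled$z_score, base$z_score, tolerance = 1e-10)
})

test_that("Moran's I rejects degenerate inputs", {
  expect_error(morans_i(rep(1, 5), 1:5, 1:5), "constant")
  expect_error(morans_i(1:3, 1:3, 1:3), "at least 4")
  expect_error(spatial_weights(c(1, 1, 2), c(1, 1, 2)), "duplicate")
})

test_that("permutation p-value agrees in order with the analytic band", {
  set.seed(14)
  x <- rep(1:6, 6)
  y <- rep(1:6, each = 6)
  v <- x + y + stats::rnorm(36, 0, 0.5) # strong positive autocorrelation
  r <- morans_i(v, x, y, n_perm = 199)
  expect_equal(r$verdict, "clustered")
  expect_lt(r$p_perm, 0.05)
})

test_that("ANN at the unit-square corners is maximally dispersed", {
  r <- average_nearest_neighbor(c(0, 1, 0, 1), c(0, 0, 1, 1), 1)
  expect_equal(r$d_obs, 1)
  expect_equal(r$d_exp, 0.25)
  expect_equal(r$statistic, 4)
  expect_equal(r$verdict, "dispersed")
})

test_that("ANN matches its brute-force oracle and scaling invariance", {
  set.seed(15)
  for (n in c(5, 12, 25)) {
    x <- stats::runif(n, 0, 15)
    y <- stats::runif(n, 0, 20)
    r <- average_nearest_neighbor(x, y, 300)
    expect_equal(r$statistic, oracle_ann_ratio(x, y, 300),
                 tolerance = 1e-10)
    # uniform coordinate scaling with consistent area leaves the ratio
    s <- 3.5
    rs <- average_nearest_neighbor(s * x, s * y, s^2 * 300)
    expect_equal(rs$statistic, r$statistic, tolerance = 1e-10)
    expect_equal(rs$z_score, r$z_score, tolerance = 1e-10)
  }
})

test_that("ANN ratio approaches 1 for homogeneous random patterns", {
  set.seed(16)
  reps <- 400
  n <- 50
  ratios <- vapply(seq_len(reps), function(k) {
    average_nearest_neighbor(stats::runif(n, 0, 100),
                             stats::runif(n, 0, 100), 1e4)$statistic
  }, numeric(1))
  # the uncorrected index carries the classical boundary bias; under CSR
  # the Donnelly approximation puts the expected mean NN distance at
  # 0.5 sqrt(A/n) + (0.051 + 0.042/sqrt(n)) P/n for perimeter P
  d_exp <- 0.5 * sqrt(1e4 / n)
  d_edge <- d_exp + (0.051 + 0.042 / sqrt(n)) * 400 / n
  se <- stats::sd(ratios) / sqrt(reps)
  expect_lt(abs(mean(ratios) - d_edge / d_exp), max(3 * se, 0.01))
})

test_that("Kruskal-Wallis reproduces hand-ranked and oracle values", {
  k <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(k$H, 7.2)
  expect_equal(k$df, 2)
  ident <- kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_lt(ident$H, 0.01)
  expect_gt(ident$p_value, 0.9)
  set.seed(17)
  for (rep in 1:10) {
    groups <- lapply(1:3, function(i) {
      round(stats::rnorm(sample(4:9, 1), i), 1) # rounding induces ties
    })
    expect_equal(kruskal_wallis(groups)$H, oracle_kw_h(groups),
                 tolerance = 1e-10)
  }
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("Kruskal-Wallis is invariant to monotone transforms", {
  set.seed(18)
  groups <- lapply(1:4, function(i) stats::rnorm(8, i / 2))
  h0 <- kruskal_wallis(groups)$H
  expect_equal(kruskal_wallis(lapply(groups, exp))$H, h0,
               tolerance = 1e-12)
  expect_equal(kruskal_wallis(lapply(groups, function(g) 5 * g - 2))$H,
               h0, tolerance = 1e-12)
})

test_that("mean-rank letters separate and merge groups correctly", {
  same <- mean_rank_comparison(list(a = c(1, 3, 5, 7), b = c(1, 3, 5, 7)))
  expect_equal(unname(same$letters), c("a", "a"))
  set.seed(19)
  far <- mean_rank_comparison(list(
    lo = stats::rnorm(30, 0, 0.1),
    mid = stats::rnorm(30, 10, 0.1),
    hi = stats::rnorm(30, 20, 0.1)
  ))
  expect_equal(length(unique(far$letters)), 3)
  expect_false(any(far$letters["lo"] == far$letters["hi"]))
})

test_that("duff-like stocks isolate the un-encroached plot in the
           lowest letter class", {
  set.seed(20)
  groups <- list(
    HSC = pmax(0, stats::rnorm(32, 0.05, 0.04)),
    LD = pmax(0, stats::rnorm(34, 0.42, 0.30)),
    HD = pmax(0, stats::rnorm(41, 0.71, 0.40)),
    PJD = pmax(0, stats::rnorm(34, 0.53, 0.35))
  )
  res <- mean_rank_comparison(groups)
  expect_lt(res$kw$p_value, 0.05)
  # HSC shares no letter with the high-duff encroached plots
  shared <- function(a, b) {
    any(strsplit(res$letters[[a]], "")[[1]] %in%
          strsplit(res$letters[[b]], "")[[1]])
  }
  expect_false(shared("HSC", "HD"))
  expect_false(shared("HSC", "PJD"))
})

test_that("spatial_summary produces a verdict per measure", {
  inv <- tiny_inventory()
  sp <- spatial_summary(inv)
  expect_true(all(c("mineral_c", "tree_ann") %in% sp$measure))
  expect_true(all(sp$verdict %in% c("clustered", "dispersed", "random")))
})
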