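#' Spatial weight matrix for Moran's I
#'
#' Builds the pairwise weight matrix over point locations. The default is
#' inverse Euclidean distance without row standardisation — the common
#' desktop-GIS default for irregular samples. A binary distance band and a
#' rook (unit-grid contiguity) scheme are also available.
#'
#' @param x,y Point coordinates (m).
#' @param scheme `"inverse_distance"`, `"band"` or `"rook"`.
#' @param band_distance Threshold for the `"band"` scheme (weight 1 within,
#'   0 beyond). For `"rook"` the threshold is the minimum positive
#'   inter-point distance (+ 1e-9), giving orthogonal-neighbour weights on
#'   a regular grid.
#' @return An n x n numeric weight matrix with zero diagonal.
#' @export
spatial_weights <- function(x, y, scheme = c("inverse_distance", "band",
                                             "rook"),
                            band_distance = NULL) {
  scheme <- match.arg(scheme)
  d <- as.matrix(stats::dist(cbind(x, y)))
  if (any(d[upper.tri(d)] == 0)) {
    stop("duplicate coordinates: jitter points before weighting")
  }
  w <- switch(scheme,
    inverse_distance = 1 / d,
    band = {
      if (is.null(band_distance)) stop("band scheme needs band_distance")
      (d <= band_distance) * 1
    },
    rook = (d <= min(d[d > 0]) + 1e-9) * 1
  )
  diag(w) <- 0
  w
}

#' Moran's I spatial autocorrelation with randomization z-score
#'
#' Global Moran's I over georeferenced values:
#' I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2.
#' The z-score uses the variance under the randomization (permutation
#' moment) assumption; the verdict is `clustered` for z above the positive
#' critical value, `dispersed` below the negative one, `random` otherwise
#' (1.96 for the 0.05 band, 2.58 for 0.01). Optionally a Monte-Carlo
#' permutation p-value is computed.
#'
#' @param values Numeric vector of observed values (non-constant, >= 4).
#' @param x,y Coordinates of the observations.
#' @param scheme,band_distance Passed to [spatial_weights()].
#' @param weights Optional precomputed weight matrix (overrides `scheme`).
#' @param n_perm Number of Monte-Carlo permutations (0 = none).
#' @return A `cluster_result` list: `statistic` (I), `expectation`, `sd`,
#'   `z_score`, `p_value` (two-sided normal), `p_band` ("ns", "0.05" or
#'   "0.01"), `verdict`, `method`, and `p_perm` when requested.
#' @export
morans_i <- function(values, x, y, scheme = "inverse_distance",
                     band_distance = NULL, weights = NULL, n_perm = 0) {
  n <- length(values)
  if (n < 4) stop("Moran's I needs at least 4 points")
  stopifnot(length(x) == n, length(y) == n)
  if (stats::sd(values) == 0) {
    stop("values are constant: Moran's I is undefined (zero variance)")
  }
  w <- if (is.null(weights)) {
    spatial_weights(x, y, scheme, band_distance)
  } else {
    weights
  }
  z <- values - mean(values)
  s0 <- sum(w)
  if (s0 <= 0) stop("all spatial weights are zero")
  i_obs <- (n / s0) * sum(w * outer(z, z)) / sum(z^2)
  e_i <- -1 / (n - 1)
  # randomization-assumption variance (Cliff & Ord moments)
  s1 <- 0.5 * sum((w + t(w))^2)
  s2 <- sum((rowSums(w) + colSums(w))^2)
  b2 <- n * sum(z^4) / (sum(z^2))^2
  num <- n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
    b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)
  var_i <- num / ((n - 1) * (n - 2) * (n - 3) * s0^2) - e_i^2
  sd_i <- sqrt(var_i)
  zs <- (i_obs - e_i) / sd_i
  res <- cluster_result(i_obs, zs, method = "morans_i")
  res$expectation <- e_i
  res$sd <- sd_i
  if (n_perm > 0) {
    exceed <- vapply(seq_len(n_perm), function(k) {
      zp <- sample(z)
      ip <- (n / s0) * sum(w * outer(zp, zp)) / sum(zp^2)
      abs(ip - e_i) >= abs(i_obs - e_i)
    }, logical(1))
    res$p_perm <- (sum(exceed) + 1) / (n_perm + 1)
  }
  res
}

#' Average nearest neighbor index
#'
#' Ratio of the observed mean nearest-neighbour distance to the expectation
#' under complete spatial randomness on the same area:
#' D_exp = 0.5 / sqrt(n / A), with z = (D_obs - D_exp) / SE and
#' SE = 0.26136 / sqrt(n^2 / A). A ratio below 1 (negative z) indicates
#' clustering; above 1 (positive z), dispersion.
#'
#' @param x,y Point coordinates (m), at least 3 points, not all coincident.
#' @param extent_area_m2 Area of the study extent (m^2).
#' @return A `cluster_result` list with `statistic` (the ANN ratio),
#'   `z_score`, `p_band`, `verdict`, plus `d_obs` and `d_exp` (m).
#' @export
average_nearest_neighbor <- function(x, y, extent_area_m2) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("average nearest neighbor needs at least 3 points")
  if (extent_area_m2 <= 0) stop("extent_area_m2 must be positive")
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  if (all(nn == 0)) stop("all points are coincident")
  d_obs <- mean(nn)
  d_exp <- 0.5 / sqrt(n / extent_area_m2)
  se <- 0.26136 / sqrt(n^2 / extent_area_m2)
  zs <- (d_obs - d_exp) / se
  res <- cluster_result(d_obs / d_exp, zs, method = "ann",
                        clustered_low = TRUE)
  res$d_obs <- d_obs
  res$d_exp <- d_exp
  res
}

#' Bundle a spatial statistic with its z-score verdict
#'
#' @param statistic The index value (Moran's I or ANN ratio).
#' @param z_score Standard-normal test statistic.
#' @param method Label of the generating statistic.
#' @param clustered_low If `TRUE` (ANN convention) a significantly low
#'   statistic means clustered; if `FALSE` (Moran convention) a
#'   significantly high z means clustered.
#' @return A list of class `cluster_result` with `p_band` ("ns", "0.05",
#'   "0.01"), a two-sided normal `p_value` and a `verdict` in
#'   clustered/dispersed/random.
#' @export
cluster_result <- function(statistic, z_score, method = "",
                           clustered_low = FALSE) {
  p_band <- if (abs(z_score) >= 2.58) {
    "0.01"
  } else if (abs(z_score) >= 1.96) {
    "0.05"
  } else {
    "ns"
  }
  verdict <- if (p_band == "ns") {
    "random"
  } else if (xor(z_score > 0, clustered_low)) {
    "clustered"
  } else {
    "dispersed"
  }
  structure(
    list(statistic = statistic, z_score = z_score,
         p_value = 2 * stats::pnorm(-abs(z_score)),
         p_band = p_band, verdict = verdict, method = method),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result ", x$method, "> statistic = ",
      signif(x$statistic, 4), ", z = ", signif(x$z_score, 3),
      " (", x$p_band, ") -> ", x$verdict, "\n", sep = "")
  invisible(x)
}

#' Kruskal-Wallis rank ANOVA over groups
#'
#' Tie-corrected Kruskal-Wallis H across k groups with a chi-square
#' approximation on k - 1 degrees of freedom (delegated to
#' [stats::kruskal.test()]), returned alongside the per-group mean ranks
#' used by [mean_rank_comparison()].
#'
#' @param groups A named (or unnamed) list of numeric vectors, each
#'   non-empty.
#' @return A list of class `rank_test_result`: `H`, `df`, `p_value`,
#'   `mean_ranks`, `n` (per-group sizes).
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(!vapply(groups, length, integer(1)))) {
    stop("every group must be non-empty")
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  kt <- stats::kruskal.test(values, g)
  r <- rank(values)
  structure(
    list(H = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value,
         mean_ranks = tapply(r, g, mean),
         n = tapply(r, g, length)),
    class = "rank_test_result"
  )
}

#' Multiple mean-rank comparison with compact letter display
#'
#' Dunn-type pairwise comparisons of group mean ranks following a
#' Kruskal-Wallis test, with a Bonferroni family-wise critical value over
#' all k(k-1)/2 pairs, summarised as a compact letter display: groups
#' sharing a letter are not significantly different. If the global test is
#' not significant at `alpha`, all groups share one letter.
#'
#' @param groups As in [kruskal_wallis()].
#' @param alpha Family-wise significance level (default 0.05).
#' @return A list: `letters` (named character, one letter set per group,
#'   ordered by descending mean rank), `pairs` (data frame of pairwise z
#'   and significance), `kw` (the global test).
#' @export
mean_rank_comparison <- function(groups, alpha = 0.05) {
  kw <- kruskal_wallis(groups)
  k <- length(kw$mean_ranks)
  nm <- names(kw$mean_ranks)
  values <- unlist(groups, use.names = FALSE)
  n_tot <- length(values)
  # tie correction to the rank variance
  tie <- table(values)
  tie_term <- sum(tie^3 - tie) / (12 * (n_tot - 1))
  var_base <- n_tot * (n_tot + 1) / 12 - tie_term
  pairs <- expand.grid(i = seq_len(k), j = seq_len(k))
  pairs <- pairs[pairs$i < pairs$j, ]
  z <- mapply(function(i, j) {
    se <- sqrt(var_base * (1 / kw$n[i] + 1 / kw$n[j]))
    (kw$mean_ranks[i] - kw$mean_ranks[j]) / se
  }, pairs$i, pairs$j)
  m <- k * (k - 1) / 2
  crit <- stats::qnorm(1 - alpha / (2 * m))
  sig <- abs(z) > crit
  if (kw$p_value > alpha) sig[] <- FALSE
  pair_df <- data.frame(group1 = nm[pairs$i], group2 = nm[pairs$j],
                        z = as.numeric(z), significant = sig)
  # compact letter display: insert-and-absorb on groups ordered by rank
  ord <- order(kw$mean_ranks, decreasing = TRUE)
  differ <- matrix(FALSE, k, k)
  differ[cbind(pairs$i, pairs$j)] <- sig
  differ <- differ | t(differ)
  cols <- list(rep(FALSE, k))
  cols[[1]][ord[1]] <- TRUE
  for (g in ord[-1]) {
    placed <- FALSE
    for (ci in seq_along(cols)) {
      members <- which(cols[[ci]])
      if (!any(differ[g, members])) {
        cols[[ci]][g] <- TRUE
        placed <- TRUE
      }
    }
    if (!placed) {
      newcol <- rep(FALSE, k)
      newcol[g] <- TRUE
      # absorb: add every group not differing from g that fits
      for (h in ord) {
        if (h != g && !any(differ[h, which(newcol)])) newcol[h] <- TRUE
      }
      newcol[g] <- TRUE
      cols[[length(cols) + 1]] <- newcol
    }
  }
  # drop columns fully contained in another
  keep <- rep(TRUE, length(cols))
  for (a in seq_along(cols)) {
    for (b in seq_along(cols)) {
      if (a != b && keep[b] && all(cols[[a]] <= cols[[b]]) &&
          !identical(cols[[a]], cols[[b]])) {
        keep[a] <- FALSE
      }
    }
  }
  cols <- cols[keep]
  lets <- vapply(seq_len(k), function(g) {
    paste0(letters[which(vapply(cols, function(cl) cl[g], logical(1)))],
           collapse = "")
  }, character(1))
  names(lets) <- nm
  list(letters = lets, pairs = pair_df, kw = kw)
}

#' Spatial clustering summary for a plot inventory
#'
#' Reproduces the per-plot spatial diagnostics: Moran's I on duff and
#' mineral soil core carbon, and the average nearest neighbor index on
#' tree locations. Duff carbon is evaluated at every sampled point
#' (0 where no duff layer was present), matching the clustering signal of
#' a patchy organic layer.
#'
#' @param inventory A [plot_inventory()] with cores and/or trees.
#' @param scheme Weight scheme for Moran's I.
#' @return Data frame rows: plot, measure (`duff_c`, `mineral_c`,
#'   `tree_ann`), statistic, z_score, p_band, verdict.
#' @export
spatial_summary <- function(inventory, scheme = "inverse_distance") {
  stopifnot(inherits(inventory, "plot_inventory"))
  out <- list()
  cores <- inventory$cores
  if (!is.null(cores) && nrow(cores)) {
    for (lay in c("duff", "mineral")) {
      lc <- cores[cores$layer == "mineral", c("x_m", "y_m"), drop = FALSE]
      if (lay == "duff") {
        dc <- cores[cores$layer == "duff", , drop = FALSE]
        v <- rep(0, nrow(lc))
        if (nrow(dc)) {
          idx <- match(
            paste(dc$x_m, dc$y_m),
            paste(lc$x_m, lc$y_m)
          )
          vals <- soil_layer_carbon(core = dc)
          v[idx[!is.na(idx)]] <- vals[!is.na(idx)]
        }
      } else {
        v <- soil_layer_carbon(core = cores[cores$layer == "mineral", ,
                                            drop = FALSE])
      }
      if (nrow(lc) >= 4 && stats::sd(v) > 0) {
        mi <- morans_i(v, lc$x_m, lc$y_m, scheme = scheme)
        out[[length(out) + 1]] <- data.frame(
          plot = inventory$plot_id,
          measure = paste0(lay, "_c"), statistic = mi$statistic,
          z_score = mi$z_score, p_band = mi$p_band, verdict = mi$verdict
        )
      }
    }
  }
  trees <- inventory$trees
  if (nrow(trees) >= 3) {
    ann <- average_nearest_neighbor(trees$x_m, trees$y_m,
                                    prod(inventory$extent_m))
    out[[length(out) + 1]] <- data.frame(
      plot = inventory$plot_id, measure = "tree_ann",
      statistic = ann$statistic, z_score = ann$z_score,
      p_band = ann$p_band, verdict = ann$verdict
    )
  }
  if (!length(out)) {
    stop("inventory holds neither analysable cores nor >= 3 trees")
  }
  do.call(rbind, out)
}
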