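# deterministic hand-built inventories used across test files

tiny_trees <- function() {
  data.frame(
    id = c("a", "b", "c"),
    species = c("pinon", "pinon", "juniper"),
    status = c("live", "dead", "live"),
    rcd_cm = c(10, 10, 20),
    canopy_area_m2 = c(4, 4, 6),
    x_m = c(2, 7, 12), y_m = c(3, 11, 17),
    establishment_year = c(1950L, 1940L, 1930L),
    death_year = c(NA, 2003L, NA),
    stringsAsFactors = FALSE
  )
}

uniform_covers <- function(value = 50, n_groups = 12) {
  do.call(rbind, lapply(seq_len(n_groups), function(g) {
    data.frame(
      subplot_id = sprintf("s%02d_%d", g, 1:4),
      group = sprintf("g%02d", g),
      x_m = rep(2, 4), y_m = rep(2, 4),
      grass = value, sagebrush = value,
      duff_litter = value, bareground = value,
      stringsAsFactors = FALSE
    )
  }))
}

tiny_cores <- function() {
  grid <- expand.grid(x_m = c(2, 7, 12), y_m = c(2, 10, 18))
  rbind(
    data.frame(
      id = sprintf("m%d", seq_len(nrow(grid))), grid, layer = "mineral",
      bulk_density_g_cm3 = 1.5, depth_cm = 10,
      percent_c_measured = seq(0.8, 1.2, length.out = nrow(grid)),
      percent_carbonate = 2, stringsAsFactors = FALSE
    ),
    data.frame(
      id = "d1", x_m = 2, y_m = 2, layer = "duff",
      bulk_density_g_cm3 = 0.2, depth_cm = 2,
      percent_c_measured = 11, percent_carbonate = 1,
      stringsAsFactors = FALSE
    )
  )
}

tiny_inventory <- function(plot_id = "T", cover_value = 20) {
  plot_inventory(plot_id, trees = tiny_trees(),
                 covers = uniform_covers(cover_value),
                 cores = tiny_cores())
}

# independent O(n^2) double-sum oracle for Moran's I
oracle_moran <- function(values, w) {
  n <- length(values)
  z <- values - mean(values)
  acc <- 0
  s0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- acc + w[i, j] * z[i] * z[j]
      s0 <- s0 + w[i, j]
    }
  }
  (n / s0) * acc / sum(z^2)
}

# brute-force nearest-neighbour mean distance
oracle_ann_ratio <- function(x, y, area) {
  n <- length(x)
  nn <- vapply(seq_len(n), function(i) {
    min(sqrt((x[-i] - x[i])^2 + (y[-i] - y[i])^2))
  }, numeric(1))
  mean(nn) / (0.5 / sqrt(n / area))
}

# tie-corrected Kruskal-Wallis H from the textbook rank formula
oracle_kw_h <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  n_tot <- length(values)
  r <- rank(values)
  sizes <- vapply(groups, length, integer(1))
  idx <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, idx, mean)
  h <- 12 / (n_tot * (n_tot + 1)) *
    sum(sizes * (rbar - (n_tot + 1) / 2)^2)
  tie <- table(values)
  h / (1 - sum(tie^3 - tie) / (n_tot^3 - n_tot))
}
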