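#' Configuration for a synthetic stand
#'
#' Collects every knob of the synthetic-data generator with defaults that
#' emulate the encroached study plots: spatially clustered trees (Thomas
#' process), ~90% pinon, a 1940s-50s recruitment pulse holding 55% of the
#' establishment mass, lognormal RCDs around 11 cm, and a noisy power-law
#' canopy-area link calibrated so crowns of ~4-5 m^2 accompany RCDs of
#' 10-14 cm. All randomness flows from `seed`.
#'
#' @param seed Integer seed (mandatory; sub-seeds for the cover, soil and
#'   scene samplers are derived deterministically from it).
#' @param extent_m c(width, height) in m; plots are 15 x 20, landscapes
#'   e.g. 500 x 500.
#' @param target_density_stems_ha Stems per hectare (live + dead).
#' @param pinon_fraction Probability a stem is pinon (default 0.9).
#' @param cluster List: `parent_intensity_ha` (Thomas parents per ha),
#'   `sigma_m` (offspring dispersal sd).
#' @param pulse Named numeric of decade weights for establishment years
#'   (names = decade start years); default concentrates 0.55 on 1940-1959.
#' @param rcd_meanlog,rcd_sdlog Lognormal RCD parameters (cm scale).
#' @param ca_link List: `a`, `b`, `sdlog` for CA = a * RCD^b * lognoise.
#' @param mortality Optional list: `year`, `fraction` (plot-wide dieback).
#' @param oldest_tree_year Optional: force the single oldest tree to this
#'   establishment year (plot chronology anchors).
#' @return A list of class `stand_config`.
#' @export
stand_config <- function(seed,
                         extent_m = c(15, 20),
                         target_density_stems_ha = 1400,
                         pinon_fraction = 0.9,
                         cluster = list(parent_intensity_ha = 150,
                                        sigma_m = 1.5),
                         pulse = c("1890" = 0.04, "1900" = 0.05,
                                   "1910" = 0.05, "1920" = 0.08,
                                   "1930" = 0.11, "1940" = 0.28,
                                   "1950" = 0.27, "1960" = 0.07,
                                   "1970" = 0.03, "1980" = 0.01,
                                   "1990" = 0.01),
                         rcd_meanlog = log(11), rcd_sdlog = 0.4,
                         ca_link = list(a = 0.39, b = 1.0, sdlog = 0.25),
                         mortality = NULL,
                         oldest_tree_year = NULL) {
  stopifnot(!missing(seed), is.numeric(seed), length(seed) == 1)
  stopifnot(length(extent_m) == 2, all(extent_m > 0),
            target_density_stems_ha > 0,
            pinon_fraction >= 0, pinon_fraction <= 1,
            abs(sum(pulse) - 1) < 1e-8)
  if (!is.null(mortality)) {
    stopifnot(mortality$fraction >= 0, mortality$fraction <= 1)
  }
  structure(
    list(seed = as.integer(seed), extent_m = extent_m,
         target_density_stems_ha = target_density_stems_ha,
         pinon_fraction = pinon_fraction, cluster = cluster,
         pulse = pulse, rcd_meanlog = rcd_meanlog, rcd_sdlog = rcd_sdlog,
         ca_link = ca_link, mortality = mortality,
         oldest_tree_year = oldest_tree_year),
    class = "stand_config"
  )
}

# deterministic sub-seed per generator stage and plot, kept below 2^31
sub_seed <- function(seed, stage, salt = "") {
  offs <- c(stand = 101L, cover = 211L, soil = 307L, scene = 401L)
  s <- sum(utf8ToInt(as.character(salt))) %% 10007L
  ((as.integer(seed) %% 250000L) * 7919L + offs[[stage]] + s * 131L) %%
    2147483647L
}

#' Generate a synthetic tree stand
#'
#' Tree locations follow a Thomas cluster process (Poisson parents,
#' Gaussian offspring dispersal) thinned or topped up to the target stem
#' count; species, establishment decades, RCDs and canopy areas follow the
#' configured distributions; mortality (if configured) marks a random
#' fraction of stems dead in the given year. Fully reproducible from the
#' config seed.
#'
#' @param config A [stand_config()].
#' @param plot_id Label for the returned inventory.
#' @return A [plot_inventory()] whose `trees` table is populated.
#' @export
generate_stand <- function(config, plot_id = "synthetic") {
  stopifnot(inherits(config, "stand_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sub_seed(config$seed, "stand", plot_id))
  ext <- config$extent_m
  area_ha <- prod(ext) / 1e4
  n_target <- round(config$target_density_stems_ha * area_ha)
  if (n_target < 1) {
    stop("target density yields no trees on this extent")
  }
  pts <- matrix(numeric(0), ncol = 2)
  kappa <- config$cluster$parent_intensity_ha
  sigma <- config$cluster$sigma_m
  mu <- n_target / max(1e-9, kappa * area_ha) # offspring per parent
  guard <- 0
  while (nrow(pts) < n_target && guard < 50) {
    n_par <- stats::rpois(1, kappa * area_ha)
    if (n_par > 0) {
      px <- stats::runif(n_par, 0, ext[1])
      py <- stats::runif(n_par, 0, ext[2])
      n_off <- stats::rpois(n_par, mu)
      ox <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, sigma)
      oy <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, sigma)
      # toroidal wrap keeps the realised intensity uniform at the edges
      ox <- ox %% ext[1]
      oy <- oy %% ext[2]
      pts <- rbind(pts, cbind(ox, oy))
    }
    guard <- guard + 1
  }
  if (nrow(pts) < n_target) stop("cluster process failed to reach density")
  pts <- pts[sample.int(nrow(pts), n_target), , drop = FALSE]
  n <- n_target
  species <- ifelse(stats::runif(n) < config$pinon_fraction,
                    "pinon", "juniper")
  decades <- as.integer(names(config$pulse))
  dec <- decades[sample.int(length(decades), n, replace = TRUE,
                            prob = config$pulse)]
  est <- dec + sample.int(10, n, replace = TRUE) - 1L
  if (!is.null(config$oldest_tree_year)) {
    est[which.min(est)] <- as.integer(config$oldest_tree_year)
  }
  rcd <- stats::rlnorm(n, config$rcd_meanlog, config$rcd_sdlog)
  ca <- config$ca_link$a * rcd^config$ca_link$b *
    stats::rlnorm(n, 0, config$ca_link$sdlog)
  status <- rep("live", n)
  death <- rep(NA_integer_, n)
  if (!is.null(config$mortality)) {
    n_dead <- round(config$mortality$fraction * n)
    dead_idx <- sample.int(n, n_dead)
    status[dead_idx] <- "dead"
    death[dead_idx] <- as.integer(config$mortality$year)
  }
  trees <- data.frame(
    id = sprintf("t%03d", seq_len(n)), species = species, status = status,
    rcd_cm = rcd, canopy_area_m2 = ca,
    x_m = pts[, 1], y_m = pts[, 2],
    establishment_year = est, death_year = death,
    stringsAsFactors = FALSE
  )
  inv <- plot_inventory(plot_id, trees = trees, extent_m = ext)
  attr(inv, "config") <- config
  inv
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# fraction of a 1 m^2 subplot at (x, y) covered by tree crowns,
# approximating each crown as a disk of the tree's canopy area
local_canopy_cover <- function(x, y, trees) {
  if (!nrow(trees)) {
    return(rep(0, length(x)))
  }
  r <- sqrt(trees$canopy_area_m2 / pi)
  cov <- vapply(seq_along(x), function(i) {
    d <- sqrt((trees$x_m - x[i])^2 + (trees$y_m - y[i])^2)
    # crude overlap: full cover if inside a crown, linear fade to 1 m out
    w <- pmax(0, pmin(1, 1 - (d - r)))
    min(1, sum(w))
  }, numeric(1))
  cov
}

#' Sample understory cover on a synthetic stand
#'
#' Lays out the field design (48 one-m^2 subplots, four per 5 x 5 m group)
#' and draws cover values: grass and sagebrush start from open-ground base
#' levels and are suppressed multiplicatively under and near tree crowns;
#' duff/litter cover rises with canopy; bareground takes up the remainder.
#'
#' @param stand A [plot_inventory()] (typically from [generate_stand()]).
#' @param base Named list of open-ground mean covers (percent); defaults
#'   emulate an un-encroached black-sagebrush site (grass 11.85, sagebrush
#'   37.03, duff 2).
#' @param suppression Fraction of understory cover lost under full canopy
#'   (0 = no suppression, default 0.85).
#' @param duff_gain Percent duff cover added per unit local canopy cover
#'   (default 70).
#' @param noise_sd Gaussian noise sd on each subplot cover (percent).
#' @return The stand with its `covers` table populated.
#' @export
sample_cover <- function(stand, base = list(grass = 11.85,
                                            sagebrush = 37.03, duff = 2),
                         suppression = 0.85, duff_gain = 70,
                         noise_sd = 3) {
  stopifnot(inherits(stand, "plot_inventory"))
  cfg <- attr(stand, "config")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sub_seed(if (is.null(cfg)) 0L else cfg$seed, "cover",
                    stand$plot_id))
  ext <- stand$extent_m
  ngx <- floor(ext[1] / 5)
  ngy <- floor(ext[2] / 5)
  if (ngx < 1 || ngy < 1) stop("subplot layout exceeds the extent")
  corners <- expand.grid(dx = c(1, 4), dy = c(1, 4))
  layout <- do.call(rbind, lapply(seq_len(ngx * ngy), function(g) {
    gx <- (g - 1) %% ngx
    gy <- (g - 1) %/% ngx
    data.frame(group = sprintf("g%02d", g),
               x_m = gx * 5 + corners$dx + 0.5,
               y_m = gy * 5 + corners$dy + 0.5)
  }))
  cov_local <- local_canopy_cover(layout$x_m, layout$y_m, stand$trees)
  clip <- function(v) pmin(100, pmax(0, v))
  n <- nrow(layout)
  grass <- clip(base$grass * (1 - suppression * cov_local) +
                  stats::rnorm(n, 0, noise_sd))
  sage <- clip(base$sagebrush * (1 - suppression * cov_local) +
                 stats::rnorm(n, 0, noise_sd))
  duff <- clip(base$duff + duff_gain * cov_local +
                 stats::rnorm(n, 0, noise_sd))
  bare <- clip(100 - grass - sage - duff)
  covers <- data.frame(
    subplot_id = sprintf("s%03d", seq_len(n)),
    group = layout$group, x_m = layout$x_m, y_m = layout$y_m,
    grass = grass, sagebrush = sage, duff_litter = duff, bareground = bare,
    stringsAsFactors = FALSE
  )
  out <- plot_inventory(stand$plot_id, trees = stand$trees,
                        covers = covers, cores = stand$cores,
                        extent_m = ext)
  attr(out, "config") <- cfg
  out
}

#' Sample a georeferenced soil survey on a synthetic stand
#'
#' Places cores on a regular grid and draws layer measurements with the
#' spatial structure the analysis assumes: mineral %C is independent noise
#' around a plot mean (spatially random), while duff presence and depth
#' are elevated under and near crowns (spatially clustered wherever trees
#' are). Bulk densities and magnitudes sit near observed semi-arid values.
#'
#' @param stand A [plot_inventory()].
#' @param spacing_m Grid spacing in m (2-2.5 in the field; default 2.5).
#' @param mineral List: `percent_c_mean`, `percent_c_sd`, `bd`, `bd_sd`,
#'   `carbonate_mean` for the mineral layer.
#' @param duff List: `base_prob` (duff presence probability in the open),
#'   `canopy_prob` (under full canopy), `depth_meanlog`, `depth_sdlog`
#'   (cm), `bd`, `percent_c` for the duff layer.
#' @return The stand with its `cores` table populated.
#' @export
sample_soil <- function(stand, spacing_m = 2.5,
                        mineral = list(percent_c_mean = 1.0,
                                       percent_c_sd = 0.25, bd = 1.4,
                                       bd_sd = 0.05, carbonate_mean = 2),
                        duff = list(base_prob = 0.08, canopy_prob = 0.95,
                                    depth_meanlog = log(1.8),
                                    depth_sdlog = 0.35, bd = 0.25,
                                    percent_c = 11)) {
  stopifnot(inherits(stand, "plot_inventory"))
  if (spacing_m <= 0) stop("spacing_m must be positive")
  cfg <- attr(stand, "config")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sub_seed(if (is.null(cfg)) 0L else cfg$seed, "soil",
                    stand$plot_id))
  ext <- stand$extent_m
  gx <- seq(spacing_m / 2, ext[1] - 1e-9, by = spacing_m)
  gy <- seq(spacing_m / 2, ext[2] - 1e-9, by = spacing_m)
  grid <- expand.grid(x_m = gx, y_m = gy)
  n <- nrow(grid)
  clip01 <- function(v, lo, hi) pmin(hi, pmax(lo, v))
  min_cores <- data.frame(
    id = sprintf("m%03d", seq_len(n)), x_m = grid$x_m, y_m = grid$y_m,
    layer = "mineral",
    bulk_density_g_cm3 = clip01(
      stats::rnorm(n, mineral$bd, mineral$bd_sd), 0.8, 2
    ),
    depth_cm = 10,
    percent_c_measured = clip01(
      stats::rnorm(n, mineral$percent_c_mean, mineral$percent_c_sd),
      0.05, 5
    ),
    percent_carbonate = clip01(
      stats::rnorm(n, mineral$carbonate_mean, 0.5), 0, 10
    ),
    stringsAsFactors = FALSE
  )
  cov_local <- local_canopy_cover(grid$x_m, grid$y_m, stand$trees)
  p_duff <- duff$base_prob + (duff$canopy_prob - duff$base_prob) * cov_local
  present <- stats::runif(n) < p_duff
  nd <- sum(present)
  duff_cores <- if (nd) {
    data.frame(
      id = sprintf("d%03d", which(present)),
      x_m = grid$x_m[present], y_m = grid$y_m[present],
      layer = "duff",
      bulk_density_g_cm3 = clip01(stats::rnorm(nd, duff$bd, 0.04), 0.05, 1),
      depth_cm = stats::rlnorm(nd, duff$depth_meanlog, duff$depth_sdlog) *
        (0.5 + cov_local[present]),
      percent_c_measured = clip01(stats::rnorm(nd, duff$percent_c, 1.5),
                                  2, 40),
      percent_carbonate = clip01(stats::rnorm(nd, 1, 0.3), 0, 5),
      stringsAsFactors = FALSE
    )
  } else {
    NULL
  }
  cores <- rbind(min_cores, duff_cores)
  out <- plot_inventory(stand$plot_id, trees = stand$trees,
                        covers = stand$covers, cores = cores,
                        extent_m = ext)
  attr(out, "config") <- cfg
  out
}

#' Rasterize a stand into a canopy scene with a historical mask
#'
#' Crowns are drawn as filled ellipses of the tree's canopy area with
#' random orientation and mild eccentricity (<= 1.3); the historical mask
#' marks pixels further than `buffer_m` from any crown of a tree
#' established before `mask_cutoff_year` (i.e. open, woody-plant-free
#' ground at that date).
#'
#' @param stand A [plot_inventory()].
#' @param res_m Pixel size in m (default 1).
#' @param mask_cutoff_year Historical photo date (default 1937); `NULL`
#'   for no mask.
#' @param buffer_m Dilation (m) of historical crowns when building the
#'   open mask (default 2).
#' @param max_eccentricity Upper bound on crown axis ratio.
#' @return A [raster_scene()].
#' @export
render_scene <- function(stand, res_m = 1, mask_cutoff_year = 1937,
                         buffer_m = 2, max_eccentricity = 1.3) {
  stopifnot(inherits(stand, "plot_inventory"))
  if (res_m <= 0) stop("res_m must be positive")
  cfg <- attr(stand, "config")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sub_seed(if (is.null(cfg)) 0L else cfg$seed, "scene",
                    stand$plot_id))
  ext <- stand$extent_m
  nc <- ceiling(ext[1] / res_m)
  nr <- ceiling(ext[2] / res_m)
  canopy <- matrix(0, nr, nc)
  trees <- stand$trees
  px <- (seq_len(nc) - 0.5) * res_m
  py <- (seq_len(nr) - 0.5) * res_m
  ecc <- if (nrow(trees)) {
    stats::runif(nrow(trees), 1, max_eccentricity)
  } else {
    numeric(0)
  }
  ang <- if (nrow(trees)) stats::runif(nrow(trees), 0, pi) else numeric(0)
  hist_mask <- matrix(1, nr, nc)
  for (i in seq_len(nrow(trees))) {
    area <- trees$canopy_area_m2[i]
    if (area <= 0) next
    # ellipse with same area: semi-axes a = r*sqrt(e), b = r/sqrt(e)
    r <- sqrt(area / pi)
    a <- r * sqrt(ecc[i])
    b <- r / sqrt(ecc[i])
    reach <- a + res_m
    xi <- which(abs(px - trees$x_m[i]) <= reach)
    yi <- which(abs(py - trees$y_m[i]) <= reach)
    if (!length(xi) || !length(yi)) next
    dx <- outer(rep(1, length(yi)), px[xi] - trees$x_m[i])
    dy <- outer(py[yi] - trees$y_m[i], rep(1, length(xi)))
    u <- dx * cos(ang[i]) + dy * sin(ang[i])
    v <- -dx * sin(ang[i]) + dy * cos(ang[i])
    inside <- (u / a)^2 + (v / b)^2 <= 1
    canopy[yi, xi][inside] <- 1
    if (!is.null(mask_cutoff_year) &&
        !is.na(trees$establishment_year[i]) &&
        trees$establishment_year[i] < mask_cutoff_year) {
      reach2 <- a + buffer_m + res_m
      xi2 <- which(abs(px - trees$x_m[i]) <= reach2)
      yi2 <- which(abs(py - trees$y_m[i]) <= reach2)
      dx2 <- outer(rep(1, length(yi2)), px[xi2] - trees$x_m[i])
      dy2 <- outer(py[yi2] - trees$y_m[i], rep(1, length(xi2)))
      u2 <- dx2 * cos(ang[i]) + dy2 * sin(ang[i])
      v2 <- -dx2 * sin(ang[i]) + dy2 * cos(ang[i])
      closed <- (u2 / (a + buffer_m))^2 + (v2 / (b + buffer_m))^2 <= 1
      hist_mask[yi2, xi2][closed] <- 0
    }
  }
  raster_scene(canopy, if (is.null(mask_cutoff_year)) NULL else hist_mask,
               res_m)
}

#' Built-in fixture configurations emulating the four study plots
#'
#' Ready-made [stand_config()]s for an un-encroached sagebrush plot
#' (`HSC`: no trees beyond a handful of juniper saplings), low- and
#' high-density encroached plots (`LD`, `HD`), a dieback plot (`PJD`, 90%
#' mortality in 2003), and a 25-ha `landscape`.
#'
#' @param plot `"HSC"`, `"LD"`, `"HD"`, `"PJD"` or `"landscape"`.
#' @param seed Integer seed.
#' @return A [stand_config()].
#' @export
fixture_config <- function(plot = c("HSC", "LD", "HD", "PJD", "landscape"),
                           seed = 1) {
  plot <- match.arg(plot)
  switch(plot,
    HSC = stand_config(seed, target_density_stems_ha = 133,
                       pinon_fraction = 0, rcd_meanlog = log(1.5),
                       rcd_sdlog = 0.2,
                       pulse = c("1990" = 1)),
    LD = stand_config(seed, target_density_stems_ha = 1033,
                      rcd_meanlog = log(10.64) - 0.4^2 / 2,
                      oldest_tree_year = 1891),
    HD = stand_config(seed, target_density_stems_ha = 1400,
                      rcd_meanlog = log(13.70) - 0.4^2 / 2,
                      oldest_tree_year = 1906),
    PJD = stand_config(seed, target_density_stems_ha = 1000,
                       rcd_meanlog = log(8.54) - 0.4^2 / 2,
                       mortality = list(year = 2003, fraction = 0.9),
                       oldest_tree_year = 1901),
    landscape = stand_config(seed, extent_m = c(500, 500),
                             target_density_stems_ha = 120,
                             cluster = list(parent_intensity_ha = 25,
                                            sigma_m = 6))
  )
}
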