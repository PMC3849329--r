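#' Establishment year from an increment core date
#'
#' Cores are taken 10-15 cm above ground, so the innermost ring postdates
#' germination; regional seedling surveys put the mean time to coring
#' height at about 11 years, which is subtracted from the inner-ring date.
#'
#' @param inner_ring_year Calendar year of the innermost ring. Vectorised.
#' @param coring_height_correction_yr Years to subtract (default 11).
#' @return Estimated establishment (germination) year.
#' @examples
#' establishment_year(1956) # 1945
#' @export
establishment_year <- function(inner_ring_year,
                               coring_height_correction_yr = 11) {
  stopifnot(all(is.finite(inner_ring_year)))
  inner_ring_year - coring_height_correction_yr
}

#' Juniper age from root collar diameter
#'
#' Junipers are rarely datable by coring; age is predicted from RCD with a
#' regional regression, age = 2.82 RCD + 19.8 (r^2 = 0.62), rounded to
#' whole years.
#'
#' @param rcd_cm Root collar diameter in cm (> 0). Vectorised.
#' @param slope,intercept Regression coefficients (yr cm^-1, yr).
#' @return Age in whole years.
#' @examples
#' juniper_age(10) # 48
#' @export
juniper_age <- function(rcd_cm, slope = 2.82, intercept = 19.8) {
  if (any(!is.finite(rcd_cm)) || any(rcd_cm <= 0)) {
    stop("rcd_cm must be positive")
  }
  round(slope * rcd_cm + intercept)
}

#' Mean annual carbon increment of a tree
#'
#' Total tree carbon divided by tree age. Ring-width series at these sites
#' show no consistent age trend that a simple decay model could capture,
#' so growth is spread evenly over the tree's life.
#'
#' @param total_tree_c_kg Total aboveground carbon at the end of the
#'   tree's life or of the record (kg), >= 0.
#' @param age_yr Tree age in years (>= 1).
#' @return kg C per year.
#' @examples
#' annual_increment(10, 50) # 0.2
#' @export
annual_increment <- function(total_tree_c_kg, age_yr) {
  if (any(!is.finite(age_yr)) || any(age_yr < 1)) {
    stop("age_yr must be >= 1")
  }
  if (any(total_tree_c_kg < 0)) stop("total_tree_c_kg must be >= 0")
  total_tree_c_kg / age_yr
}

#' Annual aboveground carbon accumulation trajectory for a plot
#'
#' Builds the year-by-year live, dead and understory aboveground carbon
#' series for one plot. Each tree contributes a constant annual increment
#' (its total carbon divided by its lifespan) from its establishment year.
#' At a mortality year the dying tree's accumulated carbon moves to the
#' dead pool (after that year's increment), minus the green-biomass
#' fraction lost on death for pinon; its growth then stops and the dead
#' pool does not decay. Understory carbon declines with cumulative
#' recruited tree density following the understory regression, rescaled so
#' that the pre-encroachment density maps onto `initial_understory_c`
#' (raw-formula mode is available but does not reproduce observed stocks;
#' the published regression's units are underdetermined).
#'
#' @param trees Data frame with `species`, `status`, `rcd_cm`,
#'   `establishment_year`, and `death_year` for dead trees. Trees
#'   establishing after `end_year` are dropped with a warning.
#' @param area_m2 Plot area (m^2), default 300.
#' @param start_year First year of the series; default the earliest
#'   establishment year.
#' @param end_year Last year (default 2005). Live trees' total carbon is
#'   attained at `end_year`; dead trees' at their death year.
#' @param initial_understory_c Pre-encroachment understory carbon
#'   (kg C m^-2) anchoring the understory series (default 0.416, a
#'   sagebrush-grassland baseline).
#' @param understory List: `slope` (-0.516), `intercept` (137.9),
#'   `density_unit` ("per_plot" or "per_ha"), `mode` ("rescaled" or
#'   "raw"). Raw mode returns the regression output directly (its unit is
#'   then g C m^-2 at face value, stored unconverted).
#' @param models Allometric registry for carbon conversion.
#' @return Data frame of class `accumulation_trajectory`: `year`,
#'   `live_tree_c`, `dead_tree_c`, `understory_c`, `total_above_c`
#'   (kg C m^-2), with the tree table (per-tree carbon and increments) as
#'   attribute `trees`.
#' @export
accumulation_trajectory <- function(trees, area_m2 = 300,
                                    start_year = NULL, end_year = 2005,
                                    initial_understory_c = 0.416,
                                    understory = list(),
                                    models = allometric_models()) {
  und <- utils::modifyList(
    list(slope = -0.516, intercept = 137.9,
         density_unit = "per_plot", mode = "rescaled"),
    understory
  )
  stopifnot(nrow(trees) > 0,
            all(is.finite(trees$establishment_year)))
  late <- trees$establishment_year > end_year
  if (any(late)) {
    warning(sum(late), " tree(s) establish after end_year: excluded")
    trees <- trees[!late, , drop = FALSE]
  }
  if (is.null(start_year)) start_year <- min(trees$establishment_year)
  stopifnot(start_year <= end_year)

  # per-tree carbon at end of life: live allometry through death
  # (standing-dead trees are treated as live until their death year)
  live_bm <- tree_biomass_rcd(trees$rcd_cm, trees$species, "live")
  pc <- ifelse(trees$species == "pinon",
               models$pinon_live$percent_c, models$juniper$percent_c)
  live_c <- biomass_to_carbon(live_bm, pc)
  dead_bm <- tree_biomass_rcd(trees$rcd_cm, trees$species, "dead")
  dead_c <- biomass_to_carbon(dead_bm, pc)
  stop_year <- ifelse(trees$status == "dead", trees$death_year, end_year)
  if (any(stop_year < trees$establishment_year)) {
    stop("death_year precedes establishment_year")
  }
  lifespan <- stop_year - trees$establishment_year + 1
  inc <- annual_increment(live_c, lifespan)

  years <- start_year:end_year
  live <- dead <- numeric(length(years))
  for (i in seq_along(years)) {
    t <- years[i]
    grown <- pmin(pmax(t - trees$establishment_year + 1, 0),
                  lifespan)
    ctree <- inc * grown
    dead_now <- trees$status == "dead" & !is.na(trees$death_year) &
      trees$death_year <= t
    # on death the green-biomass carbon is lost; the rest stands dead
    dead[i] <- sum(ctree[dead_now] * dead_c[dead_now] / live_c[dead_now])
    live[i] <- sum(ctree[!dead_now])
  }
  live <- live / area_m2
  dead <- dead / area_m2

  dens <- vapply(years, function(t) {
    sum(trees$establishment_year <= t)
  }, numeric(1))
  if (und$density_unit == "per_ha") dens <- dens / area_m2 * 1e4
  raw0 <- und$intercept # pre-encroachment density is zero
  raw <- pmax(0, und$intercept + und$slope * dens)
  under <- if (und$mode == "rescaled") {
    initial_understory_c * raw / raw0
  } else {
    raw
  }
  out <- data.frame(
    year = years, live_tree_c = live, dead_tree_c = dead,
    understory_c = under, total_above_c = live + dead + under
  )
  attr(out, "trees") <- data.frame(
    trees, total_c_kg = live_c, dead_c_kg = dead_c,
    lifespan_yr = lifespan, increment_kg_yr = inc
  )
  attr(out, "area_m2") <- area_m2
  class(out) <- c("accumulation_trajectory", "data.frame")
  out
}

#' Write an accumulation trajectory as tidy CSV
#'
#' One row per plot-year-pool, kg C m^-2, ready for plotting.
#'
#' @param trajectory An [accumulation_trajectory()].
#' @param plot_id Plot label for the `plot` column.
#' @param path Output CSV path, or `NULL` to return the tidy frame.
#' @return The tidy data frame, invisibly when written.
#' @export
write_trajectory_csv <- function(trajectory, plot_id, path = NULL) {
  pools <- c("live_tree_c", "dead_tree_c", "understory_c", "total_above_c")
  tidy <- do.call(rbind, lapply(pools, function(p) {
    data.frame(plot = plot_id, year = trajectory$year, pool = p,
               kg_c_m2 = trajectory[[p]])
  }))
  if (is.null(path)) {
    return(tidy)
  }
  utils::write.csv(tidy, path, row.names = FALSE)
  invisible(tidy)
}
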