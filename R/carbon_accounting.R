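#' Assemble a plot inventory
#'
#' Bundles the three field tables collected on one plot — the tree tally,
#' the subplot cover observations, and the soil cores — and validates that
#' all coordinates fall inside the plot extent.
#'
#' @param plot_id Plot label (e.g. `"HSC"`, `"LD"`, `"HD"`, `"PJD"`).
#' @param trees Data frame with columns `id`, `species` ("pinon"/"juniper"),
#'   `status` ("live"/"dead"), `rcd_cm`, `canopy_area_m2`, `x_m`, `y_m` and
#'   optionally `establishment_year`, `death_year`. May have zero rows.
#' @param covers Data frame with columns `subplot_id`, `group` (subplots in
#'   the same group are averaged before plot means are taken), `x_m`, `y_m`,
#'   and the cover classes `grass`, `sagebrush`, `duff_litter`, `bareground`
#'   in percent.
#' @param cores Data frame with columns `id`, `x_m`, `y_m`, `layer`
#'   ("duff"/"mineral"), `bulk_density_g_cm3`, `depth_cm`,
#'   `percent_c_measured`, `percent_carbonate`, or `NULL` when no soil
#'   survey exists.
#' @param extent_m Plot dimensions c(width, height) in m; default the
#'   15 x 20 m (300 m^2) field layout.
#' @return An object of class `plot_inventory`.
#' @export
plot_inventory <- function(plot_id, trees = NULL, covers = NULL,
                           cores = NULL, extent_m = c(15, 20)) {
  stopifnot(length(extent_m) == 2, all(extent_m > 0))
  empty_trees <- data.frame(
    id = character(), species = character(), status = character(),
    rcd_cm = numeric(), canopy_area_m2 = numeric(),
    x_m = numeric(), y_m = numeric(),
    establishment_year = integer(), death_year = integer(),
    stringsAsFactors = FALSE
  )
  if (is.null(trees)) trees <- empty_trees
  if (nrow(trees)) {
    stopifnot(all(c("species", "status", "rcd_cm", "x_m", "y_m") %in%
                    names(trees)))
    stopifnot(all(trees$species %in% c("pinon", "juniper")),
              all(trees$status %in% c("live", "dead")),
              all(trees$rcd_cm > 0))
    check_extent(trees$x_m, trees$y_m, extent_m, "trees")
    if (is.null(trees$death_year)) trees$death_year <- NA_integer_
    if (any(trees$status == "dead" & is.na(trees$death_year))) {
      stop("dead trees must carry a death_year")
    }
  }
  if (!is.null(covers) && nrow(covers)) {
    cls <- c("grass", "sagebrush", "duff_litter", "bareground")
    stopifnot(all(cls %in% names(covers)))
    vals <- unlist(covers[cls])
    if (any(vals < 0 | vals > 100, na.rm = TRUE)) {
      stop("cover percentages must lie in [0, 100]")
    }
    if (is.null(covers$group)) covers$group <- covers$subplot_id
    if (all(c("x_m", "y_m") %in% names(covers))) {
      check_extent(covers$x_m, covers$y_m, extent_m, "covers")
    }
  }
  if (!is.null(cores) && nrow(cores)) {
    stopifnot(all(c("layer", "bulk_density_g_cm3", "depth_cm",
                    "percent_c_measured", "percent_carbonate") %in%
                    names(cores)))
    stopifnot(all(cores$layer %in% c("duff", "mineral")))
    if (any(cores$depth_cm[cores$layer == "mineral"] > 10)) {
      stop("mineral cores sample the 0-10 cm layer; depth_cm must be <= 10")
    }
    check_extent(cores$x_m, cores$y_m, extent_m, "cores")
  }
  structure(
    list(plot_id = plot_id, extent_m = extent_m, trees = trees,
         covers = covers, cores = cores),
    class = "plot_inventory"
  )
}

check_extent <- function(x, y, extent_m, what) {
  if (any(x < 0 | x > extent_m[1] | y < 0 | y > extent_m[2], na.rm = TRUE)) {
    stop(what, " coordinates fall outside the plot extent")
  }
  invisible(TRUE)
}

#' @export
print.plot_inventory <- function(x, ...) {
  cat("<plot_inventory> ", x$plot_id, ": ",
      nrow(x$trees), " trees, ",
      if (is.null(x$covers)) 0L else nrow(x$covers), " cover subplots, ",
      if (is.null(x$cores)) 0L else nrow(x$cores), " soil cores on ",
      x$extent_m[1], " x ", x$extent_m[2], " m\n", sep = "")
  invisible(x)
}

#' Carbonate-correct a measured percent carbon
#'
#' Combustion %C measured on acidified (carbonate-free) sub-samples is
#' rescaled back to the whole-soil mass basis using the sample-specific
#' carbonate content: \%C_whole = \%C_measured x (1 - CO3/100). This is the
#' only direction that keeps organic C at or below the measured value while
#' using the per-sample calcimeter carbonate.
#'
#' @param percent_c_measured Percent C after acidification, in \[0, 100\].
#' @param percent_carbonate Percent CaCO3-equivalent, in \[0, 100\].
#' @return Organic percent C on the whole-soil basis.
#' @examples
#' carbonate_corrected_percent_c(1.0, 2.99) # 0.9701
#' @export
carbonate_corrected_percent_c <- function(percent_c_measured,
                                          percent_carbonate) {
  bad <- function(v) any(!is.finite(v)) || any(v < 0) || any(v > 100)
  if (bad(percent_c_measured) || bad(percent_carbonate)) {
    stop("percent values must lie in [0, 100]")
  }
  percent_c_measured * (1 - percent_carbonate / 100)
}

#' Areal carbon stock of one soil core
#'
#' Converts a bulk density, sampling depth and (carbonate-corrected)
#' percent C into an areal stock:
#' kg C m^-2 = BD (g cm^-3) x depth (cm) x \%C/100 x 10,
#' the factor 10 converting g cm^-2 to kg m^-2.
#'
#' @param bulk_density_g_cm3 Bulk density, g cm^-3 (> 0).
#' @param depth_cm Layer thickness sampled, cm (> 0).
#' @param percent_c_measured Percent C of the (acidified) sample.
#' @param percent_carbonate Percent carbonate used for the correction
#'   (default 0 = already corrected).
#' @param core Alternatively, a data frame (rows of a `cores` table) whose
#'   columns supply the four arguments.
#' @return kg C m^-2 for each core.
#' @examples
#' soil_layer_carbon(1.0, 10, 1) # 1 kg C m^-2
#' @export
soil_layer_carbon <- function(bulk_density_g_cm3, depth_cm,
                              percent_c_measured, percent_carbonate = 0,
                              core = NULL) {
  if (!is.null(core)) {
    bulk_density_g_cm3 <- core$bulk_density_g_cm3
    depth_cm <- core$depth_cm
    percent_c_measured <- core$percent_c_measured
    percent_carbonate <- core$percent_carbonate
  }
  if (any(!is.finite(bulk_density_g_cm3)) || any(bulk_density_g_cm3 <= 0) ||
      any(!is.finite(depth_cm)) || any(depth_cm < 0)) {
    stop("bulk density and depth must be present and positive")
  }
  pc <- carbonate_corrected_percent_c(percent_c_measured, percent_carbonate)
  bulk_density_g_cm3 * depth_cm * pc / 100 * 10
}

#' Plot-level cover and inventory summary
#'
#' Mean fractional cover by class with standard errors, live-stem density,
#' and mean basal canopy area and RCD for one plot. Subplot covers are
#' first averaged within their `group` (the four 1 m^2 corners of each
#' 5 m^2 subplot in the field layout); means and SEs are then taken over
#' group means.
#'
#' @param inventory A [plot_inventory()].
#' @return A list with `cover` (data frame: class, mean, se, n),
#'   `density_stems_ha` (live stems per hectare), `n_trees`,
#'   `mean_bca_m2` and `mean_rcd_cm`.
#' @export
plot_cover_summary <- function(inventory) {
  stopifnot(inherits(inventory, "plot_inventory"))
  covers <- inventory$covers
  if (is.null(covers) || !nrow(covers)) {
    stop("inventory has no cover observations")
  }
  cls <- c("grass", "sagebrush", "duff_litter", "bareground")
  grp <- lapply(cls, function(cl) {
    tapply(covers[[cl]], covers$group, mean, na.rm = TRUE)
  })
  cover <- data.frame(
    class = cls,
    mean = vapply(grp, mean, numeric(1), na.rm = TRUE),
    se = vapply(grp, function(g) stats::sd(g, na.rm = TRUE) /
                  sqrt(sum(!is.na(g))), numeric(1)),
    n = vapply(grp, function(g) sum(!is.na(g)), integer(1)),
    row.names = NULL
  )
  area_m2 <- prod(inventory$extent_m)
  trees <- inventory$trees
  live <- trees[trees$status == "live", , drop = FALSE]
  list(
    plot_id = inventory$plot_id,
    cover = cover,
    density_stems_ha = nrow(live) / area_m2 * 1e4,
    n_trees = nrow(trees),
    mean_bca_m2 = if (nrow(trees)) mean(trees$canopy_area_m2) else NA_real_,
    mean_rcd_cm = if (nrow(trees)) mean(trees$rcd_cm) else NA_real_
  )
}

#' Construct a per-plot, per-pool carbon stock table
#'
#' Validates a long ledger of carbon pools and (re)computes the `total`
#' row for each plot as the sum of the five pools.
#'
#' @param x Data frame with columns `plot`, `pool` (one of `pj_tree`,
#'   `sagebrush`, `grass`, `duff_litter`, `mineral_soil`), `kg_c_m2` and
#'   optionally `se`.
#' @return A `carbon_stock_table` data frame including `total` rows.
#' @export
carbon_stock_table <- function(x) {
  pools <- c("pj_tree", "sagebrush", "grass", "duff_litter", "mineral_soil")
  stopifnot(all(c("plot", "pool", "kg_c_m2") %in% names(x)))
  x <- x[x$pool != "total", , drop = FALSE]
  if (!all(x$pool %in% pools)) stop("unknown pool name")
  if (any(x$kg_c_m2 < 0, na.rm = TRUE)) stop("pool stocks must be >= 0")
  if (is.null(x$se)) x$se <- NA_real_
  tot <- do.call(rbind, lapply(split(x, x$plot), function(d) {
    data.frame(plot = d$plot[1], pool = "total",
               kg_c_m2 = sum(d$kg_c_m2, na.rm = TRUE), se = NA_real_)
  }))
  out <- rbind(x[c("plot", "pool", "kg_c_m2", "se")], tot)
  rownames(out) <- NULL
  class(out) <- c("carbon_stock_table", "data.frame")
  out
}

#' Carbon stock ledger for a set of plots
#'
#' Computes the per-plot, per-pool carbon ledger from field inventories:
#' \describe{
#'   \item{pj_tree}{sum of per-tree RCD-allometry carbon (status- and
#'     species-aware) divided by plot area (no SE: a plot-level census)}
#'   \item{sagebrush, grass}{cover regression applied to group-mean cover,
#'     times percent C; SE propagated from cover group means}
#'   \item{duff_litter}{per-point [soil_layer_carbon()] of duff cores
#'     averaged over all sampled points, points without a duff layer
#'     contributing 0}
#'   \item{mineral_soil}{mean of mineral-core stocks}
#' }
#' Pool totals are appended per plot.
#'
#' @param inventories A list of [plot_inventory()] objects (or one).
#' @param models Allometric model registry, default [allometric_models()].
#' @param cover_basis Multiplier from the cover-regression biomass unit to
#'   g m^-2 (default 1: slopes are read as g m^-2 per percent cover).
#' @return A [carbon_stock_table()].
#' @export
plot_carbon_table <- function(inventories, models = allometric_models(),
                              cover_basis = 1) {
  if (inherits(inventories, "plot_inventory")) {
    inventories <- list(inventories)
  }
  rows <- lapply(inventories, function(inv) {
    area <- prod(inv$extent_m)
    trees <- inv$trees
    tree_c <- 0
    if (nrow(trees)) {
      bm <- tree_biomass_rcd(trees$rcd_cm, trees$species, trees$status)
      pc <- ifelse(trees$species == "pinon",
                   models$pinon_live$percent_c, models$juniper$percent_c)
      tree_c <- sum(biomass_to_carbon(bm, pc)) / area
    }
    if (is.null(inv$covers) || !nrow(inv$covers)) {
      stop("plot ", inv$plot_id, " has no cover observations")
    }
    cov <- plot_cover_summary(inv)$cover
    und <- function(class, model) {
      m <- cov$mean[cov$class == class]
      s <- cov$se[cov$class == class]
      g_c <- biomass_to_carbon(
        understory_biomass(m, models[[model]]) * cover_basis,
        models[[model]]$percent_c
      )
      se_c <- models[[model]]$coefficients[["slope"]] * cover_basis *
        models[[model]]$percent_c / 100 * s / 1000
      c(kg = g_c / 1000, se = unname(se_c)) # g m^-2 -> kg m^-2
    }
    sage <- und("sagebrush", "sagebrush")
    grass <- und("grass", "grass")
    duff <- mineral <- c(kg = NA_real_, se = NA_real_)
    cores <- inv$cores
    if (!is.null(cores) && nrow(cores)) {
      min_cores <- cores[cores$layer == "mineral", , drop = FALSE]
      if (nrow(min_cores)) {
        v <- soil_layer_carbon(core = min_cores)
        mineral <- c(kg = mean(v), se = stats::sd(v) / sqrt(length(v)))
      }
      duff_cores <- cores[cores$layer == "duff", , drop = FALSE]
      # duff is patchy: points with no duff layer enter the plot mean as 0
      n_pts <- max(nrow(min_cores), nrow(duff_cores))
      if (n_pts > 0) {
        v <- c(if (nrow(duff_cores)) soil_layer_carbon(core = duff_cores),
               rep(0, n_pts - nrow(duff_cores)))
        duff <- c(kg = mean(v), se = stats::sd(v) / sqrt(length(v)))
      }
    }
    data.frame(
      plot = inv$plot_id,
      pool = c("pj_tree", "sagebrush", "grass", "duff_litter",
               "mineral_soil"),
      kg_c_m2 = c(tree_c, sage[["kg"]], grass[["kg"]], duff[["kg"]],
                  mineral[["kg"]]),
      se = c(NA_real_, sage[["se"]], grass[["se"]], duff[["se"]],
             mineral[["se"]])
    )
  })
  long <- do.call(rbind, rows)
  long_na <- long[is.na(long$kg_c_m2), , drop = FALSE]
  long_ok <- long[!is.na(long$kg_c_m2), , drop = FALSE]
  out <- carbon_stock_table(long_ok)
  if (nrow(long_na)) {
    out <- rbind(out, long_na)
    class(out) <- c("carbon_stock_table", "data.frame")
  }
  out
}

#' Carbon stock changes relative to an un-encroached reference plot
#'
#' Differences each plot against a reference plot (the historic sagebrush
#' condition): per-plot aboveground deltas (tree + sagebrush + grass),
#' aboveground-plus-duff deltas, and the mean per-pool delta across the
#' non-reference plots.
#'
#' @param table A [carbon_stock_table()].
#' @param reference_plot Plot label present in `table`.
#' @return A list with `per_plot` (data frame: plot, aboveground_delta,
#'   above_duff_delta, total_delta, all kg C m^-2 relative to the
#'   reference) and `mean_pool_delta` (named vector over pools, mean over
#'   non-reference plots).
#' @export
stock_deltas <- function(table, reference_plot) {
  stopifnot(inherits(table, "carbon_stock_table") || is.data.frame(table))
  if (!reference_plot %in% table$plot) {
    stop("reference plot not present in the table")
  }
  get <- function(plot, pool) {
    v <- table$kg_c_m2[table$plot == plot & table$pool == pool]
    if (!length(v)) NA_real_ else v
  }
  plots <- unique(table$plot)
  above <- function(p) {
    sum(get(p, "pj_tree"), get(p, "sagebrush"), get(p, "grass"))
  }
  ref_above <- above(reference_plot)
  ref_duff <- get(reference_plot, "duff_litter")
  per_plot <- data.frame(
    plot = plots,
    aboveground_delta = vapply(plots, function(p) above(p) - ref_above,
                               numeric(1)),
    above_duff_delta = vapply(plots, function(p) {
      above(p) + get(p, "duff_litter") - ref_above - ref_duff
    }, numeric(1)),
    total_delta = vapply(plots, function(p) {
      get(p, "total") - get(reference_plot, "total")
    }, numeric(1)),
    row.names = NULL
  )
  pools <- setdiff(unique(table$pool), "total")
  others <- setdiff(plots, reference_plot)
  mean_pool_delta <- vapply(pools, function(pl) {
    mean(vapply(others, function(p) get(p, pl), numeric(1))) -
      get(reference_plot, pl)
  }, numeric(1))
  list(per_plot = per_plot, mean_pool_delta = mean_pool_delta,
       reference_plot = reference_plot)
}

#' Read a plot inventory from a directory of CSV files
#'
#' Expects `trees.csv`, `covers.csv` and `cores.csv` (each optional except
#' covers for downstream stock tables) with the column layouts documented
#' in [plot_inventory()]. Units: m for coordinates, cm for RCD and depths,
#' m^2 for canopy areas, g cm^-3 for bulk density, percent for cover,
#' carbon and carbonate.
#'
#' @param dir Directory containing the CSV files.
#' @param plot_id Plot label; default the directory basename.
#' @param extent_m Plot extent, as in [plot_inventory()].
#' @return A [plot_inventory()].
#' @export
read_inventory_csv <- function(dir, plot_id = basename(dir),
                               extent_m = c(15, 20)) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) {
      utils::read.csv(p, stringsAsFactors = FALSE)
    } else {
      NULL
    }
  }
  plot_inventory(plot_id, trees = rd("trees.csv"), covers = rd("covers.csv"),
                 cores = rd("cores.csv"), extent_m = extent_m)
}

#' Write a plot inventory to CSV files
#'
#' Inverse of [read_inventory_csv()].
#'
#' @param inventory A [plot_inventory()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_inventory_csv <- function(inventory, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, f) {
    if (!is.null(d) && nrow(d)) {
      utils::write.csv(d, file.path(dir, f), row.names = FALSE)
    }
  }
  wr(inventory$trees, "trees.csv")
  wr(inventory$covers, "covers.csv")
  wr(inventory$cores, "cores.csv")
  invisible(dir)
}

#' Export a carbon stock table in wide (plots-as-columns) layout
#'
#' @param table A [carbon_stock_table()].
#' @param path Output CSV path, or `NULL` to return the wide data frame.
#' @return The wide data frame (pool rows, one column per plot), invisibly
#'   when written.
#' @export
write_stock_table_csv <- function(table, path = NULL) {
  pools <- c("pj_tree", "sagebrush", "grass", "duff_litter",
             "mineral_soil", "total")
  plots <- unique(table$plot)
  wide <- data.frame(pool = pools)
  for (p in plots) {
    wide[[p]] <- vapply(pools, function(pl) {
      v <- table$kg_c_m2[table$plot == p & table$pool == pl]
      if (!length(v)) NA_real_ else v
    }, numeric(1))
  }
  if (is.null(path)) {
    return(wide)
  }
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(wide)
}
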