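#' Construct a raster scene
#'
#' A scene is a canopy raster (numeric matrix; rows index y from the
#' origin upward, columns index x) at a fixed resolution, with an optional
#' aligned historical open-area mask (1 = open / woody-plant free at the
#' historical date, 0 otherwise). Values are canopy presence (0/1) or
#' cover fraction per pixel.
#'
#' @param canopy Numeric matrix of canopy presence/fraction.
#' @param mask Optional 0/1 matrix with identical dimensions.
#' @param res_m Pixel edge length in m (default 1).
#' @return An object of class `raster_scene`.
#' @export
raster_scene <- function(canopy, mask = NULL, res_m = 1) {
  stopifnot(is.matrix(canopy), res_m > 0)
  if (!length(canopy)) stop("scene is empty")
  if (!is.null(mask)) {
    stopifnot(is.matrix(mask), all(dim(mask) == dim(canopy)),
              all(mask %in% c(0, 1)))
  }
  structure(list(canopy = canopy, mask = mask, res_m = res_m),
            class = "raster_scene")
}

#' @export
print.raster_scene <- function(x, ...) {
  cat("<raster_scene> ", ncol(x$canopy) * x$res_m, " x ",
      nrow(x$canopy) * x$res_m, " m at ", x$res_m, " m; canopy cover ",
      round(100 * mean(x$canopy > 0), 1), "%",
      if (!is.null(x$mask)) {
        paste0("; open mask ", round(100 * mean(x$mask), 1), "%")
      },
      "\n", sep = "")
  invisible(x)
}

# 8-connected component labelling via union-find (vectorised pair
# generation; path-compressed find)
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) {
    return(matrix(0L, nr, nc))
  }
  parent <- seq_len(nr * nc)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  row_i <- ((idx - 1L) %% nr) + 1L
  col_i <- ((idx - 1L) %/% nr) + 1L
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (s in shifts) {
    r2 <- row_i + s[1]
    c2 <- col_i + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    src <- idx[ok][mask[nb]]
    dst <- nb[mask[nb]]
    for (k in seq_along(src)) {
      a <- find(src[k])
      b <- find(dst[k])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(idx, find, integer(1))
  lab <- matrix(0L, nr, nc)
  lab[idx] <- match(roots, unique(roots))
  lab
}

#' Delineate canopies from a raster scene
#'
#' A transparent stand-in for object-based image segmentation: pixels at
#' or above `threshold` are canopy, 8-connected components become
#' individual (or clumped) canopies, and components smaller than
#' `min_area_m2` are dropped as noise.
#'
#' @param scene A [raster_scene()].
#' @param threshold Canopy threshold on pixel values (default 0.5).
#' @param min_area_m2 Minimum retained canopy area (default 1 m^2).
#' @return A `canopy_map`: data frame with `id`, `area_m2`, `centroid_x_m`,
#'   `centroid_y_m`, carrying the labelled pixel matrix as attribute
#'   `labels`, the resolution as `res_m` and the extent area (ha) as
#'   `extent_ha`.
#' @export
delineate_canopies <- function(scene, threshold = 0.5, min_area_m2 = 1) {
  stopifnot(inherits(scene, "raster_scene"))
  mask <- scene$canopy >= threshold
  lab <- label_components(mask)
  res <- scene$res_m
  px_area <- res^2
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes * px_area < min_area_m2)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      lab[lab > 0] <- match(lab[lab > 0], sort(unique(lab[lab > 0])))
    }
  }
  n <- max(lab)
  if (n > 0) {
    idx <- which(lab > 0)
    li <- lab[idx]
    row_i <- ((idx - 1L) %% nrow(lab)) + 1L
    col_i <- ((idx - 1L) %/% nrow(lab)) + 1L
    # pixel centres: x from column, y from row
    cx <- tapply((col_i - 0.5) * res, li, mean)
    cy <- tapply((row_i - 0.5) * res, li, mean)
    area <- tabulate(li) * px_area
    map <- data.frame(id = seq_len(n), area_m2 = area,
                      centroid_x_m = as.numeric(cx),
                      centroid_y_m = as.numeric(cy))
  } else {
    map <- data.frame(id = integer(), area_m2 = numeric(),
                      centroid_x_m = numeric(), centroid_y_m = numeric())
  }
  attr(map, "labels") <- lab
  attr(map, "res_m") <- res
  attr(map, "extent_ha") <- length(scene$canopy) * px_area / 1e4
  class(map) <- c("canopy_map", "data.frame")
  map
}

#' Per-canopy and total carbon of a canopy map
#'
#' Applies the canopy-area allometry ([tree_biomass_canopy()]) to each
#' delineated canopy and converts biomass to carbon with the mean PJ
#' carbon fraction (0.46 by default).
#'
#' @param map A `canopy_map` from [delineate_canopies()], or any data
#'   frame with an `area_m2` column.
#' @param c_fraction Carbon fraction of dry biomass (default 0.46).
#' @return `map` with a `carbon_kg` column; total carbon as attribute
#'   `total_kg_c` (also retrievable by `sum(map$carbon_kg)`).
#' @export
canopy_map_carbon <- function(map, c_fraction = 0.46) {
  if (!nrow(map)) {
    map$carbon_kg <- numeric()
    attr(map, "total_kg_c") <- 0
    return(map)
  }
  if (any(map$area_m2 <= 0)) stop("zero-area canopy polygon")
  map$carbon_kg <- tree_biomass_canopy(map$area_m2) * c_fraction
  attr(map, "total_kg_c") <- sum(map$carbon_kg)
  map
}

#' Grid a canopy map into fixed-area cells
#'
#' Intersects canopy pixels with a regular grid of cells (default
#' 15 x 20 m = 300 m^2, matching the field plot geometry) and reports
#' per-cell canopy area and carbon. A canopy's carbon is apportioned to
#' cells proportionally to its pixel count in each cell, so the cell sums
#' conserve the map totals.
#'
#' @param map A `canopy_map` with `carbon_kg` (run [canopy_map_carbon()]
#'   first; without it carbon is reported as NA).
#' @param cell_m c(width, height) of a cell in m; default c(15, 20).
#' @return Data frame: `cell_x`, `cell_y` (cell indices from the origin),
#'   `canopy_area_m2`, `carbon_kg`.
#' @export
grid_canopy_summary <- function(map, cell_m = c(15, 20)) {
  lab <- attr(map, "labels")
  res <- attr(map, "res_m")
  stopifnot(!is.null(lab), !is.null(res), length(cell_m) == 2)
  if (any(cell_m > c(ncol(lab), nrow(lab)) * res)) {
    stop("grid cell larger than the scene extent")
  }
  ncx <- ceiling(ncol(lab) * res / cell_m[1])
  ncy <- ceiling(nrow(lab) * res / cell_m[2])
  idx <- which(lab > 0)
  li <- lab[idx]
  row_i <- ((idx - 1L) %% nrow(lab)) + 1L
  col_i <- ((idx - 1L) %/% nrow(lab)) + 1L
  cx <- pmin(floor((col_i - 0.5) * res / cell_m[1]) + 1L, ncx)
  cy <- pmin(floor((row_i - 0.5) * res / cell_m[2]) + 1L, ncy)
  cell_of <- (cy - 1L) * ncx + cx
  has_c <- "carbon_kg" %in% names(map)
  per_canopy_px <- tabulate(li, nbins = max(0, nrow(map)))
  key <- paste(li, cell_of)
  agg <- tapply(rep(res^2, length(idx)), key, sum)
  parts <- do.call(rbind, strsplit(names(agg), " "))
  can_id <- as.integer(parts[, 1])
  cell_id <- as.integer(parts[, 2])
  area_part <- as.numeric(agg)
  carbon_part <- if (has_c) {
    map$carbon_kg[can_id] * (area_part / res^2) / per_canopy_px[can_id]
  } else {
    NA_real_
  }
  cells <- expand.grid(cell_x = seq_len(ncx), cell_y = seq_len(ncy))
  cells$canopy_area_m2 <- 0
  cells$carbon_kg <- if (has_c) 0 else NA_real_
  pos <- (cell_id - 1L) %% ncx + 1L # recover indices
  cyi <- (cell_id - 1L) %/% ncx + 1L
  flat <- (cyi - 1L) * ncx + pos
  for (k in seq_along(flat)) {
    cells$canopy_area_m2[flat[k]] <- cells$canopy_area_m2[flat[k]] +
      area_part[k]
    if (has_c) {
      cells$carbon_kg[flat[k]] <- cells$carbon_kg[flat[k]] + carbon_part[k]
    }
  }
  cells
}

#' Scale a plot carbon stock to a landscape area
#'
#' Linear area scaling: Mg C = plot kg C x (landscape m^2 / plot m^2)
#' / 1000. The comparison of this naive scaling with image-based totals
#' quantifies the plot-selection bias in heterogeneous woodland.
#'
#' @param plot_c_kg Carbon measured on the plot (kg).
#' @param plot_area_m2 Plot area (m^2).
#' @param landscape_area_ha Landscape area (ha).
#' @return Carbon in Mg over the landscape.
#' @examples
#' scale_plot_to_landscape(937.49, 300, 25) # 781.2 Mg
#' @export
scale_plot_to_landscape <- function(plot_c_kg, plot_area_m2,
                                    landscape_area_ha) {
  if (any(plot_area_m2 <= 0) || any(landscape_area_ha <= 0)) {
    stop("areas must be positive")
  }
  plot_c_kg * (landscape_area_ha * 1e4 / plot_area_m2) / 1000
}

#' Encroachment accounting against a historical open-area mask
#'
#' Canopies whose centroid falls inside the historical woody-plant-free
#' mask are "new" since the historical date. Their carbon, expressed per
#' hectare of historically open area, divided by the photo interval gives
#' the annual accumulation rate attributable to encroachment.
#'
#' @param map A `canopy_map` with `carbon_kg`.
#' @param scene The [raster_scene()] carrying the historical mask.
#' @param span_years Years between the historical and modern imagery.
#' @return A list: `open_area_ha`, `fraction_open_occupied` (fraction of
#'   open-area pixels under canopy today), `n_new_canopies`,
#'   `new_trees_per_ha`, `new_carbon_mg_per_ha`, `span_years`,
#'   `annual_rate_mg_per_ha_yr`, `total_new_carbon_mg`.
#' @export
encroachment_account <- function(map, scene, span_years) {
  stopifnot(inherits(scene, "raster_scene"), span_years > 0)
  mask <- scene$mask
  if (is.null(mask) || !any(mask == 1)) {
    stop("scene has no historical open area")
  }
  res <- scene$res_m
  open_area_ha <- sum(mask) * res^2 / 1e4
  lab <- attr(map, "labels")
  if (nrow(map)) {
    ci <- pmin(pmax(ceiling(map$centroid_x_m / res), 1L), ncol(mask))
    ri <- pmin(pmax(ceiling(map$centroid_y_m / res), 1L), nrow(mask))
    new <- mask[cbind(ri, ci)] == 1
  } else {
    new <- logical(0)
  }
  total_new_kg <- if (any(new)) sum(map$carbon_kg[new]) else 0
  occupied <- if (!is.null(lab)) {
    sum(mask == 1 & lab > 0) / sum(mask)
  } else {
    NA_real_
  }
  new_c_mg_ha <- total_new_kg / 1000 / open_area_ha
  list(
    open_area_ha = open_area_ha,
    fraction_open_occupied = occupied,
    n_new_canopies = sum(new),
    new_trees_per_ha = sum(new) / open_area_ha,
    new_carbon_mg_per_ha = new_c_mg_ha,
    span_years = span_years,
    annual_rate_mg_per_ha_yr = new_c_mg_ha / span_years,
    total_new_carbon_mg = total_new_kg / 1000
  )
}

#' Percent difference of plot-scaled estimates against an image estimate
#'
#' 100 x (mean(plot estimates) - image estimate) / image estimate: how far
#' naive plot-to-landscape scaling departs from the density-aware
#' image-based total.
#'
#' @param plot_estimates_mg Vector of plot-scaled landscape estimates (Mg).
#' @param image_estimate_mg Image-segmentation landscape estimate (Mg, > 0).
#' @return Signed percent difference.
#' @examples
#' method_comparison(c(267, 781), 358.93) # ~46
#' @export
method_comparison <- function(plot_estimates_mg, image_estimate_mg) {
  if (!length(plot_estimates_mg)) stop("no plot estimates supplied")
  if (image_estimate_mg <= 0) stop("image estimate must be positive")
  100 * (mean(plot_estimates_mg) - image_estimate_mg) / image_estimate_mg
}

#' Read/write raster scenes as plain-text TSV grids
#'
#' Scenes serialise as tab-separated numeric grids (one row per raster
#' row); the mask, when present, goes to a sibling `*_mask.tsv` file.
#'
#' @param scene A [raster_scene()].
#' @param path Path to the canopy TSV.
#' @param res_m Resolution when reading (m).
#' @return `write_scene_tsv`: `path`, invisibly. `read_scene_tsv`: a
#'   [raster_scene()].
#' @export
write_scene_tsv <- function(scene, path) {
  utils::write.table(scene$canopy, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(scene$mask)) {
    utils::write.table(scene$mask, mask_path(path), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_scene_tsv
#' @export
read_scene_tsv <- function(path, res_m = 1) {
  canopy <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(canopy) <- NULL
  mask <- NULL
  if (file.exists(mask_path(path))) {
    mask <- as.matrix(utils::read.table(mask_path(path), sep = "\t"))
    dimnames(mask) <- NULL
  }
  raster_scene(canopy, mask, res_m)
}

mask_path <- function(path) {
  sub("(\\.[^.]+)?$", "_mask.tsv", path)
}
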