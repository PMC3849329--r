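#' Allometric model registry
#'
#' The built-in registry of allometric models used throughout the package:
#' linear cover-to-biomass regressions for grass and black sagebrush, power
#' root-collar-diameter (RCD) models for live pinon and juniper, the green
#' biomass deduction for standing-dead pinon, and the canopy-area (CA)
#' log-log model used for image-delineated crowns. Each model carries the
#' mean percent carbon of the plant material it predicts, so biomass can be
#' converted to carbon with [biomass_to_carbon()].
#'
#' Model forms:
#' \describe{
#'   \item{linear_cover}{biomass (g m^-2) = slope x percent cover}
#'   \item{power_rcd}{biomass (kg) = scale x (0.1 x RCD_cm)^exponent; the
#'     0.1 factor is the cm-to-dm conversion baked into the published
#'     coefficients, so RCD is always supplied in cm}
#'   \item{power_rcd_dead}{live-model biomass minus a green-biomass power
#'     term, floored at zero}
#'   \item{log10_canopy}{log10 biomass (kg) = intercept + slope x
#'     log10 CA (cm^2)}
#' }
#'
#' @param name Optional model name; if supplied, that single model (a list)
#'   is returned instead of the whole registry.
#' @return A named list of allometric model definitions, or one model.
#' @examples
#' allometric_models("grass")$coefficients
#' @export
allometric_models <- function(name = NULL) {
  reg <- list(
    grass = list(
      name = "grass", form = "linear_cover",
      coefficients = c(slope = 0.566), percent_c = 40.84
    ),
    sagebrush = list(
      name = "sagebrush", form = "linear_cover",
      coefficients = c(slope = 12.132), percent_c = 45.55
    ),
    pinon_live = list(
      name = "pinon_live", form = "power_rcd",
      coefficients = c(scale = 11.41, exponent = 2.6664), percent_c = 46.14
    ),
    juniper = list(
      name = "juniper", form = "power_rcd",
      coefficients = c(scale = 8.256, exponent = 2.8058), percent_c = 45.64
    ),
    pinon_dead = list(
      name = "pinon_dead", form = "power_rcd_dead",
      coefficients = c(
        scale = 11.41, exponent = 2.6664,
        green_scale = 1.853, green_exponent = 2.0268
      ),
      percent_c = 46.14
    ),
    canopy = list(
      name = "canopy", form = "log10_canopy",
      coefficients = c(intercept = -4.66, slope = 1.32), percent_c = 46
    )
  )
  if (is.null(name)) {
    return(reg)
  }
  if (!name %in% names(reg)) {
    stop("unknown allometric model: ", name)
  }
  reg[[name]]
}

#' Load allometric models from a YAML configuration file
#'
#' Entries override or extend the built-in registry. Each entry needs
#' `form`, `coefficients` (named) and `percent_c`.
#'
#' @param path Path to a YAML file whose top level maps model names to
#'   definitions.
#' @return The merged model registry (named list).
#' @export
load_allometric_models <- function(path) {
  cfg <- yaml::read_yaml(path)
  reg <- allometric_models()
  for (nm in names(cfg)) {
    m <- cfg[[nm]]
    m$name <- nm
    m$coefficients <- unlist(m$coefficients)
    stopifnot(
      is.character(m$form), all(is.finite(m$coefficients)),
      m$percent_c > 0, m$percent_c < 100
    )
    reg[[nm]] <- m
  }
  reg
}

#' Understory biomass from fractional cover
#'
#' Applies a linear cover-to-biomass regression: biomass = slope x percent
#' cover, on a per-square-metre basis.
#'
#' @param cover_percent Fractional cover in percent, in \[0, 100\].
#' @param model A `linear_cover` model from [allometric_models()], or its
#'   name (`"grass"` or `"sagebrush"`).
#' @return Areal dry biomass (g m^-2 by default slope units).
#' @examples
#' understory_biomass(10, "grass") # 5.66 g m^-2
#' @export
understory_biomass <- function(cover_percent, model = "grass") {
  if (is.character(model)) model <- allometric_models(model)
  stopifnot(model$form == "linear_cover")
  if (any(!is.finite(cover_percent)) ||
      any(cover_percent < 0) || any(cover_percent > 100)) {
    stop("cover_percent must lie in [0, 100]")
  }
  unname(model$coefficients[["slope"]] * cover_percent)
}

#' Tree biomass from root collar diameter
#'
#' Power-law RCD allometry for pinon and juniper, with the standing-dead
#' pinon correction: for dead pinon devoid of needles the green biomass
#' term is subtracted from the live prediction (floored at zero, since the
#' published coefficients cross below RCD ~0.6 cm). The source equations
#' carry no dead-juniper green term; dead junipers default to the live
#' juniper prediction scaled by `dead_juniper_multiplier`.
#'
#' @param rcd_cm Root collar diameter in cm (> 0). Vectorised.
#' @param species `"pinon"` or `"juniper"` (recycled).
#' @param status `"live"` or `"dead"` (recycled).
#' @param dead_juniper_multiplier Multiplier applied to the live juniper
#'   prediction for dead junipers (default 1).
#' @return Aboveground dry biomass in kg.
#' @examples
#' tree_biomass_rcd(10, "pinon", "live") # 11.41 kg
#' tree_biomass_rcd(10, "pinon", "dead") # 9.557 kg
#' @export
tree_biomass_rcd <- function(rcd_cm, species = "pinon", status = "live",
                             dead_juniper_multiplier = 1) {
  if (any(!is.finite(rcd_cm)) || any(rcd_cm <= 0)) {
    stop("rcd_cm must be positive")
  }
  n <- length(rcd_cm)
  species <- rep_len(match.arg(species, c("pinon", "juniper"),
                               several.ok = TRUE), n)
  status <- rep_len(match.arg(status, c("live", "dead"),
                              several.ok = TRUE), n)
  d <- 0.1 * rcd_cm # published coefficients expect RCD in dm
  live_p <- allometric_models("pinon_live")$coefficients
  live_j <- allometric_models("juniper")$coefficients
  dead_p <- allometric_models("pinon_dead")$coefficients
  out <- numeric(n)
  pin <- species == "pinon"
  out[pin] <- live_p[["scale"]] * d[pin]^live_p[["exponent"]]
  out[!pin] <- live_j[["scale"]] * d[!pin]^live_j[["exponent"]]
  dp <- pin & status == "dead"
  out[dp] <- pmax(
    0,
    out[dp] - dead_p[["green_scale"]] * d[dp]^dead_p[["green_exponent"]]
  )
  dj <- !pin & status == "dead"
  out[dj] <- out[dj] * dead_juniper_multiplier
  out
}

#' Tree biomass from canopy area
#'
#' Log-log canopy-area allometry applicable to image-delineated crowns:
#' log10 biomass (kg) = -4.66 + 1.32 log10 CA (cm^2). Canopy area is
#' supplied in m^2 and converted internally (1 m^2 = 10^4 cm^2).
#'
#' @param canopy_area_m2 Crown area in m^2 (> 0). Vectorised.
#' @return Aboveground dry biomass in kg.
#' @examples
#' tree_biomass_canopy(1) # 10^0.62 ~ 4.17 kg
#' @export
tree_biomass_canopy <- function(canopy_area_m2) {
  if (any(!is.finite(canopy_area_m2)) || any(canopy_area_m2 <= 0)) {
    stop("canopy_area_m2 must be positive")
  }
  cf <- allometric_models("canopy")$coefficients
  ca_cm2 <- canopy_area_m2 * 1e4
  10^(cf[["intercept"]] + cf[["slope"]] * log10(ca_cm2))
}

#' Convert biomass to carbon
#'
#' Multiplies biomass by a percent-carbon content; the result is on the
#' same mass or areal basis as the input.
#'
#' @param biomass Biomass (kg, or g m^-2 for areal pools); >= 0.
#' @param percent_c Percent carbon of dry mass, in (0, 100).
#' @return Carbon on the same basis as `biomass`.
#' @examples
#' biomass_to_carbon(100, 46) # 46
#' @export
biomass_to_carbon <- function(biomass, percent_c) {
  if (any(!is.finite(biomass)) || any(biomass < 0)) {
    stop("biomass must be non-negative")
  }
  if (any(percent_c <= 0) || any(percent_c >= 100)) {
    stop("percent_c must lie in (0, 100)")
  }
  biomass * percent_c / 100
}

#' Basal canopy area from circumference or perpendicular diameters
#'
#' Field crews measure large crowns by running a tape around the canopy
#' edge (circumference, assumed circular) and small crowns by two
#' perpendicular diameters (ellipse area pi d1 d2 / 4).
#'
#' @param circumference_m Canopy circumference in m.
#' @param diameters_m Numeric length-2: perpendicular crown diameters in m.
#'   Supply exactly one of `circumference_m` / `diameters_m`.
#' @return Basal canopy area (m^2).
#' @examples
#' basal_canopy_area(circumference_m = 2 * pi) # unit circle, pi m^2
#' basal_canopy_area(diameters_m = c(2, 2))    # pi m^2
#' @export
basal_canopy_area <- function(circumference_m = NULL, diameters_m = NULL) {
  if (is.null(circumference_m) == is.null(diameters_m)) {
    stop("supply exactly one of circumference_m or diameters_m")
  }
  if (!is.null(circumference_m)) {
    if (any(!is.finite(circumference_m)) || any(circumference_m <= 0)) {
      stop("circumference_m must be positive")
    }
    return(circumference_m^2 / (4 * pi))
  }
  stopifnot(length(diameters_m) == 2)
  if (any(!is.finite(diameters_m)) || any(diameters_m <= 0)) {
    stop("diameters_m must be positive")
  }
  pi * diameters_m[1] * diameters_m[2] / 4
}

#' Canopy circumference implied by a basal canopy area
#'
#' Inverse of the circular-circumference path of [basal_canopy_area()].
#'
#' @param bca_m2 Basal canopy area (m^2), > 0.
#' @return Circumference (m) of the circle with that area.
#' @export
canopy_circumference <- function(bca_m2) {
  if (any(!is.finite(bca_m2)) || any(bca_m2 <= 0)) {
    stop("bca_m2 must be positive")
  }
  sqrt(bca_m2 * 4 * pi)
}
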