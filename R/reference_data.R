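#' Bundled reference tables from a SE Utah pinon-juniper study site
#'
#' Small published field aggregates from a black-sagebrush site on the
#' Colorado Plateau (Hop Creek area, SE Utah) where pinon-juniper
#' woodland encroached through the 20th century. Four 300 m^2 plots span
#' an un-encroached historic sagebrush condition (HSC), low- and
#' high-density woodland (LD, HD), and a drought dieback stand (PJD).
#' These tables are the real-data inputs for the worked examples and the
#' reproduction script; raw per-stem and per-core records were never
#' deposited, so analyses start from these aggregates or from the
#' synthetic generator.
#'
#' @param name One of:
#' \describe{
#'   \item{plot_stocks}{per-plot, per-pool carbon stocks (kg C m^-2 with
#'     SE); feedable to [carbon_stock_table()]}
#'   \item{soil_characteristics}{bulk densities, duff depth, carbonate by
#'     plot}
#'   \item{plot_summary}{stem densities, counts, ages, mean BCA/RCD and
#'     cover by plot}
#'   \item{image_ground_comparison}{image-segmentation vs ground canopy
#'     counts, areas and carbon for the LD and HD plots}
#'   \item{encroachment_summary}{landscape-scale image-analysis results
#'     for the surrounding 25 ha (1937 vs 2006 photo pair)}
#' }
#' @return A data frame.
#' @examples
#' head(reference_table("plot_stocks"))
#' @export
reference_table <- function(name = c("plot_stocks", "soil_characteristics",
                                     "plot_summary",
                                     "image_ground_comparison",
                                     "encroachment_summary")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "pjcarbon", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
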