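# Run configuration: one flat JSON document with per-module blocks.
# Every CLI run resolves its configuration (file values overridden by
# flags) and writes the resolved copy next to its outputs.

#' Default run configuration
#'
#' @param seed Global seed; every stochastic stage derives its randomness
#'   from it.
#' @return Nested named list with per-module parameter blocks
#'   (\code{synthetic}, \code{segmentation}, \code{svm},
#'   \code{cellularity}, \code{cascade}, \code{heatmap},
#'   \code{agreement}). All scalars are JSON-native types so the
#'   configuration round-trips exactly through
#'   \code{\link{write_run_config}} / \code{\link{read_run_config}}.
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = as.numeric(seed),
    synthetic = list(n_patches = 10, size_px = 512, healthy_frac = 0.15,
                     rater_noise_sd = 5, rounding_step = 5),
    segmentation = list(min_area_um2 = 8, max_area_um2 = 250,
                        min_od = 0.25, watershed_tolerance = 1,
                        smooth_sigma = 1, microns_per_pixel = 0.5),
    svm = list(cost = 1, kernel = "radial"),
    cellularity = list(dilation_radius_um = 2.5,
                       calibration_method = "isotonic"),
    cascade = list(family = "rf", resize_px = 128, threshold = 0.5,
                   ntree = 300),
    heatmap = list(alpha = 0.4, low = "blue", high = "red",
                   stride_px = 512),
    agreement = list(variant = "agreement", conf_level = 0.95)
  )
}

#' Write / read a run configuration as JSON
#'
#' @param config Configuration list.
#' @param path JSON file path.
#' @return \code{write_run_config} returns the path invisibly;
#'   \code{read_run_config} returns the configuration list.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON has one number type; keep every numeric a double so a written
  # config reads back identical
  rapply(cfg, function(x) if (is.integer(x)) as.numeric(x) else x,
         how = "replace")
}

# Deep-merge override values into a config (flags over file over default).
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

he_config_from_run <- function(config) {
  sg <- config$segmentation
  he_config(segmentation = segmentation_params(
    min_area_um2 = sg$min_area_um2, max_area_um2 = sg$max_area_um2,
    min_od = sg$min_od, watershed_tolerance = sg$watershed_tolerance,
    smooth_sigma = sg$smooth_sigma,
    microns_per_pixel = sg$microns_per_pixel),
    dilation_radius_um = config$cellularity$dilation_radius_um,
    microns_per_pixel = sg$microns_per_pixel)
}

cascade_config_from_run <- function(config) {
  cc <- config$cascade
  cascade_config(family = cc$family, resize_px = cc$resize_px,
                 threshold = cc$threshold, ntree = cc$ntree,
                 seed = as.integer(config$seed))
}
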