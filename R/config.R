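# Run configuration: structured YAML with sections for grid, camera,
# calibration, and analysis parameters.  CLI flags override config values;
# every stochastic step's seed is recorded so a run manifest makes the run
# reproducible.

#' Default run configuration
#'
#' @return Nested list with sections `grid` (detection range and
#'   sampling), `camera` (offset `b`, gain, read noise, hot pixels, seed),
#'   `calibration` (sinusoid offsets/amplitudes of both filters), and
#'   `analysis` (intensity threshold in a.u., display jitter half-width,
#'   histogram bins, display percentile cutoff).
#' @export
default_run_config <- function() {
  list(
    grid = list(lambda_min = 400, lambda_max = 700, n_samples = 300L),
    camera = list(offset = 100, gain = 1, read_noise_sd = 2,
                  hot_pixel_rate = 1e-4, hot_pixel_value = 4095,
                  seed = 1L),
    calibration = list(o_s = 0.5, m_s = 0.5, o_c = 0.5, m_c = 0.5),
    analysis = list(threshold = 50, jitter_halfwidth = 0.02,
                    jitter_seed = 1L, histogram_bins = 256L,
                    display_cutoff_percent = 5))
}

#' Read / write a run configuration
#'
#' Values present in the file override the defaults section-wise; the
#' round trip through YAML is lossless.
#'
#' @param path YAML file path.
#' @param config Configuration list.
#' @return `read_run_config()` returns the merged configuration list.
#' @export
read_run_config <- function(path) {
  base <- default_run_config()
  if (is.null(path)) return(base)
  if (!file.exists(path)) stop("cannot read config: ", path)
  user <- yaml::read_yaml(path)
  for (sec in names(user)) {
    if (sec %in% names(base) && is.list(user[[sec]])) {
      base[[sec]] <- utils::modifyList(base[[sec]], user[[sec]])
    } else {
      base[[sec]] <- user[[sec]]
    }
  }
  base
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_camera <- function(config) do.call(camera_model, config$camera)
config_grid <- function(config) do.call(wavelength_grid, config$grid)
config_calibration <- function(config) do.call(filter_calibration,
                                               config$calibration)

#' Write a machine-readable run manifest
#'
#' Records the resolved configuration (including every seed), the
#' subcommand, and the produced outputs, so any run can be reproduced from
#' its manifest alone.
#'
#' @param path Output YAML path.
#' @param command Subcommand name.
#' @param config Resolved configuration list.
#' @param inputs,outputs Character vectors of file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config, inputs = character(),
                           outputs = character()) {
  yaml::write_yaml(list(command = command,
                        config = config,
                        inputs = as.list(inputs),
                        outputs = as.list(outputs)),
                   path)
  invisible(path)
}
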