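# Parse "key = value" lines (flat config / sidecar files).
read_key_value <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  out <- list()
  for (m in kv) if (length(m) == 3) out[[m[2]]] <- trimws(m[3])
  out
}

# Parse "# key=value" metadata lines at the top of a TSV artifact.
read_hash_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[startsWith(lines, "#")]
  lines <- sub("^#\\s*", "", lines)
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  out <- list()
  for (m in kv) if (length(m) == 3) out[[m[2]]] <- trimws(m[3])
  out
}

#' Default run configuration
#'
#' One flat configuration drives the whole chain; every default equals the
#' corresponding module default (5x5 grid, 32 pixels per axis, 256
#' quantization levels, +/-5% projection depth, >50% drop in <250 ms,
#' 1 s completion dwell, 5-point smoothing window, 30 samples/s).
#'
#' @return A named list of configuration values.
#' @export
default_config <- function() {
  list(
    side_mm = 200, usable_span_mm = 140,
    angles_deg = c(0, 120, 240), low_byte = 0x20, high_byte = 0xD0,
    dots_per_mm = 11.81,
    gain = c(1, 1, 1), spot_radius_mm = 1.0,
    rel_noise_sigma = 0.02, luminance_walk_sigma = 0.002,
    sample_rate_hz = 30, liftoff_floor = 0.05,
    grid_n = 5, samples_per_point = 30,
    pixels_per_axis = 32, bins_per_channel = 256, projection_depth = 0.05,
    drop_fraction = 0.5, drop_window_s = 0.25, completion_dwell_s = 1.0,
    require_offmap_confirmation = TRUE,
    smooth_window = 5, hesitation_dwell_s = 0.3,
    straightedge_lines = 5, traverse_s = 2
  )
}

#' Read a flat key = value configuration file
#'
#' Unknown keys are rejected; values are coerced to the type of the default.
#' Comma-separated values give vectors (e.g. `angles_deg = 0,120,240`).
#'
#' @param path Config file path, or `NULL` for the defaults.
#' @return A configuration list as from [default_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  kv <- read_key_value(path)
  unknown <- setdiff(names(kv), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in names(kv)) {
    v <- strsplit(kv[[k]], ",")[[1]]
    cfg[[k]] <- if (is.logical(cfg[[k]])) as.logical(as.numeric(v) != 0 | v %in% c("TRUE", "true"))
                else as.numeric(v)
  }
  cfg
}

# Instantiate the typed objects a configuration describes.
config_objects <- function(cfg) {
  spec <- color_map_spec(side_mm = cfg$side_mm,
                         usable_span_mm = cfg$usable_span_mm,
                         angles_deg = cfg$angles_deg,
                         low_byte = cfg$low_byte, high_byte = cfg$high_byte)
  model <- sensor_model(gain = cfg$gain, spot_radius_mm = cfg$spot_radius_mm,
                        rel_noise_sigma = cfg$rel_noise_sigma,
                        luminance_walk_sigma = cfg$luminance_walk_sigma,
                        sample_rate_hz = cfg$sample_rate_hz,
                        liftoff_floor = cfg$liftoff_floor)
  lift <- liftoff_config(drop_fraction = cfg$drop_fraction,
                         drop_window_s = cfg$drop_window_s,
                         completion_dwell_s = cfg$completion_dwell_s,
                         require_offmap_confirmation = isTRUE(cfg$require_offmap_confirmation))
  list(spec = spec, model = model, lift = lift)
}
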