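# Plain-text scene configuration files: flat TOML-style `key = value`
# lines with dotted keys for nested fields, `#` comments, and
# `[a, b]` numeric arrays.  See inst/extdata/scene_bead.toml.

parse_config_value <- function(v) {
  v <- trimws(v)
  if (grepl("^\\[.*\\]$", v)) {
    parts <- strsplit(gsub("^\\[|\\]$", "", v), ",")[[1]]
    return(as.numeric(trimws(parts)))
  }
  if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) num else v
}

read_config_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
    if (length(kv) != 2) stop("cannot parse config line: ", ln)
    out[[trimws(kv[1])]] <- parse_config_value(kv[2])
  }
  out
}

#' Load a scene configuration from a plain-text file
#'
#' The file holds flat `key = value` pairs (TOML-style) with dotted
#' keys for the nested pieces, e.g.
#'
#' ```
#' background = 200
#' target.kind = bead          # or "ellipse", or "none"
#' target.radius_um = 50
#' noise.n = 15
#' noise.keepout_px = 22
#' noise.start_t = 0.3
#' start_pos_um = [15000, 15000]
#' ```
#'
#' Unrecognized keys raise an error.  A bundled example is at
#' `system.file("extdata", "scene_bead.toml", package = "servotrack")`.
#'
#' @param path Path to the config file.
#' @return A [scene_config()].
#' @export
read_scene_config <- function(path) {
  kv <- read_config_lines(path)
  pick <- function(key, default) if (key %in% names(kv)) kv[[key]] else default
  known <- c("background", "drift_amplitude", "drift_period_s",
             "workspace_um", "start_pos_um", "start_heading", "sensor_px",
             "target.kind", "target.radius_um", "target.half_length_um",
             "target.half_width_um", "target.intensity",
             "noise.n", "noise.radius_px", "noise.intensity",
             "noise.keepout_px", "noise.start_t",
             "tool.y_um", "tool.start_x_um", "tool.stop_x_um",
             "tool.speed_um_s", "tool.width_um", "tool.start_t")
  unknown <- setdiff(names(kv), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  kind <- pick("target.kind", "bead")
  target <- switch(kind,
    bead = target_bead(radius_um = pick("target.radius_um", 50),
                       intensity = pick("target.intensity", 20)),
    ellipse = target_ellipse(
      half_length_um = pick("target.half_length_um", 75),
      half_width_um = pick("target.half_width_um", 15),
      intensity = pick("target.intensity", 20)),
    none = NULL,
    stop("unknown target.kind: ", kind))
  keepout <- pick("noise.keepout_px", NULL)
  noise <- noise_config(n = pick("noise.n", 0),
                        radius_px = pick("noise.radius_px", c(5, 25)),
                        intensity = pick("noise.intensity", 20),
                        keepout_px = keepout,
                        start_t = pick("noise.start_t", 0))
  tool <- if ("tool.y_um" %in% names(kv)) {
    tool_config(y_um = kv[["tool.y_um"]],
                start_x_um = kv[["tool.start_x_um"]],
                stop_x_um = kv[["tool.stop_x_um"]],
                speed_um_s = pick("tool.speed_um_s", 200),
                width_um = pick("tool.width_um", 50),
                start_t = pick("tool.start_t", 0))
  } else NULL
  workspace <- pick("workspace_um", c(30000, 30000))
  scene_config(
    target = target, background = pick("background", 200), noise = noise,
    drift_amplitude = pick("drift_amplitude", 0),
    drift_period_s = pick("drift_period_s", 5),
    workspace_um = workspace,
    start_pos_um = pick("start_pos_um", workspace / 2),
    start_heading = pick("start_heading", 0),
    tool = tool, sensor_px = pick("sensor_px", 256))
}
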