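#' Pipeline configuration
#'
#' Assembles the tunable parameters of the steatosis quantification pipeline.
#' All physical thresholds are in square microns and are converted to pixels
#' with the image's microns-per-pixel (mpp) scale, so results are consistent
#' across pyramid levels. The shape-filter defaults are this package's own
#' calibration against the synthetic generator: the workflow they implement
#' treats them as tunable (edit the config, re-run), and they are not claimed
#' to be canonical for any particular scanner or stain batch.
#'
#' @param mean_filter_size Side of the square mean filter applied before the
#'   tissue threshold, in pixels (odd). Default 5.
#' @param speckle_min_area Minimum area of a tissue component, um^2; smaller
#'   stained specks (debris) are discarded. Default 2000.
#' @param edge_crop Border band, in pixels, removed from the tissue mask to
#'   exclude slide-edge artifacts. Default 100.
#' @param void_max_area Interior voids of the tissue mask larger than this
#'   (um^2) are treated as folds/tears and excluded from the tissue
#'   denominator. Default 1.5e6.
#' @param void_min_convexity Interior voids with convexity below this are
#'   treated as ragged tears and excluded. Default 0.85.
#' @param bridge_span Width, in pixels, of the widest tear the closing step
#'   will bridge. Default 11.
#' @param glare_saturation_max HSV saturation below which a near-maximal-value
#'   pixel counts as coverslip glare. Default 0.10.
#' @param glare_value_min HSV value (brightness) at or above which a
#'   low-saturation pixel counts as glare. Blown-out glare clips at the sensor
#'   maximum, whereas unstained lipid vacuoles stay just below it. Default 0.995.
#' @param glare_remove If `TRUE` (default) glare pixels are removed from the
#'   tissue mask; `FALSE` keeps the literal low-saturation-intersection
#'   reading, retaining them.
#' @param dyn_window Window side of the local-mean used by the dynamic
#'   threshold, px, odd and >= 3. Default 31.
#' @param dyn_offset Gray-level offset (0-255 scale) a pixel must exceed its
#'   local mean by to be a vacuole candidate. Default 5.
#' @param vacuole_min_area,vacuole_max_area Accepted vacuole area bounds,
#'   um^2. Defaults 50 and 12000 (macrovesicular scale, roughly 8-120 um
#'   diameter).
#' @param min_roundness,min_circularity,max_compactness,min_convexity,max_anisometry
#'   Shape-filter bounds applied to candidate regions. Defaults 0.55, 0.45,
#'   2.0, 0.80, 2.5.
#' @param exclude_border If `TRUE` (default), candidate regions clipped by the
#'   image border are excluded from classification.
#' @param overlay_blend Alpha used when tinting overlay PNGs, in `[0, 1]`.
#'   Default 0.45.
#'
#' @return A list of class `steatr_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(dyn_offset = 8)
#' cfg$dyn_offset
pipeline_config <- function(mean_filter_size = 5,
                            speckle_min_area = 2000,
                            edge_crop = 100,
                            void_max_area = 1.5e6,
                            void_min_convexity = 0.85,
                            bridge_span = 11,
                            glare_saturation_max = 0.10,
                            glare_value_min = 0.995,
                            glare_remove = TRUE,
                            dyn_window = 31,
                            dyn_offset = 5,
                            vacuole_min_area = 50,
                            vacuole_max_area = 12000,
                            min_roundness = 0.55,
                            min_circularity = 0.45,
                            max_compactness = 2.0,
                            min_convexity = 0.80,
                            max_anisometry = 2.5,
                            exclude_border = TRUE,
                            overlay_blend = 0.45) {
  cfg <- list(
    mean_filter_size = mean_filter_size,
    speckle_min_area = speckle_min_area,
    edge_crop = edge_crop,
    void_max_area = void_max_area,
    void_min_convexity = void_min_convexity,
    bridge_span = bridge_span,
    glare_saturation_max = glare_saturation_max,
    glare_value_min = glare_value_min,
    glare_remove = isTRUE(glare_remove),
    dyn_window = dyn_window,
    dyn_offset = dyn_offset,
    vacuole_min_area = vacuole_min_area,
    vacuole_max_area = vacuole_max_area,
    min_roundness = min_roundness,
    min_circularity = min_circularity,
    max_compactness = max_compactness,
    min_convexity = min_convexity,
    max_anisometry = max_anisometry,
    exclude_border = isTRUE(exclude_border),
    overlay_blend = overlay_blend
  )
  validate_config(cfg)
  structure(cfg, class = "steatr_config")
}

validate_config <- function(cfg) {
  num <- c("mean_filter_size", "speckle_min_area", "edge_crop",
           "void_max_area", "void_min_convexity", "bridge_span",
           "glare_saturation_max", "glare_value_min", "dyn_window",
           "dyn_offset", "vacuole_min_area", "vacuole_max_area",
           "min_roundness", "min_circularity", "max_compactness",
           "min_convexity", "max_anisometry", "overlay_blend")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      abort(sprintf("config field '%s' must be a single number", f),
            class = "steatr_error_config")
    }
  }
  if (cfg$edge_crop < 0) {
    abort("edge_crop must be >= 0", class = "steatr_error_config")
  }
  pos <- c("mean_filter_size", "speckle_min_area", "void_max_area",
           "dyn_window", "vacuole_min_area", "vacuole_max_area")
  for (f in pos) {
    if (cfg[[f]] <= 0) {
      abort(sprintf("config field '%s' must be positive", f),
            class = "steatr_error_config")
    }
  }
  if (cfg$dyn_window < 3 || cfg$dyn_window %% 2 != 1) {
    abort("dyn_window must be odd and >= 3", class = "steatr_error_config")
  }
  if (cfg$vacuole_min_area > cfg$vacuole_max_area) {
    abort("vacuole_min_area must not exceed vacuole_max_area",
          class = "steatr_error_config")
  }
  if (cfg$overlay_blend < 0 || cfg$overlay_blend > 1) {
    abort("overlay_blend must lie in [0, 1]", class = "steatr_error_config")
  }
  if (cfg$glare_saturation_max < 0 || cfg$glare_saturation_max > 1) {
    abort("glare_saturation_max must lie in [0, 1]",
          class = "steatr_error_config")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Every field is optional; unspecified fields take the [pipeline_config()]
#' defaults. Unknown fields are an error, so typos do not silently fall back
#' to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys mirror the
#'   [pipeline_config()] argument names.
#' @return A `steatr_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "steatr_error_io")
  }
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(sprintf("unknown config fields: %s", paste(bad, collapse = ", ")),
          class = "steatr_error_config")
  }
  do.call(pipeline_config, vals)
}

#' @export
print.steatr_config <- function(x, ...) {
  cat("<steatr pipeline config>\n")
  for (f in names(x)) cat(sprintf("  %-22s %s\n", f, format(x[[f]])))
  invisible(x)
}
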