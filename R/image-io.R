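#' Slide image container
#'
#' A lightweight in-memory representation of an RGB histology raster: an
#' `height x width x 3` numeric array of 8-bit channel values (0-255), the
#' physical scale in microns per pixel, and provenance (source path, pyramid
#' level read). Coordinates are 1-based `(row, col)` with the origin at the
#' top-left pixel.
#'
#' @param pixels Numeric array `h x w x 3` with values in `[0, 255]`.
#' @param mpp Microns per pixel (isotropic), > 0.
#' @param level Pyramid level index the raster was read from (0-based).
#' @param source_path Provenance string.
#' @param mpp_assumed `TRUE` when `mpp` is a fallback default rather than
#'   embedded metadata.
#' @return An object of class `slide_image`.
#' @export
slide_image <- function(pixels, mpp, level = 0L, source_path = "<memory>",
                        mpp_assumed = FALSE) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (length(dim(pixels)) != 3L || dim(pixels)[3] < 3L) {
    abort("pixels must be an h x w x 3 array", class = "steatr_error_format")
  }
  pixels <- pixels[, , 1:3, drop = FALSE]
  if (!is.numeric(mpp) || length(mpp) != 1L || !is.finite(mpp) || mpp <= 0) {
    abort("mpp must be a single positive number", class = "steatr_error_format")
  }
  if (any(dim(pixels)[1:2] < 1L)) {
    abort("image must be at least 1 x 1", class = "steatr_error_format")
  }
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255) {
    abort("channel values must lie in [0, 255]", class = "steatr_error_format")
  }
  structure(
    list(pixels = pixels, mpp = as.numeric(mpp), level = as.integer(level),
         source_path = source_path, mpp_assumed = isTRUE(mpp_assumed)),
    class = "slide_image"
  )
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_image %d x %d px, mpp %.4g um/px%s, level %d, %s>\n",
              d[1], d[2], x$mpp, if (x$mpp_assumed) " (assumed)" else "",
              x$level, x$source_path))
  invisible(x)
}

#' @export
dim.slide_image <- function(x) dim(x$pixels)[1:2]

#' Read a histology raster with physical scale
#'
#' Reads plain PNG/TIFF rasters and multi-page pyramidal TIFF files. For
#' pyramidal files each page is treated as one pyramid level (page order =
#' level order, level 0 the largest); the microns-per-pixel of a level is the
#' base mpp multiplied by that level's downsample factor, taken from the
#' page-dimension ratio. When no scale metadata is embedded the fallback
#' default of [read_mpp()] is used and flagged as assumed.
#'
#' @param path Path to a PNG or (possibly multi-page) TIFF file.
#' @param level Pyramid level to read (0-based). Default 0 (full resolution).
#' @param default_mpp Fallback scale when metadata is absent; see [read_mpp()].
#' @return A [slide_image()].
#' @export
read_slide <- function(path, level = 0L, default_mpp = 0.249) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read image: file not found: %s", path),
          class = "steatr_error_format")
  }
  ext <- tolower(tools::file_ext(path))
  level <- as.integer(level)
  if (ext == "png") {
    if (level != 0L) {
      abort(sprintf("level %d requested but plain raster %s has only level 0",
                    level, path),
            class = "steatr_error_level")
    }
    px <- tryCatch(png::readPNG(path), error = function(e) {
      abort(sprintf("unreadable PNG file: %s", path),
            class = "steatr_error_format")
    })
    m <- read_mpp(path, default_mpp = default_mpp)
    return(slide_image(to_rgb255(px), mpp = m$mpp, level = 0L,
                       source_path = path, mpp_assumed = m$assumed))
  }
  if (ext %in% c("tif", "tiff", "svs")) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) {
                        abort(sprintf("unreadable TIFF file: %s", path),
                              class = "steatr_error_format")
                      })
    if (!is.list(pages)) pages <- list(pages)
    if (level < 0L || level >= length(pages)) {
      abort(sprintf("level %d not present in %s; available levels: %s",
                    level, path,
                    paste(seq_along(pages) - 1L, collapse = ", ")),
            class = "steatr_error_level")
    }
    base_w <- ncol_raster(pages[[1]])
    this_w <- ncol_raster(pages[[level + 1L]])
    downsample <- base_w / this_w
    m <- read_mpp(path, default_mpp = default_mpp)
    return(slide_image(to_rgb255(pages[[level + 1L]]),
                       mpp = m$mpp * downsample, level = level,
                       source_path = path, mpp_assumed = m$assumed))
  }
  abort(sprintf("unsupported image format '%s': %s", ext, path),
        class = "steatr_error_format")
}

ncol_raster <- function(px) {
  d <- dim(px)
  d[2]
}

# normalize readPNG/readTIFF output ([0,1], 1/2/3/4 channels) to h x w x 3
# in 0..255
to_rgb255 <- function(px) {
  if (is.matrix(px)) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] == 2L) {              # gray + alpha
    px <- array(rep(px[, , 1], 3L), dim = c(dim(px)[1:2], 3L))
  }
  px[, , 1:3, drop = FALSE] * 255
}

#' Read the microns-per-pixel scale of an image file
#'
#' Looks for scale metadata embedded in TIFF files: an Aperio-style
#' `MPP = <value>` entry in the ImageDescription tag, or the X-resolution tag
#' with an inch/cm unit. When neither is present (plain PNGs have no such
#' metadata), or the embedded value is not a positive number, the fallback
#' default is returned and flagged as assumed. The fallback 0.249 um/px is a
#' common maximum resolution of clinical slide scanners.
#'
#' @param path Image file path.
#' @param default_mpp Fallback value, um/px. Default 0.249.
#' @return A list with `mpp` (numeric, um/px of the base level) and `assumed`
#'   (`TRUE` when the fallback was used).
#' @export
read_mpp <- function(path, default_mpp = 0.249) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read image: file not found: %s", path),
          class = "steatr_error_format")
  }
  fallback <- list(mpp = default_mpp, assumed = TRUE)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("tif", "tiff", "svs")) return(fallback)
  info <- tryCatch(tiff::readTIFF(path, payload = FALSE),
                   error = function(e) NULL)
  if (is.null(info)) return(fallback)
  if (is.list(info) && !is.data.frame(info) && length(info) &&
      is.list(info[[1]])) {
    info <- info[[1]]                  # base level of a multi-page file
  }
  desc <- info[["description"]]
  if (!is.null(desc) && is.character(desc) && length(desc)) {
    desc <- desc[1]
    m <- regmatches(desc, regexec("MPP\\s*=\\s*([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)",
                                  desc))[[1]]
    if (length(m) >= 2) {
      v <- suppressWarnings(as.numeric(m[2]))
      if (is.finite(v) && v > 0) return(list(mpp = v, assumed = FALSE))
    }
  }
  xres <- info[["x.resolution"]][1]
  unit <- info[["resolution.unit"]][1]
  if (!is.null(xres) && is.numeric(xres) && is.finite(xres) && xres > 0 &&
      !is.null(unit) && !is.na(unit)) {
    per_unit_um <- if (identical(unit, "inch") || identical(unit, 2L)) {
      25400
    } else if (identical(unit, "cm") || identical(unit, 3L)) {
      10000
    } else {
      NA_real_
    }
    if (is.finite(per_unit_um)) {
      v <- per_unit_um / xres
      if (is.finite(v) && v > 0) return(list(mpp = v, assumed = FALSE))
    }
  }
  fallback
}

#' Write an overlay PNG of accepted and rejected detections
#'
#' Renders the classification result the way pathologists review it: accepted
#' lipid vacuoles tinted green, rejected bright/round candidates (vessels,
#' tears, debris) tinted yellow, alpha-blended over the original RGB image.
#' Pixels outside both masks are written unchanged.
#'
#' @param image A [slide_image()].
#' @param accepted,rejected Logical matrices congruent with the image.
#' @param path Output PNG path.
#' @param blend Alpha in `[0, 1]`; 1 replaces masked pixels by the pure
#'   overlay color. Default 0.45.
#' @return The output path, invisibly.
#' @export
write_overlay <- function(image, accepted, rejected, path, blend = 0.45) {
  d <- dim(image$pixels)[1:2]
  for (m in list(accepted, rejected)) {
    if (!is.matrix(m) || !identical(dim(m), d)) {
      abort("overlay masks must match the image dimensions",
            class = "steatr_error_geometry")
    }
  }
  out <- image$pixels / 255
  green <- c(0, 1, 0)
  yellow <- c(1, 1, 0)
  for (k in 1:3) {
    ch <- out[, , k]
    ch[rejected] <- (1 - blend) * ch[rejected] + blend * yellow[k]
    ch[accepted] <- (1 - blend) * ch[accepted] + blend * green[k]
    out[, , k] <- ch
  }
  png::writePNG(out, path)
  invisible(path)
}

#' Downsample a slide image by an integer factor
#'
#' Block-averages `factor x factor` pixel blocks and scales the
#' microns-per-pixel accordingly, emulating reading a coarser pyramid level.
#'
#' @param image A [slide_image()].
#' @param factor Integer downsample factor >= 1.
#' @return A [slide_image()] with `mpp * factor`.
#' @export
downsample_slide <- function(image, factor = 2L) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor == 1L) return(image)
  d <- dim(image$pixels)
  nr <- d[1] %/% factor; nc <- d[2] %/% factor
  out <- array(0, dim = c(nr, nc, 3))
  for (k in 1:3) {
    blk <- image$pixels[seq_len(nr * factor), seq_len(nc * factor), k]
    dim(blk) <- c(factor, nr, factor * nc)
    blk <- colMeans(blk)                  # average within block rows
    dim(blk) <- c(nr, factor, nc)
    out[, , k] <- apply(blk, c(1, 3), mean)
  }
  slide_image(out, mpp = image$mpp * factor,
              level = image$level + as.integer(log2(max(factor, 2))),
              source_path = image$source_path,
              mpp_assumed = image$mpp_assumed)
}

#' Write a slide image to PNG
#'
#' @param image A [slide_image()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_slide_png <- function(image, path) {
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}
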