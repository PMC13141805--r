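#' @keywords internal
# Rec.601 luminance in [0, 1]
luminance <- function(image) {
  px <- image$pixels
  (0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]) / 255
}

# HSV saturation and value of an RGB slide
hsv_sv <- function(image) {
  px <- image$pixels
  mx <- pmax(px[, , 1], px[, , 2], px[, , 3])
  mn <- pmin(px[, , 1], px[, , 2], px[, , 3])
  s <- ifelse(mx > 0, 1 - mn / mx, 0)
  dim(s) <- dim(mx)
  list(s = s, v = mx / 255)
}

# k x k mean filter with replicated borders
box_mean <- function(x, k) {
  if (k <= 1) return(x)
  kern <- matrix(1 / (k * k), k, k)
  as.matrix(EBImage::filter2(x, kern, boundary = "replicate"))
}

drop_small_components <- function(mask, min_px, connectivity = 8L) {
  if (!any(mask)) return(mask)
  lab <- .cc_label(mask, as.integer(connectivity))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_px)
  out <- array(lab %in% keep, dim = dim(mask))
  out
}

ebi_binary <- function(mask) EBImage::Image(mask * 1)

morph_close <- function(mask, size) {
  if (size < 2 || !any(mask)) return(mask)
  brush <- EBImage::makeBrush(odd_size(size), shape = "disc")
  as.matrix(EBImage::closing(ebi_binary(mask), brush)) > 0.5
}

morph_open <- function(mask, size) {
  if (size < 2 || !any(mask)) return(mask)
  brush <- EBImage::makeBrush(odd_size(size), shape = "disc")
  as.matrix(EBImage::opening(ebi_binary(mask), brush)) > 0.5
}

odd_size <- function(k) {
  k <- max(3L, as.integer(round(k)))
  if (k %% 2L == 0L) k + 1L else k
}

# approximate convexity of a pixel set: filled pixel count over the lattice
# points of its convex hull (Pick-style estimate A + P/2 + 1)
pixel_convexity <- function(px) {
  if (nrow(px) < 4) return(1)
  hull <- chull(px[, 1], px[, 2])
  if (length(hull) < 3) return(1)
  hp <- px[hull, , drop = FALSE]
  a <- abs(shoelace(hp[, 1], hp[, 2]))
  p <- polygon_perimeter(rbind(hp, hp[1, , drop = FALSE]))
  min(nrow(px) / (a + p / 2 + 1), 1)
}

#' Tissue mask generation
#'
#' Converts the RGB slide to grayscale (luminance), smooths it with a square
#' mean filter, and separates the darker stained tissue from the bright
#' background with an Otsu threshold. Components smaller than the speckle
#' threshold (debris) are removed and a border band of `edge_crop` pixels is
#' cleared to exclude slide-edge artifacts.
#'
#' @param image A [slide_image()].
#' @param config A [pipeline_config()].
#' @return Logical matrix (`TRUE` = tissue) congruent with the image.
#' @export
tissue_mask <- function(image, config = pipeline_config()) {
  d <- dim(image$pixels)[1:2]
  if (any(d <= 2 * config$edge_crop)) {
    abort(sprintf(paste0("image (%d x %d) is too small for an edge crop of ",
                         "%d px; set a smaller edge_crop"),
                  d[1], d[2], config$edge_crop),
          class = "steatr_error_config")
  }
  gray <- luminance(image)
  sm <- box_mean(gray, config$mean_filter_size)
  if (diff(range(sm)) < 1e-3) {
    return(matrix(FALSE, d[1], d[2]))          # no foreground/background split
  }
  thr <- EBImage::otsu(EBImage::Image(pmin(pmax(sm, 0), 1)))
  mask <- sm < thr
  min_px <- config$speckle_min_area / image$mpp^2
  mask <- drop_small_components(mask, min_px)
  crop_border(mask, config$edge_crop)
}

crop_border <- function(mask, crop) {
  if (crop <= 0) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  mask[c(seq_len(crop), seq.int(nr - crop + 1L, nr)), ] <- FALSE
  mask[, c(seq_len(crop), seq.int(nc - crop + 1L, nc))] <- FALSE
  mask
}

#' Artifact suppression
#'
#' Refines a tissue mask so downstream quantification runs only on viable
#' tissue: (i) morphological closing bridges narrow tears; (ii) interior
#' voids are filled, then voids that are too large (folds/tears, area above
#' `void_max_area`) or too ragged (convexity below `void_min_convexity`) are
#' carved back out so they never enter the tissue denominator — compact voids
#' such as unstained lipid vacuoles stay filled, because vacuoles are tissue;
#' (iii) coverslip glare (low saturation at near-maximal brightness) is
#' removed. Pathological inputs degrade to pass-through with a warning.
#'
#' @param mask Logical tissue mask from [tissue_mask()].
#' @param image The corresponding [slide_image()].
#' @param config A [pipeline_config()].
#' @return Refined logical tissue mask.
#' @export
suppress_artifacts <- function(mask, image, config = pipeline_config()) {
  tryCatch({
    if (!any(mask)) return(mask)
    m1 <- morph_close(mask, config$bridge_span)
    m2 <- fill_holes(m1)
    voids <- m2 & !m1
    if (any(voids)) {
      lab <- .cc_label(voids, 4L)
      sizes <- tabulate(lab)
      max_px <- config$void_max_area / image$mpp^2
      carve <- logical(length(sizes))
      for (l in seq_along(sizes)) {
        if (sizes[l] > max_px) {
          carve[l] <- TRUE
        } else if (sizes[l] >= 64) {
          px <- arrayInd(which(lab == l), dim(lab))
          carve[l] <- pixel_convexity(px) < config$void_min_convexity
        }
      }
      if (any(carve)) {
        m2[array(lab %in% which(carve), dim = dim(lab))] <- FALSE
      }
    }
    if (config$glare_remove) {
      sv <- hsv_sv(image)
      glare <- sv$s < config$glare_saturation_max & sv$v >= config$glare_value_min
      m2 <- m2 & !glare
    }
    m2
  }, error = function(e) {
    warn(sprintf("artifact suppression degraded to pass-through: %s",
                 conditionMessage(e)))
    mask
  })
}

#' Vacuole candidate detection
#'
#' Brightness-adaptive (dynamic) threshold inside the tissue mask: a pixel is
#' a candidate iff its gray value is at least `dyn_offset` gray levels above
#' the mean of its `dyn_window` x `dyn_window` neighborhood. Lipid vacuoles
#' are unstained and bright on the darker eosin-stained tissue, so the
#' comparison is one-sided towards bright. A small morphological opening
#' (`candidate_opening`) removes single-pixel noise responses. Candidates
#' never appear outside the tissue mask.
#'
#' @param image A [slide_image()].
#' @param tissue Artifact-suppressed tissue mask.
#' @param config A [pipeline_config()].
#' @param candidate_opening Size (px) of the opening applied to the raw
#'   threshold response; 0 disables. Default 3.
#' @return Logical candidate mask.
#' @export
detect_candidates <- function(image, tissue, config = pipeline_config(),
                              candidate_opening = 3) {
  if (!any(tissue)) {
    warn("empty tissue mask: no vacuole candidates")
    return(tissue)
  }
  gray <- luminance(image) * 255
  lm <- box_mean(gray, config$dyn_window)
  cand <- gray >= lm + config$dyn_offset
  if (candidate_opening >= 2) cand <- morph_open(cand, candidate_opening)
  cand <- cand & tissue
  # a vacuole wider than the window responds only along its rim (its center
  # matches its own local mean); the enclosed interior is part of the vacuole
  if (any(cand)) cand <- fill_holes(cand) & tissue
  cand
}

#' Classify candidate regions into vacuoles and artifacts
#'
#' Applies the geometry-only acceptance rule: a region is accepted iff its
#' area lies within the vacuole bounds AND roundness, circularity and
#' convexity are at or above their minima AND compactness and anisometry are
#' at or below their maxima. Rejected regions carry the first failing
#' criterion, checked in the fixed order border (if enabled), area,
#' roundness, circularity, compactness, convexity, anisometry, for
#' deterministic reporting.
#'
#' @param features A region-feature table from [region_features()].
#' @param config A [pipeline_config()].
#' @return The input tibble with logical `accepted` and character `reason`
#'   (`NA` for accepted regions) columns appended.
#' @export
classify_candidates <- function(features, config = pipeline_config()) {
  if (!nrow(features)) {
    return(dplyr::mutate(features, accepted = logical(0),
                         reason = character(0)))
  }
  checks <- list(
    border = if (config$exclude_border && "touches_border" %in% names(features))
      features$touches_border else rep(FALSE, nrow(features)),
    area = features$area_um2 < config$vacuole_min_area |
      features$area_um2 > config$vacuole_max_area,
    roundness = features$roundness < config$min_roundness,
    circularity = features$circularity < config$min_circularity,
    compactness = features$compactness > config$max_compactness,
    convexity = features$convexity < config$min_convexity,
    anisometry = features$anisometry > config$max_anisometry
  )
  reason <- rep(NA_character_, nrow(features))
  for (nm in names(checks)) {
    reason[is.na(reason) & checks[[nm]]] <- nm
  }
  dplyr::mutate(features, accepted = is.na(reason), reason = reason)
}

#' Quantify steatosis from classified regions
#'
#' The steatosis percentage is the accepted vacuole area as a fraction of the
#' artifact-suppressed tissue area (which includes vacuole pixels — vacuoles
#' are tissue), times 100, plus the ordinal grade from [bin_category()].
#'
#' @param classified Output of [classify_candidates()].
#' @param tissue Logical tissue mask (the denominator).
#' @param mpp Microns per pixel.
#' @return A `steatosis_result` object; see [run_pipeline()].
#' @export
quantify_steatosis <- function(classified, tissue, mpp) {
  tissue_area <- sum(tissue) * mpp^2
  if (tissue_area <= 0) {
    abort("no tissue detected: slide rejected as non-tissue",
          class = "steatr_error_no_tissue")
  }
  vac_area <- sum(classified$area_um2[classified$accepted])
  if (vac_area > tissue_area) {
    warn("accepted vacuole area exceeded tissue area; clamping")
    vac_area <- tissue_area
  }
  pct <- 100 * vac_area / tissue_area
  structure(
    list(
      steatosis_pct = pct,
      tissue_area_um2 = tissue_area,
      vacuole_area_um2 = vac_area,
      n_accepted = sum(classified$accepted),
      n_rejected = sum(!classified$accepted),
      category = as.character(bin_category(pct)),
      per_region = classified,
      mpp = mpp
    ),
    class = "steatosis_result"
  )
}

#' Ordinal steatosis grade
#'
#' Bins a steatosis percentage into the ordinal categories used for grading
#' and for the weighted-kappa agreement statistics: exactly 0, then the
#' half-open intervals (0,5], (5,10], (10,15], (15,20], (20,30], (30,100].
#'
#' @param pct Numeric vector of percentages in `[0, 100]`.
#' @return Ordered factor over [steatosis_bins()].
#' @export
#' @examples
#' bin_category(c(0, 6.67, 30, 30.01))
bin_category <- function(pct) {
  if (any(!is.finite(pct)) || any(pct < 0 | pct > 100)) {
    abort("steatosis percentage must lie in [0, 100]",
          class = "steatr_error_domain")
  }
  cut(pct, breaks = c(-Inf, 0, 5, 10, 15, 20, 30, 100),
      labels = steatosis_bins(), right = TRUE, ordered_result = TRUE)
}

#' The ordinal steatosis category labels, in order
#' @return Character vector of length 7.
#' @export
steatosis_bins <- function() {
  c("0%", "1-5%", "6-10%", "11-15%", "16-20%", "21-30%", ">30%")
}

#' Run the full steatosis quantification pipeline
#'
#' Composes the whole workflow: read the slide, generate the tissue mask,
#' suppress artifacts, detect bright vacuole candidates, extract regions and
#' their shape descriptors, classify them, and quantify the steatosis area
#' fraction. Fully deterministic for a fixed input and configuration. Stage
#' errors are re-signalled with the failing stage named.
#'
#' @param input A file path or a [slide_image()].
#' @param config A [pipeline_config()].
#' @param level Pyramid level to read when `input` is a path.
#' @param default_mpp Scale assumed for files without embedded
#'   microns-per-pixel metadata (see [read_mpp()]). All physical thresholds
#'   depend on it, so set it explicitly for plain rasters.
#' @return A `steatosis_result`: steatosis percentage, ordinal category,
#'   tissue and vacuole areas (um^2), acceptance counts, the per-region
#'   feature/classification table, and the accepted/rejected masks used for
#'   overlay rendering.
#' @export
run_pipeline <- function(input, config = pipeline_config(), level = 0L,
                         default_mpp = 0.249) {
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        abort(sprintf("pipeline stage '%s' failed: %s", name,
                      conditionMessage(e)),
              class = class(e)[1])
      }),
      warning = function(w) {
        warn(sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  }
  image <- if (inherits(input, "slide_image")) input else {
    stage("read_slide",
          read_slide(input, level = level, default_mpp = default_mpp))
  }
  tissue0 <- stage("tissue_mask", tissue_mask(image, config))
  tissue <- stage("suppress_artifacts",
                  suppress_artifacts(tissue0, image, config))
  cand <- stage("detect_candidates", detect_candidates(image, tissue, config))
  feats <- stage("region_features", region_features(cand, mpp = image$mpp))
  classified <- stage("classify_candidates",
                      classify_candidates(feats, config))
  res <- stage("quantify", quantify_steatosis(classified, tissue, image$mpp))
  res$input <- image$source_path
  res$mpp_assumed <- image$mpp_assumed
  res$level <- image$level
  res$config <- config
  res$accepted_mask <- region_mask(classified, dim(image$pixels)[1:2], TRUE)
  res$rejected_mask <- region_mask(classified, dim(image$pixels)[1:2], FALSE)
  res
}

region_mask <- function(classified, d, accepted) {
  m <- matrix(FALSE, d[1], d[2])
  if (!nrow(classified)) return(m)
  px <- classified$pixels[classified$accepted == accepted]
  for (p in px) m[p] <- TRUE
  m
}

#' @export
print.steatosis_result <- function(x, ...) {
  cat(sprintf(paste0("<steatosis_result> %.2f%% (%s)\n",
                     "  tissue %.4g um^2, vacuoles %.4g um^2\n",
                     "  %d accepted / %d rejected regions\n"),
              x$steatosis_pct, x$category, x$tissue_area_um2,
              x$vacuole_area_um2, x$n_accepted, x$n_rejected))
  invisible(x)
}
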