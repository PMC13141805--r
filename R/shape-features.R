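#' Extract labeled connected regions from a binary mask
#'
#' Labels the foreground of a binary mask into connected components and
#' returns one row per region with its pixel set, sub-pixel contour and
#' centroid. Interior holes are filled before labeling, so a vacuole whose
#' lumen contains debris is one region and its area is the filled area.
#' Labels are assigned deterministically in scanline order of each region's
#' topmost-leftmost pixel.
#'
#' @param mask Logical matrix (`TRUE` = foreground).
#' @param connectivity 8 (default, standard for bright candidate objects) or 4.
#' @return A tibble with columns `label`, `n_pixels`, `centroid_row`,
#'   `centroid_col`, `touches_border`, and list-columns `pixels` (n x 2 matrix
#'   of row/col indices, 1-based) and `contour` (closed polygon of sub-pixel
#'   boundary points, n x 2 row/col). An empty mask yields zero rows.
#' @export
extract_regions <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  if (!is.logical(mask)) mask <- mask > 0
  if (!connectivity %in% c(4, 8)) {
    abort("connectivity must be 4 or 8", class = "steatr_error_config")
  }
  empty <- tibble(
    label = integer(), n_pixels = integer(),
    centroid_row = numeric(), centroid_col = numeric(),
    touches_border = logical(), pixels = list(), contour = list()
  )
  if (!any(mask)) return(empty)
  filled <- fill_holes(mask, fg_connectivity = connectivity)
  lab <- .cc_label(filled, as.integer(connectivity))
  idx <- which(lab > 0L)
  if (!length(idx)) return(empty)
  rc <- arrayInd(idx, dim(lab))
  labs <- lab[idx]
  ord <- order(labs)
  rc <- rc[ord, , drop = FALSE]
  labs <- labs[ord]
  splits <- split(seq_len(nrow(rc)), labs)
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- lapply(names(splits), function(l) {
    px <- rc[splits[[l]], , drop = FALSE]
    colnames(px) <- c("row", "col")
    tibble(
      label = as.integer(l),
      n_pixels = nrow(px),
      centroid_row = mean(px[, 1]),
      centroid_col = mean(px[, 2]),
      touches_border = any(px[, 1] == 1L | px[, 1] == nr |
                             px[, 2] == 1L | px[, 2] == nc),
      pixels = list(px),
      contour = list(region_contour(px))
    )
  })
  dplyr::bind_rows(rows)
}

# fill interior holes (background components not reaching the image border);
# the background connectivity is the digital-topology dual of the foreground
# connectivity (8-connected objects pair with 4-connected background)
fill_holes <- function(mask, fg_connectivity = 8) {
  bg <- .cc_label(!mask, if (fg_connectivity == 8) 4L else 8L)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0L]
  hole <- bg > 0L & !(bg %in% border_labels)
  dim(hole) <- dim(mask)
  mask | hole
}

# sub-pixel iso-contour (level 0.5, marching squares via contourLines) of a
# region given by its pixel coordinates; returns a closed row/col polygon
region_contour <- function(px) {
  r0 <- min(px[, 1]); r1 <- max(px[, 1])
  c0 <- min(px[, 2]); c1 <- max(px[, 2])
  sub <- matrix(0, r1 - r0 + 3L, c1 - c0 + 3L)
  sub[cbind(px[, 1] - r0 + 2L, px[, 2] - c0 + 2L)] <- 1
  xs <- seq.int(r0 - 1L, r1 + 1L)
  ys <- seq.int(c0 - 1L, c1 + 1L)
  cl <- contourLines(xs, ys, sub, levels = 0.5)
  if (!length(cl)) {
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  }
  areas <- vapply(cl, function(p) abs(shoelace(p$x, p$y)), numeric(1))
  p <- cl[[which.max(areas)]]
  out <- cbind(row = p$x, col = p$y)
  if (nrow(out) >= 2 && any(out[1, ] != out[nrow(out), ])) {
    out <- rbind(out, out[1, ])
  }
  out
}

shoelace <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

polygon_perimeter <- function(poly) {
  if (nrow(poly) < 2) return(0)
  d <- diff(poly)
  sum(sqrt(rowSums(d^2)))
}

# light circular smoothing (iterated 1/4-1/2-1/4 kernel) of a closed polygon;
# suppresses the marching-squares staircase, whose ripple otherwise inflates
# the perimeter by several percent, while barely rounding true corners
smooth_polygon <- function(poly, iterations = 4) {
  if (iterations < 1 || nrow(poly) < 5) return(poly)
  q <- poly[-nrow(poly), , drop = FALSE]
  n <- nrow(q)
  for (i in seq_len(iterations)) {
    q <- 0.25 * q[c(n, seq_len(n - 1)), , drop = FALSE] + 0.5 * q +
      0.25 * q[c(seq.int(2, n), 1), , drop = FALSE]
  }
  rbind(q, q[1, , drop = FALSE])
}

#' Compute shape descriptors for one region
#'
#' The descriptors are the geometry-only features used to separate lipid
#' vacuoles from vessels and processing artifacts. With `F` the filled pixel
#' count, `c` the pixel centroid, `p_i` the sub-pixel contour points,
#' `L` the contour polygon length, `A` the contour polygon area and
#' `d_i = ||p_i - c||`:
#'
#' * `area_um2 = F * mpp^2`
#' * `roundness = 1 - sd(d) / mean(d)` (disc -> 1; ragged or elongated -> lower)
#' * `circularity = A / (pi * max(d)^2)` (disc -> 1)
#' * `compactness = L^2 / (4 * pi * A)` (disc -> 1; larger = less compact)
#' * `convexity = A / area(convex hull of contour)` (convex -> 1)
#' * `anisometry = Ra / Rb`, the axis ratio of the second-moment equivalent
#'   ellipse of the pixel set (disc -> 1; vessels high)
#' * `equivalent_diameter_um = 2 * mpp * sqrt(F / pi)`
#'
#' Ratio descriptors use the contour polygon area so that numerator and
#' denominator share one geometry; the reported physical area uses the pixel
#' count. Degenerate regions (a single pixel, a collinear contour) take the
#' neutral guard values roundness = circularity = compactness = convexity =
#' anisometry = 1.
#'
#' The contour polygon is lightly smoothed (default 4 iterations of a
#' 1/4-1/2-1/4 circular kernel) before any contour-based quantity is taken,
#' which removes the residual staircase ripple of the rasterized boundary;
#' without it a disc's perimeter — and hence compactness — is biased upward
#' by several percent.
#'
#' @param pixels n x 2 matrix of (row, col) pixel indices of the filled region.
#' @param contour Closed polygon of sub-pixel boundary points (n x 2 row/col),
#'   e.g. from [extract_regions()].
#' @param mpp Microns per pixel.
#' @param smooth_iter Contour smoothing iterations (0 disables). Default 4.
#' @return A one-row tibble with the descriptor columns listed above plus
#'   `perimeter_um`.
#' @export
compute_features <- function(pixels, contour, mpp = 1, smooth_iter = 4) {
  F_px <- nrow(pixels)
  area_um2 <- F_px * mpp^2
  eq_diam <- 2 * mpp * sqrt(F_px / pi)
  contour <- smooth_polygon(contour, smooth_iter)
  a_poly <- if (nrow(contour) >= 4) abs(shoelace(contour[, 1], contour[, 2])) else 0
  per <- polygon_perimeter(contour)
  degenerate <- F_px <= 1L || nrow(contour) < 4 || a_poly <= 1e-9
  if (degenerate) {
    return(tibble(
      area_um2 = area_um2, equivalent_diameter_um = eq_diam,
      perimeter_um = per * mpp, roundness = 1, circularity = 1,
      compactness = 1, convexity = 1, anisometry = 1
    ))
  }
  ctr <- c(mean(pixels[, 1]), mean(pixels[, 2]))
  pts <- contour[-nrow(contour), , drop = FALSE]   # drop duplicated closer
  d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  dbar <- mean(d)
  sdd <- sqrt(mean((d - dbar)^2))
  roundness <- if (dbar > 0) 1 - sdd / dbar else 1
  circularity <- a_poly / (pi * max(d)^2)
  compactness <- per^2 / (4 * pi * a_poly)
  hull <- chull(pts[, 1], pts[, 2])
  hull_area <- abs(shoelace(pts[hull, 1], pts[hull, 2]))
  convexity <- if (hull_area > 0) a_poly / hull_area else 1
  # second-moment equivalent ellipse of the pixel set; the 1/12 term is the
  # variance of a unit pixel, which keeps a single pixel isotropic
  vr <- mean((pixels[, 1] - ctr[1])^2) + 1 / 12
  vc <- mean((pixels[, 2] - ctr[2])^2) + 1 / 12
  vrc <- mean((pixels[, 1] - ctr[1]) * (pixels[, 2] - ctr[2]))
  tr <- vr + vc
  det <- vr * vc - vrc^2
  disc <- max(tr^2 / 4 - det, 0)
  l1 <- tr / 2 + sqrt(disc)
  l2 <- tr / 2 - sqrt(disc)
  anisometry <- if (l2 > 0) sqrt(l1 / l2) else 1
  tibble(
    area_um2 = area_um2, equivalent_diameter_um = eq_diam,
    perimeter_um = per * mpp, roundness = roundness,
    circularity = min(circularity, 1 + 0.05),
    compactness = compactness, convexity = min(convexity, 1 + 0.05),
    anisometry = anisometry
  )
}

#' Shape descriptors for every region of a binary mask
#'
#' Convenience wrapper: [extract_regions()] followed by [compute_features()]
#' per region, returned as one tidy table (one region per row).
#'
#' @inheritParams extract_regions
#' @param mpp Microns per pixel.
#' @return A tibble with the [extract_regions()] identification columns
#'   followed by the [compute_features()] descriptor columns.
#' @export
region_features <- function(mask, mpp = 1, connectivity = 8) {
  regs <- extract_regions(mask, connectivity = connectivity)
  if (!nrow(regs)) {
    feats <- compute_features(cbind(1L, 1L),
                              matrix(numeric(0), 0, 2), mpp)[0, ]
    out <- dplyr::bind_cols(
      regs[, c("label", "n_pixels", "centroid_row", "centroid_col",
               "touches_border")],
      feats
    )
    out$pixels <- list()
    return(out)
  }
  feats <- purrr::map2(regs$pixels, regs$contour, compute_features, mpp = mpp)
  out <- dplyr::bind_cols(
    regs[, c("label", "n_pixels", "centroid_row", "centroid_col",
             "touches_border")],
    dplyr::bind_rows(feats)
  )
  out$pixels <- regs$pixels                # kept for mask/overlay rendering
  out
}
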