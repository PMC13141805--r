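#' Specification for a synthetic H&E-like test slide
#'
#' Describes the scene the generator renders: a pink eosin-like tissue region
#' on a white background containing bright, slightly irregular round lipid
#' vacuoles at a known area fraction, plus the artifact classes the pipeline
#' must reject — elongated bright vessel lumina, background-colored tears,
#' and blown-out low-saturation glare patches. The seed fixes the entire
#' sample path, so a spec renders bit-identically every time.
#'
#' @param size Image side, px (square). Default 1024.
#' @param mpp Microns per pixel. Default 1.
#' @param fraction Target vacuole area fraction of tissue, in `[0, 0.5]`.
#'   Default 0.10.
#' @param tissue_shape `"disc"` or `"blob"` (disc with low-frequency radial
#'   perturbation). Default `"blob"`.
#' @param tissue_color RGB anchor of stained tissue. Default `c(230, 160, 180)`.
#' @param color_noise_sd SD of the multiplicative texture noise. Default 0.03.
#' @param vacuole_diameter_um Diameter range of vacuoles, um (macrovesicular
#'   scale). Default `c(15, 100)`.
#' @param n_vessels Number of elongated bright vessel lumina. Default 4.
#' @param vessel_axis_ratio Axis-ratio range of vessels. Default `c(3, 6)`.
#' @param n_tears Number of background-colored tears. Default 2.
#' @param n_glare Number of clipped glare patches. Default 2.
#' @param seed Integer RNG seed (required).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(size = 1024, mpp = 1, fraction = 0.10,
                           tissue_shape = c("blob", "disc"),
                           tissue_color = c(230, 160, 180),
                           color_noise_sd = 0.03,
                           vacuole_diameter_um = c(15, 100),
                           n_vessels = 4, vessel_axis_ratio = c(3, 6),
                           n_tears = 2, n_glare = 2, seed = 1L) {
  tissue_shape <- match.arg(tissue_shape)
  if (!is.numeric(fraction) || fraction < 0 || fraction > 0.5) {
    abort("fraction must lie in [0, 0.5]", class = "steatr_error_config")
  }
  if (any(vacuole_diameter_um <= 0) ||
      vacuole_diameter_um[1] > vacuole_diameter_um[2]) {
    abort("vacuole_diameter_um must be a positive increasing range",
          class = "steatr_error_config")
  }
  structure(
    list(size = as.integer(size), mpp = mpp, fraction = fraction,
         tissue_shape = tissue_shape, tissue_color = tissue_color,
         color_noise_sd = color_noise_sd,
         vacuole_diameter_um = vacuole_diameter_um,
         n_vessels = n_vessels, vessel_axis_ratio = vessel_axis_ratio,
         n_tears = n_tears, n_glare = n_glare, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render a synthetic slide with ground-truth masks
#'
#' Renders the scene described by a [synthetic_spec()] and returns the exact
#' per-structure masks. Vacuoles are placed without overlap (rejection
#' sampling) until the vacuole/tissue pixel ratio is within 0.3 percentage
#' points of the target fraction; tears are carved out of the tissue before
#' vacuole placement, and glare patches are excluded from the ground-truth
#' tissue mask (they obscure the tissue beneath them). Identical specs render
#' identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `slide` (a [slide_image()]) and `truth`, itself a list
#'   of logical masks `tissue_mask`, `vacuole_mask`, `vessel_mask`,
#'   `tear_mask`, `glare_mask` and the realized `true_fraction`.
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, render_slide(spec))
}

render_slide <- function(spec) {
  n <- spec$size
  rw <- matrix(seq_len(n), n, n)
  cl <- matrix(seq_len(n), n, n, byrow = TRUE)
  # the biopsy sits centered well inside the scanned frame, so the pipeline's
  # fixed-pixel edge crop removes background only — also when the same scene
  # is analyzed at a coarser pyramid level
  ctr <- (n + 1) / 2
  r0 <- 0.27 * n
  dx <- rw - ctr; dy <- cl - ctr
  dist <- sqrt(dx^2 + dy^2)
  if (spec$tissue_shape == "disc") {
    tissue <- dist <= r0
  } else {
    theta <- atan2(dy, dx)
    mod <- matrix(1, n, n)
    for (k in 2:5) {
      mod <- mod + runif(1, -0.025, 0.025) * cos(k * theta + runif(1, 0, 2 * pi))
    }
    tissue <- dist <= r0 * mod
  }

  # base render: white background, textured pink tissue
  tex <- 1 + matrix(rnorm(n * n, 0, spec$color_noise_sd), n, n)
  img <- array(255, dim = c(n, n, 3))
  for (k in 1:3) {
    ch <- img[, , k]
    ch[tissue] <- pmin(pmax(spec$tissue_color[k] * tex[tissue], 0), 254)
    img[, , k] <- ch
  }

  # tears: mounting medium showing through a crack — bright, but just below
  # the sensor clipping that characterizes glare
  tear_mask <- matrix(FALSE, n, n)
  for (i in seq_len(spec$n_tears)) {
    tr <- draw_tear(tissue & !tear_mask, n)
    if (!is.null(tr)) tear_mask <- tear_mask | tr
  }
  if (any(tear_mask)) {
    for (k in 1:3) {
      ch <- img[, , k]; ch[tear_mask] <- 252; img[, , k] <- ch
    }
    tissue <- tissue & !tear_mask
  }

  # glare: clipped, fully desaturated patches; carved out of the usable
  # tissue before anything else is placed, since they obscure what is below
  dt <- as.matrix(EBImage::distmap(EBImage::Image(tissue * 1)))
  glare_mask <- matrix(FALSE, n, n)
  for (i in seq_len(spec$n_glare)) {
    g <- draw_glare(tissue, dt, glare_mask, n)
    if (!is.null(g)) glare_mask <- glare_mask | g
  }
  if (any(glare_mask)) {
    for (k in 1:3) {
      ch <- img[, , k]; ch[glare_mask] <- 255; img[, , k] <- ch
    }
    tissue <- tissue & !glare_mask
  }

  dt <- as.matrix(EBImage::distmap(EBImage::Image(tissue * 1)))

  vessel_mask <- matrix(FALSE, n, n)
  occupied <- matrix(FALSE, n, n)
  for (i in seq_len(spec$n_vessels)) {
    v <- draw_vessel(tissue, dt, occupied, spec, n)
    if (is.null(v)) next
    vessel_mask <- vessel_mask | v
    occupied <- occupied | v
  }
  if (any(vessel_mask)) {
    lum <- pmin(pmax(246 + rnorm(sum(vessel_mask), 0, 2), 238), 253)
    for (k in 1:3) {
      ch <- img[, , k]; ch[vessel_mask] <- lum; img[, , k] <- ch
    }
  }

  vac <- place_vacuoles(tissue, dt, occupied, spec)
  vac_mask <- vac$mask
  if (any(vac_mask)) {
    val <- pmin(pmax(248 + rnorm(sum(vac_mask), 0, 2), 240), 253)
    for (k in 1:3) {
      ch <- img[, , k]; ch[vac_mask] <- val; img[, , k] <- ch
    }
  }

  true_fraction <- if (any(tissue)) sum(vac_mask & tissue) / sum(tissue) else 0
  slide <- slide_image(img, mpp = spec$mpp, level = 0L,
                       source_path = sprintf("<synthetic seed=%d>", spec$seed),
                       mpp_assumed = FALSE)
  list(
    slide = slide,
    truth = list(tissue_mask = tissue, vacuole_mask = vac_mask,
                 vessel_mask = vessel_mask, tear_mask = tear_mask,
                 glare_mask = glare_mask, true_fraction = true_fraction)
  )
}

# rejection-sampled non-overlapping irregular discs until the vacuole/tissue
# ratio is within +-0.3 percentage points of the target
place_vacuoles <- function(tissue, dt, occupied, spec) {
  n <- spec$size
  mask <- matrix(FALSE, n, n)
  tissue_px <- sum(tissue)
  target <- spec$fraction * tissue_px
  tol <- 0.003 * tissue_px
  if (target <= tol || tissue_px == 0) {
    return(list(mask = mask, placed = 0))
  }
  rmin <- spec$vacuole_diameter_um[1] / 2 / spec$mpp
  rmax0 <- spec$vacuole_diameter_um[2] / 2 / spec$mpp
  placed <- 0
  failures <- 0
  unreachable <- function() {
    abort(paste0("cannot reach the target vacuole fraction; reduce the ",
                 "fraction or the vacuole diameters relative to the ",
                 "tissue size"),
          class = "steatr_error_generation")
  }
  while (placed < target - tol) {
    deficit <- target - placed
    min_area <- pi * rmin^2
    last <- FALSE
    if (min_area > deficit + tol) {
      # even the smallest vacuole overshoots the target band: place one last
      # minimum-size vacuole only if that ends closer to the target than
      # stopping short does
      if (min_area >= 2 * deficit) {
        if (placed == 0) unreachable()   # could not place anything at all
        break
      }
      r <- rmin
      last <- TRUE
    } else {
      rcap <- sqrt((deficit + tol) / pi) / 1.06  # irregular boundary margin
      rmax <- min(rmax0 * 0.8^min(failures %/% 25, 8), rcap)
      r <- runif(1, rmin, max(rmin, rmax))
    }
    elig <- which(dt > 1.08 * r + 3)
    if (!length(elig)) {
      failures <- failures + 1
      if (failures > 8000) unreachable()
      next
    }
    c0 <- arrayInd(elig[sample.int(length(elig), 1L)], dim(tissue))
    d <- stamp_irregular_disc(c0[1], c0[2], r, n)
    hit <- d$idx[d$inside_wide, , drop = FALSE]
    if (any(mask[hit]) || any(occupied[hit]) || any(!tissue[hit])) {
      failures <- failures + 1
      if (failures > 8000) unreachable()
      next
    }
    mask[d$idx[d$inside, , drop = FALSE]] <- TRUE
    placed <- placed + sum(d$inside)
    if (last) break
  }
  list(mask = mask, placed = placed)
}

# an irregular disc: radius modulated by low-order harmonics (amplitude <= 6%)
stamp_irregular_disc <- function(cr, cc, r, n) {
  pad <- ceiling(1.08 * r + 2)
  rows <- max(1, cr - pad):min(n, cr + pad)
  cols <- max(1, cc - pad):min(n, cc + pad)
  lr <- matrix(rows - cr, length(rows), length(cols))
  lc <- matrix(cols - cc, length(rows), length(cols), byrow = TRUE)
  d <- sqrt(lr^2 + lc^2)
  th <- atan2(lc, lr)
  amp <- runif(3, 0, 0.03)
  ph <- runif(3, 0, 2 * pi)
  rth <- r * (1 + amp[1] * cos(2 * th + ph[1]) + amp[2] * cos(3 * th + ph[2]) +
                amp[3] * cos(4 * th + ph[3]))
  idx <- cbind(rep(rows, times = length(cols)),
               rep(cols, each = length(rows)))
  list(idx = idx, inside = as.vector(d <= rth),
       inside_wide = as.vector(d <= rth + 2))
}

draw_vessel <- function(tissue, dt, occupied, spec, n) {
  for (attempt in 1:200) {
    ratio <- runif(1, spec$vessel_axis_ratio[1], spec$vessel_axis_ratio[2])
    b <- runif(1, 6, 11)
    a <- b * ratio
    elig <- which(dt > a + 3)
    if (!length(elig)) elig <- which(dt > b + 3)
    if (!length(elig)) return(NULL)
    c0 <- arrayInd(elig[sample.int(length(elig), 1L)], dim(tissue))
    th <- runif(1, 0, pi)
    pad <- ceiling(a + 2)
    rows <- max(1, c0[1] - pad):min(n, c0[1] + pad)
    cols <- max(1, c0[2] - pad):min(n, c0[2] + pad)
    lr <- matrix(rows - c0[1], length(rows), length(cols))
    lc <- matrix(cols - c0[2], length(rows), length(cols), byrow = TRUE)
    u <- lr * cos(th) + lc * sin(th)
    v <- -lr * sin(th) + lc * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    idx <- cbind(rep(rows, times = length(cols)),
                 rep(cols, each = length(rows)))[as.vector(inside), ,
                                                 drop = FALSE]
    keep <- tissue[idx] & !occupied[idx]
    if (sum(keep) < 0.9 * nrow(idx)) next
    m <- matrix(FALSE, n, n)
    m[idx[keep, , drop = FALSE]] <- TRUE
    return(m)
  }
  NULL
}

draw_tear <- function(tissue, n) {
  elig <- which(tissue)
  if (!length(elig)) return(NULL)
  c0 <- arrayInd(elig[sample.int(length(elig), 1L)], dim(tissue))
  th <- runif(1, 0, pi)
  half <- runif(1, 0.12, 0.25) * n
  w <- runif(1, 3, 6)
  pad <- ceiling(half + w)
  rows <- max(1, c0[1] - pad):min(n, c0[1] + pad)
  cols <- max(1, c0[2] - pad):min(n, c0[2] + pad)
  lr <- matrix(rows - c0[1], length(rows), length(cols))
  lc <- matrix(cols - c0[2], length(rows), length(cols), byrow = TRUE)
  u <- lr * cos(th) + lc * sin(th)        # along the tear
  v <- -lr * sin(th) + lc * cos(th)       # across
  inside <- abs(u) <= half & abs(v) <= w / 2
  idx <- cbind(rep(rows, times = length(cols)),
               rep(cols, each = length(rows)))[as.vector(inside), ,
                                               drop = FALSE]
  keep <- tissue[idx]
  if (!any(keep)) return(NULL)
  m <- matrix(FALSE, n, n)
  m[idx[keep, , drop = FALSE]] <- TRUE
  m
}

draw_glare <- function(tissue, dt, occupied, n) {
  for (attempt in 1:200) {
    r <- runif(1, 15, 40)
    elig <- which(dt > r + 2)
    if (!length(elig)) return(NULL)
    c0 <- arrayInd(elig[sample.int(length(elig), 1L)], dim(tissue))
    pad <- ceiling(r)
    rows <- max(1, c0[1] - pad):min(n, c0[1] + pad)
    cols <- max(1, c0[2] - pad):min(n, c0[2] + pad)
    lr <- matrix(rows - c0[1], length(rows), length(cols))
    lc <- matrix(cols - c0[2], length(rows), length(cols), byrow = TRUE)
    inside <- lr^2 + lc^2 <= r^2
    idx <- cbind(rep(rows, times = length(cols)),
                 rep(cols, each = length(rows)))[as.vector(inside), ,
                                                 drop = FALSE]
    if (any(occupied[idx])) next
    m <- matrix(FALSE, n, n)
    m[idx] <- TRUE
    return(m)
  }
  NULL
}

#' Generate a cohort of synthetic slides
#'
#' Draws `n` slides whose target vacuole fractions are sampled from a grid
#' (defaults span the 1-35% range typical of clinical donor-liver cohorts,
#' which are right-skewed with most cases below 20%). Child seeds are derived
#' deterministically from the master seed, so the whole cohort is
#' reproducible and slides are pairwise distinct.
#'
#' @param n Number of slides.
#' @param fractions Grid of target fractions to sample from.
#' @param weights Optional sampling weights over `fractions` (uniform when
#'   `NULL`).
#' @param seed Master seed.
#' @param ... Passed to [synthetic_spec()] (e.g. `size`, `n_vessels`).
#' @return A tibble with one row per slide: `id`, `target_fraction`,
#'   `true_fraction`, `seed`, and list-columns `slide` and `truth`.
#' @export
generate_cohort <- function(n, fractions = seq(0.01, 0.35, by = 0.02),
                            weights = NULL, seed = 1L, ...) {
  stopifnot(n >= 1)
  fr <- with_seed(seed, sample(fractions, n, replace = TRUE, prob = weights))
  child_seeds <- (as.double(seed) * 10007 + seq_len(n) * 9973) %%
    .Machine$integer.max
  rows <- purrr::map(seq_len(n), function(i) {
    sp <- synthetic_spec(fraction = fr[i], seed = as.integer(child_seeds[i]),
                         ...)
    out <- generate_slide(sp)
    tibble(id = i, target_fraction = fr[i],
           true_fraction = out$truth$true_fraction,
           seed = as.integer(child_seeds[i]),
           slide = list(out$slide), truth = list(out$truth))
  })
  dplyr::bind_rows(rows)
}
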