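#' Tidy the per-region table of a steatosis result
#'
#' @param x A `steatosis_result` from [run_pipeline()] or
#'   [quantify_steatosis()].
#' @param ... Unused.
#' @return A tibble with one row per candidate region: identification,
#'   shape descriptors, `accepted`, `reason`.
#' @export
tidy.steatosis_result <- function(x, ...) {
  pr <- x$per_region
  drop <- intersect(c("pixels", "contour"), names(pr))
  as_tibble(pr[, setdiff(names(pr), drop)])
}

#' One-row summary of a steatosis result
#'
#' @inheritParams tidy.steatosis_result
#' @return A one-row tibble: `steatosis_pct`, `category`, `tissue_area_um2`,
#'   `vacuole_area_um2`, `n_accepted`, `n_rejected`, `mpp`.
#' @export
glance.steatosis_result <- function(x, ...) {
  tibble(
    steatosis_pct = x$steatosis_pct, category = x$category,
    tissue_area_um2 = x$tissue_area_um2,
    vacuole_area_um2 = x$vacuole_area_um2,
    n_accepted = x$n_accepted, n_rejected = x$n_rejected, mpp = x$mpp
  )
}

#' @export
tidy.agreement_report <- function(x, ...) as_tibble(x$pairs)

#' @export
glance.agreement_report <- function(x, ...) {
  tibble(
    n_raters = x$n_raters,
    n_pairs = nrow(x$pairs),
    mean_pearson_r = mean(x$pairs$pearson_r, na.rm = TRUE),
    mean_kappa = mean(x$pairs$kappa, na.rm = TRUE),
    tolerance_rate = if (!is.null(x$tolerance)) x$tolerance$rate else NA_real_
  )
}

#' Shape-feature plot of classified candidate regions
#'
#' Scatter of equivalent diameter against roundness for every candidate
#' region, colored by acceptance, faceted nowhere — a quick view of where
#' the shape filters cut.
#'
#' @param object A `steatosis_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.steatosis_result <- function(object, ...) {
  d <- tidy(object)
  d$status <- ifelse(d$accepted, "accepted",
                     paste0("rejected: ", d$reason))
  ggplot2::ggplot(d, ggplot2::aes(.data$equivalent_diameter_um,
                                  .data$roundness, color = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "equivalent diameter (um)", y = "roundness",
      title = sprintf("steatosis %.2f%% (%s)", object$steatosis_pct,
                      object$category)
    )
}

#' Bland-Altman mean-difference plot
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot object: per-case differences against the pair mean with
#'   the bias and the 1.96 SD limits of agreement.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(.data$reference, .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = 2) +
    ggplot2::labs(x = "mean of pair (%)", y = "difference (pp)",
                  title = sprintf("bias %.2f, LoA [%.2f, %.2f]",
                                  object$bias, object$loa_low,
                                  object$loa_high))
}

#' Recovery plot for a quantified synthetic cohort
#'
#' @param data A tibble with `true_fraction` and `estimated_pct` columns
#'   (e.g. from quantifying a [generate_cohort()] output).
#' @return A ggplot of estimated vs true steatosis with the identity line.
#' @export
plot_recovery <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(100 * .data$true_fraction,
                                     .data$estimated_pct)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "true steatosis (%)", y = "estimated steatosis (%)")
}
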