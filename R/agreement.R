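check_pairs <- function(x, y, min_n = 3) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "steatr_error_domain")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_n) {
    abort(sprintf("need at least %d overlapping pairs, got %d",
                  min_n, length(x)),
          class = "steatr_error_domain")
  }
  list(x = x, y = y, n = length(x))
}

#' Pearson correlation with confidence interval and R-squared
#'
#' Product-moment correlation with Fisher-z 95% CI and the two-sided t test
#' p-value. The coefficient of determination is returned as `r.squared`;
#' for simple bivariate correlation R-squared equals r squared exactly.
#'
#' @param x,y Numeric vectors (pairwise-complete; NAs dropped).
#' @param conf_level Confidence level for the CI. Default 0.95.
#' @return One-row tibble: `estimate` (r), `conf.low`, `conf.high`,
#'   `r.squared`, `statistic` (t), `p.value`, `n`.
#' @export
cor_pearson <- function(x, y, conf_level = 0.95) {
  p <- check_pairs(x, y, 3)
  if (sd(p$x) == 0 || sd(p$y) == 0) {
    abort("correlation undefined: zero variance",
          class = "steatr_error_degenerate")
  }
  ct <- cor.test(p$x, p$y, method = "pearson", conf.level = conf_level)
  tibble(
    estimate = unname(ct$estimate),
    conf.low = ct$conf.int[1], conf.high = ct$conf.int[2],
    r.squared = unname(ct$estimate)^2,
    statistic = unname(ct$statistic), p.value = ct$p.value, n = p$n
  )
}

#' Spearman rank correlation
#'
#' Pearson correlation on mid-ranks (average ranks for ties), with the
#' two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @inheritParams cor_pearson
#' @return One-row tibble: `estimate` (rho), `p.value`, `n`.
#' @export
cor_spearman <- function(x, y) {
  p <- check_pairs(x, y, 3)
  rx <- rank(p$x); ry <- rank(p$y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("correlation undefined: zero rank variance (all values tied)",
          class = "steatr_error_degenerate")
  }
  rho <- cor(rx, ry)
  pv <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((p$n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = p$n - 2)
  }
  tibble(estimate = rho, p.value = pv, n = p$n)
}

#' Root mean square error between paired scores
#'
#' @inheritParams cor_pearson
#' @return `sqrt(mean((x - y)^2))`, in the units of the scores (percentage
#'   points for steatosis).
#' @export
rmse <- function(x, y) {
  p <- check_pairs(x, y, 1)
  sqrt(mean((p$x - p$y)^2))
}

quadratic_weights <- function(k) {
  outer(seq_len(k), seq_len(k), function(i, j) (i - j)^2 / (k - 1)^2)
}

to_bins <- function(v, bins) {
  if (is.numeric(v)) return(bin_category(v))
  f <- factor(as.character(v), levels = bins, ordered = TRUE)
  if (anyNA(f) && !anyNA(v)) {
    abort("categorical scores contain labels outside the bin set",
          class = "steatr_error_domain")
  }
  f
}

#' Quadratically weighted Cohen's kappa
#'
#' Chance-corrected agreement for ordinal categories with quadratic
#' disagreement weights `w_ij = (i - j)^2 / (k - 1)^2`:
#' `kappa = 1 - sum(w * O) / sum(w * E)`, where `O` holds observed cell
#' proportions and `E` the products of the marginals. Continuous percentage
#' scores are first binned with [bin_category()]. The default confidence
#' interval uses the large-sample (Fleiss-Cohen-Everitt) standard error; a
#' seeded case-resampling bootstrap is available for sparse tables.
#'
#' @param a,b Paired scores: numeric percentages or categories over `bins`.
#' @param bins Ordered category labels. Default [steatosis_bins()].
#' @param method `"asymptotic"` (default) or `"bootstrap"`.
#' @param conf_level Confidence level. Default 0.95.
#' @param boot_n,boot_seed Bootstrap resamples and seed (bootstrap method).
#' @return One-row tibble: `kappa`, `conf.low`, `conf.high`, `se`, `band`
#'   (Landis-Koch label), `n`, `method`.
#' @export
weighted_kappa <- function(a, b, bins = steatosis_bins(),
                           method = c("asymptotic", "bootstrap"),
                           conf_level = 0.95, boot_n = 2000, boot_seed = 1L) {
  method <- match.arg(method)
  fa <- to_bins(a, bins); fb <- to_bins(b, bins)
  ok <- !is.na(fa) & !is.na(fb)
  fa <- fa[ok]; fb <- fb[ok]
  n <- length(fa)
  if (n < 2) {
    abort("need at least 2 overlapping rated cases",
          class = "steatr_error_domain")
  }
  if (length(unique(fa)) < 2 || length(unique(fb)) < 2) {
    abort("kappa undefined: a rater used a single category (degenerate marginals)",
          class = "steatr_error_degenerate")
  }
  k <- length(bins)
  w <- quadratic_weights(k)
  kap <- kappa_point(as.integer(fa), as.integer(fb), k, w)
  if (method == "asymptotic") {
    se <- kappa_se(as.integer(fa), as.integer(fb), k, w, kap)
    z <- qnorm(1 - (1 - conf_level) / 2)
    lo <- max(-1, kap - z * se); hi <- min(1, kap + z * se)
  } else {
    bk <- with_seed(boot_seed, {
      vapply(seq_len(boot_n), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        ba <- as.integer(fa[idx]); bb <- as.integer(fb[idx])
        if (length(unique(ba)) < 2 || length(unique(bb)) < 2) return(NA_real_)
        kappa_point(ba, bb, k, w)
      }, numeric(1))
    })
    qs <- quantile(bk, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                   na.rm = TRUE, names = FALSE)
    lo <- qs[1]; hi <- qs[2]; se <- sd(bk, na.rm = TRUE)
  }
  tibble(kappa = kap, conf.low = lo, conf.high = hi, se = se,
         band = interpret_kappa(kap), n = n, method = method)
}

kappa_point <- function(ia, ib, k, w) {
  O <- matrix(0, k, k)
  for (t in seq_along(ia)) O[ia[t], ib[t]] <- O[ia[t], ib[t]] + 1
  O <- O / length(ia)
  E <- outer(rowSums(O), colSums(O))
  1 - sum(w * O) / sum(w * E)
}

# large-sample SE of weighted kappa (Fleiss, Cohen & Everitt 1969), in the
# agreement-weight formulation u = 1 - w
kappa_se <- function(ia, ib, k, w, kap) {
  n <- length(ia)
  O <- matrix(0, k, k)
  for (t in seq_along(ia)) O[ia[t], ib[t]] <- O[ia[t], ib[t]] + 1
  O <- O / n
  p <- rowSums(O); q <- colSums(O)
  u <- 1 - w
  pe <- sum(outer(p, q) * u)
  ubar_row <- as.vector(u %*% q)        # sum_j q_j u_ij
  ubar_col <- as.vector(p %*% u)        # sum_i p_i u_ij
  term <- outer(ubar_row, ubar_col, "+")
  inner <- (u - term * (1 - kap))^2
  v <- (sum(O * inner) - (kap - pe * (1 - kap))^2) / (n * (1 - pe)^2)
  sqrt(max(v, 0))
}

#' Landis-Koch interpretation band for kappa
#'
#' @param kappa Numeric in `[-1, 1]`.
#' @return Character vector of band labels: negative values "poor (less than
#'   chance)", then "slight" (up to 0.20), "fair" (to 0.40), "moderate"
#'   (to 0.60), "substantial" (to 0.80), "almost perfect" (to 1).
#' @export
#' @examples
#' interpret_kappa(c(0.595, 0.729))
interpret_kappa <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa < -1 | kappa > 1)) {
    abort("kappa must lie in [-1, 1]", class = "steatr_error_domain")
  }
  dplyr::case_when(
    kappa < 0 ~ "poor (less than chance)",
    kappa <= 0.20 ~ "slight",
    kappa <= 0.40 ~ "fair",
    kappa <= 0.60 ~ "moderate",
    kappa <= 0.80 ~ "substantial",
    TRUE ~ "almost perfect"
  )
}

#' Bland-Altman limits of agreement
#'
#' Differences `d = x - y`, bias = mean(d), limits of agreement
#' `bias +- 1.96 * SD(d)` (sample SD), plus the per-case (reference, d)
#' table for the mean-difference plot.
#'
#' @inheritParams cor_pearson
#' @return A list of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `n`, and `table` (tibble with `reference` = pair mean and `diff`).
#' @export
bland_altman <- function(x, y) {
  p <- check_pairs(x, y, 2)
  d <- p$x - p$y
  s <- if (p$n > 1) sd(d) else 0
  structure(
    list(bias = mean(d), loa_low = mean(d) - 1.96 * s,
         loa_high = mean(d) + 1.96 * s, n = p$n,
         table = tibble(reference = (p$x + p$y) / 2, diff = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.3f, LoA [%.3f, %.3f], n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' @param x Numeric vector, 3 <= n <= 5000, non-constant.
#' @return One-row tibble: `statistic` (W), `p.value`, `n`.
#' @export
normality_test <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000) {
    abort("Shapiro-Wilk requires 3 <= n <= 5000",
          class = "steatr_error_domain")
  }
  if (sd(x) == 0) {
    abort("normality test undefined for a constant sample (zero variance)",
          class = "steatr_error_degenerate")
  }
  sw <- shapiro.test(x)
  tibble(statistic = unname(sw$statistic), p.value = sw$p.value,
         n = length(x))
}

#' Noise reduction from averaging independent raters
#'
#' When `n` raters with uncorrelated errors are averaged,
#' `Var(mean) = Var(individual) / n`, so the error SD shrinks by
#' `sqrt(1 / n)` — the reason correlations against a rater consensus exceed
#' correlations against individual raters.
#'
#' @param n Number of raters.
#' @return `sqrt(1 / n)`.
#' @export
#' @examples
#' averaging_noise_factor(3)  # ~0.58: a 3-rater mean has 58% of the noise
averaging_noise_factor <- function(n) {
  stopifnot(n >= 1)
  sqrt(1 / n)
}

#' R-squared of a bivariate correlation
#'
#' For simple bivariate correlation the coefficient of determination is the
#' square of Pearson's r.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @return `r^2`.
#' @export
#' @examples
#' r_to_r_squared(0.80)  # 0.64
r_to_r_squared <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) > 1)) {
    abort("r must lie in [-1, 1]", class = "steatr_error_domain")
  }
  r^2
}

# ---- rating-table (long tibble) operations --------------------------------

check_ratings <- function(ratings) {
  need <- c("case_id", "rater", "score_pct")
  if (!all(need %in% names(ratings))) {
    abort(sprintf("ratings must have columns %s", paste(need, collapse = ", ")),
          class = "steatr_error_domain")
  }
  sc <- ratings$score_pct
  if (any(is.finite(sc) & (sc < 0 | sc > 100))) {
    abort("scores must lie in [0, 100]", class = "steatr_error_domain")
  }
  dplyr::filter(ratings, is.finite(.data$score_pct))
}

ratings_wide <- function(ratings) {
  tidyr::pivot_wider(check_ratings(ratings),
                     id_cols = "case_id", names_from = "rater",
                     values_from = "score_pct")
}

# per-case AI score and mean over the other available raters
ai_vs_mean <- function(ratings, ai_rater) {
  r <- check_ratings(ratings)
  ai <- dplyr::filter(r, .data$rater == ai_rater)
  others <- dplyr::filter(r, .data$rater != ai_rater) |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(rater_mean = mean(.data$score_pct),
                     rater_min = min(.data$score_pct),
                     rater_max = max(.data$score_pct),
                     n_raters = dplyr::n(), .groups = "drop")
  dplyr::inner_join(ai[, c("case_id", "score_pct")], others, by = "case_id") |>
    dplyr::rename(ai = "score_pct")
}

#' Fraction of cases where the automated score falls within tolerance of the
#' rater mean
#'
#' For each case the reference is the mean over the raters that scored it
#' (averaging n raters reduces the error SD by `sqrt(1/n)`); the rate is the
#' fraction of cases with `|ai - mean| <= tol`, boundary inclusive, with the
#' tolerance in absolute percentage points. Cases without any reference
#' rater are excluded and counted.
#'
#' @param ratings Long tibble with columns `case_id`, `rater`, `score_pct`.
#' @param ai_rater Name of the automated rater. Default `"AI"`.
#' @param tol Tolerance in percentage points. Default 5.
#' @return One-row tibble: `rate`, `n`, `n_excluded`.
#' @export
tolerance_rate <- function(ratings, ai_rater = "AI", tol = 5) {
  cmp <- ai_vs_mean(ratings, ai_rater)
  n_ai <- dplyr::n_distinct(
    dplyr::filter(check_ratings(ratings), .data$rater == ai_rater)$case_id)
  tibble(
    rate = mean(abs(cmp$ai - cmp$rater_mean) <= tol),
    n = nrow(cmp),
    n_excluded = n_ai - nrow(cmp)
  )
}

#' Classify the automated score against the range of rater scores
#'
#' Per case: `higher` iff the automated score exceeds every rater's score,
#' `lower` iff it is below every rater's score, else `within` (inclusive at
#' the extremes).
#'
#' @inheritParams tolerance_rate
#' @return A list with `counts` (tibble `class`, `n` over higher/lower/within)
#'   and `cases` (per-case table with the classification).
#' @export
range_classification <- function(ratings, ai_rater = "AI") {
  cmp <- ai_vs_mean(ratings, ai_rater)
  cmp$class <- dplyr::case_when(
    cmp$ai > cmp$rater_max ~ "higher",
    cmp$ai < cmp$rater_min ~ "lower",
    TRUE ~ "within"
  )
  counts <- tibble(class = c("higher", "lower", "within")) |>
    dplyr::left_join(dplyr::count(cmp, .data$class), by = "class") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  list(counts = counts, cases = cmp)
}

#' Full rater-agreement report
#'
#' Computes, for every pair of raters with at least `min_overlap` common
#' cases, the continuous agreement statistics (Pearson r with CI and
#' R-squared, Spearman rho, RMSE), the ordinal agreement (quadratically
#' weighted kappa on [bin_category()] bins with its Landis-Koch band), and a
#' Bland-Altman analysis. When the table contains the automated rater, the
#' report additionally compares it with the mean of the other raters per
#' case, and adds the tolerance rate and range classification.
#'
#' @inheritParams tolerance_rate
#' @param min_overlap Minimum overlapping cases per pair. Default 3.
#' @param kappa_method Passed to [weighted_kappa()].
#' @return An object of class `agreement_report` with elements `pairs`
#'   (tidy per-pair statistics), `bland_altman` (named list), `tolerance`,
#'   `range` and `ai_rater`. `tidy()` returns the pair table, `glance()` a
#'   one-row summary.
#' @export
agreement_report <- function(ratings, ai_rater = "AI", tol = 5,
                             min_overlap = 3,
                             kappa_method = c("asymptotic", "bootstrap")) {
  kappa_method <- match.arg(kappa_method)
  r <- check_ratings(ratings)
  raters <- unique(r$rater)
  if (length(raters) < 2) {
    abort("agreement needs at least 2 raters", class = "steatr_error_usage")
  }
  wide <- ratings_wide(r)
  combos <- utils::combn(raters, 2, simplify = FALSE)
  has_ai <- ai_rater %in% raters
  if (has_ai) {
    cmp <- ai_vs_mean(r, ai_rater)
    wide_mean <- tibble(case_id = cmp$case_id, a = cmp$ai, b = cmp$rater_mean)
  }
  pair_row <- function(nm_a, nm_b, x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < min_overlap) {
      warn(sprintf("skipping pair %s vs %s: only %d overlapping cases",
                   nm_a, nm_b, length(x)))
      return(NULL)
    }
    pe <- tryCatch(cor_pearson(x, y), error = function(e) NULL)
    sp <- tryCatch(cor_spearman(x, y), error = function(e) NULL)
    ka <- tryCatch(weighted_kappa(x, y, method = kappa_method),
                   error = function(e) NULL)
    tibble(
      rater_a = nm_a, rater_b = nm_b, n = length(x),
      pearson_r = pe$estimate %||% NA_real_,
      r_conf.low = pe$conf.low %||% NA_real_,
      r_conf.high = pe$conf.high %||% NA_real_,
      r_squared = pe$r.squared %||% NA_real_,
      pearson_p = pe$p.value %||% NA_real_,
      spearman_rho = sp$estimate %||% NA_real_,
      spearman_p = sp$p.value %||% NA_real_,
      rmse = rmse(x, y),
      kappa = ka$kappa %||% NA_real_,
      kappa_conf.low = ka$conf.low %||% NA_real_,
      kappa_conf.high = ka$conf.high %||% NA_real_,
      kappa_band = ka$band %||% NA_character_
    )
  }
  pairs <- purrr::map(combos, function(cb) {
    pair_row(cb[1], cb[2], wide[[cb[1]]], wide[[cb[2]]])
  })
  ba <- list()
  for (cb in combos) {
    ok <- is.finite(wide[[cb[1]]]) & is.finite(wide[[cb[2]]])
    if (sum(ok) >= 2) {
      ba[[paste(cb[1], "vs", cb[2])]] <-
        bland_altman(wide[[cb[1]]][ok], wide[[cb[2]]][ok])
    }
  }
  if (has_ai && nrow(wide_mean) >= min_overlap) {
    pairs <- c(pairs, list(pair_row(ai_rater, "mean(others)",
                                    wide_mean$a, wide_mean$b)))
    ba[[paste(ai_rater, "vs mean(others)")]] <-
      bland_altman(wide_mean$a, wide_mean$b)
  }
  structure(
    list(
      pairs = dplyr::bind_rows(pairs),
      bland_altman = ba,
      tolerance = if (has_ai) tolerance_rate(r, ai_rater, tol) else NULL,
      range = if (has_ai) range_classification(r, ai_rater) else NULL,
      ai_rater = if (has_ai) ai_rater else NA_character_,
      n_raters = length(raters)
    ),
    class = "agreement_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d raters, %d pair comparisons\n",
              x$n_raters, nrow(x$pairs)))
  print(x$pairs[, c("rater_a", "rater_b", "n", "pearson_r", "r_squared",
                    "rmse", "kappa", "kappa_band")])
  if (!is.null(x$tolerance)) {
    cat(sprintf("AI within tolerance of rater mean: %.1f%% of %d cases\n",
                100 * x$tolerance$rate, x$tolerance$n))
  }
  invisible(x)
}
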