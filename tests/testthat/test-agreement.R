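test_that("Pearson r matches the covariance formula and its CI behaves", {
  expect_equal(cor_pearson(1:10, 3 * (1:10) - 7)$estimate, 1)
  expect_equal(cor_pearson(1:10, 3 * (1:10) - 7)$r.squared, 1)
  set.seed(8)
  for (i in 1:100) {
    x <- rnorm(30)
    y <- 0.6 * x + rnorm(30) * 0.8
    got <- cor_pearson(x, y)
    expect_equal(got$estimate, oracle_pearson(x, y), tolerance = 1e-12)
    expect_identical(got$r.squared, got$estimate^2)
    expect_true(got$conf.low <= got$estimate && got$estimate <= got$conf.high)
  }
  expect_error(cor_pearson(rep(1, 5), 1:5),
               class = "steatr_error_degenerate")
  # invariance under positive affine transforms
  set.seed(9); x <- runif(20); y <- runif(20)
  expect_equal(cor_pearson(2 * x + 3, y)$estimate,
               cor_pearson(x, y)$estimate, tolerance = 1e-12)
})

test_that("Spearman rho is Pearson on midranks", {
  expect_equal(cor_spearman(1:8, 8:1)$estimate, -1)
  expect_error(cor_spearman(rep(2, 6), 1:6),
               class = "steatr_error_degenerate")
  set.seed(12)
  for (i in 1:100) {
    x <- sample(0:10, 25, replace = TRUE)      # heavy ties
    y <- sample(0:10, 25, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(cor_spearman(x, y)$estimate,
                 oracle_pearson(rank(x), rank(y)), tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  set.seed(13); x <- runif(30); y <- x + rnorm(30, 0, 0.2)
  expect_equal(cor_spearman(exp(3 * x), y)$estimate,
               cor_spearman(x, y)$estimate, tolerance = 1e-12)
})

test_that("rmse matches its definition", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(4, 5, 6), c(1, 2, 3)), 3)
  set.seed(14)
  for (i in 1:100) {
    x <- runif(15, 0, 40); y <- runif(15, 0, 40)
    expect_equal(rmse(x, y), sqrt(mean((x - y)^2)), tolerance = 1e-12)
  }
})

test_that("weighted kappa matches a brute-force double summation", {
  set.seed(15)
  for (i in 1:100) {
    a <- pmin(100, pmax(0, rnorm(40, 12, 10)))
    b <- pmin(100, pmax(0, a + rnorm(40, 0, 7)))
    ia <- as.integer(bin_category(a)); ib <- as.integer(bin_category(b))
    if (length(unique(ia)) < 2 || length(unique(ib)) < 2) next
    got <- weighted_kappa(a, b)$kappa
    expect_equal(got, oracle_kappa(ia, ib, 7), tolerance = 1e-12)
    # symmetry in the two raters
    expect_equal(weighted_kappa(b, a)$kappa, got, tolerance = 1e-12)
  }
})

test_that("kappa is 1 on self-agreement and drops under a category shift", {
  a <- c(0, 3, 7, 12, 18, 25, 40, 2, 9, 14, 22, 33, 6, 11)
  expect_equal(weighted_kappa(a, a)$kappa, 1)
  shifted_bin <- pmin(as.integer(bin_category(a)) + 1L, 7L)
  bins <- steatosis_bins()
  k_shift <- weighted_kappa(bin_category(a), bins[shifted_bin])$kappa
  expect_lt(k_shift, 1)
  expect_error(weighted_kappa(rep(2, 10), seq(1, 40, length.out = 10)),
               class = "steatr_error_degenerate")
  # the bootstrap interval is seeded and reproducible
  b <- pmin(100, pmax(0, a + c(2, -3, 4, -2, 5, -4, 3, 1, -2, 4, -5, 2, 3, -1)))
  k1 <- weighted_kappa(a, b, method = "bootstrap", boot_n = 200, boot_seed = 4)
  k2 <- weighted_kappa(a, b, method = "bootstrap", boot_n = 200, boot_seed = 4)
  expect_identical(k1, k2)
  expect_equal(k1$kappa, weighted_kappa(a, b)$kappa)
})

test_that("quadratic weights span 0 within a bin to 1 across the full range", {
  # two cases in the extreme bins realize the endpoint weights: kappa of a
  # 2x2 table concentrated on the diagonal is 1, fully off-diagonal is < 0
  a <- c(0, 0, 40, 40)
  expect_equal(weighted_kappa(a, a)$kappa, 1)
  expect_lt(weighted_kappa(a, c(40, 40, 0, 0))$kappa, 0)
})

test_that("Landis-Koch bands reproduce the published labels", {
  expect_equal(interpret_kappa(0.595), "moderate")
  expect_equal(interpret_kappa(0.729), "substantial")
  expect_equal(interpret_kappa(0.205), "fair")
  expect_equal(interpret_kappa(0.15), "slight")
  expect_equal(interpret_kappa(0.9), "almost perfect")
  expect_equal(interpret_kappa(-0.2), "poor (less than chance)")
  expect_error(interpret_kappa(1.2), class = "steatr_error_domain")
})

test_that("Bland-Altman bias and limits match their definitions", {
  ba0 <- bland_altman(c(1, 5, 9), c(1, 5, 9))
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  ba3 <- bland_altman(4:13 + 3, 4:13)
  expect_equal(ba3$bias, 3)
  expect_equal(c(ba3$loa_low, ba3$loa_high), c(3, 3))
  set.seed(16)
  for (i in 1:100) {
    x <- runif(12, 0, 40); y <- x + rnorm(12, 1, 2)
    ba <- bland_altman(x, y)
    d <- x - y
    expect_equal(ba$bias, mean(d), tolerance = 1e-12)
    expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
    expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
    expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)
  }
  expect_s3_class(ggplot2::autoplot(ba3), "ggplot")
})

make_ratings <- function(ai, raters) {
  long <- list(tibble::tibble(case_id = seq_along(ai), rater = "AI",
                              score_pct = ai))
  for (nm in names(raters)) {
    long <- c(long, list(tibble::tibble(case_id = seq_along(raters[[nm]]),
                                        rater = nm,
                                        score_pct = raters[[nm]])))
  }
  out <- dplyr::bind_rows(long)
  out[is.finite(out$score_pct), ]
}

test_that("tolerance rate counts absolute deviations, boundary inclusive", {
  ai <- c(5, 10, 20, 8)
  rt <- make_ratings(ai, list(P1 = ai, P2 = ai))
  expect_equal(tolerance_rate(rt)$rate, 1)

  rt5 <- make_ratings(c(10, 20, 30), list(P1 = c(5, 15, 25)))
  expect_equal(tolerance_rate(rt5)$rate, 1)          # all diffs exactly 5

  # a case scored only by the AI is excluded and counted
  rt_ex <- make_ratings(c(10, 20, 30), list(P1 = c(12, 18, NA)))
  out <- tolerance_rate(rt_ex)
  expect_equal(out$n, 2)
  expect_equal(out$n_excluded, 1)

  set.seed(17)
  ai <- runif(40, 0, 40)
  p1 <- pmin(100, pmax(0, ai + rnorm(40, 0, 6)))
  p2 <- pmin(100, pmax(0, ai + rnorm(40, 0, 6)))
  got <- tolerance_rate(make_ratings(ai, list(P1 = p1, P2 = p2)))$rate
  expect_equal(got, mean(abs(ai - (p1 + p2) / 2) <= 5))
})

test_that("range classification is inclusive at the extremes", {
  rt <- make_ratings(c(9, 3, 6, 4), list(P1 = c(4, 4, 4, 4),
                                         P2 = c(8, 8, 8, 4)))
  rc <- range_classification(rt)
  expect_equal(rc$cases$class, c("higher", "lower", "within", "within"))
  expect_equal(rc$counts$n[rc$counts$class == "higher"], 1L)
  set.seed(18)
  ai <- runif(50, 0, 40)
  p1 <- runif(50, 0, 40); p2 <- runif(50, 0, 40)
  rc2 <- range_classification(make_ratings(ai, list(P1 = p1, P2 = p2)))
  manual <- ifelse(ai > pmax(p1, p2), "higher",
                   ifelse(ai < pmin(p1, p2), "lower", "within"))
  expect_equal(rc2$cases$class[order(rc2$cases$case_id)], manual)
})

test_that("Shapiro-Wilk wrapper is calibrated under the null and powered", {
  set.seed(19)
  p_null <- vapply(1:100, function(i) normality_test(rnorm(200))$p.value,
                   numeric(1))
  expect_gte(mean(p_null > 0.05), 0.90)
  set.seed(20)
  expect_lt(normality_test(exp(rnorm(100, 0, 1.5)))$p.value, 0.001)
  expect_error(normality_test(rep(3, 10)), class = "steatr_error_degenerate")
  expect_error(normality_test(c(1, 2)), class = "steatr_error_domain")
})

test_that("averaging three raters shrinks the error SD by about sqrt(1/3)", {
  set.seed(22)
  truth <- runif(1000, 0, 30)
  raters <- replicate(3, truth + rnorm(1000, 0, 4))
  sd_single <- sd(raters[, 1] - truth)
  sd_mean <- sd(rowMeans(raters) - truth)
  expect_equal(sd_mean / sd_single, averaging_noise_factor(3),
               tolerance = 0.10)
  expect_equal(round(averaging_noise_factor(3), 2), 0.58)
})

test_that("the agreement report composes the module statistics faithfully", {
  set.seed(24)
  truth <- pmin(100, pmax(0, rexp(60, 1 / 10)))
  ai <- pmin(100, pmax(0, truth + rnorm(60, 1, 4)))
  p1 <- pmin(100, pmax(0, truth + rnorm(60, 0, 5)))
  p2 <- pmin(100, pmax(0, truth + rnorm(60, -1, 5)))
  p2[50:60] <- NA                      # partial coverage, pairwise deletion
  rt <- make_ratings(ai, list(P1 = p1, P2 = p2))
  rep <- agreement_report(rt)
  expect_s3_class(rep, "agreement_report")
  expect_equal(nrow(rep$pairs), 4)     # 3 pairs + AI vs mean(others)

  row <- dplyr::filter(rep$pairs, rater_a == "AI", rater_b == "P1")
  direct <- cor_pearson(ai, p1)
  expect_equal(row$pearson_r, direct$estimate)
  expect_equal(row$r_squared, direct$r.squared)
  expect_equal(row$rmse, rmse(ai, p1))
  expect_equal(row$kappa, weighted_kappa(ai, p1)$kappa)

  ok <- is.finite(p2)
  row2 <- dplyr::filter(rep$pairs, rater_a == "P1", rater_b == "P2")
  expect_equal(row2$n, sum(ok))
  expect_equal(row2$spearman_rho, cor_spearman(p1[ok], p2[ok])$estimate)

  gl <- glance(rep)
  expect_equal(gl$tolerance_rate, tolerance_rate(rt)$rate)
  expect_equal(nrow(tidy(rep)), 4)

  expect_error(agreement_report(make_ratings(ai, list())),
               class = "steatr_error_usage")
})
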