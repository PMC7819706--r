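test_that("phylostratigraphy slopes recover exact linear relationships", {
  d <- tibble::tibble(age_my = seq(100, 4000, length.out = 30))
  d$value <- 1 - 0.05 * d$age_my / 1000
  td <- tidy(phylostrat_slope(d, "value"))
  expect_equal(td$slope, -0.05)
  expect_equal(td$r_squared, 1)
  expect_equal(td$n, 30L)
  expect_true(td$ci_low <= td$slope && td$slope <= td$ci_high)
  # constant response: zero slope
  d$value <- 0.7
  expect_equal(tidy(phylostrat_slope(d, "value"))$slope, 0, tolerance = 1e-12)
  # fewer than 3 points: no fit, with a message
  expect_message(res <- phylostrat_slope(d[1:2, ], "value"), "Fewer than 3")
  expect_null(res)
})

test_that("slopes are equivariant under age scaling and value shifts", {
  set.seed(3)
  d <- tibble::tibble(age_my = runif(40, 0, 4000), value = rnorm(40))
  base <- tidy(phylostrat_slope(d, "value"))$slope
  d2 <- dplyr::mutate(d, age_my = age_my * 2)
  expect_equal(tidy(phylostrat_slope(d2, "value"))$slope, base / 2)
  d3 <- dplyr::mutate(d, value = value + 5)
  expect_equal(tidy(phylostrat_slope(d3, "value"))$slope, base)
  # scale argument multiplies the response
  expect_equal(tidy(phylostrat_slope(d, "value", scale = 100))$slope,
               100 * base)
})

test_that("per-amino-acid slopes are mutually constrained to sum to zero", {
  set.seed(8)
  n <- 60
  comp <- matrix(rexp(20 * n), n, 20)
  comp <- comp / rowSums(comp)
  colnames(comp) <- phylotrends:::AA_STANDARD
  d <- dplyr::bind_cols(tibble::tibble(age_my = runif(n, 0, 4000)),
                        tibble::as_tibble(comp))
  prof <- aa_slope_profile(d)
  expect_equal(nrow(prof), 20L)
  expect_equal(sum(prof$slope), 0, tolerance = 1e-9)
  # flat compositions give zero slopes
  d2 <- d
  d2[phylotrends:::AA_STANDARD] <- rep(as.list(rep(0.05, 20)), 1)
  prof2 <- aa_slope_profile(d2)
  expect_equal(prof2$slope, rep(0, 20), tolerance = 1e-12)
})

test_that("profile correlations match a brute-force rank oracle", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  cr <- correlate_profiles(x, y, method = "spearman")
  expect_equal(cr$rho, oracle_spearman(x, y), tolerance = 1e-12)
  expect_equal(correlate_profiles(x, x)$rho, 1)
  expect_equal(correlate_profiles(x, -x)$rho, -1)
  # symmetry
  expect_equal(correlate_profiles(y, x)$rho, cr$rho)
  # invariance under monotone transforms
  expect_equal(correlate_profiles(exp(x), y)$rho, cr$rho)
  # pearson agrees with the closed form
  cp <- correlate_profiles(x, y, method = "pearson")
  expect_equal(cp$rho, cov(x, y) / (sd(x) * sd(y)))
  # missing entries dropped pairwise; tiny n yields no p-value
  cr2 <- correlate_profiles(c(x, NA), c(y, 1))
  expect_equal(cr2$n, 8L)
  expect_true(is.na(correlate_profiles(1:3, c(2, 1, 3))$p_value))
})

test_that("Fisher-transform standard errors attach to Spearman rho", {
  set.seed(12)
  x <- rnorm(20)
  y <- x + rnorm(20)
  cr <- correlate_profiles(x, y)
  expect_equal(cr$fisher_se, sqrt(1.06 / 17))
  expect_equal(cr$rho_low, tanh(atanh(cr$rho) - cr$fisher_se))
  expect_equal(cr$rho_high, tanh(atanh(cr$rho) + cr$fisher_se))
  expect_true(cr$rho_low < cr$rho && cr$rho < cr$rho_high)
  expect_true(is.na(correlate_profiles(x, y, method = "pearson")$fisher_se))
})

test_that("consensus recruitment order is the mean rank over retained criteria", {
  m1 <- matrix(1:20, 20, 1, dimnames = list(LETTERS[1:20], "c1"))
  expect_equal(unname(consensus_recruitment_order(m1)), 1:20)
  # two mutually reversed rankings
  m2 <- cbind(c1 = 1:20, c2 = 20:1)
  expect_equal(unname(consensus_recruitment_order(m2)), rep(10.5, 20))
  # excluding a column equals recomputing on the reduced matrix
  set.seed(4)
  m3 <- phylotrends::synthetic_recruitment_criteria(m = 5)
  expect_equal(consensus_recruitment_order(m3, excluded_criteria = "criterion_03"),
               consensus_recruitment_order(m3[, -3]))
  expect_error(consensus_recruitment_order(m3, excluded_criteria = colnames(m3)),
               "All criteria excluded")
  expect_error(consensus_recruitment_order(m3, excluded_criteria = "nope"),
               "Unknown")
})

test_that("minimum-age sweeps reduce to the full-profile correlation at zero", {
  set.seed(19)
  aa <- phylotrends:::AA_STANDARD
  props <- synthetic_aa_properties()
  rank_vec <- setNames(props$recruitment_rank, props$aa)
  # compositions whose trend follows -rank only above the LECA age
  n <- 120
  ages <- c(runif(n / 2, 100, 2000), runif(n / 2, 2300, 4090))
  base <- rep(1 / 20, 20)
  comp <- t(vapply(ages, function(a) {
    drift <- if (a > 2101) -(rank_vec - mean(rank_vec)) * 2e-3 * (a - 2101) / 1000 else 0
    x <- base + drift + rnorm(20, 0, 5e-4)
    x / sum(x)
  }, numeric(20)))
  colnames(comp) <- aa
  d <- dplyr::bind_cols(tibble::tibble(age_my = ages), tibble::as_tibble(comp))
  sweep <- min_age_sweep(d, thresholds = c(0, 2101, 5000), rank_vec)
  full <- aa_slope_profile(d)
  direct <- correlate_profiles(full$slope, unname(rank_vec[full$aa]))
  expect_equal(sweep$rho[1], direct$rho)
  # planted signal: correlation strongest when only old strata are included
  expect_true(abs(sweep$rho[2]) >= abs(sweep$rho[1]))
  expect_lte(sweep$rho[2], -0.5)
  # a threshold above all ages yields a missing entry
  expect_true(is.na(sweep$rho[3]))
})

test_that("group comparisons cover Welch, paired Wilcoxon, and the sign test", {
  # identical paired vectors: no nonzero differences
  w <- group_comparisons(c(1, 2, 3), c(1, 2, 3), type = "wilcoxon")
  expect_equal(w$p_value, 1)
  # paired alignment by keys; mismatched keys error
  expect_error(group_comparisons(1:3, 1:3, type = "wilcoxon",
                                 keys_a = c("a", "b", "c"),
                                 keys_b = c("a", "b", "d")),
               "matching keys")
  wk <- group_comparisons(c(1, 2, 3), c(3.5, 1.2, 2.1), type = "wilcoxon",
                          keys_a = c("a", "b", "c"), keys_b = c("c", "a", "b"))
  expect_equal(wk$estimate, median(c(1, 2, 3) - c(1.2, 2.1, 3.5)))
  # exact one-tailed binomial tail for 6 positives of 9
  b <- group_comparisons(c(rep(1, 6), rep(-1, 3)), type = "binomial")
  expect_equal(b$p_value, 130 / 512)
  expect_equal(b$statistic, 6)
  # Welch on clearly separated groups
  set.seed(10)
  we <- group_comparisons(rnorm(30, 1), rnorm(30, 0), type = "welch")
  expect_lt(we$p_value, 0.01)
  expect_gt(we$estimate, 0)
})

test_that("transforms: Box-Cox closed forms, lambda recovery, arcsine domain", {
  x <- rexp(50) + 0.5
  t1 <- transform_values(x, "boxcox", lambda = 1)
  expect_equal(t1$transformed, x - 1)
  t0 <- transform_values(x, "boxcox", lambda = 0)
  expect_equal(t0$transformed, log(x))
  # ML lambda recovery within 0.2 at n = 500
  set.seed(14)
  lam <- 0.5
  y <- (lam * rnorm(500, 8, 1) + 1)^(1 / lam)
  fit <- transform_values(y, "boxcox")
  expect_lt(abs(fit$lambda - lam), 0.2)
  # arcsine endpoints and domain
  ta <- transform_values(c(0, 1, 0.25), "arcsine")
  expect_equal(ta$transformed, c(0, pi / 2, asin(sqrt(0.25))))
  expect_error(transform_values(c(-0.1, 0.5), "arcsine"), "\\[0, 1\\]")
  # non-positive values shift before Box-Cox, recorded
  ts <- transform_values(c(-1, 0, 2), "boxcox", lambda = 1)
  expect_gt(ts$shift, 1)
})
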