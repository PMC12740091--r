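# ROI and vertexwise age-association statistics

test_that("age regression recovers exact linear relationships", {
  age <- seq(20, 84, length.out = 40)
  sex <- rep(c(0, 1), 20)
  y <- 2 + 0.05 * age
  # summary.lm warns on an exactly perfect fit; that is the fixture's point
  fit <- suppressWarnings(ols_age_model(y, age, sex, model = "M3"))
  expect_equal(fit$beta1, 0.05, tolerance = 1e-12)
  expect_equal(fit$beta0, 2, tolerance = 1e-10)
  expect_lt(fit$p, 1e-12)
  expect_equal(fit$r, 1)
  # sex coding does not affect the age t-statistic
  yn <- y + 0.3 * sex + withr::with_seed(1, stats::rnorm(40, 0, 0.2))
  fit2 <- ols_age_model(yn, age, sex, model = "M3")
  fit3 <- ols_age_model(yn, age, 1 - sex, model = "M3")
  expect_equal(fit2$t, fit3$t, tolerance = 1e-9)
  expect_error(ols_age_model(y, age, NULL, model = "M3"), "require")
  expect_error(ols_age_model(y, age, sex = age, model = "M3"), "collinear")
})

test_that("the r <-> t identity holds for every age-only fit", {
  set.seed(4)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    age <- stats::runif(n, 19, 85)
    y <- stats::rnorm(n) + stats::runif(1, -0.05, 0.05) * age
    fit <- ols_age_model(y, age, model = "M1")
    expect_equal(fit$t, fit$r * sqrt(fit$n - 2) / sqrt(1 - fit$r^2),
                 tolerance = 1e-10)
  }
  # the printed identity at r = 0.5, n = 72: t = 0.5 sqrt(70) / sqrt(0.75)
  age <- seq(19, 85, length.out = 72)
  # construct y with exact sample correlation 0.5
  x <- scale(age)[, 1]
  z <- stats::residuals(stats::lm(stats::rnorm(72) ~ x))
  y <- 0.5 * x + sqrt(1 - 0.25) * scale(z)[, 1]
  fit <- ols_age_model(y, age, model = "M1")
  expect_equal(fit$r, 0.5, tolerance = 1e-10)
  expect_equal(fit$t, 0.5 * sqrt(70) / sqrt(0.75), tolerance = 1e-8)
})

test_that("null data yield calibrated age-coefficient p-values", {
  set.seed(7)
  age <- stats::runif(36, 19, 85)
  sex <- rep(c(0, 1), 18)
  base <- stats::rnorm(36)
  X <- cbind(1, age, sex)
  XtXinv <- solve(crossprod(X))
  rejections <- replicate(500, {
    y <- sample(base)
    b <- XtXinv %*% crossprod(X, y)
    r <- y - X %*% b
    se <- sqrt(sum(r^2) / (36 - 3) * XtXinv[2, 2])
    p <- 2 * stats::pt(-abs(b[2] / se), 36 - 3)
    p < 0.05
  })
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("BH adjustment equals the brute-force step-up", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(12)
  for (i in 1:50) {
    p <- stats::runif(sample(c(1, 2, 5, 20, 100), 1))^sample(1:3, 1)
    adj <- bh_fdr(p)
    expect_equal(adj, bh_brute_force(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # step-up monotonicity: adjusted values ordered like the raw ones
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("Welch t from summaries reproduces the raw-data statistic", {
  # the cohort's printed male/female age summaries
  res <- welch_t_from_summary(32, 42.25, 17.99, 40, 40.75, 17.98)
  expect_lt(abs(res$t - 0.3517), 1e-4)
  expect_equal(res$p, 0.7261, tolerance = 1e-3)
  expect_equal(welch_t_from_summary(10, 5, 2, 12, 5, 2)$t, 0)
  # summaries computed from raw samples reproduce t.test exactly
  set.seed(3)
  a <- stats::rnorm(14, 50, 9); b <- stats::rnorm(21, 46, 11)
  res2 <- welch_t_from_summary(14, mean(a), stats::sd(a),
                               21, mean(b), stats::sd(b))
  tt <- stats::t.test(a, b)
  expect_equal(res2$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res2$dof, unname(tt$parameter), tolerance = 1e-12)
  expect_error(welch_t_from_summary(5, 1, 0, 5, 1, 1), "> 0")
})

test_that("nested model comparison behaves as a likelihood-ratio test", {
  age <- seq(19, 85, length.out = 60)
  sex <- rep(c(0, 1), 30)
  d1 <- age_model_design(age, model = "M1")
  d4 <- age_model_design(age, sex, model = "M4")
  set.seed(8)
  y <- stats::rnorm(60)
  expect_equal(lrt_nested(y, d1, d1)$statistic, 0)
  expect_equal(lrt_nested(y, d1, d1)$p, 1)
  # a strong true quadratic term is detected
  yq <- 0.002 * (age - 50)^2 + stats::rnorm(60, 0, 0.5)
  d2 <- age_model_design(age, model = "M2")
  expect_lt(lrt_nested(yq, d1, d2)$p, 1e-3)
  # null: adding a pure-noise column gives uniform p-values
  noise_col <- stats::rnorm(60)
  ps <- replicate(400, {
    yn <- stats::rnorm(60)
    lrt_nested(yn, d1, cbind(d1, sample(noise_col)))$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_error(lrt_nested(y, cbind(1, sex), d2), "nested")
})

test_that("vertexwise regression maps r, t and FDR across the template", {
  v <- simulate_vertex_cohort(40, 300, slope = 0, noise_sd = 1, seed = 21)
  res <- vertexwise_regression(v$maps, v$age, v$sex)
  expect_equal(nrow(res), 300)
  expect_lte(mean(res$significant), 0.05)
  expect_true(all(res$p_fdr >= res$p))
  # constant metric: r = 0 everywhere
  cmaps <- matrix(5, 40, 10)
  rc <- vertexwise_regression(cmaps, v$age, v$sex)
  expect_equal(rc$r, rep(0, 10))
  # effect injected in a labelled patch localises
  slope <- rep(0, 300); slope[41:80] <- 0.08
  ve <- simulate_vertex_cohort(60, 300, slope = slope, noise_sd = 1,
                               seed = 22)
  re <- vertexwise_regression(ve$maps, ve$age, ve$sex)
  found <- which(re$significant)
  jacc <- length(intersect(found, 41:80)) / length(union(found, 41:80))
  expect_gt(jacc, 0.5)
  expect_error(vertexwise_regression(v$maps, v$age[-1], v$sex[-1]),
               "covariate length")
})

test_that("spatial correlation matrices match brute-force Pearson", {
  set.seed(9)
  maps <- matrix(stats::rnorm(500 * 4), 500, 4,
                 dimnames = list(NULL, c("a", "b", "c", "d")))
  maps[sample(2000, 40)] <- NA
  res <- spatial_correlation_matrix(maps)
  expect_equal(diag(res$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(res$r, t(res$r))
  for (i in 1:3) for (j in (i + 1):4) {
    ok <- stats::complete.cases(maps[, c(i, j)])
    expect_equal(res$r[i, j], stats::cor(maps[ok, i], maps[ok, j]),
                 tolerance = 1e-12)
  }
  expect_equal(res$r[cbind(1:4, 1:4)], rep(1, 4))
  neg <- cbind(x = maps[, 1], y = -maps[, 1])
  resn <- spatial_correlation_matrix(neg)
  expect_equal(resn$r[1, 2], -1)
  expect_error(spatial_correlation_matrix(matrix(c(1, 2, NA, NA, NA, 1),
                                                 3, 2)), "fewer than 3")
})

test_that("ROI summaries are unweighted vertex means", {
  maps <- rbind(s1 = c(1, 1, 5, 5, 9), s2 = c(2, 2, 6, 6, 10))
  labels <- c("CA1", "CA1", "DG", "DG", "Sub")
  res <- roi_summary(maps, labels, subjects = c("s1", "s2"))
  expect_equal(res$value[res$roi == "CA1"], c(1, 2))
  expect_equal(res$value[res$roi == "Sub"], c(9, 10))
  # uniform map returns the constant
  resu <- roi_summary(matrix(3, 2, 5), labels)
  expect_true(all(resu$value == 3))
  # NA vertices (e.g. DG thickness) are dropped; an all-NA ROI errors
  mth <- maps; mth[, 3:4] <- NA
  expect_error(roi_summary(mth, labels), "no defined vertices")
  mth2 <- maps; mth2[, 3] <- NA
  res2 <- roi_summary(mth2, labels)
  expect_equal(res2$value[res2$roi == "DG"], c(5, 6))
  # documents the unweighted choice: area weighting shifts a skewed-area
  # fixture by the analytic amount
  areas <- c(4, 1)
  vals <- maps[1, 1:2] * c(1, 3)   # make the two CA1 vertices differ: 1, 3
  unweighted <- mean(vals)
  weighted <- sum(areas * vals) / sum(areas)
  expect_equal(unweighted - weighted, mean(c(1, 3)) - 7 / 5)
  got <- roi_summary(rbind(vals), c("CA1", "CA1"))
  expect_equal(got$value, unweighted)
})

test_that("cohort-table regression applies per-metric FDR families", {
  cohort <- simulate_cohort(seed = 77)
  fit <- age_regression(cohort, model = "M3")
  expect_s3_class(fit, "hippo_age_fit")
  expect_equal(sort(unique(fit$roi)), sort(subfield_params()$roi))
  expect_equal(nrow(fit), 5 * 6)
  # FDR applied within each metric across its 6 ROIs
  for (m in unique(fit$metric)) {
    sel <- fit$metric == m
    expect_equal(fit$p_fdr[sel], bh_fdr(fit$p[sel]))
  }
  # the injected negative f_soma trend is detected
  fs <- fit[fit$metric == "f_soma", ]
  expect_true(all(fs$r < 0))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
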