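# spherical means, SNR estimation, training and tree-ensemble inversion

test_that("shell means are normalised per-voxel powder averages", {
  # constant shell value v with b0 = w gives v / w
  d <- c(3, 3, 3)
  bvals <- c(0, 0.8, 0.8, 2.4, 2.4)
  bvecs <- rbind(c(0, 0, 0), diag(3)[c(1, 2), ], diag(3)[c(1, 3), ])
  data <- array(0, c(d, 5))
  data[, , , 1] <- 50
  data[, , , 2] <- data[, , , 3] <- 30
  data[, , , 4] <- data[, , , 5] <- 10
  dwi <- new_dwi_volume(data, bvals, bvecs)
  sm <- spherical_mean_shells(dwi)
  expect_equal(unname(sm$means[, 1]), rep(30 / 50, 27))
  expect_equal(unname(sm$means[, 2]), rep(10 / 50, 27))
  # global rescaling leaves the normalised means unchanged
  dwi2 <- dwi; dwi2$data <- dwi$data * 7.3
  expect_equal(spherical_mean_shells(dwi2)$means, sm$means)
  # missing b0 errors
  dwi3 <- new_dwi_volume(data[, , , -1, drop = FALSE], bvals[-1], bvecs[-1, ])
  expect_error(spherical_mean_shells(dwi3), "b = 0")
})

test_that("direction-sampled stick signal matches the closed form", {
  # 64 quasi-uniform directions sampling exp(-b D (g.n)^2) for a z-stick
  dirs <- fibonacci_directions(64)
  b <- 3.45; d_in <- 2
  d <- c(2, 2, 2)
  data <- array(0, c(d, 65))
  data[, , , 1] <- 1
  for (i in seq_len(64))
    data[, , , i + 1] <- exp(-b * d_in * dirs[i, 3]^2)
  dwi <- new_dwi_volume(data, c(0, rep(b, 64)),
                        rbind(c(0, 0, 0), dirs))
  sm <- spherical_mean_shells(dwi)
  expect_lt(abs(sm$means[1, 1] - sphmean_stick(b, d_in)) /
              sphmean_stick(b, d_in), 0.005)
})

test_that("SNR estimation follows the variance-domain upsampling rule", {
  b0 <- array(100, c(4, 4, 4))
  sig <- array(2, c(4, 4, 4))
  out <- estimate_snr(b0, sig)
  expect_equal(unname(out$snr), array(50, c(4, 4, 4)))
  expect_equal(out$median_snr, 50)
  # block-constant variance map: in-block SNR unchanged after upsampling
  b0h <- array(100, c(4, 4, 4))
  sigl <- array(2, c(2, 2, 2))
  outh <- estimate_snr(b0h, sigl, upsample_factor = 2)
  expect_equal(unname(outh$snr), array(50, c(4, 4, 4)))
  # zero sigma in-mask is a hard error naming the voxel count
  sig0 <- sig; sig0[1:3] <- 0
  expect_error(estimate_snr(b0, sig0), "3 in-mask")
  # Rician data at known sigma: median estimated SNR within 10% of nominal
  nominal <- 50
  b0s <- withr::with_seed(11, add_rician_noise(array(100, c(6, 6, 6, 20)),
                                               100 / nominal))
  est <- estimate_snr(apply(b0s, 1:3, mean), estimate_noise_sigma(b0s))
  expect_lt(abs(est$median_snr - nominal) / nominal, 0.10)
})

test_that("training sets are reproducible simplex samples of the prior", {
  ts <- build_training_set(5000, small_protocol(), seed = 42)
  fr <- ts$targets$f_soma + ts$targets$f_neurite
  expect_true(all(fr <= 1 + 1e-12))
  expect_true(all(1 - ts$targets$f_soma - ts$targets$f_neurite >= -1e-12))
  ts2 <- build_training_set(5000, small_protocol(), seed = 42)
  expect_identical(ts$signals, ts2$signals)
  expect_identical(ts$targets, ts2$targets)
  # marginal of r_soma uniform on [1, 12]
  ks <- stats::ks.test(ts$targets$r_soma, "punif", 1, 12)
  expect_gt(ks$p.value, 0.01)
  # noiseless signals are the exact forward model
  expect_equal(ts$signals, sandi_signal_matrix(ts$targets, small_protocol()),
               tolerance = 1e-14)
})

test_that("inverter training is deterministic and degenerate targets error", {
  ts <- build_training_set(400, small_protocol(), seed = 3)
  inv1 <- train_sandi_inverter(ts, n_trees = 20)
  inv2 <- train_sandi_inverter(ts, n_trees = 20)
  probe <- build_training_set(50, small_protocol(), seed = 4)
  expect_equal(predict(inv1, probe$signals), predict(inv2, probe$signals))
  ts_bad <- ts
  ts_bad$targets$d_in <- 1.5
  expect_error(train_sandi_inverter(ts_bad, 20), "degenerate")
})

test_that("closed-loop recovery is accurate to the model's identifiability", {
  proto <- small_protocol()
  ts <- build_training_set(4000, proto, seed = 10)
  inv <- train_sandi_inverter(ts, n_trees = 50)
  test <- build_training_set(800, proto, seed = 11)
  pred <- predict(inv, test$signals)
  # fractions: informative recovery (prior sd of f_soma on the simplex is
  # ~0.24; the model space itself limits RMSE to ~0.15, see vignette)
  expect_lt(sqrt(mean((pred$f_soma - test$targets$f_soma)^2)), 0.2)
  expect_gt(stats::cor(pred$f_soma, test$targets$f_soma), 0.6)
  # soma radius in the sensitive range
  sel <- test$targets$r_soma >= 3 & test$targets$r_soma <= 10
  expect_lt(stats::median(abs(pred$r_soma - test$targets$r_soma)[sel]), 1.5)
  # clipping contract: predictions never leave the training ranges
  rng <- sandi_ranges()
  for (p in names(rng)) {
    expect_gte(min(pred[[p]]), rng[[p]][1])
    expect_lte(max(pred[[p]]), rng[[p]][2])
  }
  # constraint: fractions sum to one exactly
  expect_equal(pred$f_soma + pred$f_neurite + pred$f_extra,
               rep(1, nrow(pred)))
  # monotonicity: increasing true f_extra raises fitted f_extra on
  # average (predictions averaged over random base settings at a common
  # f_extra grid; a single sweep is degeneracy-limited, see vignette)
  fe_grid <- seq(0.05, 0.9, length.out = 10)
  sweeps <- withr::with_seed(44, purrr::map_dfr(1:30, function(k) {
    rho <- stats::runif(1, 0.2, 0.8)
    data.frame(f_soma = (1 - rho) * (1 - fe_grid),
               f_neurite = rho * (1 - fe_grid),
               r_soma = stats::runif(1, 2, 11),
               d_in = stats::runif(1, 0.4, 2.8),
               d_e = stats::runif(1, 0.4, 2.8))
  }))
  p_sweep <- predict(inv, sandi_signal_matrix(sweeps, proto))
  avg_fe <- tapply(p_sweep$f_extra, rep(fe_grid, 30), mean)
  expect_gt(stats::cor(fe_grid, as.numeric(avg_fe), method = "spearman"),
            0.9)
})

test_that("map fitting propagates masks and validates shell counts", {
  proto <- small_protocol()
  ts <- build_training_set(300, proto, seed = 5)
  inv <- train_sandi_inverter(ts, 10)
  ph <- make_phantom(phantom_spec(shape = c(8, 8, 8)))
  sim <- simulate_subject_dwi(ph, proto, snr = NULL, seed = 1)
  sm <- spherical_mean_shells(sim$clean)
  maps <- fit_sandi(sm, inv)
  # background voxels (no b0 signal) are missing, never zero
  expect_true(all(is.na(maps$f_soma[!ph$mask])))
  expect_true(all(is.finite(maps$f_soma[ph$mask])))
  expect_equal(maps$f_soma + maps$f_neurite + maps$f_extra,
               array(ifelse(ph$mask, 1, NA_real_), dim(ph$mask)))
  sm_bad <- sm
  sm_bad$means <- sm$means[, -1]
  expect_error(fit_sandi(sm_bad, inv), "mismatch")
})

test_that("inverter round-trips through its archive with metadata", {
  ts <- build_training_set(200, small_protocol(), snr = 40, seed = 6)
  inv <- train_sandi_inverter(ts, 10)
  path <- withr::local_tempfile(fileext = ".rds")
  save_sandi_inverter(inv, path)
  inv2 <- load_sandi_inverter(path)
  probe <- build_training_set(20, small_protocol(), seed = 7)
  expect_equal(predict(inv, probe$signals), predict(inv2, probe$signals))
  g <- glance(inv2)
  expect_equal(g$training_snr, 40)
  expect_equal(g$seed, 6)
  td <- tidy(inv2)
  expect_equal(nrow(td), 5)
  expect_true(all(td$n_trees == 10))
})
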