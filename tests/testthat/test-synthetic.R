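# ground-truth generators: phantoms, DWI simulation, cohorts, toy meshes

test_that("phantoms are labelled, simplex-valid and reproducible", {
  spec <- phantom_spec(shape = c(12, 12, 12))
  ph <- make_phantom(spec)
  fg <- ph$mask
  expect_true(any(fg))
  s <- ph$params$f_soma + ph$params$f_neurite + ph$params$f_extra
  expect_equal(s[fg], rep(1, sum(fg)))
  expect_true(all(ph$labels[fg] %in% 1:6))
  expect_true(all(ph$labels[!fg] == 0))
  # region means equal the spec values when perturbation is off
  for (r in 1:6) {
    sel <- ph$labels == r
    expect_equal(mean(ph$params$r_soma[sel]), subfield_params()$r_soma[r])
  }
  ph2 <- make_phantom(spec)
  expect_identical(ph$params, ph2$params)
  # perturbed phantom stays within the training ranges
  php <- make_phantom(phantom_spec(shape = c(12, 12, 12), perturb_sd = 0.1))
  rng <- sandi_ranges()
  expect_true(all(php$params$r_soma[fg] >= rng$r_soma[1] - 1e-12))
  expect_true(all(php$params$r_soma[fg] <= rng$r_soma[2] + 1e-12))
  sp <- php$params$f_soma + php$params$f_neurite + php$params$f_extra
  expect_equal(sp[fg], rep(1, sum(fg)))
  expect_false(identical(php$params$r_soma, ph$params$r_soma))
})

test_that("noise-free simulated DWI inverts exactly to the forward model", {
  ph <- make_phantom(phantom_spec(shape = c(8, 8, 8)))
  proto <- small_protocol(dirs = 4)
  sim <- simulate_subject_dwi(ph, proto, snr = NULL, seed = 1)
  expect_identical(sim$dwi$data, sim$clean$data)
  sm <- spherical_mean_shells(sim$clean)
  fg <- which(ph$mask)
  theta <- data.frame(f_soma = ph$params$f_soma[fg],
                      f_neurite = ph$params$f_neurite[fg],
                      r_soma = ph$params$r_soma[fg],
                      d_in = ph$params$d_in[fg],
                      d_e = ph$params$d_e[fg])
  expect_equal(sm$means[fg, ], sandi_signal_matrix(theta, proto),
               tolerance = 1e-12, ignore_attr = TRUE)
  # b0 volumes are interleaved every 16 DWIs
  b0_pos <- which(sim$clean$bvals == 0)
  expect_equal(diff(b0_pos)[1], 17)
  expect_equal(dim(sim$clean$data)[4],
               sum(proto$directions_per_shell) +
                 ceiling(sum(proto$directions_per_shell) / 16))
})

test_that("Rician noise has the documented small-sigma moments", {
  s <- 10; sigma <- 1
  draws <- withr::with_seed(5, add_rician_noise(rep(s, 1e4), sigma))
  # E[S'] ~ S + sigma^2 / (2 S) at high SNR
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - (s + sigma^2 / (2 * s))), 3 * se)
  expect_identical(add_rician_noise(rep(s, 5), 0), rep(s, 5))
})

test_that("low-resolution degradation pairs with the retained truth", {
  ph <- make_phantom(phantom_spec(shape = c(8, 8, 8)))
  proto <- acq_protocol(c(0.8), 3, b0_count = 1)
  sim <- simulate_subject_dwi(ph, proto, snr = NULL, seed = 2)
  lr <- degrade_to_lowres(sim$clean, 2, snr = NULL)
  expect_equal(dim(lr$data)[1:3], c(4, 4, 4))
  expect_equal(lr$voxdim, c(2, 2, 2))
  # noiseless degrade of a constant region-free volume is the constant
  cst <- sim$clean
  cst$data[] <- 4
  lrc <- degrade_to_lowres(cst, 2, snr = NULL)
  expect_true(all(lrc$data == 4))
  # degrade o nearest_upsample is the identity on low-resolution volumes
  v <- lr$data[, , , 1]
  expect_equal(block_downsample(nearest_upsample(v, 2), 2), v)
  # seeded noisy pair is bit-identical across regenerations
  lr1 <- degrade_to_lowres(sim$clean, 2, snr = 30, seed = 9)
  lr2 <- degrade_to_lowres(sim$clean, 2, snr = 30, seed = 9)
  expect_identical(lr1$data, lr2$data)
})

test_that("anatomical references are aligned piecewise-constant volumes", {
  ph <- make_phantom(phantom_spec(shape = c(12, 12, 12)))
  ref <- make_t1_reference(ph$labels)
  # zero noise/bias: exactly constant within each label
  for (l in 0:6) expect_equal(stats::sd(ref[ph$labels == l]), 0)
  # distinct contrasts: boundaries present exactly where labels change
  dx_lab <- ph$labels[-1, , ] != ph$labels[-12, , ]
  dx_ref <- ref[-1, , ] != ref[-12, , ]
  expect_identical(dx_lab, dx_ref)
  # permuting intensities moves values, not boundary geometry
  ref2 <- make_t1_reference(ph$labels, contrast = c(5, 160, 60, 80, 100,
                                                    120, 140))
  dx_ref2 <- ref2[-1, , ] != ref2[-12, , ]
  expect_identical(dx_ref2, dx_ref)
  expect_false(identical(ref, ref2))
})

test_that("cohort generator calibrates to the target correlations", {
  # zero slopes and zero subject noise give identical subjects
  eff0 <- age_effect_model(target_r = c(f_soma = 0), noise_sd = c(f_soma = 0))
  ch0 <- simulate_cohort(eff0, seed = 1)
  expect_equal(stats::sd(ch0$f_soma[ch0$roi == "CA1"]), 0)
  # sex split and age range follow the configuration
  ch <- simulate_cohort(seed = 2)
  one <- ch[ch$roi == "CA1", ]
  expect_equal(nrow(one), 72)
  expect_equal(sum(one$sex), 32)
  expect_true(all(one$age >= 19 & one$age <= 85))
  # empirical r across replicates centres on the target
  rs <- vapply(1:60, function(s) {
    d <- simulate_cohort(seed = 1000 + s)
    d <- d[d$roi == "CA1", ]
    stats::cor(d$f_soma, d$age)
  }, numeric(1))
  target <- -0.5
  z <- atanh(rs)
  expect_lt(abs(mean(z) - atanh(target)), 2 / sqrt(69) / sqrt(60) * 3 + 0.03)
  # sex carries no injected effect
  rej <- vapply(1:60, function(s) {
    d <- simulate_cohort(seed = 2000 + s)
    d <- d[d$roi == "Sub", ]
    fit <- summary(stats::lm(f_neurite ~ age + sex, data = d))
    fit$coefficients["sex", 4] < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
  # infeasible effects are recorded in provenance
  eff_bad <- age_effect_model(target_r = c(f_soma = -0.9),
                              noise_sd = c(f_soma = 0.5))
  chb <- simulate_cohort(eff_bad, seed = 3)
  expect_false(is.null(attr(chb, "provenance")$warning))
})

test_that("toy meshes carry their analytic ground truth", {
  s <- make_toy_mesh("sphere", radius = 1, subdivisions = 3)
  expect_equal(sqrt(rowSums(s$vertices^2)), rep(1, nrow(s$vertices)))
  # flat-limit sinusoid has unit gyrification
  f <- make_toy_mesh("sinusoid", amplitude = 0, nx = 12, ny = 12)
  expect_equal(gyrification(f$native, f$unfolded),
               rep(1, nrow(f$native$vertices)))
  pair <- make_toy_mesh("concentric_pair", radii = c(10, 12),
                        subdivisions = 2)
  expect_equal(thickness(pair$inner, pair$outer),
               rep(2, nrow(pair$inner$vertices)), tolerance = 1e-9)
})
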