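#' Per-voxel spherical-mean shell signals
#'
#' Averages the diffusion-weighted volumes within each b-shell and divides by
#' the mean b = 0 signal, producing the powder-average signal vector the
#' SANDI inverter consumes. Voxels with non-positive b0 mean are masked out
#' (returned as NA).
#'
#' @param dwi a `dwi_volume` as returned by [read_dwi()] or
#'   [simulate_subject_dwi()].
#' @return List with `means` (n_voxel x n_shell matrix, masked voxels NA),
#'   `shells` (shell b-values, ms/um^2), `mask` (logical vector) and `dim`
#'   (spatial grid).
#' @export
spherical_mean_shells <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_volume"))
  d <- dim(dwi$data)
  nvol <- d[4]
  if (length(dwi$bvals) != nvol)
    stop("gradient table length does not match the 4th dimension")
  shell_of <- group_shells(dwi$bvals)
  shells <- attr(shell_of, "shells")
  if (!any(shell_of == 0)) stop("no b = 0 volume present")
  flat <- matrix(dwi$data, prod(d[1:3]), nvol)
  b0 <- rowMeans(flat[, shell_of == 0, drop = FALSE])
  mask <- is.finite(b0) & b0 > 0
  means <- matrix(NA_real_, nrow(flat), length(shells))
  for (s in seq_along(shells)) {
    sel <- which(shell_of == s)
    if (length(sel) == 0) stop("shell with zero directions")
    means[mask, s] <- rowMeans(flat[mask, sel, drop = FALSE]) / b0[mask]
  }
  colnames(means) <- paste0("b", format(shells * 1000, trim = TRUE))
  list(means = means, shells = shells, mask = mask, dim = d[1:3])
}

#' Voxelwise SNR of the b = 0 images
#'
#' SNR = mean b0 signal / noise sigma. When the noise map was estimated at a
#' lower resolution the variance map (sigma squared, not sigma) is upsampled
#' and re-rooted, accounting for the increase in variance from i.i.d. noise;
#' trilinear interpolation is used so the squaring actually matters at
#' region boundaries.
#'
#' @param b0 3D array (or 4D stack averaged internally) of b = 0 signal on
#'   the target grid.
#' @param noise_sigma 3D array of noise sigma, possibly on a coarser grid.
#' @param upsample_factor integer factor relating the sigma grid to the b0
#'   grid (1 = same grid).
#' @param mask optional logical array on the b0 grid.
#' @return List with `snr` (array), `sigma` (upsampled sigma array) and
#'   `median_snr` (scalar summary used for inverter training).
#' @export
estimate_snr <- function(b0, noise_sigma, upsample_factor = 1, mask = NULL) {
  if (length(dim(b0)) == 4) b0 <- apply(b0, 1:3, mean)
  if (upsample_factor > 1)
    noise_sigma <- sqrt(trilinear_upsample(noise_sigma^2, upsample_factor))
  if (!all(dim(noise_sigma) == dim(b0)))
    stop("sigma grid does not match the b0 grid after upsampling")
  if (is.null(mask)) mask <- array(TRUE, dim(b0))
  bad <- sum(mask & noise_sigma <= 0)
  if (bad > 0)
    stop("noise sigma is zero or negative in ", bad, " in-mask voxels")
  snr <- array(NA_real_, dim(b0))
  snr[mask] <- b0[mask] / noise_sigma[mask]
  list(snr = snr, sigma = noise_sigma,
       median_snr = stats::median(snr[mask], na.rm = TRUE))
}

#' Noise sigma from repeated b = 0 volumes
#'
#' Per-voxel standard deviation across b0 repeats; at the SNR levels of the
#' protocol the Rician magnitude noise is well approximated as Gaussian, so
#' the sample sd estimates sigma.
#'
#' @param b0_stack 4D array of repeated b = 0 volumes.
#' @return 3D sigma array.
#' @export
estimate_noise_sigma <- function(b0_stack) {
  stopifnot(length(dim(b0_stack)) == 4, dim(b0_stack)[4] >= 2)
  apply(b0_stack, 1:3, stats::sd)
}

#' Simulated SANDI training set
#'
#' Draws parameter vectors uniformly within the SANDI ranges — the fraction
#' pair uniform on the simplex slice f_soma + f_neurite <= 1 with f_extra
#' the remainder — evaluates the forward spherical-mean model on the
#' protocol's shells, and optionally perturbs the signals with Rician noise
#' at the given SNR (sigma = 1/snr on the b0-normalised scale).
#'
#' @param n_samples number of parameter combinations (100,000 at full
#'   scale).
#' @param protocol an [acq_protocol()].
#' @param snr positive scalar SNR, or NULL for noiseless signals.
#' @param seed integer seed; the set is a pure function of
#'   (n_samples, protocol, snr, seed).
#' @return Object of class `sandi_training_set`: list with `signals`
#'   (n x n_shell), `targets` (n x 5 data frame), `snr`, `seed`, `shells`.
#' @export
build_training_set <- function(n_samples, protocol = sandi_protocol(),
                               snr = NULL, seed = 20250101) {
  stopifnot(n_samples >= 1)
  if (!is.null(snr) && snr <= 0) stop("snr must be positive or NULL")
  rng <- sandi_ranges()
  targets <- withr::with_seed(seed, {
    # rejection keeps the pair uniform on the triangle f_s + f_n <= 1
    fs <- fn <- numeric(0)
    while (length(fs) < n_samples) {
      m <- 2 * (n_samples - length(fs)) + 16
      a <- stats::runif(m); b <- stats::runif(m)
      keep <- a + b <= 1
      fs <- c(fs, a[keep]); fn <- c(fn, b[keep])
    }
    data.frame(
      f_soma = fs[seq_len(n_samples)],
      f_neurite = fn[seq_len(n_samples)],
      r_soma = stats::runif(n_samples, rng$r_soma[1], rng$r_soma[2]),
      d_in = stats::runif(n_samples, rng$d_in[1], rng$d_in[2]),
      d_e = stats::runif(n_samples, rng$d_e[1], rng$d_e[2]))
  })
  signals <- sandi_signal_matrix(targets, protocol)
  if (!is.null(snr))
    signals <- withr::with_seed(seed + 1L,
                                add_rician_noise(signals, sigma = 1 / snr))
  structure(list(signals = signals, targets = targets, snr = snr,
                 seed = seed, shells = protocol$shells),
            class = "sandi_training_set")
}

#' Train the SANDI tree-ensemble inverter
#'
#' Fits one random-forest regressor (ranger) per SANDI parameter on the
#' simulated training signals, mirroring the simulation-trained inversion of
#' the spherical-mean model: 200 trees at full scale, library defaults
#' otherwise, single-threaded for reproducibility.
#'
#' @param training_set a `sandi_training_set` from [build_training_set()].
#' @param n_trees trees per forest (200 at full scale).
#' @return Object of class `sandi_inverter` holding one fitted forest per
#'   parameter plus training metadata.
#' @export
train_sandi_inverter <- function(training_set, n_trees = 200) {
  stopifnot(inherits(training_set, "sandi_training_set"))
  x <- as.data.frame(training_set$signals)
  pars <- colnames(training_set$targets)
  for (p in pars)
    if (stats::sd(training_set$targets[[p]]) == 0)
      stop("degenerate (constant) training target: ", p)
  forests <- lapply(pars, function(p) {
    d <- cbind(x, .y = training_set$targets[[p]])
    ranger::ranger(.y ~ ., data = d, num.trees = n_trees,
                   num.threads = 1, seed = training_set$seed,
                   respect.unordered.factors = FALSE)
  })
  names(forests) <- pars
  structure(list(forests = forests, n_trees = n_trees,
                 shells = training_set$shells, snr = training_set$snr,
                 seed = training_set$seed, feature_names = colnames(x),
                 ranges = sandi_ranges()),
            class = "sandi_inverter")
}

#' @export
print.sandi_inverter <- function(x, ...) {
  cat("<sandi_inverter> ", x$n_trees, " trees/forest, ",
      length(x$forests), " parameters, ", length(x$shells), " shells",
      if (is.null(x$snr)) ", noiseless training" else
        paste0(", training SNR ", x$snr), "\n", sep = "")
  invisible(x)
}

#' Predict SANDI parameters from spherical-mean signals
#'
#' @param object a `sandi_inverter`.
#' @param signals n x n_shell matrix of b0-normalised shell means.
#' @param ... unused.
#' @return Tibble with one row per signal row: f_soma, f_neurite, f_extra,
#'   r_soma, d_in, d_e. Predictions are clipped to the training ranges and
#'   the fraction triple is projected back onto the simplex (negative
#'   f_extra remainders clipped to 0 and the pair rescaled).
#' @export
predict.sandi_inverter <- function(object, signals, ...) {
  signals <- as.matrix(signals)
  if (ncol(signals) != length(object$shells))
    stop("signal matrix has ", ncol(signals), " shells but the model was ",
         "trained on ", length(object$shells))
  x <- as.data.frame(signals)
  colnames(x) <- object$feature_names
  pred <- lapply(object$forests, function(f)
    stats::predict(f, data = x, num.threads = 1)$predictions)
  out <- tibble::as_tibble(pred)
  for (p in names(object$ranges))
    out[[p]] <- pmin(pmax(out[[p]], object$ranges[[p]][1]),
                     object$ranges[[p]][2])
  # simplex projection: clip negative remainder, rescale the pair
  s <- out$f_soma + out$f_neurite
  over <- s > 1
  out$f_soma[over] <- out$f_soma[over] / s[over]
  out$f_neurite[over] <- out$f_neurite[over] / s[over]
  out$f_extra <- pmax(0, 1 - out$f_soma - out$f_neurite)
  out[, c("f_soma", "f_neurite", "f_extra", "r_soma", "d_in", "d_e")]
}

#' Invert shell means to SANDI parameter maps
#'
#' Applies a trained inverter to the output of [spherical_mean_shells()],
#' propagating masked voxels as NA (never 0) and enforcing the fraction
#' constraint f_soma + f_neurite + f_extra = 1.
#'
#' @param shell_means result of [spherical_mean_shells()].
#' @param model a `sandi_inverter`.
#' @return Named list of 3D parameter arrays (f_soma, f_neurite, f_extra,
#'   r_soma, d_in, d_e).
#' @export
fit_sandi <- function(shell_means, model) {
  stopifnot(inherits(model, "sandi_inverter"))
  if (ncol(shell_means$means) != length(model$shells))
    stop("shell count mismatch between data and model")
  ok <- shell_means$mask
  pred <- predict(model, shell_means$means[ok, , drop = FALSE])
  maps <- lapply(names(pred), function(p) {
    a <- array(NA_real_, shell_means$dim)
    a[ok] <- pred[[p]]
    a
  })
  names(maps) <- names(pred)
  maps
}

#' Serialise / restore a SANDI inverter
#'
#' The model and its metadata (seed, SNR, shells, ranges) are written to a
#' single RDS archive.
#'
#' @param model a `sandi_inverter`.
#' @param path file path.
#' @return `save_sandi_inverter` returns `path` invisibly;
#'   `load_sandi_inverter` returns the model.
#' @export
save_sandi_inverter <- function(model, path) {
  stopifnot(inherits(model, "sandi_inverter"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_sandi_inverter
#' @export
load_sandi_inverter <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "sandi_inverter"))
  m
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-parameter forests of a SANDI inverter
#'
#' @param x a `sandi_inverter`.
#' @param ... unused.
#' @return Tibble with one row per target parameter: number of trees,
#'   out-of-bag MSE and out-of-bag R^2.
#' @export
tidy.sandi_inverter <- function(x, ...) {
  tibble::tibble(
    parameter = names(x$forests),
    n_trees = vapply(x$forests, function(f) f$num.trees, numeric(1)),
    oob_mse = vapply(x$forests, function(f) f$prediction.error, numeric(1)),
    oob_r_squared = vapply(x$forests, function(f) f$r.squared, numeric(1)))
}

#' One-row training summary of a SANDI inverter
#'
#' @param x a `sandi_inverter`.
#' @param ... unused.
#' @return One-row tibble: trees, shells, training SNR, seed.
#' @export
glance.sandi_inverter <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees, n_shells = length(x$shells),
                 training_snr = if (is.null(x$snr)) NA_real_ else x$snr,
                 seed = x$seed)
}
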