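#' SANDI compartment parameters
#'
#' The six-parameter voxel description of the SANDI gray-matter model:
#' signal fractions of the soma (restricted sphere), neurite (stick) and
#' extracellular (isotropic Gaussian) compartments, the effective soma
#' radius, and the intra-neurite and extracellular diffusivities. The
#' intra-soma diffusivity is fixed at 3 um^2/ms.
#'
#' @param f_soma,f_neurite,f_extra signal fractions in \[0,1\]; must sum to 1.
#' @param r_soma soma radius in um, within \[1, 12\].
#' @param d_in intra-neurite diffusivity in um^2/ms, within \[0.25, 3\].
#' @param d_e extracellular diffusivity in um^2/ms, within \[0.25, 3\].
#' @param d_is intra-soma diffusivity in um^2/ms (fixed constant, 3).
#' @return An object of class `sandi_params`.
#' @export
sandi_params <- function(f_soma, f_neurite, f_extra = 1 - f_soma - f_neurite,
                         r_soma, d_in, d_e, d_is = 3) {
  p <- list(f_soma = f_soma, f_neurite = f_neurite, f_extra = f_extra,
            r_soma = r_soma, d_in = d_in, d_e = d_e, d_is = d_is)
  validate_sandi_params(p)
  structure(p, class = "sandi_params")
}

validate_sandi_params <- function(p) {
  fr <- c(p$f_soma, p$f_neurite, p$f_extra)
  if (any(fr < -1e-9) || any(fr > 1 + 1e-9))
    stop("signal fractions must lie in [0, 1]")
  if (abs(sum(fr) - 1) > 1e-9)
    stop("f_soma + f_neurite + f_extra must equal 1")
  if (p$r_soma < 1 - 1e-9 || p$r_soma > 12 + 1e-9)
    stop("r_soma must lie in [1, 12] um")
  if (p$d_in < 0.25 - 1e-9 || p$d_in > 3 + 1e-9 ||
      p$d_e < 0.25 - 1e-9 || p$d_e > 3 + 1e-9)
    stop("d_in and d_e must lie in [0.25, 3] um^2/ms")
  invisible(p)
}

#' Default SANDI sampling ranges
#'
#' Training ranges for the five free parameters: fractions in \[0,1\]
#' (subject to the simplex constraint), soma radius 1-12 um, both
#' diffusivities 0.25-3 um^2/ms. Used by the training-set generator and to
#' clip inverter predictions.
#'
#' @return Named list of `c(lo, hi)` ranges.
#' @export
sandi_ranges <- function() {
  list(f_soma = c(0, 1), f_neurite = c(0, 1), r_soma = c(1, 12),
       d_in = c(0.25, 3), d_e = c(0.25, 3))
}

#' Spherical-mean stick (neurite) signal
#'
#' Direction average over the unit sphere of `exp(-b * d_in * cos^2 theta)`,
#' the powder-averaged signal of an impermeable zero-radius cylinder:
#' `S = sqrt(pi / (4 b d_in)) * erf(sqrt(b d_in))`, continuous at b = 0 with
#' limit 1.
#'
#' @param b b-value(s) in ms/um^2.
#' @param d_in intra-neurite diffusivity in um^2/ms.
#' @return Signal fraction(s) in (0, 1\].
#' @export
sphmean_stick <- function(b, d_in) {
  if (any(b < 0)) stop("b must be non-negative")
  if (any(d_in <= 0)) stop("d_in must be positive")
  bd <- b * d_in
  out <- ifelse(bd < 1e-8, 1 - bd / 3,
                sqrt(pi / (4 * pmax(bd, 1e-300))) * erf(sqrt(bd)))
  pmin(out, 1)
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Spherical-mean ball (extracellular) signal
#'
#' Isotropic Gaussian compartment, `S = exp(-b * d_e)`; the spherical mean
#' equals the per-direction signal because the compartment is isotropic.
#'
#' @param b b-value(s) in ms/um^2.
#' @param d_e extracellular diffusivity in um^2/ms.
#' @return Signal fraction(s) in (0, 1\].
#' @export
sphmean_ball <- function(b, d_e) {
  if (any(b < 0) || any(d_e < 0)) stop("b and d_e must be non-negative")
  exp(-b * d_e)
}

# cache for the sphere eigenvalue roots
.gpd_cache <- new.env(parent = emptyenv())

#' Eigenvalue roots of the reflecting-sphere boundary condition
#'
#' First `n` positive roots x_m of `x J'_{3/2}(x) = (1/2) J_{3/2}(x)`, the
#' dimensionless eigenvalues (x_m = alpha_m R) of the Gaussian-phase
#' -distribution signal for diffusion restricted in a reflecting sphere.
#' Roots are found by a dense sign-change scan plus bisection (residual
#' below 1e-10) and cached after the first computation.
#'
#' @param n number of roots (default 20; the series is converged well
#'   before that for all protocol b-values).
#' @return Strictly increasing numeric vector of length `n`.
#' @export
gpd_roots <- function(n = 20) {
  stopifnot(n >= 1)
  key <- as.character(n)
  if (!is.null(.gpd_cache[[key]])) return(.gpd_cache[[key]])
  f <- function(x) x * dbesselJ32(x) - 0.5 * besselJ(x, 1.5)
  # roots are interlaced ~pi apart; scan finely far enough out
  upper <- pi * (n + 2)
  xs <- seq(1e-3, upper, by = 0.01)
  fx <- f(xs)
  sgn <- which(fx[-1] * fx[-length(fx)] < 0)
  if (length(sgn) < n)
    stop("root bracketing failed on (0, ", round(upper, 2), ")")
  roots <- vapply(sgn[seq_len(n)], function(i) {
    stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-14)$root
  }, numeric(1))
  if (any(abs(f(roots)) >= 1e-10))
    stop("boundary-condition residual exceeded 1e-10")
  .gpd_cache[[key]] <- roots
  roots
}

# derivative of J_{3/2} via the standard recurrence
dbesselJ32 <- function(x) {
  0.5 * (besselJ(x, 0.5) - besselJ(x, 2.5))
}

#' Restricted-sphere (soma) spherical-mean signal, Murday-Cotts GPD form
#'
#' Finite-pulse Gaussian-phase-distribution attenuation for spins restricted
#' inside a reflecting sphere of radius `r_soma` under a rectangular PGSE
#' pulse pair (delta, Delta). With alpha_m = x_m / R the attenuation is
#' \deqn{-\ln S = \frac{2 (\gamma g)^2}{D} \sum_m
#'   \frac{\alpha_m^{-4}}{\alpha_m^2 R^2 - 2}\Big[2\delta -
#'   \frac{2 + e^{-\alpha_m^2 D (\Delta-\delta)} - 2 e^{-\alpha_m^2 D \delta}
#'   - 2 e^{-\alpha_m^2 D \Delta} + e^{-\alpha_m^2 D(\Delta+\delta)}}
#'   {\alpha_m^2 D}\Big]}
#' where `(gamma g)^2` is recovered from `b = (gamma g)^2 delta^2
#' (Delta - delta/3)`, so no explicit gyromagnetic constant appears.
#'
#' @param b b-value(s) in ms/um^2.
#' @param r_soma sphere radius in um (may be a vector matching `b` or
#'   scalar).
#' @param d_is intra-sphere diffusivity in um^2/ms.
#' @param protocol an [acq_protocol()] providing delta and Delta.
#' @param roots eigenvalue roots from [gpd_roots()].
#' @return Signal fraction(s) in (0, 1\].
#' @export
sphere_gpd_signal <- function(b, r_soma, d_is = 3, protocol = sandi_protocol(),
                              roots = gpd_roots(20)) {
  if (any(b < 0)) stop("b must be non-negative")
  if (any(r_soma <= 0)) stop("r_soma must be positive")
  if (d_is <= 0) stop("d_is must be positive")
  del <- protocol$delta_small; Del <- protocol$delta_big
  if (any(b > 0) && del >= Del)
    stop("degenerate PGSE timings: delta must be < Delta")
  n <- max(length(b), length(r_soma))
  b <- rep_len(b, n); r_soma <- rep_len(r_soma, n)
  gg2 <- b / (del^2 * (Del - del / 3))          # (gamma g)^2, 1/(um^2 ms^2)
  alpha <- outer(1 / r_soma, roots)             # n x m, 1/um
  a2D <- alpha^2 * d_is                         # 1/ms
  # the constant terms of the exponential sum cancel exactly; writing it
  # with expm1 avoids catastrophic cancellation in the frozen-spin limit
  esum <- expm1(-a2D * (Del - del)) - 2 * expm1(-a2D * del) -
    2 * expm1(-a2D * Del) + expm1(-a2D * (Del + del))
  brack <- 2 * del - esum / a2D
  series <- rowSums(brack / (alpha^4 * (alpha^2 * r_soma^2 - 2)))
  exp(-2 * gg2 / d_is * series)
}

#' SANDI spherical-mean mixture signal
#'
#' b0-normalised per-shell powder-average signal of the three-compartment
#' mixture
#' `S(b) = f_soma * S_sphere(b) + f_neurite * S_stick(b) + f_extra * S_ball(b)`.
#'
#' @param params a [sandi_params()] object.
#' @param protocol an [acq_protocol()].
#' @param roots GPD eigenvalue roots, see [gpd_roots()].
#' @return Named numeric vector, one value per shell (plus a leading 1 for
#'   the b = 0 shell when the protocol includes b0 volumes).
#' @export
sandi_signal <- function(params, protocol = sandi_protocol(),
                         roots = gpd_roots(20)) {
  validate_sandi_params(params)
  b <- protocol$shells
  s <- params$f_soma * sphere_gpd_signal(b, params$r_soma, params$d_is,
                                         protocol, roots) +
    params$f_neurite * sphmean_stick(b, params$d_in) +
    params$f_extra * sphmean_ball(b, params$d_e)
  if (protocol$b0_count > 0) {
    s <- c(1, s)
    names(s) <- c("b0", paste0("b", format(b * 1000, trim = TRUE)))
  } else {
    names(s) <- paste0("b", format(b * 1000, trim = TRUE))
  }
  s
}

#' Matrix SANDI forward signals for many parameter sets
#'
#' Vectorised forward model used by the training-set generator and the
#' phantom simulator: rows are parameter sets, columns are the protocol's
#' non-zero shells.
#'
#' @param theta data frame / matrix with columns f_soma, f_neurite, r_soma,
#'   d_in, d_e (f_extra implied as the simplex remainder).
#' @param protocol an [acq_protocol()].
#' @param d_is intra-soma diffusivity.
#' @param roots GPD eigenvalue roots.
#' @return n x n_shells matrix of b0-normalised spherical-mean signals.
#' @export
sandi_signal_matrix <- function(theta, protocol = sandi_protocol(), d_is = 3,
                                roots = gpd_roots(20)) {
  theta <- as.data.frame(theta)
  b <- protocol$shells
  f_extra <- 1 - theta$f_soma - theta$f_neurite
  if (any(f_extra < -1e-9)) stop("fraction rows must satisfy the simplex")
  out <- matrix(NA_real_, nrow(theta), length(b))
  for (j in seq_along(b)) {
    out[, j] <- theta$f_soma *
      sphere_gpd_signal(b[j], theta$r_soma, d_is, protocol, roots) +
      theta$f_neurite * sphmean_stick(b[j], theta$d_in) +
      f_extra * sphmean_ball(b[j], theta$d_e)
  }
  colnames(out) <- paste0("b", format(b * 1000, trim = TRUE))
  out
}

#' Monte-Carlo reflecting-sphere PGSE signal (validation oracle)
#'
#' Brute-force random-walk simulation of restricted diffusion inside a
#' reflecting sphere under the same rectangular PGSE pulse pair as
#' [sphere_gpd_signal()]. Used to validate the closed-form GPD series; kept
#' deliberately independent of it (own RNG stream, phase accumulation, no
#' shared code).
#'
#' @inheritParams sphere_gpd_signal
#' @param n_walkers number of random walkers.
#' @param dt time step in ms; default resolves the sphere radius with at
#'   least ~20 steps per radius.
#' @param seed integer seed for the simulation's own RNG stream.
#' @return Scalar signal estimate.
#' @export
mc_sphere_signal <- function(b, r_soma, d_is = 3, protocol = sandi_protocol(),
                             n_walkers = 1e5, dt = NULL, seed = 1) {
  stopifnot(length(b) == 1, b >= 0, r_soma > 0, d_is > 0)
  del <- protocol$delta_small; Del <- protocol$delta_big
  if (is.null(dt)) dt <- min(r_soma^2 / (800 * d_is), 0.01)
  # snap dt to 1/k ms so integer-ms lobe edges land on the step grid
  dt <- 1 / ceiling(1 / dt)
  gam_g <- sqrt(b / (del^2 * (Del - del / 3)))
  .mc_sphere_signal_cpp(r_soma, d_is, del, Del, gam_g,
                        as.integer(n_walkers), dt, as.integer(seed))
}
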