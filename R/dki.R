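# Diffusion kurtosis representation
#
# ln S = ln S0 - b D(n) + (b^2/6) MD^2 K(n), parameterised by the 6 unique
# diffusion-tensor elements and the 15 unique elements of V = MD^2 W, so the
# design is linear in 22 coefficients.  K(n) is recovered as V(n)/MD^2.

# multipliers for the 6 unique D elements at direction n
dki_d6 <- function(n) {
  cbind(n[, 1]^2, n[, 2]^2, n[, 3]^2,
        2 * n[, 1] * n[, 2], 2 * n[, 1] * n[, 3], 2 * n[, 2] * n[, 3])
}

# multipliers for the 15 unique 4th-order elements at direction n
dki_v15 <- function(n) {
  x <- n[, 1]; y <- n[, 2]; z <- n[, 3]
  cbind(x^4, y^4, z^4,
        4 * x^3 * y, 4 * x^3 * z, 4 * x * y^3, 4 * y^3 * z,
        4 * x * z^3, 4 * y * z^3,
        6 * x^2 * y^2, 6 * x^2 * z^2, 6 * y^2 * z^2,
        12 * x^2 * y * z, 12 * x * y^2 * z, 12 * x * y * z^2)
}

dki_design <- function(bvals, bvecs) {
  cbind(1, -bvals * dki_d6(bvecs), (bvals^2 / 6) * dki_v15(bvecs))
}

dki_tensor <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

#' Fit the kurtosis representation to one voxel's signals
#'
#' Weighted linear least squares on the log-signal in the 22-coefficient
#' tensor/kurtosis basis (weights = squared predicted signal, two passes).
#' With `constrain = TRUE` the apparent diffusivity D(n), apparent kurtosis
#' K(n) and monotonic signal decay over the fitted b-range are enforced as
#' non-negativity constraints on the acquired directions plus a 60-direction
#' test sphere, via quadratic-penalty refinement started from the
#' unconstrained solution.
#'
#' @param signals positive signal vector, one entry per volume.
#' @param bvals b-values in ms/um^2 (include the b = 0 volumes).
#' @param bvecs n x 3 unit direction matrix (rows for b = 0 are ignored).
#' @param constrain enforce the non-negativity/monotonicity constraints.
#' @return List with `beta` (22 coefficients), `metrics` (named vector MD,
#'   AD, RD, FA, MK, AK, RK) and `constrained` (logical: did constraints
#'   bind).
#' @export
dki_fit_signals <- function(signals, bvals, bvecs, constrain = TRUE) {
  stopifnot(length(signals) == length(bvals), nrow(bvecs) == length(bvals))
  if (any(signals <= 0)) stop("signals must be positive for the log fit")
  nb <- sum(bvals > 1e-8)
  if (length(unique(round(bvals[bvals > 1e-8], 6))) < 2 || nb < 15)
    stop("need at least 2 non-zero shells and 15 weighted volumes")
  X <- dki_design(bvals, bvecs)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design: direction set does not span the ",
         "22-coefficient kurtosis basis")
  y <- log(signals)
  beta <- stats::lm.fit(X, y)$coefficients
  # WLLS pass with weights from predicted signals
  w <- exp(2 * as.vector(X %*% beta))
  beta <- stats::lm.fit(X * sqrt(w), y * sqrt(w))$coefficients
  constrained <- FALSE
  if (constrain) {
    ndir <- rbind(bvecs[bvals > 1e-8, , drop = FALSE],
                  fibonacci_directions(60))
    bmax <- max(bvals)
    viol <- dki_violations(beta, ndir, bmax)
    if (viol > 1e-10) {
      constrained <- TRUE
      beta <- dki_penalty_refine(beta, X, y, w, ndir, bmax)
    }
  }
  list(beta = beta, metrics = dki_metrics_from_beta(beta),
       constrained = constrained)
}

# summed squared constraint violations at beta
dki_violations <- function(beta, ndir, bmax) {
  Dn <- as.vector(dki_d6(ndir) %*% beta[2:7])
  Vn <- as.vector(dki_v15(ndir) %*% beta[8:22])
  mono <- Dn - (bmax / 3) * Vn
  sum(pmin(Dn, 0)^2) + sum(pmin(Vn, 0)^2) + sum(pmin(mono, 0)^2)
}

dki_penalty_refine <- function(beta, X, y, w, ndir, bmax) {
  D6 <- dki_d6(ndir); V15 <- dki_v15(ndir)
  # constraint rows c'beta >= 0: D(n), K(n), monotone decay at b_max
  C <- rbind(cbind(0, D6, matrix(0, nrow(ndir), 15)),
             cbind(0, matrix(0, nrow(ndir), 6), V15),
             cbind(0, D6, -(bmax / 3) * V15))
  XtW <- t(X * w)
  obj <- function(b, lambda) {
    r <- y - as.vector(X %*% b)
    cb <- pmin(as.vector(C %*% b), 0)
    sum(w * r^2) + lambda * sum(cb^2)
  }
  grad <- function(b, lambda) {
    r <- y - as.vector(X %*% b)
    cb <- pmin(as.vector(C %*% b), 0)
    -2 * as.vector(XtW %*% r) + 2 * lambda * as.vector(t(C) %*% cb)
  }
  # penalty scale anchored to the data's weighted variance so that exactly
  # representable (zero-residual) signals still see a strong penalty
  scale <- max(sum(w * (y - as.vector(X %*% beta))^2),
               1e-2 * sum(w * (y - mean(y))^2), 1e-4)
  for (lambda in scale * c(1e2, 1e4, 1e6, 1e8)) {
    fit <- stats::optim(beta, obj, grad, lambda = lambda, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-12))
    beta <- fit$par
  }
  beta
}

# eigen-summaries and directional kurtosis summaries from the coefficients
dki_metrics_from_beta <- function(beta, n_mk = 256) {
  Dt <- dki_tensor(beta[2:7])
  ev <- eigen(Dt, symmetric = TRUE)
  lam <- ev$values                      # decreasing
  md <- mean(lam)
  ad <- lam[1]
  rd <- mean(lam[2:3])
  denom <- sqrt(sum(lam^2))
  fa <- if (denom > 0) sqrt(1.5 * sum((lam - md)^2)) / denom else 0
  v15 <- beta[8:22]
  kapp <- function(n) {
    v <- as.vector(dki_v15(n) %*% v15)
    if (md > 0) v / md^2 else rep(0, nrow(n))
  }
  mk <- mean(kapp(fibonacci_directions(n_mk)))
  e1 <- ev$vectors[, 1]
  ak <- kapp(matrix(e1, 1))
  # radial: average around the plane orthogonal to e1
  e2 <- ev$vectors[, 2]; e3 <- ev$vectors[, 3]
  ang <- seq(0, pi, length.out = 61)[-61]
  perp <- t(vapply(ang, function(a) cos(a) * e2 + sin(a) * e3, numeric(3)))
  rk <- mean(kapp(perp))
  c(MD = md, AD = ad, RD = rd, FA = fa, MK = mk, AK = ak, RK = rk)
}

#' Voxelwise constrained DKI fit of the low-b shells
#'
#' Restricts a multi-shell acquisition to shells at or below `b_max`
#' (default 3.45 ms/um^2, i.e. b = 0, 800, 1500, 2400, 3450 s/mm^2 under the
#' study protocol) and fits the kurtosis representation in every in-mask
#' voxel.
#'
#' @param dwi a `dwi_volume`.
#' @param b_max largest shell to include, ms/um^2.
#' @param mask optional logical 3D array; default: voxels with positive b0.
#' @param constrain see [dki_fit_signals()].
#' @return Named list of 3D metric arrays (MD, AD, RD, FA, MK, AK, RK),
#'   masked voxels NA.
#' @export
fit_dki <- function(dwi, b_max = 3.45, mask = NULL, constrain = TRUE) {
  stopifnot(inherits(dwi, "dwi_volume"))
  keep <- dwi$bvals <= b_max + 0.05
  bv <- dwi$bvals[keep]
  vecs <- dwi$bvecs[keep, , drop = FALSE]
  d <- dim(dwi$data)
  flat <- matrix(dwi$data, prod(d[1:3]), d[4])[, keep, drop = FALSE]
  b0 <- rowMeans(flat[, bv <= 1e-8, drop = FALSE])
  if (is.null(mask)) mask <- array(b0 > 0, d[1:3])
  vox <- which(as.vector(mask) & b0 > 0 &
                 apply(flat > 0, 1, all))
  metrics <- c("MD", "AD", "RD", "FA", "MK", "AK", "RK")
  maps <- lapply(metrics, function(m) array(NA_real_, d[1:3]))
  names(maps) <- metrics
  for (v in vox) {
    fit <- dki_fit_signals(flat[v, ], bv, vecs, constrain = constrain)
    for (m in metrics) maps[[m]][v] <- fit$metrics[[m]]
  }
  maps
}
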