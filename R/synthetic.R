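#' Rician noise
#'
#' Magnitude-MRI noise model: `S' = sqrt((S + e1)^2 + e2^2)` with
#' independent `e ~ N(0, sigma^2)`. Uses the current RNG state; wrap with a
#' seed for reproducibility.
#'
#' @param x numeric vector, matrix or array of noise-free signals.
#' @param sigma noise standard deviation (same units as `x`).
#' @return Noisy values with the shape of `x`.
#' @export
add_rician_noise <- function(x, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(x)
  e1 <- stats::rnorm(length(x), 0, sigma)
  e2 <- stats::rnorm(length(x), 0, sigma)
  out <- sqrt((x + e1)^2 + e2^2)
  attributes(out) <- attributes(x)
  out
}

# deterministic per-shell rotation so shells do not reuse identical
# direction sets (keeps the joint direction set well-conditioned for DKI)
rotate_directions <- function(dirs, k) {
  golden <- pi * (3 - sqrt(5))
  a <- k * golden; b <- k * golden / 2
  rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  dirs %*% (rz %*% ry)
}

#' Default pseudo-subfield SANDI parameters
#'
#' Region table for the six hippocampal pseudo-subfields of the phantom,
#' with gray-matter-plausible SANDI values inside the model's training
#' ranges.
#'
#' @return Tibble with one row per region.
#' @export
subfield_params <- function() {
  tibble::tibble(
    roi = c("Sub", "CA1", "CA2", "CA3", "CA4", "DG"),
    f_soma = c(0.35, 0.40, 0.45, 0.48, 0.42, 0.50),
    f_neurite = c(0.30, 0.25, 0.20, 0.22, 0.28, 0.25),
    r_soma = c(7.0, 8.0, 8.5, 9.0, 7.5, 6.5),
    d_in = c(2.0, 2.2, 2.4, 2.1, 2.0, 1.8),
    d_e = c(1.0, 0.9, 0.8, 0.85, 0.95, 0.8))
}

#' Phantom specification
#'
#' Defines the ground-truth grid (1-mm voxels), the labelled pseudo-subfield
#' geometry (an ellipsoidal foreground split into six slabs) and the
#' per-region SANDI parameters.
#'
#' @param shape integer grid extents (default 32^3).
#' @param regions region parameter table as from [subfield_params()].
#' @param perturb_sd sd of an optional smooth within-region perturbation of
#'   the fraction/diffusivity maps (0 = piecewise constant).
#' @param seed integer seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32, 32), regions = subfield_params(),
                         perturb_sd = 0, seed = 20250101) {
  stopifnot(length(shape) == 3, all(shape >= 4), nrow(regions) >= 1)
  structure(list(shape = as.integer(shape), regions = regions,
                 perturb_sd = perturb_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Build the ground-truth phantom
#'
#' Voxelwise SANDI parameter maps constant within the labelled regions (plus
#' an optional smooth perturbation clamped to the valid ranges), a label
#' volume (0 = background) and the foreground mask. A pure function of
#' (spec, seed); provenance is attached as an attribute.
#'
#' @param spec a [phantom_spec()].
#' @param seed overrides the spec seed if given.
#' @return List: `labels` (3D integer array), `roi_names`, `mask`, `params`
#'   (named list of 3D arrays f_soma, f_neurite, f_extra, r_soma, d_in,
#'   d_e), `spec`.
#' @export
make_phantom <- function(spec = phantom_spec(), seed = spec$seed) {
  d <- spec$shape
  cx <- (d + 1) / 2
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  rad <- ((g$x - cx[1]) / (0.42 * d[1]))^2 +
    ((g$y - cx[2]) / (0.40 * d[2]))^2 +
    ((g$z - cx[3]) / (0.38 * d[3]))^2
  fg <- rad <= 1
  nreg <- nrow(spec$regions)
  # slabs along x inside the foreground
  xr <- range(g$x[fg])
  slab <- pmin(nreg, 1 + floor((g$x - xr[1]) / (diff(xr) + 1) * nreg))
  labels <- array(0L, d)
  labels[fg] <- slab[fg]
  mask <- array(fg, d)
  rng <- sandi_ranges()
  params <- lapply(c("f_soma", "f_neurite", "r_soma", "d_in", "d_e"),
                   function(p) {
    a <- array(NA_real_, d)
    a[fg] <- spec$regions[[p]][slab[fg]]
    a
  })
  names(params) <- c("f_soma", "f_neurite", "r_soma", "d_in", "d_e")
  if (spec$perturb_sd > 0) {
    params <- withr::with_seed(seed, {
      lapply(stats::setNames(names(params), names(params)), function(p) {
        a <- params[[p]]
        noise <- smooth_field(d, spec$perturb_sd)
        scale <- if (p %in% c("f_soma", "f_neurite")) 1 else diff(rng[[p]])
        a[fg] <- a[fg] + noise[fg] * scale
        lo <- rng[[p]][1]; hi <- rng[[p]][2]
        a[fg] <- pmin(pmax(a[fg], lo), hi)
        a
      })
    })
    # keep the fraction pair on the simplex after perturbation
    s <- params$f_soma + params$f_neurite
    over <- !is.na(s) & s > 1
    params$f_soma[over] <- params$f_soma[over] / s[over]
    params$f_neurite[over] <- params$f_neurite[over] / s[over]
  }
  params$f_extra <- 1 - params$f_soma - params$f_neurite
  out <- list(labels = labels, roi_names = spec$regions$roi, mask = mask,
              params = params, spec = spec)
  attr(out, "provenance") <- list(seed = seed, spec = unclass(spec),
                                  package = "hippomicro")
  out
}

# smooth zero-mean random field: white noise box-smoothed twice
smooth_field <- function(d, sd) {
  a <- array(stats::rnorm(prod(d)), d)
  for (i in 1:2) a <- box_smooth3(a)
  a * sd / stats::sd(a)
}

box_smooth3 <- function(a) {
  d <- dim(a)
  pad <- function(i, n) pmin(pmax(i, 1), n)
  out <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
    out <- out + a[pad(seq_len(d[1]) + dx, d[1]),
                   pad(seq_len(d[2]) + dy, d[2]),
                   pad(seq_len(d[3]) + dz, d[3])]
  out / 27
}

#' Simulate a subject's multi-shell DWI from parameter maps
#'
#' Evaluates the SANDI forward model voxelwise and expands the per-shell
#' spherical means to per-direction volumes (each direction of a shell
#' carries the shell's powder-average value, sufficient for every
#' spherical-mean consumer downstream), interleaving one b = 0 volume every
#' 16 DWIs. Rician noise with `sigma = b0_level / snr` is added when `snr`
#' is given; a noise-free copy is always returned.
#'
#' @param phantom result of [make_phantom()] (or any list with `params` and
#'   `mask`).
#' @param protocol an [acq_protocol()].
#' @param snr positive scalar SNR on the b = 0 images, or NULL for
#'   noise-free data.
#' @param b0_level b = 0 signal intensity of foreground voxels.
#' @param seed integer seed for the noise stream.
#' @return List with `dwi` (noisy `dwi_volume`) and `clean` (noise-free
#'   copy).
#' @export
simulate_subject_dwi <- function(phantom, protocol = sandi_protocol(),
                                 snr = NULL, b0_level = 100,
                                 seed = 20250101) {
  if (!is.null(snr) && snr <= 0) stop("snr must be positive or NULL")
  mask <- phantom$mask
  d <- dim(mask)
  fg <- which(mask)
  theta <- data.frame(
    f_soma = phantom$params$f_soma[fg],
    f_neurite = phantom$params$f_neurite[fg],
    r_soma = phantom$params$r_soma[fg],
    d_in = phantom$params$d_in[fg],
    d_e = phantom$params$d_e[fg])
  sig <- sandi_signal_matrix(theta, protocol)     # n_fg x n_shell
  # volume ordering: shells in order, b0 interleaved every 16 DWIs
  b <- protocol$shells
  dirs <- protocol$directions_per_shell
  bvals <- c(); bvecs <- NULL; shell_idx <- c()
  for (s in seq_along(b)) {
    bvals <- c(bvals, rep(b[s], dirs[s]))
    bvecs <- rbind(bvecs, rotate_directions(fibonacci_directions(dirs[s]),
                                            s - 1))
    shell_idx <- c(shell_idx, rep(s, dirs[s]))
  }
  n_dwi <- length(bvals)
  ins <- seq(1, n_dwi + 1, by = 16)               # b0 before every 16 DWIs
  order_b <- integer(0); order_shell <- integer(0)
  pos <- 1
  for (i in seq_len(n_dwi)) {
    if (pos <= length(ins) && i == ins[pos]) {
      order_shell <- c(order_shell, 0L); pos <- pos + 1
    }
    order_shell <- c(order_shell, shell_idx[i])
  }
  dwi_slots <- which(order_shell != 0)
  nvol <- length(order_shell)
  all_bvals <- numeric(nvol); all_bvecs <- matrix(0, nvol, 3)
  all_bvals[dwi_slots] <- bvals
  all_bvecs[dwi_slots, ] <- bvecs
  data <- array(0, c(d, nvol))
  flat <- matrix(0, prod(d), nvol)
  for (v in seq_len(nvol)) {
    s <- order_shell[v]
    flat[fg, v] <- if (s == 0) b0_level else b0_level * sig[, s]
  }
  data <- array(flat, c(d, nvol))
  clean <- new_dwi_volume(data, all_bvals, all_bvecs, voxdim = c(1, 1, 1))
  noisy <- clean
  if (!is.null(snr)) {
    sigma <- b0_level / snr
    noisy$data <- withr::with_seed(seed, add_rician_noise(clean$data, sigma))
  }
  list(dwi = noisy, clean = clean)
}

#' Degrade a high-resolution acquisition to low resolution
#'
#' Block-mean downsampling of every volume (scanner partial-volume model)
#' followed by Rician noise, producing the matched low/high-resolution pair
#' used to benchmark super-resolution.
#'
#' @param dwi_hr a `dwi_volume` on the ground-truth grid.
#' @param factor integer downsampling factor (>= 2).
#' @param snr SNR on the low-resolution b = 0 images, or NULL.
#' @param seed integer noise seed.
#' @return A low-resolution `dwi_volume`.
#' @export
degrade_to_lowres <- function(dwi_hr, factor = 2, snr = NULL,
                              seed = 20250101) {
  stopifnot(inherits(dwi_hr, "dwi_volume"), factor >= 2)
  d <- dim(dwi_hr$data)
  nvol <- d[4]
  dl <- d[1:3] %/% factor
  data <- array(0, c(dl, nvol))
  for (v in seq_len(nvol))
    data[, , , v] <- block_downsample(dwi_hr$data[, , , v], factor)
  lr <- new_dwi_volume(data, dwi_hr$bvals, dwi_hr$bvecs,
                       voxdim = dwi_hr$voxdim * factor)
  if (!is.null(snr)) {
    b0 <- data[, , , lr$bvals <= 1e-8, drop = FALSE]
    b0_level <- mean(b0[b0 > 0])
    lr$data <- withr::with_seed(seed,
                                add_rician_noise(lr$data, b0_level / snr))
  }
  lr
}

#' Synthetic anatomical reference volume
#'
#' High-resolution piecewise-constant volume assigning a distinct intensity
#' to every phantom region (background included), with optional smooth bias
#' field and Gaussian noise; exactly aligned with the ground-truth grid.
#'
#' @param labels 3D integer label array (0 = background).
#' @param contrast numeric vector of intensities, one per label value
#'   0, 1, 2, ...; default a spread of distinct values.
#' @param bias_sd relative amplitude of a smooth multiplicative bias field.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed integer seed.
#' @return 3D reference array.
#' @export
make_t1_reference <- function(labels, contrast = NULL, bias_sd = 0,
                              noise_sd = 0, seed = 20250101) {
  nlab <- max(labels) + 1
  if (is.null(contrast)) contrast <- c(5, seq(60, 160, length.out = nlab - 1))
  stopifnot(length(contrast) == nlab)
  ref <- array(contrast[labels + 1], dim(labels))
  if (bias_sd > 0 || noise_sd > 0) {
    ref <- withr::with_seed(seed, {
      if (bias_sd > 0)
        ref <- ref * (1 + smooth_field(dim(labels), bias_sd))
      if (noise_sd > 0)
        ref <- ref + array(stats::rnorm(length(ref), 0, noise_sd),
                           dim(labels))
      ref
    })
  }
  ref
}

#' Age-effect model for cohort simulation
#'
#' Linear per-year trends chosen to induce a target cross-sectional Pearson
#' correlation with age at the configured cohort size: for target r and
#' subject noise sd `s`, the slope is `r / sqrt(1 - r^2) * s / sd(age)`
#' with sd(age) of the uniform age range.
#'
#' @param target_r named numeric vector of target correlations per SANDI
#'   parameter (defaults emulate moderate aging effects).
#' @param noise_sd named (or scalar) subject-level noise sd per parameter.
#' @param age_range cohort age range in years.
#' @param n_male,n_female sex split (32/40 by default at n = 72).
#' @return Object of class `age_effect_model`.
#' @export
age_effect_model <- function(target_r = c(f_soma = -0.5, f_neurite = 0.3,
                                          r_soma = 0.4, d_in = 0, d_e = 0.3),
                             noise_sd = c(f_soma = 0.04, f_neurite = 0.04,
                                          r_soma = 0.6, d_in = 0.15,
                                          d_e = 0.15),
                             age_range = c(19, 85),
                             n_male = 32, n_female = 40) {
  stopifnot(all(abs(target_r) < 1), all(noise_sd >= 0))
  if (any(noise_sd == 0 & rep_len(target_r, length(noise_sd)) != 0))
    stop("a non-zero target correlation needs non-zero subject noise")
  structure(list(target_r = target_r, noise_sd = noise_sd,
                 age_range = age_range, n_male = n_male,
                 n_female = n_female),
            class = "age_effect_model")
}

#' Simulate an age-structured cohort of ROI parameter values
#'
#' Draws ages uniformly over the configured range with the configured sex
#' split, then generates per-subject, per-region SANDI parameters as
#' baseline + slope x (age - mean age) + subject noise, clamped to the
#' valid ranges. Sex carries no injected effect. Returns both the cohort
#' table and the ground-truth slopes for recovery testing; if clamping
#' saturates more than 20% of subjects for some parameter a warning is
#' recorded in the provenance attribute.
#'
#' @param effect an [age_effect_model()].
#' @param regions region baseline table (default [subfield_params()]).
#' @param seed integer seed.
#' @return Tibble of class `hippo_cohort`: subject, age, sex (0 = female,
#'   1 = male), roi, and one column per SANDI parameter. Ground truth in
#'   `attr(, "truth")`, provenance in `attr(, "provenance")`.
#' @export
simulate_cohort <- function(effect = age_effect_model(),
                            regions = subfield_params(), seed = 20250101) {
  n <- effect$n_male + effect$n_female
  stopifnot(n >= 4)
  pars <- names(effect$target_r)
  sd_age <- diff(effect$age_range) / sqrt(12)
  noise_sd <- rep(effect$noise_sd, length.out = length(pars))
  names(noise_sd) <- pars
  slopes <- effect$target_r / sqrt(1 - effect$target_r^2) *
    noise_sd[pars] / sd_age
  rng <- sandi_ranges()
  out <- withr::with_seed(seed, {
    age <- stats::runif(n, effect$age_range[1], effect$age_range[2])
    sex <- sample(rep(c(1, 0), c(effect$n_male, effect$n_female)))
    rows <- tidyr::expand_grid(subject = seq_len(n),
                               roi = regions$roi)
    rows$age <- age[rows$subject]
    rows$sex <- sex[rows$subject]
    clamped <- stats::setNames(numeric(length(pars)), pars)
    for (p in pars) {
      base <- regions[[p]][match(rows$roi, regions$roi)]
      val <- base + slopes[p] * (rows$age - mean(effect$age_range)) +
        stats::rnorm(nrow(rows), 0, noise_sd[p])
      lim <- if (p %in% c("f_soma", "f_neurite")) c(0, 1) else rng[[p]]
      hit <- val < lim[1] | val > lim[2]
      clamped[p] <- mean(hit)
      rows[[p]] <- pmin(pmax(val, lim[1]), lim[2])
    }
    attr(rows, "clamped_fraction") <- clamped
    rows
  })
  cl <- attr(out, "clamped_fraction")
  prov <- list(seed = seed, effect = unclass(effect), slopes = slopes,
               clamped_fraction = cl,
               warning = if (any(cl > 0.2))
                 paste("clamping saturated >20% of subjects for:",
                       paste(names(cl)[cl > 0.2], collapse = ", ")))
  attr(out, "truth") <- tibble::tibble(parameter = pars,
                                       target_r = effect$target_r,
                                       slope_per_year = unname(slopes),
                                       noise_sd = unname(noise_sd[pars]))
  attr(out, "provenance") <- prov
  class(out) <- c("hippo_cohort", class(out))
  out
}

#' Simulate a cohort of per-vertex metric maps
#'
#' Per-subject vertex maps `baseline + slope_v * (age - mean age) + noise`,
#' with a per-vertex slope vector (zero for a null cohort, or non-zero in a
#' labelled patch for localisation experiments).
#'
#' @param n_subjects cohort size.
#' @param n_vertices template vertex count.
#' @param slope per-vertex slope vector (recycled; default 0).
#' @param noise_sd subject-level noise sd.
#' @param age_range ages drawn uniformly over this range.
#' @param seed integer seed.
#' @return List: `maps` (n_subjects x n_vertices), `age`, `sex`.
#' @export
simulate_vertex_cohort <- function(n_subjects, n_vertices, slope = 0,
                                   noise_sd = 1, age_range = c(19, 85),
                                   seed = 20250101) {
  slope <- rep_len(slope, n_vertices)
  withr::with_seed(seed, {
    age <- stats::runif(n_subjects, age_range[1], age_range[2])
    sex <- stats::rbinom(n_subjects, 1, 0.5)
    maps <- outer(age - mean(age_range), slope) +
      matrix(stats::rnorm(n_subjects * n_vertices, 0, noise_sd),
             n_subjects, n_vertices)
    list(maps = maps, age = age, sex = sex)
  })
}

#' Analytic toy meshes
#'
#' Fixtures with known curvature, area and thickness: `sphere` (icosphere),
#' `plane` (triangulated sheet), `cylinder` (open tube), `sinusoid`
#' (z = a sin(k x) sheet plus its flat projection in correspondence) and
#' `concentric_pair` (two radially corresponding icospheres).
#'
#' @param kind one of "sphere", "plane", "cylinder", "sinusoid",
#'   "concentric_pair".
#' @param radius sphere/cylinder radius.
#' @param subdivisions icosphere subdivision level.
#' @param nx,ny grid resolution for sheets; `nu,nv` for the cylinder.
#' @param lx,ly sheet extents (mm).
#' @param amplitude,wavenumber sinusoid parameters a and k.
#' @param height cylinder height.
#' @param radii the two radii of the concentric pair.
#' @return A [surface_mesh()]; for `sinusoid` a list (native, unfolded); for
#'   `concentric_pair` a list (inner, outer).
#' @export
make_toy_mesh <- function(kind = c("sphere", "plane", "cylinder", "sinusoid",
                                   "concentric_pair"),
                          radius = 1, subdivisions = 4, nx = 40, ny = 40,
                          lx = 10, ly = 10, amplitude = 1, wavenumber = 1,
                          height = 10, nu = 72, nv = 30, radii = c(10, 12)) {
  kind <- match.arg(kind)
  switch(kind,
    sphere = icosphere(radius, subdivisions),
    plane = sheet_mesh(nx, ny, lx, ly, function(x, y) 0 * x),
    cylinder = cylinder_mesh(radius, height, nu, nv),
    sinusoid = list(
      native = sheet_mesh(nx, ny, lx, ly,
                          function(x, y) amplitude * sin(wavenumber * x)),
      unfolded = sheet_mesh(nx, ny, lx, ly, function(x, y) 0 * x)),
    concentric_pair = {
      inner <- icosphere(radii[1], subdivisions)
      outer <- inner
      outer$vertices <- inner$vertices * radii[2] / radii[1]
      list(inner = inner, outer = outer)
    })
}

icosphere <- function(radius = 1, subdivisions = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf[4 * i - 3, ] <- c(a, ab, ca)
      nf[4 * i - 2, ] <- c(b, bc, ab)
      nf[4 * i - 1, ] <- c(c3, ca, bc)
      nf[4 * i, ] <- c(ab, bc, ca)
    }
    f <- nf
  }
  # enforce outward winding
  nrm <- face_normals(v, f)
  cen <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  flip <- rowSums(nrm * cen) < 0
  f[flip, ] <- f[flip, c(1, 3, 2)]
  surface_mesh(v * radius, f)
}

sheet_mesh <- function(nx, ny, lx, ly, zfun) {
  xs <- seq(0, lx, length.out = nx)
  ys <- seq(0, ly, length.out = ny)
  g <- expand.grid(x = xs, y = ys)
  v <- cbind(g$x, g$y, zfun(g$x, g$y))
  id <- function(i, j) (j - 1) * nx + i
  f <- matrix(0L, 0, 3)
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    f <- rbind(f,
               c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
               c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  surface_mesh(v, f)
}

cylinder_mesh <- function(radius, height, nu, nv) {
  th <- seq(0, 2 * pi, length.out = nu + 1)[-(nu + 1)]
  zs <- seq(0, height, length.out = nv)
  g <- expand.grid(u = seq_len(nu), v = seq_len(nv))
  v <- cbind(radius * cos(th[g$u]), radius * sin(th[g$u]), zs[g$v])
  id <- function(i, j) (j - 1) * nu + i
  nxt <- function(i) ifelse(i == nu, 1L, i + 1L)
  f <- matrix(0L, 0, 3)
  for (j in seq_len(nv - 1)) for (i in seq_len(nu)) {
    f <- rbind(f,
               c(id(i, j), id(nxt(i), j), id(nxt(i), j + 1)),
               c(id(i, j), id(nxt(i), j + 1), id(i, j + 1)))
  }
  surface_mesh(v, f)
}
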