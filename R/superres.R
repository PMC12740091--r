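#' Super-resolution configuration
#'
#' Settings of the anatomically guided self-similarity super-resolution:
#' weights are computed in a 5 x 5 x 5 kernel from the similarity of
#' 3 x 3 x 3 patches in the diffusion volume and of the voxel intensities in
#' the co-registered high-resolution reference, with a smoothing parameter
#' series h = (1, 2, 4, 6, 8, 16) over six iterations; each iteration is
#' followed by an exact data-consistency correction against the original
#' low-resolution data.
#'
#' @param kernel odd cubic search-kernel edge length (voxels).
#' @param patch odd cubic patch edge length (voxels).
#' @param h_series positive reals, one per iteration.
#' @param factor integer upsampling factor per axis.
#' @return Object of class `sr_config`.
#' @export
sr_config <- function(kernel = 5, patch = 3, h_series = c(1, 2, 4, 6, 8, 16),
                      factor = 2) {
  stopifnot(kernel %% 2 == 1, patch %% 2 == 1, kernel >= patch,
            all(h_series > 0), factor >= 1)
  structure(list(kernel = as.integer(kernel), patch = as.integer(patch),
                 h_series = as.numeric(h_series),
                 factor = as.integer(factor)),
            class = "sr_config")
}

#' Nearest-neighbour upsampling
#'
#' Replicates every low-resolution voxel into its `factor`^3 children.
#' Exact right inverse of [block_downsample()].
#'
#' @param vol 3D array.
#' @param factor integer factor per axis.
#' @return Upsampled 3D array.
#' @export
nearest_upsample <- function(vol, factor) {
  stopifnot(length(dim(vol)) == 3, factor >= 1)
  if (factor == 1) return(vol)
  d <- dim(vol)
  ix <- rep(seq_len(d[1]), each = factor)
  iy <- rep(seq_len(d[2]), each = factor)
  iz <- rep(seq_len(d[3]), each = factor)
  vol[ix, iy, iz]
}

#' Block-mean downsampling
#'
#' Mean over each `factor`^3 block, modelling scanner partial-volume
#' averaging; together with [nearest_upsample()] it forms the adjoint pair
#' that makes the data-consistency step exact.
#'
#' @param vol 3D array with extents divisible by `factor`.
#' @param factor integer factor per axis.
#' @return Downsampled 3D array.
#' @export
block_downsample <- function(vol, factor) {
  stopifnot(length(dim(vol)) == 3, factor >= 1)
  if (factor == 1) return(vol)
  d <- dim(vol)
  if (any(d %% factor != 0))
    stop("volume extents must be divisible by the downsampling factor")
  dl <- d %/% factor
  # average over each axis in turn
  a <- array(vol, c(factor, dl[1], d[2], d[3]))
  a <- colMeans(a)
  a <- aperm(array(a, c(dl[1], factor, dl[2], d[3])), c(2, 1, 3, 4))
  a <- colMeans(a)
  a <- aperm(array(a, c(dl[1], dl[2], factor, dl[3])), c(3, 1, 2, 4))
  array(colMeans(a), dl)
}

# trilinear upsampling used for variance-map handling
trilinear_upsample <- function(vol, factor) {
  stopifnot(length(dim(vol)) == 3, factor >= 1)
  if (factor == 1) return(vol)
  d <- dim(vol)
  affine <- diag(4)                # identity: work in voxel coordinates
  # child voxel centres in parent voxel coordinates (0-based centres)
  coord1 <- function(n) (seq_len(n * factor) - 0.5) / factor - 0.5
  g <- expand.grid(x = coord1(d[1]), y = coord1(d[2]), z = coord1(d[3]))
  vals <- interp_trilinear(vol, as.matrix(g), clamp = TRUE)
  array(vals, d * factor)
}

#' Self-similarity weight
#'
#' Weight between a centre voxel and a kernel neighbour:
#' `-ln w = h^2 * (ssd_patch / (patch_voxels * k_dwi) + dt1^2 / k_t1w)`,
#' so `w = 1` iff both the patch difference and the reference difference
#' vanish. Exposed mainly for testing; the iteration uses the same formula
#' in compiled code.
#'
#' @param ssd_patch sum of squared DWI patch differences.
#' @param dt1 reference-intensity difference at the two centres.
#' @param h smoothing parameter for this iteration.
#' @param k_dwi,k_t1w normalisation constants: mean squared DWI / reference
#'   intensity within the mask.
#' @param patch_voxels number of voxel pairs actually compared (27 for a
#'   full 3 x 3 x 3 patch; fewer at volume boundaries).
#' @return Weight in (0, 1\].
#' @export
sr_weight <- function(ssd_patch, dt1, h, k_dwi, k_t1w, patch_voxels = 27) {
  if (k_dwi <= 0 || k_t1w <= 0) stop("normalisation constants must be > 0")
  stopifnot(patch_voxels >= 1)
  exp(-h^2 * (ssd_patch / (patch_voxels * k_dwi) + dt1^2 / k_t1w))
}

#' One super-resolution weighting iteration
#'
#' Replaces every in-mask voxel by the weight-normalised average of its
#' search kernel (the centre participates with weight 1); out-of-mask voxels
#' are untouched.
#'
#' @param dwi_hr 3D array, current high-resolution estimate.
#' @param reference 3D array, co-registered anatomical reference on the same
#'   grid.
#' @param h smoothing parameter of this iteration.
#' @param config an [sr_config()].
#' @param mask logical 3D array; default all TRUE.
#' @param k_dwi,k_t1w normalisation constants; default mean squared in-mask
#'   intensity of `dwi_hr` / `reference`.
#' @return Updated 3D array.
#' @export
sr_iteration <- function(dwi_hr, reference, h, config = sr_config(),
                         mask = NULL, k_dwi = NULL, k_t1w = NULL) {
  stopifnot(all(dim(dwi_hr) == dim(reference)))
  if (is.null(mask)) mask <- array(TRUE, dim(dwi_hr))
  if (is.null(k_dwi)) k_dwi <- mean(dwi_hr[mask]^2)
  if (is.null(k_t1w)) k_t1w <- mean(reference[mask]^2)
  if (k_dwi <= 0 || k_t1w <= 0) stop("normalisation constants must be > 0")
  .sr_iteration_cpp(dwi_hr, reference, mask, dim(dwi_hr), h,
                    config$kernel, config$patch, k_dwi, k_t1w)
}

#' Data-consistency correction
#'
#' Adds back the nearest-upsampled residual between the original
#' low-resolution volume and the block-downsampled high-resolution estimate;
#' afterwards `block_downsample(output)` equals the low-resolution input
#' exactly. Idempotent.
#'
#' @param dwi_hr 3D high-resolution array.
#' @param dwi_lr 3D low-resolution array (`dim(dwi_hr) / factor`).
#' @param factor integer grid factor.
#' @return Corrected high-resolution array.
#' @export
data_consistency <- function(dwi_hr, dwi_lr, factor) {
  if (!all(dim(dwi_hr) == dim(dwi_lr) * factor))
    stop("grids are not related by the stated factor")
  resid <- dwi_lr - block_downsample(dwi_hr, factor)
  dwi_hr + nearest_upsample(resid, factor)
}

#' Anatomically guided self-similarity super-resolution
#'
#' Super-resolves a low-resolution multi-volume diffusion series with a
#' co-registered high-resolution reference: each 3D volume is independently
#' initialised by nearest-neighbour upsampling and refined by alternating
#' self-similarity weighting ([sr_iteration()], one pass per h in the
#' series) and exact data consistency against the original low-resolution
#' volume. Voxel distance is deliberately excluded from the weights. The
#' DWI normalisation constant is computed per 3D volume (intensity scale
#' varies strongly across shells), the reference constant once.
#'
#' @param dwi_lr 3D array or 4D series at low resolution.
#' @param reference high-resolution 3D reference on the target grid.
#' @param config an [sr_config()].
#' @param mask logical high-resolution 3D array; default all TRUE.
#' @return Array of the same rank as `dwi_lr` on the high-resolution grid.
#' @export
super_resolve <- function(dwi_lr, reference, config = sr_config(),
                          mask = NULL) {
  f <- config$factor
  is4d <- length(dim(dwi_lr)) == 4
  vols <- if (is4d) dim(dwi_lr)[4] else 1L
  dhr <- (if (is4d) dim(dwi_lr)[1:3] else dim(dwi_lr)) * f
  stopifnot(all(dim(reference) == dhr))
  if (is.null(mask)) mask <- array(TRUE, dhr)
  k_t1w <- mean(reference[mask]^2)
  one <- function(lr) {
    hr <- nearest_upsample(lr, f)
    k_dwi <- mean(hr[mask]^2)
    for (h in config$h_series) {
      hr <- sr_iteration(hr, reference, h, config, mask,
                         k_dwi = k_dwi, k_t1w = k_t1w)
      hr <- data_consistency(hr, lr, f)
    }
    hr
  }
  if (!is4d) return(one(dwi_lr))
  out <- array(NA_real_, c(dhr, vols))
  for (v in seq_len(vols)) out[, , , v] <- one(dwi_lr[, , , v])
  out
}
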