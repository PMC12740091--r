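#' Diffusion-weighted volume container
#'
#' 4D image grid plus its gradient table: b-values in ms/um^2, unit
#' direction vectors, voxel size in mm and a voxel-to-world affine (0-based
#' voxel indices).
#'
#' @param data 4D numeric array (x, y, z, volume).
#' @param bvals per-volume b-values in ms/um^2.
#' @param bvecs n x 3 direction matrix; rows for b = 0 may be zero.
#' @param voxdim voxel edge lengths in mm.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @return Object of class `dwi_volume`.
#' @export
new_dwi_volume <- function(data, bvals, bvecs, voxdim = c(1, 1, 1),
                           affine = NULL) {
  stopifnot(length(dim(data)) == 4)
  if (dim(data)[4] != length(bvals))
    stop("gradient table length does not match the 4th dimension")
  bvecs <- as.matrix(bvecs)
  stopifnot(nrow(bvecs) == length(bvals), ncol(bvecs) == 3)
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- bvals > 1e-8 & abs(nrm - 1) > 1e-3
  if (any(bad)) stop(sum(bad), " non-unit direction vectors")
  if (is.null(affine)) {
    affine <- diag(c(voxdim, 1))
  }
  structure(list(data = data, bvals = as.numeric(bvals), bvecs = bvecs,
                 voxdim = as.numeric(voxdim), affine = affine),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<dwi_volume> ", paste(d[1:3], collapse = " x "), " voxels x ", d[4],
      " volumes, voxel ", paste(format(x$voxdim), collapse = " x "),
      " mm\n  shells (s/mm^2): ",
      paste(sort(unique(round(x$bvals * 1000))), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Read a DWI series with its FSL-style gradient table
#'
#' Loads a NIfTI volume plus `bvals` (one row, s/mm^2 — converted to
#' ms/um^2 on read) and `bvecs` (three rows of unit vectors) text files.
#'
#' @param nifti_path path to the 4D NIfTI file.
#' @param bvals_path,bvecs_path paths to the gradient table files.
#' @return A `dwi_volume`.
#' @export
read_dwi <- function(nifti_path, bvals_path, bvecs_path) {
  img <- RNifti::readNifti(nifti_path)
  data <- array(as.numeric(img), dim(img))
  bvals <- as.numeric(scan(bvals_path, quiet = TRUE)) / 1000
  bv <- as.matrix(utils::read.table(bvecs_path))
  if (nrow(bv) == 3) bv <- t(bv)
  if (dim(data)[4] != length(bvals))
    stop("gradient table length does not match the 4th dimension")
  vox <- RNifti::pixdim(img)[1:3]
  new_dwi_volume(data, bvals, bv, voxdim = vox,
                 affine = structure(RNifti::xform(img), dimnames = NULL))
}

#' Write a DWI series with its gradient table
#'
#' @param dwi a `dwi_volume`.
#' @param nifti_path,bvals_path,bvecs_path output paths; b-values are
#'   written in s/mm^2, bvecs as three rows.
#' @return `nifti_path`, invisibly.
#' @export
write_dwi <- function(dwi, nifti_path, bvals_path, bvecs_path) {
  img <- RNifti::asNifti(dwi$data)
  RNifti::pixdim(img) <- c(dwi$voxdim, 1)
  RNifti::writeNifti(img, nifti_path)
  writeLines(paste(format(dwi$bvals * 1000, trim = TRUE, scientific = FALSE),
                   collapse = " "), bvals_path)
  utils::write.table(t(dwi$bvecs), bvecs_path, row.names = FALSE,
                     col.names = FALSE)
  invisible(nifti_path)
}

#' Write / read a 3D map as NIfTI
#'
#' @param vol 3D array.
#' @param path output path.
#' @param voxdim voxel size in mm.
#' @return `read_volume` returns the array with a `voxdim` attribute.
#' @export
write_volume <- function(vol, path, voxdim = c(1, 1, 1)) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- voxdim
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  structure(array(as.numeric(img), dim(img)),
            voxdim = RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))])
}

#' Write a surface mesh as ASCII PLY
#'
#' Per-vertex scalars and labels are written as extra float/int vertex
#' properties.
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  scal <- mesh$scalars
  props <- c("property float x", "property float y", "property float z")
  cols <- mesh$vertices
  if (!is.null(mesh$labels)) {
    lev <- unique(as.character(mesh$labels))
    props <- c(props, "property int label")
    cols <- cbind(cols, match(as.character(mesh$labels), lev) - 1L)
  }
  for (s in names(scal)) {
    props <- c(props, paste("property float", s))
    cols <- cbind(cols, scal[[s]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               if (!is.null(mesh$labels))
                 paste("comment labels", paste(unique(as.character(
                   mesh$labels)), collapse = " ")),
               paste("element vertex", nv), props,
               paste("element face", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(cols, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASCII PLY surface mesh
#'
#' @param path PLY file path.
#' @return A [surface_mesh()]; extra vertex properties become scalars, an
#'   integer `label` property (with its comment-encoded level names)
#'   becomes labels.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- which(lines == "end_header")
  hdr <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                   hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face",
                                                 hdr, value = TRUE)))
  vprops <- sub("^property \\S+ ", "",
                grep("^property (float|int)", hdr, value = TRUE))
  lab_line <- grep("^comment labels ", hdr, value = TRUE)
  vtab <- utils::read.table(text = lines[end + seq_len(nv)])
  names(vtab) <- vprops
  ftab <- utils::read.table(text = lines[end + nv + seq_len(nf)])
  labels <- NULL
  if ("label" %in% vprops && length(lab_line)) {
    lev <- strsplit(sub("^comment labels ", "", lab_line), " ")[[1]]
    labels <- lev[vtab$label + 1]
  }
  scal <- as.list(vtab[setdiff(vprops, c("x", "y", "z", "label"))])
  surface_mesh(as.matrix(vtab[, c("x", "y", "z")]),
               as.matrix(ftab[, 2:4]) + 1L, labels = labels,
               scalars = scal)
}

#' Write per-vertex scalars as TSV keyed by vertex index
#'
#' @param values named list or data frame of per-vertex vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vertex_tsv <- function(values, path) {
  d <- as.data.frame(values)
  d <- cbind(vertex = seq_len(nrow(d)), d)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default end-to-end demonstration configuration
#'
#' A desk-scale configuration of the full pipeline: a small phantom, the
#' 8-shell protocol with reduced direction counts, factor-2 degradation and
#' super-resolution, a reduced SANDI training set, DKI on the low-b shells,
#' toy-mesh surface metrics and an n = 72 cohort regression.
#'
#' @param out_dir output directory.
#' @param seed top-level seed; every stage's randomness derives from it.
#' @return Nested configuration list (serialisable as YAML).
#' @export
demo_config <- function(out_dir = tempfile("hippomicro_run_"),
                        seed = 20250101) {
  list(
    out_dir = out_dir,
    seed = seed,
    phantom = list(shape = c(16, 16, 16), perturb_sd = 0),
    protocol = list(bvals = c(0.05, 0.35, 0.8, 1.5, 2.4, 3.45, 4.75, 6.0),
                    directions = c(6, 6, 6, 6, 6, 6, 6, 6),
                    delta_small = 8, delta_big = 19, b0_count = 3),
    supres = list(factor = 2, kernel = 5, patch = 3,
                  h_series = c(1, 2, 4, 6, 8, 16), snr = 50),
    sandi = list(n_train = 2000, n_trees = 50, snr = 50),
    dki = list(b_max = 3.45),
    stats = list(model = "M3", alpha = 0.05))
}

#' Run the full phantom pipeline
#'
#' Executes simulate -> degrade -> super-resolve -> spherical means -> SANDI
#' fit -> DKI fit -> surface metrics -> cohort age regression on synthetic
#' data with known ground truth, writing parameter maps (NIfTI), tables
#' (TSV) and a machine-readable JSON report of every statistic, seed and
#' FDR decision. Deterministic: rerunning with the same configuration
#' reproduces all outputs.
#'
#' @param config configuration list as from [demo_config()], or the path of
#'   a YAML file with the same structure.
#' @return The report list, invisibly; artifacts under `config$out_dir`.
#' @export
run_pipeline <- function(config = demo_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  report <- list(seed = seed,
                 package_version = as.character(utils::packageVersion(
                   "hippomicro")))

  proto <- acq_protocol(config$protocol$bvals, config$protocol$directions,
                        config$protocol$delta_small,
                        config$protocol$delta_big,
                        config$protocol$b0_count)
  # --- simulate ---
  spec <- phantom_spec(shape = config$phantom$shape,
                       perturb_sd = config$phantom$perturb_sd, seed = seed)
  phantom <- make_phantom(spec)
  sim <- simulate_subject_dwi(phantom, proto, snr = NULL, seed = seed)
  hr_clean <- sim$clean
  lr <- degrade_to_lowres(hr_clean, config$supres$factor,
                          snr = config$supres$snr, seed = seed + 1)
  ref <- make_t1_reference(phantom$labels)
  report$simulate <- list(shape = spec$shape, n_volumes = dim(lr$data)[4],
                          snr = config$supres$snr)

  # --- super-resolve ---
  cfg <- sr_config(config$supres$kernel, config$supres$patch,
                   config$supres$h_series, config$supres$factor)
  mask_hr <- phantom$mask
  hr_sr <- super_resolve(lr$data, ref, cfg, mask = mask_hr)
  sr_dwi <- new_dwi_volume(hr_sr, lr$bvals, lr$bvecs,
                           voxdim = lr$voxdim / cfg$factor)
  nn <- array(NA_real_, dim(hr_sr))
  for (v in seq_len(dim(lr$data)[4]))
    nn[, , , v] <- nearest_upsample(lr$data[, , , v], cfg$factor)
  m4 <- array(mask_hr, dim(hr_sr))
  rmse4 <- function(a) sqrt(mean((a[m4] - hr_clean$data[m4])^2))
  report$supres <- list(rmse_sr = rmse4(hr_sr), rmse_nearest = rmse4(nn),
                        h_series = cfg$h_series)

  # --- SANDI fit ---
  ts <- build_training_set(config$sandi$n_train, proto,
                           snr = config$sandi$snr, seed = seed + 2)
  inv <- train_sandi_inverter(ts, config$sandi$n_trees)
  sm <- spherical_mean_shells(sr_dwi)
  sm$mask <- sm$mask & as.vector(mask_hr)
  maps <- fit_sandi(sm, inv)
  for (p in names(maps))
    write_volume(maps[[p]], file.path(config$out_dir,
                                      paste0(p, ".nii.gz")),
                 voxdim = sr_dwi$voxdim)
  truth_err <- vapply(c("f_soma", "f_neurite", "f_extra"), function(p) {
    sqrt(mean((maps[[p]][mask_hr] - phantom$params[[p]][mask_hr])^2))
  }, numeric(1))
  report$sandi <- list(n_train = config$sandi$n_train,
                       n_trees = config$sandi$n_trees,
                       training_snr = config$sandi$snr,
                       fraction_rmse_vs_truth = as.list(truth_err))

  # --- DKI fit ---
  dki <- fit_dki(sr_dwi, b_max = config$dki$b_max, mask = mask_hr)
  for (p in names(dki))
    write_volume(dki[[p]], file.path(config$out_dir,
                                     paste0(tolower(p), ".nii.gz")),
                 voxdim = sr_dwi$voxdim)
  report$dki <- list(median_md = stats::median(dki$MD, na.rm = TRUE),
                     median_mk = stats::median(dki$MK, na.rm = TRUE))

  # --- surface metrics on a toy folded sheet sampled from the f_soma map --
  sheet <- make_toy_mesh("sinusoid", nx = 24, ny = 24,
                         lx = dim(hr_sr)[1] - 1, ly = dim(hr_sr)[2] - 1,
                         amplitude = 1.5, wavenumber = 0.5)
  mid <- sheet$native
  mid$vertices[, 3] <- mid$vertices[, 3] + dim(hr_sr)[3] / 2
  gyr <- gyrification(sheet$native, sheet$unfolded)
  curv <- mean_curvature(sheet$native)
  fsoma_on_surf <- sample_at_vertices(maps$f_soma, mid)
  write_vertex_tsv(list(gyrification = gyr, mean_curvature = curv,
                        f_soma = fsoma_on_surf),
                   file.path(config$out_dir, "surface_metrics.tsv"))
  report$surface <- list(mean_gyrification = mean(gyr, na.rm = TRUE),
                         n_vertices = nrow(mid$vertices))

  # --- cohort regression ---
  cohort <- simulate_cohort(seed = seed + 3)
  fit <- age_regression(cohort, model = config$stats$model)
  utils::write.table(fit, file.path(config$out_dir, "age_regression.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  report$regression <- lapply(seq_len(nrow(fit)), function(i)
    list(metric = fit$metric[i], roi = fit$roi[i], r = fit$r[i],
         t = fit$t[i], p = fit$p[i], p_fdr = fit$p_fdr[i],
         significant = fit$p_fdr[i] < config$stats$alpha))

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
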