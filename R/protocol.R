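#' Multi-shell PGSE acquisition protocol
#'
#' Bundles the shell b-values, per-shell direction counts and the pulsed
#' gradient spin-echo timings that parameterise every forward signal in the
#' package. b-values are stored internally in ms/um^2 (1 ms/um^2 =
#' 1000 s/mm^2) so that all magnitudes stay O(1); diffusivities are um^2/ms
#' and times ms throughout.
#'
#' @param shells numeric vector of non-zero shell b-values in ms/um^2.
#' @param directions_per_shell integer vector, one count per shell.
#' @param delta_small gradient pulse duration delta in ms.
#' @param delta_big diffusion time Delta in ms; must exceed `delta_small`.
#' @param b0_count number of b = 0 volumes in the acquisition.
#' @return An object of class `acq_protocol`.
#' @seealso [sandi_protocol()] for the study default.
#' @export
acq_protocol <- function(shells, directions_per_shell, delta_small = 8,
                         delta_big = 19, b0_count = 1) {
  stopifnot(is.numeric(shells), length(shells) >= 1)
  if (any(shells < 0)) stop("shell b-values must be non-negative")
  if (length(directions_per_shell) == 1)
    directions_per_shell <- rep(directions_per_shell, length(shells))
  if (length(directions_per_shell) != length(shells))
    stop("need one direction count per shell")
  if (any(directions_per_shell < 1 & shells > 0))
    stop("every b > 0 shell needs at least one direction")
  if (!(delta_small < delta_big))
    stop("pulse duration delta must be shorter than diffusion time Delta")
  if (b0_count < 0) stop("b0_count must be non-negative")
  structure(
    list(shells = as.numeric(shells),
         directions_per_shell = as.integer(directions_per_shell),
         delta_small = delta_small, delta_big = delta_big,
         b0_count = as.integer(b0_count)),
    class = "acq_protocol")
}

#' The 8-shell Connectome hippocampus protocol
#'
#' Shells at b = 50, 350, 800, 1500, 2400, 3450, 4750 and 6000 s/mm^2 with
#' delta = 8 ms, Delta = 19 ms, 32 gradient directions for shells below
#' 2300 s/mm^2 and 64 above, and one interleaved b = 0 volume per 16 DWIs.
#'
#' @return An `acq_protocol` object.
#' @export
sandi_protocol <- function() {
  b <- c(0.05, 0.35, 0.8, 1.5, 2.4, 3.45, 4.75, 6.0)
  dirs <- ifelse(b < 2.3, 32L, 64L)
  acq_protocol(b, dirs, delta_small = 8, delta_big = 19,
               b0_count = as.integer(ceiling(sum(dirs) / 16)))
}

#' @export
print.acq_protocol <- function(x, ...) {
  cat("<acq_protocol> ", length(x$shells), " shells, b = ",
      paste(format(x$shells * 1000), collapse = ", "), " s/mm^2\n",
      "  directions: ", paste(x$directions_per_shell, collapse = ", "),
      "; b0 volumes: ", x$b0_count, "\n",
      "  delta = ", x$delta_small, " ms, Delta = ", x$delta_big, " ms\n",
      sep = "")
  invisible(x)
}

#' Quasi-uniform unit directions on the sphere
#'
#' Deterministic Fibonacci-lattice direction set used wherever a gradient
#' scheme or a test sphere of directions is needed.
#'
#' @param n number of directions.
#' @return An `n` x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Group measured b-values into shells
#'
#' @param bvals numeric vector of per-volume b-values in ms/um^2.
#' @param tol grouping tolerance, default 0.05 ms/um^2 (50 s/mm^2),
#'   accommodating vendor rounding.
#' @return integer vector of shell indices (0 = b0 shell) and the shell
#'   centre table as attribute `"shells"`.
#' @keywords internal
group_shells <- function(bvals, tol = 0.05) {
  ord <- order(bvals)
  centres <- c()
  id <- integer(length(bvals))
  for (i in ord) {
    hit <- which(abs(centres - bvals[i]) < tol)
    if (length(hit) == 0) {
      centres <- c(centres, bvals[i])
      hit <- length(centres)
    }
    id[i] <- hit[1]
  }
  # recentre on shell means, label the b0 shell 0 and renumber the rest in
  # increasing-b order
  centres <- vapply(seq_along(centres), function(s) mean(bvals[id == s]),
                    numeric(1))
  is_b0 <- centres < tol
  remap <- integer(length(centres))
  remap[!is_b0] <- rank(centres[!is_b0])
  structure(remap[id], shells = sort(centres[!is_b0]))
}
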