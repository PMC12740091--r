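# shared small fixtures, built in code at test time

# reduced 8-shell protocol: paper shells/timings, few directions per shell
small_protocol <- function(dirs = 6, b0 = 2) {
  acq_protocol(c(0.05, 0.35, 0.8, 1.5, 2.4, 3.45, 4.75, 6.0), dirs,
               delta_small = 8, delta_big = 19, b0_count = b0)
}

# two-tissue phantom spec used by the super-resolution benchmarks
two_tissue_spec <- function(shape = c(16, 16, 16)) {
  phantom_spec(shape = shape, regions = subfield_params()[c(1, 6), ])
}

# gradient scheme rows (bvals, bvecs) with distinct directions per shell,
# enough to span the kurtosis basis
dki_scheme <- function(shells = c(0.8, 1.5, 2.4, 3.45), ndir = 20,
                       n_b0 = 2) {
  dirs <- fibonacci_directions(ndir)
  bvals <- c(rep(0, n_b0), rep(shells, each = ndir))
  bvecs <- rbind(matrix(0, n_b0, 3),
                 do.call(rbind, replicate(length(shells), dirs,
                                          simplify = FALSE)))
  list(bvals = bvals, bvecs = bvecs)
}

# independent brute-force Benjamini-Hochberg step-up: for each p_i,
# min over j with p_j >= p_i of n * p_j / rank_j, capped at 1
bh_brute_force <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(n), function(i) {
    tail_js <- which(p >= p[i])
    min(1, min(n * p[tail_js] / r[tail_js]))
  }, numeric(1))
}
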