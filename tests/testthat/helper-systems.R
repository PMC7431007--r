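## Bundled parameter sets used across test files
lpmo <- lpmo_spin_systems()

## random unit vectors in the positive octant (tensor symmetry)
random_orientations <- function(n, seed) {
  set.seed(seed)
  t(replicate(n, {
    v <- abs(stats::rnorm(3))
    v / sqrt(sum(v^2))
  }))
}
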