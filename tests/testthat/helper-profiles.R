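# Shared fixtures: seeded random smooth profiles and common objects.

random_profiles <- function(n = 5, phase = phase_constant(), seed0 = 100) {
  lapply(seq_len(n), function(i)
    fixture_profiles("random_smooth", seed = seed0 + i, phase = phase))
}

# cache expensive shared objects across test files
sys47 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- analytic_system(4.7)
    val
  }
})

kernel47 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- compute_kernels(4.7, n = 100)
    val
  }
})

rel_diff <- function(a, b) abs(a - b) / max(abs(a), abs(b))
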