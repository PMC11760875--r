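# Shared fixtures: small analytic configurations and reduced synthetic
# cohorts, all built in code.

deg <- pi / 180

mean_crescent <- function(taper = 0.75) {
  crescent_params(10.64867, 1.74493, 4.12101, taper)
}

# a small calibrated cohort for module tests (full default spec, n = 107)
small_cohort <- function(seed = 11L) {
  suppressWarnings(sample_population(default_calibration(seed = seed)))
}

# a simple Gaussian-noise population with one host and no asymmetry
plain_spec <- function(seed = 5L, n = 40L, mode1_sd = 0.05, mode2_sd = 0.02,
                       asymmetry_sd = 0, digitization_sd = 0.05,
                       size_cv = 0.1) {
  population_spec(mean_crescent(), mode1_sd = mode1_sd, mode2_sd = mode2_sd,
                  host_count = 1L, host_sizes = n, size_cv = size_cv,
                  asymmetry_sd = asymmetry_sd,
                  digitization_sd = digitization_sd, seed = seed,
                  n_vertices = 256L)
}

# right-angle configuration from the traditional-measurement example
right_angle_config <- function() {
  cfg <- rbind(L1 = c(0, 1.5), L2 = c(-1.2, 1.2), L3 = c(-1, 1),
               L4 = c(-0.4, 0.5), L5 = c(0, 0), L6 = c(0.4, 0.5),
               L7 = c(1, 1), L8 = c(1.2, 1.2))
  colnames(cfg) <- c("x", "y")
  cfg
}

rigid_motion <- function(config, angle = 0, shift = c(0, 0)) {
  Rm <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  sweep(config %*% Rm, 2L, -shift)
}

random_config <- function(k = 8L) {
  matrix(stats::rnorm(2L * k), k, 2L)
}

# all permutations of 1..n (used for exhaustive permutation oracles)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
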