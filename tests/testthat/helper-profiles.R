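# Shared fixtures, built in code.

# Default profile on a coarse time grid: strand lengths are exactly
# n-invariant (increments telescope to EF(tf)), so trait statistics match the
# fine grid while large ensembles stay cheap.
fast_profile <- function(n = 20L) {
  prof <- default_maize_profile()
  prof$params$n <- n
  prof
}

# Profile whose lateral densities are tiny, for structural checks (axis
# counts, origins) where lateral generation is irrelevant cost.
lean_profile <- function(n = 20L) {
  prof <- fast_profile(n)
  for (cls in c("primary", "seminal", "crown", "brace"))
    prof$dists[[cls]]$lateral_density_per_cm <-
      trait_dist("normal", mean = 0.02, sd = 0.001, lower = 1e-6)
  prof
}

table3_specs <- function(dists = default_maize_profile()$dists) {
  list(
    primLen = dists$primary$axis_length_norm,
    semLen = dists$seminal$axis_length_norm,
    croLen = dists$crown$axis_length_norm,
    braLen = dists$brace$axis_length_norm,
    primLatLen = dists$primary$lateral_length_norm,
    semLatLen = dists$seminal$lateral_length_norm,
    croLatLen = dists$crown$lateral_length_norm,
    braLatLen = dists$brace$lateral_length_norm,
    semBranch = dists$seminal$axis_count,
    croBranch = dists$crown$axis_count,
    braBranch = dists$brace$axis_count,
    primLatBranch = dists$primary$lateral_density_per_cm,
    semLatBranch = dists$seminal$lateral_density_per_cm,
    croLatBranch = dists$crown$lateral_density_per_cm,
    braLatBranch = dists$brace$lateral_density_per_cm
  )
}

raw_sd <- function(spec) {
  p <- spec$params
  switch(spec$family,
         gamma = sqrt(p$shape) * p$scale,
         normal = p$sd,
         binomial = sqrt(p$trials * p$prob * (1 - p$prob)))
}
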