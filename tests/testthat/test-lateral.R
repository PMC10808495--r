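test_that("branch points are counted from density x length and lie on the parent", {
  prof <- fast_profile()
  # near-degenerate density so m is predictable: 2 branches/cm on a 10 cm root
  prof$dists$primary$lateral_density_per_cm <-
    trait_dist("normal", mean = 2, sd = 1e-9, lower = 1e-6)
  ax <- build_axis("primary", prof, 0, rand_stream(1, "bp"), wd = 2)
  # rescale the axis to exactly 10 cm for arithmetic clarity
  L0 <- axis_length(ax$points)
  ax$points <- ax$points * (10 / L0)
  bs <- locate_branch_points(ax, prof, rand_stream(1, "bp_draws"))
  expect_identical(bs$m, 20L)
  expect_equal(bs$MedL, 2 * 10, tolerance = 1e-6)
  expect_length(bs$positions, 20)
  # every branch point lies within 1e-9 of the parent polyline
  d <- axis_direction(ax$A, ax$B)
  for (p in seq_len(bs$m)) {
    rel <- bs$points[p, ] - ax$origin
    expect_lt(abs(sqrt(sum(rel^2)) - bs$positions[p]), 1e-9)
    expect_lt(max(abs(rel - bs$positions[p] * d)), 1e-9)
  }
})

test_that("a zero-length parent yields no branch points", {
  prof <- fast_profile()
  ax <- build_axis("primary", prof, 0, rand_stream(2, "bp0"), wd = 2)
  ax$points <- ax$points[1, , drop = FALSE]
  bs <- locate_branch_points(ax, prof, rand_stream(2, "bp0_draws"))
  expect_identical(bs$m, 0L)
  expect_identical(nrow(bs$points), 0L)
})

test_that("MedL scales the bootstrap median of the density by parent length", {
  prof <- fast_profile()
  ax <- build_axis("primary", prof, 0, rand_stream(3, "medl"), wd = 2)
  L <- axis_length(ax$points)
  bs <- locate_branch_points(ax, prof, rand_stream(3, "medl_draws"))
  # bootstrap median of normal(6.65, 0.63) is within its sampling spread of 6.65
  expect_lt(abs(bs$MedL / L - 6.65), 3 * 1.2533 * 0.63 / sqrt(1000))
})

test_that("branch decisions occur with probability min(SBT/MaxL, 1)", {
  s <- rand_stream(4, "decide")
  expect_false(any(decide_branching(10, 0, s, n = 1000)))
  expect_true(all(decide_branching(10, 10, s, n = 1000)))
  n <- 1e5
  freq <- mean(decide_branching(10, 5, s, n = n))
  expect_lt(abs(freq - 0.5), 3 * sqrt(0.25 / n))
  freq2 <- mean(decide_branching(8, 2, s, n = n))
  expect_lt(abs(freq2 - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("lateral points sit at G_lat(t_q) * LLD from the branch point", {
  prof <- fast_profile(n = 50L)
  dt <- prof$params$tf / prof$params$n
  for (seed in 1:25) {
    lat <- grow_lateral(c(1, 2, -3), A = 300, B = 45, "crown", prof,
                        rand_stream(seed, "lat_geom"))
    q <- nrow(lat$points) - 1L
    expect_gte(q, 1L)
    expect_lte(q, prof$params$n)
    rel <- sweep(lat$points[-1, , drop = FALSE], 2, c(1, 2, -3))
    dist <- sqrt(rowSums(rel^2))
    expect_equal(dist,
                 growth_Glat(seq_len(q) * dt, prof$params$k_lat) * lat$LLD,
                 tolerance = 1e-9)
    # direction uses (A +/- R, B +/- R) with one sign for the whole lateral
    d <- axis_direction(300 + lat$sign * lat$R, 45 + lat$sign * lat$R)
    expect_lt(max(abs(rel / dist - matrix(d, q, 3, byrow = TRUE))), 1e-9)
    expect_true(lat$LRGT >= 0.4 && lat$LRGT <= 0.9)
  }
})

test_that("lateral growth duration is geometric in the growth threshold", {
  prof <- fast_profile(n = 200L)
  prof$params$lrgt_range <- c(0.4, 0.4)  # fixed continue probability 0.4
  extra <- vapply(1:4000, function(i) {
    nrow(grow_lateral(c(0, 0, 0), 200, 60, "primary", prof,
                      rand_stream(i, "lat_geo"))$points) - 2L
  }, integer(1))
  # expected extra points p/(1-p) = 2/3; sd of geometric = sqrt(p)/(1-p)
  se <- (sqrt(0.4) / 0.6) / sqrt(4000)
  expect_lt(abs(mean(extra) - 0.4 / 0.6), 3 * se)
})

test_that("attach_laterals respects the branch-count cap and the SL multiplier", {
  prof <- fast_profile()
  counts <- function(sl, n_par, tag) {
    vapply(seq_len(n_par), function(i) {
      ax <- build_axis("primary", prof, sl, rand_stream(i, c(tag, "ax")), wd = 2)
      ax <- attach_laterals(ax, prof, sl, rand_stream(i, c(tag, "lat")))
      expect_lte(length(ax$laterals), ax$branching$m)
      length(ax$laterals) / axis_length(ax$points)
    }, numeric(1))
  }
  n_par <- 300
  d0 <- counts(0, n_par, "wt")
  d5 <- counts(5, n_par, "sl5")
  ratio <- mean(d5) / mean(d0)
  # oracle for the realized-density ratio under the threshold rule:
  # E[min(0.73 MedL, B)] / E[min(MedL, B)] with B ~ N(6.65, 0.63) ~ 0.759
  oracle <- local({
    set.seed(31)
    b <- rnorm(2e5, 6.65, 0.63)
    mean(pmin(0.73 * 6.65, b)) / mean(pmin(6.65, b))
  })
  expect_lt(abs(ratio - oracle), 0.05)
  expect_lt(ratio, 1)  # branching is suppressed at 5 uM
})

test_that("an axis with no candidate points gets no laterals", {
  prof <- fast_profile()
  prof$dists$primary$lateral_density_per_cm <-
    trait_dist("normal", mean = 1e-4, sd = 1e-6, lower = 1e-9)
  ax <- build_axis("primary", prof, 0, rand_stream(5, "none"), wd = 2)
  ax <- attach_laterals(ax, prof, 0, rand_stream(5, "none_lat"))
  expect_identical(ax$branching$m, 0L)
  expect_length(ax$laterals, 0)
})
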