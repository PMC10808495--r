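test_that("identical (seed, path) replays identical draws; distinct paths differ", {
  a1 <- rand_stream(11, c("rsa_1", "crown_axis_3"))
  a2 <- rand_stream(11, c("rsa_1", "crown_axis_3"))
  b  <- rand_stream(11, c("rsa_1", "crown_axis_4"))
  x1 <- stream_eval(a1, runif(10))
  x2 <- stream_eval(a2, runif(10))
  y  <- stream_eval(b, runif(10))
  expect_identical(x1, x2)
  expect_false(any(x1 == y))
  # successive calls continue the sequence rather than restarting
  more <- stream_eval(a1, runif(5))
  expect_false(any(more %in% x1))
})

test_that("streams do not perturb each other or the global RNG", {
  set.seed(123)
  before <- .Random.seed
  s1 <- rand_stream(5, "unit_a")
  first <- stream_eval(s1, runif(3))
  # interleave another stream, then continue s1: unchanged continuation
  s2 <- rand_stream(5, "unit_b")
  stream_eval(s2, runif(100))
  cont <- stream_eval(s1, runif(3))
  s1_ref <- rand_stream(5, "unit_a")
  ref <- stream_eval(s1_ref, runif(6))
  expect_identical(c(first, cont), ref)
  expect_identical(.Random.seed, before)
})

test_that("raw draws recover every configured distribution mean", {
  specs <- table3_specs()
  stream <- rand_stream(2024, "mean_recovery")
  n <- 1e5
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    x <- sample_trait(spec, n, stream, raw = TRUE)
    se <- raw_sd(spec) / sqrt(n)
    expect_lt(abs(mean(x) - trait_mean(spec)), 3 * se,
              label = sprintf("|mean - expected| for %s", nm))
  }
})

test_that("axis-count sampling truncates, rounds, and rejects the primary class", {
  prof <- default_maize_profile()
  s <- rand_stream(3, "counts")
  sem <- sample_axis_count("seminal", prof$dists, s, n = 1e5)
  expect_true(all(sem >= 0 & sem <= 19))
  expect_lt(abs(mean(sem) - 19 * 0.16), 3 * raw_sd(prof$dists$seminal$axis_count) / sqrt(1e5))

  cro <- sample_axis_count("crown", prof$dists, s, n = 1e5)
  expect_true(all(cro == round(cro)))
  expect_lt(abs(mean(cro) - 91.89 * 0.41), 0.1)

  bra <- sample_axis_count("brace", prof$dists, s, n = 1e5)
  expect_true(all(bra >= 0))
  expect_true(all(bra == round(bra)))

  expect_error(sample_axis_count("primary", prof$dists, s), "fixed at 1")
})

test_that("normalized length and density draws are positive with correct means", {
  prof <- default_maize_profile()
  s <- rand_stream(4, "lengths")
  cro <- sample_normalized_length("crown", "axis", prof$dists, s, n = 1e5)
  expect_true(all(cro > 0))
  expect_lt(abs(mean(cro) - 0.98), 3 * 0.11 / sqrt(1e5))

  prim <- sample_normalized_length("primary", "axis", prof$dists, s, n = 1e5)
  expect_lt(abs(mean(prim) - 5 * 0.22), 3 * raw_sd(prof$dists$primary$axis_length_norm) / sqrt(1e5))

  d_prim <- sample_lateral_density("primary", prof$dists, s, n = 1e5)
  expect_true(all(d_prim > 0))
  expect_lt(abs(mean(d_prim) - 6.65), 3 * 0.63 / sqrt(1e5))
  d_sem <- sample_lateral_density("seminal", prof$dists, s, n = 1e5)
  expect_lt(abs(mean(d_sem) - 5.05), 3 * 0.66 / sqrt(1e5))
})

test_that("bootstrap_median matches degenerate and large-sample behaviour", {
  s <- rand_stream(5, "boot")
  const <- trait_dist("normal", mean = 7, sd = 1e-12)
  expect_equal(bootstrap_median(const, 1000, s), 7, tolerance = 1e-9)

  spec <- trait_dist("normal", mean = 18.83, sd = 9.12)
  med <- bootstrap_median(spec, 1000, s)
  # sampling sd of the median of 1000 normals ~ 1.2533 * sd / sqrt(n) ~ 0.36
  expect_lt(abs(med - 18.83), 3 * 1.2533 * 9.12 / sqrt(1000))

  one <- rand_stream(5, "boot_single")
  single <- bootstrap_median(spec, 1, one)
  ref <- sample_trait(spec, 1, rand_stream(5, "boot_single"))
  expect_identical(single, ref)
})

test_that("angle and threshold draws respect their supports and uniform means", {
  s <- rand_stream(6, "angles")
  ab <- t(replicate(2000, sample_axial_angles(s)))
  expect_true(all(ab[, "A"] >= 180 & ab[, "A"] <= 360))
  expect_true(all(ab[, "B"] >= 0 & ab[, "B"] <= 180))
  expect_lt(abs(mean(ab[, "A"]) - 270), 3 * (180 / sqrt(12)) / sqrt(2000))
  expect_lt(abs(mean(ab[, "B"]) - 90), 3 * (180 / sqrt(12)) / sqrt(2000))

  r <- sample_radial_angle(s, n = 1e4)
  expect_true(all(r >= 0 & r <= 180))
  g <- sample_lrgt(s, n = 1e4)
  expect_true(all(g >= 0.4 & g <= 0.9))
  expect_lt(abs(mean(g) - 0.65), 3 * (0.5 / sqrt(12)) / sqrt(1e4))

  fixed1 <- sample_axial_angles(rand_stream(9, "fix"))
  fixed2 <- sample_axial_angles(rand_stream(9, "fix"))
  expect_identical(fixed1, fixed2)
})
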