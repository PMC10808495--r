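test_that("axial direction vectors are unit norm with downward z", {
  s <- rand_stream(1, "dirs")
  for (i in 1:200) {
    ab <- sample_axial_angles(s)
    d <- axis_direction(ab["A"], ab["B"])
    expect_lt(abs(sqrt(sum(d^2)) - 1), 1e-12)
    expect_lte(d[3], 0)
  }
  expect_equal(axis_direction(270, 90), c(0, 0, -1), tolerance = 1e-12)
  expect_equal(axis_direction(180, 0), c(-1, 0, 0), tolerance = 1e-12)
})

test_that("origins follow the whorl placement rules", {
  s <- rand_stream(2, "origins")
  expect_identical(place_origin("primary", 2, s), c(0, 0, 0))
  bz <- replicate(300, place_origin("brace", 2, s)[3])
  expect_true(all(bz %in% c(2, 4)))
  expect_setequal(unique(bz), c(2, 4))
  cz <- replicate(600, place_origin("crown", 2, s)[3])
  expect_true(all(cz %in% c(0, -2, -4, -6, -8, -10)))
  expect_setequal(unique(cz), c(0, -2, -4, -6, -8, -10))
  sz <- replicate(300, place_origin("seminal", 2, s)[3])
  expect_true(all(sz >= -2 & sz <= 0))
  expect_error(place_origin("brace", 0, s), "wd")
})

test_that("extend_axis walks straight with segment lengths equal to increments", {
  p1 <- extend_axis(c(0, 0, 0), 270, 90, 1)
  expect_equal(p1[2, ], c(x = 0, y = 0, z = -1), tolerance = 1e-12)
  p2 <- extend_axis(c(1, 1, 1), 180, 0, 1)
  expect_equal(p2[2, ], c(x = 0, y = 1, z = 1), tolerance = 1e-12)

  s <- rand_stream(3, "ext")
  for (i in 1:50) {
    ab <- sample_axial_angles(s)
    inc <- stream_eval(s, sort(runif(20), decreasing = TRUE))
    pts <- extend_axis(c(0, 0, 0), ab["A"], ab["B"], inc)
    expect_identical(nrow(pts), 21L)
    seg <- sqrt(rowSums(diff(pts)^2))
    expect_lt(max(abs(seg - inc)), 1e-12)
  }
  expect_error(extend_axis(c(0, 0, 0), 200, 90, numeric(0)), "non-empty")
})

test_that("built axes satisfy their geometric invariants", {
  prof <- fast_profile()
  for (seed in 1:30) {
    cls <- c("primary", "seminal", "crown", "brace")[(seed %% 4) + 1]
    ax <- build_axis(cls, prof, sl = 0, rand_stream(seed, "axinv"), wd = 2)
    k <- switch(cls, primary = prof$params$k_prim, seminal = prof$params$k_sem,
                crown = prof$params$k_cro, brace = prof$params$k_bra)
    ef <- elongation_EF(prof$params$tf, k, prof$params$r, ax$LD,
                        ax$sl_length_mult)
    expect_equal(axis_length(ax$points), ef, tolerance = 1e-9)
    expect_true(all(diff(ax$points[, "z"]) <= 0))
    expect_identical(nrow(ax$points), prof$params$n + 1L)
  }
})

test_that("SL concentration scales axis length by the class length curve", {
  prof <- fast_profile()
  g_tf <- growth_G(prof$params$tf, prof$params$k_prim, prof$params$r)
  wt <- build_axis("primary", prof, sl = 0, rand_stream(7, "sl_ax"), wd = 2)
  expect_equal(axis_length(wt$points), g_tf * wt$LD, tolerance = 1e-9)
  hi <- build_axis("primary", prof, sl = 10, rand_stream(7, "sl_ax"), wd = 2)
  expect_identical(hi$LD, wt$LD)  # same stream, same draws
  expect_equal(axis_length(hi$points), g_tf * hi$LD * 0.63, tolerance = 1e-9)
  # linearity: doubling the SL multiplier doubles every increment
  expect_equal(diff(hi$points[, "x"]) * (1 / 0.63),
               diff(wt$points[, "x"]), tolerance = 1e-9)
})

test_that("axis construction is reproducible from its stream", {
  prof <- fast_profile()
  a <- build_axis("crown", prof, 2.5, rand_stream(42, c("r", "c1")), wd = 1.8)
  b <- build_axis("crown", prof, 2.5, rand_stream(42, c("r", "c1")), wd = 1.8)
  expect_identical(a, b)
})

test_that("large axis ensembles recover the configured mean lengths within 1%", {
  prof <- fast_profile()
  g_tf <- growth_G(prof$params$tf, prof$params$k_prim, prof$params$r)
  n_ax <- 20000
  stream <- rand_stream(2026, "recovery_primary")
  norm_len <- vapply(seq_len(n_ax), function(i) {
    ax <- build_axis("primary", prof, 0, stream, wd = 2)
    axis_length(ax$points) / g_tf
  }, numeric(1))
  expect_lt(abs(mean(norm_len) - 1.1) / 1.1, 0.01)
})
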