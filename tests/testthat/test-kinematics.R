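test_that("a segment at rest with zero spin carries no angular momentum", {
  seg <- static_segment(50, at = c(0, 0.3, 1.1))
  body <- list(pos = matrix(0, 50, 3), vel = matrix(0, 50, 3))
  L <- segment_angular_momentum(seg, mass = 2, inertia = 0.1,
                                body_pos = body$pos, body_vel = body$vel)
  expect_equal(L, matrix(0, 50, 3))
})

test_that("a point mass on a circle about a static CoM gives m r^2 w", {
  n <- 120
  for (case in list(c(r = 1, w = 2), c(r = 0.5, w = 2), c(r = 0.3, w = -4))) {
    seg <- circle_segment(n, radius = case[["r"]], omega_rate = case[["w"]])
    L <- segment_angular_momentum(seg, mass = 1, inertia = 0,
                                  body_pos = matrix(0, n, 3),
                                  body_vel = matrix(0, n, 3))
    expect_equal(L[, 1], rep(case[["r"]]^2 * case[["w"]], n), tolerance = 1e-12)
    expect_equal(L[, 2], rep(0, n), tolerance = 1e-12)
  }
})

test_that("with CoM coincident with the body CoM only the spin term remains", {
  n <- 30
  seg <- static_segment(n, at = c(0, 0, 0))
  seg$omega <- matrix(rep(c(3, 0, 0), each = n), n, 3)
  L <- segment_angular_momentum(seg, mass = 1, inertia = 0.1,
                                body_pos = matrix(0, n, 3),
                                body_vel = matrix(0, n, 3))
  expect_equal(L[, 1], rep(0.3, n))
  expect_equal(L[, 2:3], matrix(0, n, 2))
})

test_that("mismatched series lengths are an alignment error", {
  seg <- static_segment(50)
  expect_error(
    segment_angular_momentum(seg, 1, 0, matrix(0, 40, 3), matrix(0, 40, 3)),
    class = "wbam_alignment_error")
})

test_that("an all-static trial has zero WBAM", {
  trial <- make_trial(masses = rep(1, 12))
  expect_equal(whole_body_angular_momentum(trial), rep(0, 240))
})

test_that("two point masses in antiphase circular motion match the two-body closed form", {
  n <- 240
  r <- 0.4; w <- 3
  trial <- make_trial(overrides = list(
    p_thigh = circle_segment(n, r, w, centre = c(0, 0, 1), phase = 0),
    n_thigh = circle_segment(n, r, w, centre = c(0, 0, 1), phase = pi)
  ))
  # equal masses in antiphase: common CoM static, each contributes m r^2 w
  lx <- whole_body_angular_momentum(trial)
  expect_equal(lx, rep(2 * r^2 * w, n), tolerance = 1e-9)
})

test_that("WBAM about the CoM is invariant under a Galilean boost", {
  cfg <- gait_config(seed = 7, n_cycles = 2)
  trial <- generate_synthetic_gait(cfg)
  lx <- whole_body_angular_momentum(trial)
  boost <- c(0.5, 0, 0)
  t <- attr(trial, "times")
  boosted <- trial
  boosted$segments <- lapply(trial$segments, function(s) {
    s$pos <- s$pos + outer(t, rep(1, 3)) * rep(boost, each = length(t))
    s$vel <- sweep(s$vel, 2, boost, `+`)
    s
  })
  lx2 <- whole_body_angular_momentum(boosted)
  expect_lt(max(abs(lx2 - lx)) / max(abs(lx)), 1e-10)
})

test_that("WBAM is additive over disjoint segment sets about a common CoM", {
  n <- 120
  s1 <- circle_segment(n, 0.3, 2, centre = c(0, 0.5, 1))
  s2 <- circle_segment(n, 0.2, -5, centre = c(0, -0.5, 1))
  com <- list(pos = matrix(0, n, 3), vel = matrix(0, n, 3))
  both <- segment_angular_momentum(s1, 2, 0, com$pos, com$vel) +
    segment_angular_momentum(s2, 1.5, 0, com$pos, com$vel)
  expect_equal(both,
               segment_angular_momentum(s1, 2, 0, com$pos, com$vel) +
               segment_angular_momentum(s2, 1.5, 0, com$pos, com$vel))
  # and the whole-body sum over a trial equals the sum of per-segment terms
  masses <- rep(1e-12, 12)
  masses[segment_names() == "p_shank"] <- 2
  masses[segment_names() == "n_shank"] <- 1.5
  trial <- make_trial(overrides = list(p_shank = s1, n_shank = s2),
                      masses = masses, n = n)
  bc <- body_com(trial)
  manual <- matrix(0, n, 3)
  for (s in segment_names()) {
    m <- trial$inertial$mass[trial$inertial$segment == s]
    manual <- manual + segment_angular_momentum(trial$segments[[s]], m, 0,
                                                bc$pos, bc$vel)
  }
  expect_equal(whole_body_angular_momentum(trial), manual[, 1], tolerance = 1e-12)
})

test_that("the sign convention mirrors for right-paretic subjects", {
  n <- 120
  seg <- circle_segment(n, 0.4, 2)
  left <- make_trial(overrides = list(trunk = seg), n = n)
  right <- make_trial(overrides = list(trunk = seg), paretic_side = "right", n = n)
  expect_equal(whole_body_angular_momentum(right),
               -whole_body_angular_momentum(left))
})

test_that("a missing segment is a model-incomplete error", {
  segs <- lapply(1:11, function(k) static_segment(10))
  names(segs) <- segment_names()[1:11]
  expect_error(gait_trial(segs, 70, 1.7, 1, "left"),
               class = "wbam_model_incomplete")
})

test_that("time normalization maps a cycle onto an exact 101-point grid", {
  # already-uniform 101 samples pass through unchanged
  x <- sin(seq(0, 2 * pi, length.out = 101))
  expect_equal(as.numeric(time_normalize_cycle(x, 1, 101)), x)
  # a linear ramp hits 0.5 at 50% of the cycle
  ramp <- seq(0, 1, length.out = 201)
  y <- time_normalize_cycle(ramp, 1, 201)
  expect_equal(y[51], 0.5)
  expect_equal(y[1], 0)
  expect_equal(y[101], 1)
  # quadratic sampled densely: interpolation error below 1e-4
  tq <- seq(0, 1, length.out = 1000)
  yq <- time_normalize_cycle(tq^2, 1, 1000)
  expect_lt(max(abs(yq - seq(0, 1, length.out = 101)^2)), 1e-4)
  expect_error(time_normalize_cycle(1:10, 5, 6), class = "wbam_length_error")
})

test_that("dimensionless normalization divides by mass x height x speed", {
  x <- sin(seq(0, 2 * pi, length.out = 101))
  expect_equal(normalize_wbam(x, 1, 1, 1), x)
  expect_equal(normalize_wbam(x, 2, 1, 1), x / 2)
  expect_equal(normalize_wbam(0.06, 68.7, 1.69, 1.0), 0.06 / (68.7 * 1.69))
  expect_equal(normalize_wbam(0.06, 68.7, 1.69, 1.0), 5.168e-4, tolerance = 1e-4)
  expect_error(normalize_wbam(x, -1, 1, 1), class = "wbam_domain_error")
})

test_that("the WBAM range is max minus min, non-negative, shift-invariant", {
  expect_equal(wbam_range(rep(0.2, 101)), 0)
  a <- 0.013
  s <- a * sin(seq(0, 2 * pi, length.out = 101))
  expect_equal(wbam_range(s), 2 * a, tolerance = 1e-12)
  expect_equal(wbam_range(c(-0.01, 0.02, 0.005)), 0.03)
  expect_equal(wbam_range(s + 5), wbam_range(s), tolerance = 1e-12)
  expect_error(wbam_range(0.5), class = "wbam_length_error")
})
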