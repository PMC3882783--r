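test_that("twist angle is zero without rotation and exact under rigid rotation", {
  none <- synthetic_points(function(X, k) X)
  expect_equal(twist_angle(none, c(16, 16)), c(0, 0, 0))
  th <- 5 * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- synthetic_points(function(X, k)
    if (k < 3) X else t(Rm %*% t(X - 16)) + 16)
  expect_equal(twist_angle(rot, c(16, 16)), c(0, 0, 5), tolerance = 1e-10)
  few <- synthetic_points(function(X, k) X)
  few$reference <- few$reference[1:5, ]
  few$traj <- few$traj[1:5, , , drop = FALSE]
  few$valid <- few$valid[1:5, , drop = FALSE]
  expect_error(twist_angle(few, c(16, 16)), "too few")
})

test_that("phantom apical twist recovers the configured peak", {
  fx <- lowfat_fixture()
  expect_lt(abs(max(fx$analysis$twist$apical) - 8.8), 0.1)
  expect_lt(max(abs(fx$analysis$twist$basal)), 0.1)
})

test_that("torsion is the normalised twist difference with unit conversion", {
  tr <- torsion(rep(0, 3), c(0, 4, 8.8), 1.0)
  expect_equal(tr$peak_torsion, 8.8)
  expect_equal(tr$peak_torsion_deg_per_mm, 0.88)
  expect_equal(torsion(c(0, 2, 5), c(0, 2, 5), 1.0)$torsion_curve, rep(0, 3))
  expect_error(torsion(0:2, 0:2, 0), "positive")
  expect_error(torsion(0:2, 0:3, 1), "equal length")
  # invariant under a constant rotation added to both slices
  expect_equal(torsion(c(0, 1, 2) + 3, c(0, 4, 8.8) + 3, 1.0)$peak_torsion,
               torsion(c(0, 1, 2), c(0, 4, 8.8), 1.0)$peak_torsion)
  # scales as 1/L
  expect_equal(torsion(rep(0, 3), c(0, 4, 8.8), 2.0)$peak_torsion, 4.4)
})

test_that("uniformity index satisfies its limiting cases", {
  N <- 24; Tn <- 10
  uniform <- matrix(rep(-seq(0, 17, length.out = Tn), each = N), N, Tn)
  expect_equal(uniformity_index(uniform)$index, 1)
  # pure first harmonic: zero index, checked against a brute-force
  # summation oracle for the harmonic powers
  j <- seq_len(N) - 1
  prof <- matrix(rep(cos(2 * pi * j / N), Tn), N, Tn)
  res <- uniformity_index(prof)
  expect_equal(res$index, 0, tolerance = 1e-12)
  brute_c <- function(v, k) sum(v * exp(-2i * pi * k * j / N)) / N
  for (t in c(1, 4)) {
    expect_equal(res$P0[t], Mod(brute_c(prof[, t], 0))^2, tolerance = 1e-12)
    expect_equal(res$P1[t],
                 Mod(brute_c(prof[, t], 1))^2 + Mod(brute_c(prof[, t], N - 1))^2,
                 tolerance = 1e-12)
  }
  expect_error(uniformity_index(matrix(0, N, Tn)), "undefined")
  expect_error(uniformity_index(matrix(1, 4, 5)), "8 sectors")
  expect_error(uniformity_index(matrix(1, 24, 1)), "2 frames")
})

test_that("index decreases monotonically as a first-harmonic perturbation grows", {
  N <- 24; Tn <- 8
  j <- seq_len(N) - 1
  base <- matrix(rep(-10 * sin(pi * seq_len(Tn) / Tn), each = N), N, Tn)
  idx <- vapply(c(0, 0.5, 1, 2, 4), function(a)
    uniformity_index(base + a * cos(2 * pi * j / N))$index, numeric(1))
  expect_true(all(diff(idx) < 0))
})

test_that("analytic RURE is 1 at zero delay and strictly decreasing in delay", {
  cfg <- lowfat_config()
  rure_of <- function(amp) {
    cfg$delay_amplitude_ms <- amp
    mean(vapply(c("basal", "mid", "apical"), function(sl)
      uniformity_index(analytic_sector_curves(cfg, sl, "radial"))$index,
      numeric(1)))
  }
  vals <- vapply(c(0, 5, 10, 15, 20, 25, 30), rure_of, numeric(1))
  expect_equal(vals[1], 1)
  expect_true(all(diff(vals) < 0))
})

test_that("the dyssynchronous config is calibrated against a synchronous control", {
  cfg <- highfat_config()
  rure_hf <- mean(vapply(c("basal", "mid", "apical"), function(sl)
    uniformity_index(analytic_sector_curves(cfg, sl, "radial"))$index,
    numeric(1)))
  expect_lt(abs(rure_hf - 0.91), 0.005)
  ctrl <- cfg
  ctrl$delay_amplitude_ms <- 0
  rure_ctrl <- mean(vapply(c("basal", "mid", "apical"), function(sl)
    uniformity_index(analytic_sector_curves(ctrl, sl, "radial"))$index,
    numeric(1)))
  expect_gte(rure_ctrl, 0.95)
})
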