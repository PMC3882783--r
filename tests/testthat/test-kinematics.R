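test_that("tracking reproduces zero and rigid translation exactly", {
  f0 <- compute_displacement_field(translation_slice(0, 0))
  p0 <- track_points(f0)
  for (k in 1:4)
    expect_equal(p0$traj[, , k], p0$reference, tolerance = 1e-9)

  ft <- compute_displacement_field(translation_slice(0.3, 0))
  pt <- track_points(ft)
  off <- pt$traj[, , 4] - pt$reference
  expect_equal(unname(colMeans(off)), c(0.3, 0), tolerance = 1e-9)
  expect_lt(max(abs(off[, 1] - 0.3)), 1e-9)
  expect_true(all(pt$valid))
})

test_that("tracking follows the analytic material map on a rotation-only phantom", {
  cfg <- phantom_config(circ_stretch_endo = 1, circ_stretch_epi = 1,
                        long_stretch = 1, twist_base_peak = 4,
                        twist_apex_peak = 12)
  rs <- render_study(cfg)
  sl <- rs$study$slices$apical
  f <- compute_displacement_field(sl)
  pts <- track_points(f)
  for (k in c(5, 8, 12)) {
    truth <- material_map(cfg, pts$reference, "apical", sl$meta$frame_times[k])
    expect_lt(max(sqrt(rowSums((pts$traj[, , k] - truth)^2))), 0.05)
  }
})

test_that("deformation-gradient fit is exact for affine motions", {
  scale <- synthetic_points(function(X, k)
    if (k == 1) X else 1.1 * (X - 16) + 16)
  F <- fit_deformation_gradient(scale, index = 10, frame = 2)
  expect_equal(F, 1.1 * diag(2), tolerance = 1e-10)

  th <- 30 * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- synthetic_points(function(X, k)
    if (k == 1) X else t(Rm %*% t(X - 16)) + 16)
  Fr <- fit_deformation_gradient(rot, index = 25, frame = 2)
  expect_equal(Fr, Rm, tolerance = 1e-10)
  expect_equal(t(Fr) %*% Fr, diag(2), tolerance = 1e-10)
  # Frobenius agreement with the exact gradient
  expect_lt(sqrt(sum((Fr - Rm)^2)), 1e-3)
})

test_that("deformation-gradient fit matches the analytic phantom gradient", {
  fx <- lowfat_fixture()
  cfg <- fx$cfg
  pts <- fx$analysis$points$mid
  geo <- cinedense:::phantom_geometry(cfg)
  z <- geo$slice_z[["mid"]]
  re <- cinedense:::endo_radius_at(geo, z)
  rp <- cinedense:::epi_radius_at(geo, z)
  R <- sqrt(rowSums((pts$reference -
                       matrix(geo$center, nrow(pts$reference), 2,
                              byrow = TRUE))^2))
  d <- (R - re) / (rp - re)
  interior <- which(d > 0.25 & d < 0.75)
  k <- 8; t <- pts$meta$frame_times[k]
  eps <- 1e-5
  errs <- vapply(interior, function(i) {
    X <- pts$reference[i, ]
    Fa <- cbind(
      t(material_map(cfg, rbind(X + c(eps, 0)), "mid", t) -
          material_map(cfg, rbind(X - c(eps, 0)), "mid", t)) / (2 * eps),
      t(material_map(cfg, rbind(X + c(0, eps)), "mid", t) -
          material_map(cfg, rbind(X - c(0, eps)), "mid", t)) / (2 * eps))
    Fm <- fit_deformation_gradient(pts, i, k)
    sqrt(sum((Fm - Fa)^2))
  }, numeric(1))
  expect_lt(stats::median(errs), 1e-3)
  expect_lt(max(errs), 2.5e-3)
})

test_that("rigid-body motion yields zero strain everywhere", {
  th <- 17 * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rigid <- synthetic_points(function(X, k) {
    if (k == 1) return(X)
    t(Rm %*% t(X - 16)) + 16 + matrix(c(0.4, -0.2), nrow(X), 2, byrow = TRUE)
  })
  cen <- c(16, 16)
  cs <- contour_set(circle_contour(1.2), circle_contour(2.4))
  ss <- strain_samples(rigid, cs, "mid")
  s2 <- ss[ss$frame == 2, ]
  expect_lt(max(abs(s2$ecc), na.rm = TRUE), 0.1)
  expect_lt(max(abs(s2$err), na.rm = TRUE), 0.1)
})

test_that("strain is zero at the end-diastolic reference frame", {
  fx <- lowfat_fixture()
  s1 <- fx$analysis$samples$mid
  s1 <- s1[s1$frame == 1, ]
  expect_lt(max(abs(s1$ecc), na.rm = TRUE), 1e-8)
  expect_lt(max(abs(s1$err), na.rm = TRUE), 1e-8)
})

test_that("strain projection converts tensors to engineering percent", {
  expect_equal(unname(project_strain(matrix(0, 2, 2), c(1, 0), c(0, 0))),
               c(0, 0))
  F <- 1.1 * diag(2)
  pr <- project_strain(green_lagrange(F), c(2, 1), c(0, 0))
  expect_equal(unname(pr), c(10, 10), tolerance = 1e-10)
  expect_error(project_strain(matrix(0, 2, 2), c(1, 1), c(1, 1)), "centroid")
})

test_that("layer and segment assignment follows the 16-segment convention", {
  cs <- contour_set(circle_contour(1.2), circle_contour(2.4))
  # point on the endocardial contour: depth 0, layer endo
  on_endo <- assign_layers_segments(rbind(c(16 + 1.2, 16)), cs, "mid")
  expect_equal(on_endo$depth, 0, tolerance = 1e-9)
  expect_equal(as.character(on_endo$layer), "endo")
  # midpoint of the centroid ray: depth 0.5, layer mid
  half <- assign_layers_segments(rbind(c(16 + 1.8, 16)), cs, "basal")
  expect_equal(half$depth, 0.5, tolerance = 1e-9)
  expect_equal(as.character(half$layer), "mid")
  # segment counts and id ranges per slice
  th <- seq(0, 2 * pi, length.out = 100)[-100]
  ring <- cbind(16 + 1.8 * cos(th), 16 + 1.8 * sin(th))
  expect_setequal(unique(assign_layers_segments(ring, cs, "basal")$segment_id),
                  1:6)
  expect_setequal(unique(assign_layers_segments(ring, cs, "mid")$segment_id),
                  7:12)
  expect_setequal(unique(assign_layers_segments(ring, cs, "apical")$segment_id),
                  13:16)
  # a point outside the annulus is flagged
  out <- assign_layers_segments(rbind(c(16 + 3.5, 16)), cs, "mid")
  expect_false(out$in_wall)
})

test_that("peak strain takes the signed extremum by direction", {
  expect_equal(peak_strain(c(0, -5, -17, -10), "circumferential"), -17)
  expect_equal(peak_strain(c(0, 10, 36, 20), "radial"), 36)
  expect_equal(peak_strain(c(0, 0, 0), "longitudinal"), 0)
  expect_error(peak_strain(numeric(0), "radial"), "empty")
})
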