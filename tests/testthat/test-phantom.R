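test_that("slice planning follows the 50%/20% rule", {
  expect_equal(plan_slices(8), c(basal = 5.6, mid = 4.0, apical = 2.4))
  expect_equal(plan_slices(10), c(basal = 7.0, mid = 5.0, apical = 3.0))
  expect_error(plan_slices(0), "positive")
})

test_that("activation envelope is a raised cosine with the prescribed peak", {
  period <- 131.3; ts <- 49.7
  expect_equal(activation(10, delay = 10, period, ts), 0)
  expect_equal(activation(10 + ts, delay = 10, period, ts), 1)
  expect_equal(activation(0, 0, period, ts), 0)
  # two sectors with delays 0 and 10 ms peak exactly 10 ms apart
  tt <- seq(0, period, by = 0.01)
  p0 <- tt[which.max(activation(tt, 0, period, ts))]
  p10 <- tt[which.max(activation(tt, 10, period, ts))]
  expect_equal(p10 - p0, 10, tolerance = 0.02)
  # continuity across the onset and the peak
  a <- activation(seq(9.9, 10.1, by = 0.001), 10, period, ts)
  expect_lt(max(abs(diff(a))), 1e-3)
})

test_that("material map reduces to identity and closed-form cases", {
  cfg0 <- phantom_config(circ_stretch_endo = 1, circ_stretch_epi = 1,
                         long_stretch = 1, twist_base_peak = 0,
                         twist_apex_peak = 0)
  geo <- cinedense:::phantom_geometry(cfg0)
  z <- geo$slice_z[["mid"]]
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  R <- (cinedense:::endo_radius_at(geo, z) + cinedense:::epi_radius_at(geo, z)) / 2
  X <- cbind(geo$center[1] + R * cos(th), geo$center[2] + R * sin(th))
  for (t in c(0, 30, 60))
    expect_equal(material_map(cfg0, X, "mid", t), X, tolerance = 1e-12)

  # uniform circumferential stretch 0.9: endocardial point lands at 0.9 R
  cfg9 <- phantom_config(circ_stretch_endo = 0.9, circ_stretch_epi = 0.9,
                         long_stretch = 1, twist_apex_peak = 0)
  geo9 <- cinedense:::phantom_geometry(cfg9)
  re <- cinedense:::endo_radius_at(geo9, geo9$slice_z[["mid"]])
  Xe <- cbind(geo9$center[1] + re, geo9$center[2])
  t_peak <- cfg9$systole_ms   # zero delay: peak activation
  y <- material_map(cfg9, Xe, "mid", t_peak)
  expect_equal(sqrt(sum((y - geo9$center)^2)), 0.9 * re, tolerance = 1e-10)

  # twist-only: apical-slice point rotated by twist_apex_peak about centre
  cfgt <- phantom_config(circ_stretch_endo = 1, circ_stretch_epi = 1,
                         long_stretch = 1, twist_base_peak = 0,
                         twist_apex_peak = 8.8)
  geot <- cinedense:::phantom_geometry(cfgt)
  za <- geot$slice_z[["apical"]]
  Ra <- (cinedense:::endo_radius_at(geot, za) +
           cinedense:::epi_radius_at(geot, za)) / 2
  Xa <- cbind(geot$center[1] + Ra, geot$center[2])
  ya <- material_map(cfgt, Xa, "apical", cfgt$systole_ms)
  ang <- atan2(ya[2] - geot$center[2], ya[1] - geot$center[1])
  expect_equal(ang * 180 / pi, 8.8, tolerance = 1e-8)

  # outside the annulus is a domain error
  expect_error(material_map(cfg0, cbind(geo$center[1], geo$center[2]),
                            "mid", 0),
               "outside")
})

test_that("frame count follows floor(60000 / HR / TR) and stays in range", {
  cfg <- phantom_config(heart_rate = 457, tr = 7.1)
  expect_equal(cfg$n_frames, 18)
  expect_gte(cfg$n_frames, 15)
  expect_lte(cfg$n_frames, 20)
  expect_error(render_study(phantom_config(heart_rate = 20000)),
               "frame count")
})

test_that("zero-deformation, zero-noise rendering gives exactly zero phase", {
  cfg <- phantom_config(circ_stretch_endo = 1, circ_stretch_epi = 1,
                        long_stretch = 1, twist_base_peak = 0,
                        twist_apex_peak = 0, phase_noise_sd = 0,
                        field_of_view = 16, matrix_size = 64,
                        heart_rate = 1200)
  rs <- render_study(cfg)
  for (sl in rs$study$slices) {
    expect_identical(max(abs(sl$phase_x)), 0)
    expect_identical(max(abs(sl$phase_y)), 0)
  }
})

test_that("rendering is deterministic given config and seed", {
  cfg <- small_config(phase_noise_sd = 0.05, random_seed = 7L)
  a <- render_study(cfg)
  b <- render_study(cfg)
  expect_identical(a$study$slices$mid$phase_x, b$study$slices$mid$phase_x)
  expect_identical(a$study$slices$four_chamber$phase_y,
                   b$study$slices$four_chamber$phase_y)
})

test_that("analytic ground-truth strains match a finite-difference oracle", {
  cfg <- lowfat_config()
  geo <- cinedense:::phantom_geometry(cfg)
  t_peak <- cfg$systole_ms
  for (sl in c("basal", "mid", "apical")) {
    z <- geo$slice_z[[sl]]
    re <- cinedense:::endo_radius_at(geo, z)
    rp <- cinedense:::epi_radius_at(geo, z)
    for (d in c(1 / 6, 0.5, 5 / 6)) {
      R <- re + d * (rp - re)
      for (th in c(0.3, 2.1, 4.4)) {
        X <- geo$center + R * c(cos(th), sin(th))
        eps <- 1e-5
        Fm <- cbind(
          t(material_map(cfg, rbind(X + c(eps, 0)), sl, t_peak) -
              material_map(cfg, rbind(X - c(eps, 0)), sl, t_peak)) / (2 * eps),
          t(material_map(cfg, rbind(X + c(0, eps)), sl, t_peak) -
              material_map(cfg, rbind(X - c(0, eps)), sl, t_peak)) / (2 * eps))
        pr <- project_strain(green_lagrange(Fm), X, geo$center)
        truth <- cinedense:::analytic_peak_strains(cfg, geo, z, d)
        expect_lt(abs(pr[["ecc"]] - truth$ecc), 0.1)
        expect_lt(abs(pr[["err"]] - truth$err), 0.1)
      }
    }
  }
})

test_that("ground truth mirrors the configured generative parameters", {
  fx <- lowfat_fixture()
  truth <- fx$truth
  expect_equal(truth$strain$ecc[truth$strain$layer == "endo"], -17)
  expect_equal(truth$strain$ecc[truth$strain$layer == "epi"], -9.4)
  expect_equal(truth$peak_torsion, 8.8)
  expect_equal(truth$ef, 100 * (truth$edv - truth$esv) / truth$edv)
  expect_equal(truth$cure, 1)
  expect_equal(truth$rure, 1)
  # radial truth positive under the transmural stretch gradient
  expect_true(all(truth$strain$err > 0))
})

test_that("torsion ground truth is invariant to a constant rotation of both slices", {
  cfg1 <- phantom_config(twist_base_peak = 0, twist_apex_peak = 8.8)
  cfg2 <- phantom_config(twist_base_peak = 5, twist_apex_peak = 13.8)
  expect_equal(ground_truth(cfg1)$peak_torsion, ground_truth(cfg2)$peak_torsion)
})
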