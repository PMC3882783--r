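test_that("acquisition metadata enforces its invariants", {
  m <- acquisition_meta(ke = 0.9, field_of_view = 32, matrix_size = 128,
                        tr = 7.1, frame_times = seq(0, by = 7.1, length.out = 18))
  expect_equal(m$pixel_spacing, 0.25)
  expect_error(acquisition_meta(0, 32, 128, 7.1, 0:5), "ke")
  expect_error(acquisition_meta(1, 32, 128, 7.1, c(0, 7.1, 7.1)),
               "strictly increasing")
  expect_error(acquisition_meta(1, 32, 128, 7.1, c(-1, 7.1)),
               "strictly increasing|>= 0")
})

test_that("encoding-frequency range check warns outside [0.8, 1.0] only", {
  meta_at <- function(ke) acquisition_meta(ke, 32, 128, 7.1, c(0, 7.1))
  expect_length(validate_encoding_range(meta_at(0.9)), 0)
  expect_length(validate_encoding_range(meta_at(1.0)), 0)   # inclusive bound
  expect_length(validate_encoding_range(meta_at(0.8)), 0)
  w <- validate_encoding_range(meta_at(0.5))
  expect_length(w, 1)
  expect_match(w, "ke")
})

test_that("slice construction rejects phase outside (-pi, pi] and shape mismatch", {
  meta <- acquisition_meta(1, 16, 8, 7.1, c(0, 7.1))
  ok <- array(0, c(8, 8, 2))
  bad <- ok; bad[1, 1, 1] <- 4   # > pi
  expect_error(dense_slice("mid", ok, bad, ok, meta), "\\(-pi, pi\\]")
  expect_error(dense_slice("mid", ok, ok, array(0, c(8, 8, 3)), meta),
               "identical dimensions")
  expect_silent(dense_slice("mid", ok, ok, ok, meta))
})

test_that("contour invariants: simplicity and enclosure", {
  endo <- circle_contour(1.2)
  epi <- circle_contour(2.4)
  expect_s3_class(contour_set(endo, epi), "contour_set")
  expect_error(contour_set(epi, endo), "enclose")
  bow <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2)) +
    matrix(c(15, 15), 4, 2, byrow = TRUE)
  expect_error(contour_set(bow, circle_contour(6)), "self-intersecting")
})

test_that("a study requires all five prescribed views", {
  fx <- lowfat_fixture()
  sl <- fx$study$slices
  ct <- fx$study$ed_contours
  expect_error(dense_study(sl[c("basal", "mid", "two_chamber", "four_chamber")],
                           ct),
               "incomplete study: apical")
})

test_that("write/read round trip preserves the study exactly", {
  cfg <- small_config()
  rs <- render_study(cfg)
  dir <- withr::local_tempdir()
  write_study(rs$study, dir)
  back <- read_study(dir)
  for (lab in names(rs$study$slices)) {
    expect_identical(dim(back$slices[[lab]]$magnitude),
                     dim(rs$study$slices[[lab]]$magnitude))
    expect_equal(back$slices[[lab]]$phase_x, rs$study$slices[[lab]]$phase_x,
                 tolerance = 0)
    expect_equal(back$slices[[lab]]$phase_y, rs$study$slices[[lab]]$phase_y,
                 tolerance = 0)
    expect_equal(back$slices[[lab]]$meta$ke, rs$study$slices[[lab]]$meta$ke)
    expect_equal(back$ed_contours[[lab]]$endocardium,
                 rs$study$ed_contours[[lab]]$endocardium, tolerance = 0)
  }
  expect_identical(back$subject_id, rs$study$subject_id)
  # frame count preserved in the image container
  expect_equal(dim(back$slices$mid$magnitude)[3], cfg$n_frames)
})

test_that("serialization is deterministic and ke round-trips through the sidecar", {
  cfg <- small_config(ke = 0.9)
  rs <- render_study(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(rs$study, d1)
  write_study(rs$study, d2)
  for (f in c("study.json", "contours.json"))
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  expect_equal(read_study(d1)$slices$mid$meta$ke, 0.9)
})

test_that("reading an incomplete directory names the missing view", {
  cfg <- small_config()
  rs <- render_study(cfg)
  dir <- withr::local_tempdir()
  write_study(rs$study, dir)
  file.remove(file.path(dir, "apical_mag.nii"))
  expect_error(read_study(dir), "incomplete study: apical")
})
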