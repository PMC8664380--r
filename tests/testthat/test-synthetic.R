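test_that("rendering is deterministic and neutral at phase zero", {
  cfg <- small_config()
  r1 <- render_face(cfg, "S01", "AU1+2", "LowerNone", phase = 0)
  r0 <- render_face(cfg, "S01", "UpperNone", "LowerNone", phase = 1)
  expect_equal(r1$image, r0$image)  # phase 0 renders the neutral geometry
  set.seed(4)
  a <- render_face(cfg, "S01", "AU1+2", "AU25+26")
  set.seed(4)
  b <- render_face(cfg, "S01", "AU1+2", "AU25+26")
  expect_identical(a$image, b$image)
  expect_error(render_face(cfg, "S01", "AU25+26", "LowerNone"), "upper")
  expect_error(render_face(cfg, "S01", "UpperNone", "AU1+2"), "lower")
})

test_that("deformations are local to their region's ROI at zero noise", {
  cfg <- small_config()
  rois <- synthetic_rois(cfg)
  neutral <- render_face(cfg, "S01", "UpperNone", "LowerNone")$image
  for (cl in c("AU1+2", "AU43_5")) {
    delta <- render_face(cfg, "S01", cl, "LowerNone")$image - neutral
    expect_gt(sum(abs(crop_roi(delta, rois$upper))), 0)
    expect_equal(sum(abs(crop_roi(delta, rois$lower))), 0)
  }
  for (cl in au_target_classes("lower")) {
    delta <- render_face(cfg, "S01", "UpperNone", cl)$image - neutral
    expect_gt(sum(abs(crop_roi(delta, rois$lower))), 0)
    expect_equal(sum(abs(crop_roi(delta, rois$upper))), 0)
  }
})

test_that("distinct subjects render distinct appearances, same landmarks", {
  cfg <- small_config()
  r1 <- render_face(cfg, "S01", "UpperNone", "LowerNone")
  r2 <- render_face(cfg, "S02", "UpperNone", "LowerNone")
  expect_gt(max(abs(r1$image - r2$image)), 1)
  expect_equal(r1$landmarks$points, r2$landmarks$points)
  # per-subject parameters are a pure function of (seed, id)
  expect_identical(subject_params(cfg, "S01"), subject_params(cfg, "S01"))
})

test_that("datasets regenerate bit-identically from the same seed", {
  cfg <- small_config()
  g1 <- generate_dataset(cfg)
  g2 <- generate_dataset(cfg)
  expect_identical(g1$dataset$videos[[1]]$frames,
                   g2$dataset$videos[[1]]$frames)
  expect_identical(g1$dataset$videos[[3]]$labels,
                   g2$dataset$videos[[3]]$labels)
  expect_equal(g1$truth$pose[[2]]$matrix, g2$truth$pose[[2]]$matrix)
})

test_that("posed rendering matches the analytic pose of the landmarks", {
  fx <- small_aligned()
  cfg <- fx$config
  for (vid in names(fx$raw$videos)[1:2]) {
    pose <- fx$truth$pose[[vid]]
    want <- apply_affine(pose,
                         reference_landmarks(cfg$image_size[1],
                                             cfg$image_size[2])$points)
    expect_equal(unname(fx$truth$landmarks[[vid]]$points), unname(want),
                 tolerance = 1e-10)
  }
})

test_that("episode structure keeps AU runs contiguous and >= 3 frames", {
  cfg <- synthetic_config(image_size = c(32, 28), n_subjects = 1,
                          videos_per_subject = 1, frames_per_video = 400,
                          class_frequencies = balanced_freqs(), seed = 10)
  g <- generate_dataset(cfg)
  lab <- g$dataset$videos[[1]]$labels
  for (region in c("upper", "lower")) {
    runs <- rle(lab[[region]])
    au_runs <- runs$lengths[runs$values != region_neutral_class(region)]
    # interior AU episodes span at least 3 frames (the last may be truncated)
    if (length(au_runs) > 1)
      expect_true(all(au_runs[-length(au_runs)] >= 3))
  }
})

test_that("generated class frequencies track the configured rates", {
  # one long video so episode clustering averages out
  cfg <- synthetic_config(image_size = c(32, 28), n_subjects = 1,
                          videos_per_subject = 1, frames_per_video = 4000,
                          seed = 77)
  g <- generate_dataset(cfg)
  lab <- g$dataset$videos[[1]]$labels
  for (region in c("upper", "lower")) {
    want <- cfg$class_frequencies[[region]]
    got <- table(lab[[region]]) / nrow(lab)
    for (cl in names(want))
      # slack reflects episode-level (not frame-level) sampling variance
      expect_lt(abs(got[cl] - want[cl]), 0.05)
  }
})

test_that("zero pose jitter and noise make alignment a near-identity", {
  cfg <- synthetic_config(image_size = c(48, 42), n_subjects = 1,
                          videos_per_subject = 1, frames_per_video = 6,
                          class_frequencies = balanced_freqs(),
                          pose_jitter = list(rotation_deg = 0, scale = 0,
                                             translation_px = 0),
                          noise_sd = 0, seed = 2)
  g <- generate_dataset(cfg)
  al <- align_dataset(g$dataset, g$truth$landmarks)
  for (f in seq_along(al$videos[[1]]$frames))
    expect_equal(al$videos[[1]]$frames[[f]], g$dataset$videos[[1]]$frames[[f]],
                 tolerance = 1e-6)
})

test_that("written datasets reload through the standard file interfaces", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(image_size = c(32, 28), n_subjects = 1,
                          videos_per_subject = 1, frames_per_video = 12,
                          class_frequencies = balanced_freqs(), seed = 6)
  g <- generate_dataset(cfg)
  write_dataset(g, dir)
  vid <- g$dataset$videos[[1]]
  vdir <- file.path(dir, vid$video_id)
  v <- load_image_sequence(vdir, file.path(vdir, "manifest.txt"))
  expect_identical(v$video_id, vid$video_id)
  expect_length(v$frames, 12)
  # 8-bit PNG quantization only
  expect_lt(max(abs(v$frames[[3]] - vid$frames[[3]])), 0.51)
  v <- attach_labels(v, read_label_table(file.path(dir, "labels.csv")))
  expect_identical(v$labels$upper, vid$labels$upper)
  expect_identical(v$labels$lower, vid$labels$lower)
  lms <- read_landmark_table(file.path(dir, "landmarks.csv"))
  expect_equal(lms[[vid$video_id]]$points,
               g$truth$landmarks[[vid$video_id]]$points, tolerance = 1e-6)
})
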