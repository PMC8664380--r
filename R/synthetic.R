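#' Configuration for the synthetic face-video generator
#'
#' The generator renders schematic frontal macaque-like faces (smooth
#' background blob, brows, eye ellipses, nose, mouth) with parametric
#' action-unit deformations, deterministic per-subject appearance offsets,
#' one random camera-pose offset per video, and additive Gaussian intensity
#' noise, so that every stage of the recognition pipeline has real work to
#' do on data with known ground truth.
#'
#' Class frequencies default to a regime where the region-neutral class
#' dominates and brow raising is rare, mirroring the shape of spontaneous
#' head-fixed recordings.
#'
#' @param image_size `c(width, height)` in pixels.
#' @param n_subjects,videos_per_subject,frames_per_video corpus shape.
#' @param class_frequencies list with `upper` and `lower` named probability
#'   vectors over the region's classes (targets + neutral); each sums to 1.
#' @param deformation_magnitude per-AU peak displacement in pixels; a scalar
#'   applies to every AU, or a named vector with names `AU1+2`, `AU43_5`,
#'   `AU25+26`, `AU16`, `AU18i`.
#' @param noise_sd SD of additive Gaussian intensity noise (0--255 scale).
#' @param pose_jitter list with `rotation_deg`, `scale`, `translation_px`:
#'   half-ranges of the per-video uniform pose draws (rotation about the
#'   image centre, scale factor `1 +/- scale`, translation in pixels).
#' @param episode_mean_frames mean length of an action-unit episode
#'   (episodes are temporally contiguous, always >= 3 frames).
#' @param seed integer; fixes the full generation stream.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(image_size = c(800, 700),
                             n_subjects = 3L,
                             videos_per_subject = 2L,
                             frames_per_video = 120L,
                             class_frequencies = list(
                               upper = c("UpperNone" = 0.78, "AU43_5" = 0.16,
                                         "AU1+2" = 0.06),
                               lower = c("LowerNone" = 0.55, "AU25+26" = 0.20,
                                         "AU25+26+18i" = 0.17,
                                         "AU25+26+16" = 0.08)),
                             deformation_magnitude = 10,
                             noise_sd = 0,
                             pose_jitter = list(rotation_deg = 6,
                                                scale = 0.06,
                                                translation_px = 8),
                             episode_mean_frames = 6,
                             seed = 1L) {
  for (r in c("upper", "lower")) {
    f <- class_frequencies[[r]]
    if (abs(sum(f) - 1) > 1e-8)
      stop(r, " class frequencies must sum to 1", call. = FALSE)
    if (!all(names(f) %in% au_all_classes(r)))
      stop("unknown class in ", r, " frequencies", call. = FALSE)
  }
  if (any(unlist(deformation_magnitude) < 0))
    stop("deformation magnitudes must be >= 0", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 n_subjects = as.integer(n_subjects),
                 videos_per_subject = as.integer(videos_per_subject),
                 frames_per_video = as.integer(frames_per_video),
                 class_frequencies = class_frequencies,
                 deformation_magnitude = deformation_magnitude,
                 noise_sd = noise_sd, pose_jitter = pose_jitter,
                 episode_mean_frames = episode_mean_frames,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# quartic compact-support bump: nonzero only where d2 < 1, so feature
# rendering is exactly local (no Gaussian tails crossing ROI borders)
bump <- function(d2) {
  b <- 1 - d2
  b[b < 0] <- 0
  b * b
}

au_magnitude <- function(config, au) {
  m <- config$deformation_magnitude
  if (length(m) == 1L && is.null(names(m))) return(as.numeric(m))
  if (!au %in% names(m)) stop("no magnitude for ", au, call. = FALSE)
  as.numeric(m[[au]])
}

with_local_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

string_seed <- function(...) {
  s <- paste(..., collapse = "|")
  v <- utf8ToInt(s)
  as.integer(sum(v * (seq_along(v) %% 13 + 1) * 997) %% 2147483647)
}

#' Deterministic per-subject appearance parameters
#'
#' @param config a [synthetic_config()].
#' @param subject_id character id; the parameters depend only on
#'   `(config$seed, subject_id)`.
#' @return named list of appearance factors.
#' @export
subject_params <- function(config, subject_id) {
  with_local_seed(derive_seed(config$seed, string_seed(subject_id)), {
    u <- stats::runif(4)
    list(shade = -12 + 24 * u[1],        # baseline brightness offset
         brow = 0.8 + 0.5 * u[2],        # brow thickness factor
         eye = 0.85 + 0.3 * u[3],        # eye aperture factor
         feat = 0.9 + 0.2 * u[4])        # feature contrast factor
  })
}

canonical_landmarks <- function(width, height) reference_landmarks(width, height)

# intensity of the schematic face at canonical coordinates (x, y), vectorized
face_value <- function(x, y, w, h, sp, upper_class, lower_class, phase,
                       config) {
  val <- 100 + sp$shade +
    45 * bump(((x - 0.5 * w) / (0.48 * w))^2 + ((y - 0.46 * h) / (0.52 * h))^2)
  # brows: displaced upward by the brow-raiser AU
  raise <- if (upper_class == "AU1+2") phase * au_magnitude(config, "AU1+2") else 0
  by <- 0.24 * h - raise
  brh <- 0.011 * h * sp$brow
  for (ex in c(0.45, 0.55) * w)
    val <- val - 65 * sp$feat *
      bump(((x - ex) / (0.045 * w))^2 + ((y - by) / brh)^2)
  # eyes: aperture shrinks toward 0 under eye closure
  erh0 <- 0.018 * h * sp$eye
  shrink <- if (upper_class == "AU43_5")
    min(0.92 * erh0, phase * au_magnitude(config, "AU43_5")) else 0
  erh <- erh0 - shrink
  for (ex in c(0.45, 0.55) * w)
    val <- val - 75 * sp$feat *
      bump(((x - ex) / (0.03 * w))^2 + ((y - 0.30 * h) / erh)^2)
  # nose (static)
  val <- val - 30 * bump(((x - 0.5 * w) / (0.022 * w))^2 +
                           ((y - 0.42 * h) / (0.025 * h))^2)
  # mouth: aperture opens downward under lips-part + jaw-drop
  open <- if (lower_class %in% au_target_classes("lower"))
    phase * au_magnitude(config, "AU25+26") else 0
  mrw <- 0.06 * w
  if (lower_class == "AU25+26+18i")  # pucker pulls the corners inward
    mrw <- mrw - min(0.45 * mrw, 0.5 * phase * au_magnitude(config, "AU18i"))
  mcy <- 0.53 * h + open / 2
  mrh <- 0.012 * h + open / 2
  val <- val - 70 * sp$feat *
    bump(((x - 0.5 * w) / mrw)^2 + ((y - mcy) / mrh)^2)
  if (lower_class == "AU25+26+16") { # lower-lip depressor: bar pushed down
    amp <- 50 * min(1, phase * au_magnitude(config, "AU16") / 8)
    ly <- 0.53 * h + open + 0.6 * phase * au_magnitude(config, "AU16")
    val <- val - amp * bump(((x - 0.5 * w) / (0.05 * w))^2 +
                              ((y - ly) / (0.014 * h + 0.8))^2)
  }
  if (lower_class == "AU25+26+18i") { # protrusion shading
    amp <- 45 * min(1, phase * au_magnitude(config, "AU18i") / 8)
    val <- val + amp * bump(((x - 0.5 * w) / (0.042 * w))^2 +
                              ((y - 0.56 * h) / (0.045 * h))^2)
  }
  val
}

#' Render one synthetic face frame
#'
#' Renders the schematic face for the given subject and per-region classes
#' at deformation phase `phase` (0 = neutral geometry, 1 = full
#' displacement). When a `pose` transform is given the face is rendered
#' directly in posed coordinates (analytically, without resampling) and the
#' returned landmarks are the posed landmark positions. Noise (if
#' `config$noise_sd > 0`) is drawn from the current RNG stream.
#'
#' @param config a [synthetic_config()].
#' @param subject_id subject identifier (fixes appearance).
#' @param upper_class,lower_class classes valid for their regions.
#' @param phase deformation phase in `[0, 1]`.
#' @param pose optional [affine_transform()] mapping canonical to image
#'   coordinates (identity when `NULL`).
#' @return list with `image` (h x w matrix, 0--255) and `landmarks`
#'   (a [landmark_set()] in image coordinates).
#' @export
render_face <- function(config, subject_id, upper_class = "UpperNone",
                        lower_class = "LowerNone", phase = 1, pose = NULL) {
  if (!upper_class %in% au_all_classes("upper"))
    stop("invalid upper-face class: ", upper_class, call. = FALSE)
  if (!lower_class %in% au_all_classes("lower"))
    stop("invalid lower-face class: ", lower_class, call. = FALSE)
  w <- config$image_size[1]; h <- config$image_size[2]
  sp <- subject_params(config, subject_id)
  x <- rep(0:(w - 1L), each = h)
  y <- rep.int(0:(h - 1L), w)
  if (!is.null(pose)) {
    inv <- invert_affine(pose)$matrix
    cx <- inv[1, 1] * x + inv[1, 2] * y + inv[1, 3]
    cy <- inv[2, 1] * x + inv[2, 2] * y + inv[2, 3]
  } else {
    cx <- x; cy <- y
  }
  val <- face_value(cx, cy, w, h, sp, upper_class, lower_class, phase, config)
  if (config$noise_sd > 0)
    val <- val + stats::rnorm(length(val), 0, config$noise_sd)
  img <- matrix(pmin(pmax(val, 0), 255), nrow = h, ncol = w)
  lm <- canonical_landmarks(w, h)
  pts <- if (is.null(pose)) lm$points else apply_affine(pose, lm$points)
  rownames(pts) <- rownames(lm$points)
  list(image = img, landmarks = landmark_set(pts))
}

pose_transform <- function(w, h, rot_deg, scale, tx, ty) {
  th <- rot_deg * pi / 180
  A <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- c((w - 1) / 2, (h - 1) / 2)
  b <- ctr - A %*% ctr + c(tx, ty)
  affine_transform(cbind(A, b))
}

# episode-structured class sequence; AU episodes span >= 3 frames and class
# frame-frequencies match `freqs` in expectation (episode draw probabilities
# are length-corrected)
sample_label_sequence <- function(n, freqs, neutral_class, mean_au_len) {
  exp_len <- ifelse(names(freqs) == neutral_class, 4,
                    pmax(mean_au_len, 3))
  pw <- freqs / exp_len
  out <- character(0)
  while (length(out) < n) {
    cl <- sample(names(freqs), 1, prob = pw)
    len <- if (cl == neutral_class) 1L + stats::rgeom(1, 1 / 4)
           else 3L + stats::rgeom(1, 1 / (max(mean_au_len, 3.5) - 2.5))
    out <- c(out, rep(cl, len))
  }
  out[seq_len(n)]
}

#' Generate a fully labeled synthetic dataset with ground truth
#'
#' Draws one camera-pose offset per video (so the alignment stage has real
#' work), episode-structured per-frame class labels per region, and renders
#' every frame. The full stream is fixed by `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with `dataset` (an [au_dataset()]), and `truth`: per-video
#'   `pose` ([affine_transform()]s), `landmarks` (posed [landmark_set()]s,
#'   what a human annotator would mark on the mean neutral image), and the
#'   per-frame labels (inside each video).
#' @export
generate_dataset <- function(config) {
  w <- config$image_size[1]; h <- config$image_size[2]
  videos <- list(); poses <- list(); lms <- list()
  set.seed(config$seed)
  for (si in seq_len(config$n_subjects)) {
    subj <- sprintf("S%02d", si)
    for (vi in seq_len(config$videos_per_subject)) {
      vid <- sprintf("%s_v%02d", subj, vi)
      pj <- config$pose_jitter
      pose <- pose_transform(w, h,
                             stats::runif(1, -pj$rotation_deg, pj$rotation_deg),
                             stats::runif(1, 1 - pj$scale, 1 + pj$scale),
                             stats::runif(1, -pj$translation_px, pj$translation_px),
                             stats::runif(1, -pj$translation_px, pj$translation_px))
      n <- config$frames_per_video
      upper <- sample_label_sequence(n, config$class_frequencies$upper,
                                     "UpperNone", config$episode_mean_frames)
      lower <- sample_label_sequence(n, config$class_frequencies$lower,
                                     "LowerNone", config$episode_mean_frames)
      # guarantee at least one neutral frame for the alignment stage
      if (!any(upper == "UpperNone" & lower == "LowerNone")) {
        upper[1] <- "UpperNone"; lower[1] <- "LowerNone"
      }
      frames <- vector("list", n)
      lm1 <- NULL
      for (f in seq_len(n)) {
        r <- render_face(config, subj, upper[f], lower[f], phase = 1,
                         pose = pose)
        frames[[f]] <- r$image
        lm1 <- r$landmarks
      }
      videos[[vid]] <- labeled_video(
        vid, subj, "synthetic", frames, fps = 30,
        labels = data.frame(frame = seq_len(n) - 1L, upper = upper,
                            lower = lower, stringsAsFactors = FALSE))
      poses[[vid]] <- pose
      lms[[vid]] <- lm1
    }
  }
  list(dataset = au_dataset(videos),
       truth = list(pose = poses, landmarks = lms))
}

#' Default ROI rectangles for the synthetic face template
#'
#' Chosen so that, at the default geometry, upper-face action units deform
#' pixels only inside the upper rectangle and lower-face units only inside
#' the lower rectangle.
#'
#' @param config a [synthetic_config()].
#' @return list with `upper` and `lower` [roi_spec()]s.
#' @export
synthetic_rois <- function(config) {
  w <- config$image_size[1]; h <- config$image_size[2]
  rect <- function(region, fx0, fy0, fx1, fy1) {
    x0 <- floor(fx0 * w); y0 <- floor(fy0 * h)
    roi_spec(region, x0, y0, floor(fx1 * w) - x0, floor(fy1 * h) - y0)
  }
  list(upper = rect("upper", 0.18, 0.02, 0.82, 0.45),
       lower = rect("lower", 0.22, 0.45, 0.78, 0.95))
}

class_to_codes <- function(class) {
  switch(class,
         "UpperNone" = "", "LowerNone" = "",
         "AU1+2" = "AU1+2", "AU43_5" = "AU43",
         "AU25+26" = "AU25+AU26",
         "AU25+26+16" = "AU25+AU26+AU16",
         "AU25+26+18i" = "AU25+AU26+AU18i",
         "")
}

#' Write a synthetic dataset to disk in the pipeline's file formats
#'
#' Emits, under `dir`: one sub-directory of PNG frames plus a `manifest.txt`
#' per video, a single `labels.csv` per-frame label table (rows only for
#' non-neutral frames), and a `landmarks.csv` annotation table, so the file
#' based pipeline runs unmodified on synthetic data.
#'
#' @param generated result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (v in generated$dataset$videos) {
    vdir <- file.path(dir, v$video_id)
    dir.create(vdir, showWarnings = FALSE)
    for (f in seq_along(v$frames))
      png::writePNG(v$frames[[f]] / 255,
                    file.path(vdir, sprintf("frame_%05d.png", f - 1L)))
    writeLines(c(paste0("video_id: ", v$video_id),
                 paste0("subject_id: ", v$subject_id),
                 paste0("species: ", v$species),
                 paste0("fps: ", v$fps)),
               file.path(vdir, "manifest.txt"))
    for (region in c("upper", "lower")) {
      lab <- v$labels[[region]]
      keep <- which(lab != region_neutral_class(region))
      if (!length(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        video_id = v$video_id, frame_index = keep - 1L, region = region,
        codes = vapply(lab[keep], class_to_codes, ""), intensity = "",
        stringsAsFactors = FALSE)
    }
  }
  lab_tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(video_id = character(0), frame_index = integer(0),
               region = character(0), codes = character(0),
               intensity = character(0))
  write_label_table(lab_tab, file.path(dir, "labels.csv"))
  write_landmark_table(generated$truth$landmarks, file.path(dir, "landmarks.csv"))
  invisible(dir)
}
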