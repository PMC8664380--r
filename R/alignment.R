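#' @keywords internal
landmark_names <- c("left_eye_outer", "left_eye_inner", "right_eye_inner",
                    "right_eye_outer", "mouth_left", "mouth_right",
                    "mouth_center")

#' Construct a 7-point facial landmark set
#'
#' Pixel coordinates use the convention: 0-based, `x` = column, `y` = row,
#' origin at the top-left, continuous coordinates at pixel centres.
#'
#' @param points 7 x 2 numeric matrix (columns x, y) with rows named
#'   `left_eye_outer`, `left_eye_inner`, `right_eye_inner`,
#'   `right_eye_outer`, `mouth_left`, `mouth_right`, `mouth_center`.
#' @param width,height image size in pixels (optional; when given, points
#'   must lie inside `[0, width) x [0, height)`).
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(points, width = NA, height = NA) {
  points <- as.matrix(points)
  if (nrow(points) != 7L || ncol(points) != 2L)
    stop("a landmark set has 7 (x, y) points", call. = FALSE)
  if (is.null(rownames(points))) rownames(points) <- landmark_names
  if (!setequal(rownames(points), landmark_names))
    stop("landmark names must be: ", paste(landmark_names, collapse = ", "),
         call. = FALSE)
  points <- points[landmark_names, , drop = FALSE]
  colnames(points) <- c("x", "y")
  if (!is.na(width) && !is.na(height) &&
      (any(points[, 1] < 0) || any(points[, 1] >= width) ||
       any(points[, 2] < 0) || any(points[, 2] >= height)))
    stop("landmark outside image bounds", call. = FALSE)
  structure(list(points = points, width = width, height = height),
            class = "landmark_set")
}

#' Reference landmark positions for an aligned frame
#'
#' The common coordinate frame every video is mapped into places the seven
#' landmarks at fixed fractions of the image width `w` and height `h`:
#' eye corners at 0.42/0.48/0.52/0.58 `w` and 0.3 `h`, mouth corners at
#' 0.44/0.56 `w` and 0.55 `h`, mouth centre at 0.5 `w`, 0.5 `h`.
#'
#' @param width,height target frame size in pixels (>= 1).
#' @return a [landmark_set()].
#' @export
reference_landmarks <- function(width, height) {
  if (width < 1 || height < 1)
    stop("width and height must be >= 1", call. = FALSE)
  fx <- c(0.42, 0.48, 0.52, 0.58, 0.44, 0.56, 0.50)
  fy <- c(0.30, 0.30, 0.30, 0.30, 0.55, 0.55, 0.50)
  pts <- cbind(x = fx * width, y = fy * height)
  rownames(pts) <- landmark_names
  landmark_set(pts, width, height)
}

#' Read per-video landmark annotations
#'
#' Delimited text with header and columns `video_id`, `point_name`, `x`, `y`.
#'
#' @param path file path.
#' @return named list of [landmark_set()] objects, one per video.
#' @export
read_landmark_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$video_id), function(sub) {
    pts <- as.matrix(sub[c("x", "y")])
    rownames(pts) <- sub$point_name
    landmark_set(pts)
  })
}

#' Write per-video landmark annotations
#'
#' @param landmarks named list of [landmark_set()] (names = video ids).
#' @param path output file.
#' @export
write_landmark_table <- function(landmarks, path) {
  rows <- lapply(names(landmarks), function(v) {
    p <- landmarks[[v]]$points
    data.frame(video_id = v, point_name = rownames(p),
               x = p[, 1], y = p[, 2], stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Affine transform between pixel coordinate frames
#'
#' @param matrix 2 x 3 real matrix mapping source `(x, y, 1)` to destination
#'   `(x', y')`. The 2 x 2 linear block must be nonsingular.
#' @return object of class `affine_transform`.
#' @export
affine_transform <- function(matrix) {
  m <- base::matrix(as.numeric(matrix), 2L, 3L)
  if (abs(det(m[, 1:2])) <= 1e-12)
    stop("degenerate affine transform (singular linear block)", call. = FALSE)
  structure(list(matrix = m), class = "affine_transform")
}

#' Apply an affine transform to points
#'
#' @param transform an [affine_transform()].
#' @param points n x 2 matrix of (x, y) coordinates.
#' @return n x 2 matrix of mapped coordinates.
#' @export
apply_affine <- function(transform, points) {
  p <- as.matrix(points)
  out <- cbind(p, 1) %*% t(transform$matrix)
  colnames(out) <- c("x", "y")
  out
}

#' Invert an affine transform
#'
#' @param transform an [affine_transform()].
#' @return the inverse [affine_transform()].
#' @export
invert_affine <- function(transform) {
  A <- transform$matrix[, 1:2]
  b <- transform$matrix[, 3]
  Ai <- solve(A)
  affine_transform(cbind(Ai, -Ai %*% b))
}

#' Estimate the least-squares affine transform between landmark sets
#'
#' Seven correspondences over-determine the six affine parameters, so the
#' transform is the ordinary least-squares minimizer of
#' sum ||A source_i - destination_i||^2. For affine-consistent
#' correspondences the fit is exact (residual < 1e-9 per point).
#'
#' @param src,dst [landmark_set()] objects (or n x 2 point matrices with
#'   matching row order, n >= 3).
#' @return an [affine_transform()].
#' @export
estimate_affine <- function(src, dst) {
  sp <- if (inherits(src, "landmark_set")) src$points else as.matrix(src)
  dp <- if (inherits(dst, "landmark_set")) dst$points else as.matrix(dst)
  if (nrow(sp) != nrow(dp) || nrow(sp) < 3L)
    stop("need matching point sets with >= 3 correspondences", call. = FALSE)
  ctr <- sweep(sp, 2, colMeans(sp))
  if (min(svd(ctr)$d) < 1e-9 * max(svd(ctr)$d, 1))
    stop("degenerate configuration: source points are collinear", call. = FALSE)
  M <- cbind(sp, 1)
  coef <- solve(crossprod(M), crossprod(M, dp))  # 3 x 2
  affine_transform(t(coef))
}

#' Warp a frame with an affine transform
#'
#' Output pixels are inverse-mapped into the source frame and sampled with
#' bilinear interpolation; samples falling outside the source are zero.
#'
#' @param frame numeric matrix (h x w).
#' @param transform [affine_transform()] mapping source to output coordinates.
#' @param out_size `c(width, height)` of the output (defaults to the input).
#' @return numeric matrix (`out_size[2]` x `out_size[1]`).
#' @export
warp_frame <- function(frame, transform, out_size = c(ncol(frame), nrow(frame))) {
  inv <- invert_affine(transform)$matrix
  w <- as.integer(out_size[1]); h <- as.integer(out_size[2])
  x <- rep(0:(w - 1L), each = h)
  y <- rep.int(0:(h - 1L), w)
  sx <- inv[1, 1] * x + inv[1, 2] * y + inv[1, 3]
  sy <- inv[2, 1] * x + inv[2, 2] * y + inv[2, 3]
  x0 <- floor(sx); y0 <- floor(sy)
  dx <- sx - x0; dy <- sy - y0
  sw <- ncol(frame); sh <- nrow(frame)
  px <- function(yy, xx) {
    v <- numeric(length(xx))
    ok <- xx >= 0 & xx < sw & yy >= 0 & yy < sh
    v[ok] <- frame[cbind(yy[ok] + 1L, xx[ok] + 1L)]
    v
  }
  vals <- (1 - dx) * (1 - dy) * px(y0, x0) + dx * (1 - dy) * px(y0, x0 + 1) +
    (1 - dx) * dy * px(y0 + 1, x0) + dx * dy * px(y0 + 1, x0 + 1)
  matrix(vals, nrow = h, ncol = w)
}

neutral_frame_indices <- function(video) {
  which(video$labels$upper == "UpperNone" & video$labels$lower == "LowerNone")
}

#' Mean of a video's neutral-expression frames
#'
#' A frame is neutral when its upper class is `UpperNone` and its lower class
#' is `LowerNone` (no coded action in either region). Landmarks are annotated
#' on this mean image.
#'
#' @param video a [labeled_video()].
#' @return numeric matrix, the pixel-wise mean over neutral frames.
#' @export
mean_neutral_image <- function(video) {
  idx <- neutral_frame_indices(video)
  if (!length(idx))
    stop("video ", video$video_id, " has no neutral frames", call. = FALSE)
  Reduce(`+`, video$frames[idx]) / length(idx)
}

#' Align all frames of a video to the reference landmarks
#'
#' One affine transform is estimated per video, from the landmarks annotated
#' on its mean neutral image to [reference_landmarks()] of the frame size,
#' and applied identically to every frame. Labels are carried over unchanged.
#'
#' @param video a [labeled_video()].
#' @param landmarks [landmark_set()] annotated on the video's mean neutral
#'   image.
#' @return the aligned [labeled_video()]; the transform used is stored in
#'   attribute `"transform"`.
#' @export
align_video <- function(video, landmarks) {
  d <- dim(video$frames[[1]])
  ref <- reference_landmarks(d[2], d[1])
  tr <- estimate_affine(landmarks, ref)
  video$frames <- lapply(video$frames, warp_frame, transform = tr,
                         out_size = c(d[2], d[1]))
  attr(video, "transform") <- tr
  video
}
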