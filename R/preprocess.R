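#' Rectangular region of interest on aligned frames
#'
#' @param region `"upper"` or `"lower"`.
#' @param x0,y0 top-left corner (0-based pixels).
#' @param width,height extent in pixels (>= 1); the rectangle is half-open,
#'   `[x0, x0 + width) x [y0, y0 + height)`.
#' @return object of class `roi_spec`.
#' @export
roi_spec <- function(region, x0, y0, width, height) {
  region <- match_region(region)
  if (width < 1 || height < 1 || x0 < 0 || y0 < 0)
    stop("invalid ROI rectangle", call. = FALSE)
  structure(list(region = region, x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi_spec")
}

#' Read upper/lower ROI rectangles from a key-value config file
#'
#' Lines `upper.rect = x0,y0,width,height` and `lower.rect = ...`.
#'
#' @param path config file.
#' @return named list with `upper` and `lower` [roi_spec()]s.
#' @export
read_roi_config <- function(path) {
  kv <- read_manifest(path)
  parse1 <- function(region) {
    v <- as.integer(strsplit(kv[[paste0(region, ".rect")]], ",")[[1]])
    roi_spec(region, v[1], v[2], v[3], v[4])
  }
  list(upper = parse1("upper"), lower = parse1("lower"))
}

#' Total average image over a collection of aligned videos
#'
#' Unweighted mean of the per-video mean neutral images; the canvas on which
#' ROIs are marked.
#'
#' @param videos list of aligned [labeled_video()] objects.
#' @return numeric matrix.
#' @export
total_average_image <- function(videos) {
  if (!length(videos)) stop("empty video collection", call. = FALSE)
  means <- lapply(videos, mean_neutral_image)
  Reduce(`+`, means) / length(means)
}

#' Select the optimal neutral frame of a video
#'
#' Among the neutral frames, returns the 0-based index of the frame with the
#' smallest L2 distance to the video's mean neutral image (a stable automated
#' proxy for an expert's choice); ties go to the smallest index. A manual
#' override, when supplied, is honoured verbatim.
#'
#' @param video an aligned [labeled_video()].
#' @param override optional 0-based frame index chosen manually.
#' @return 0-based frame index.
#' @export
select_optimal_neutral <- function(video, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  idx <- neutral_frame_indices(video)
  if (!length(idx))
    stop("video ", video$video_id, " has no neutral frames", call. = FALSE)
  m <- mean_neutral_image(video)
  d2 <- vapply(idx, function(i) sum((video$frames[[i]] - m)^2), 0)
  idx[which.min(d2)] - 1L
}

#' Crop a frame to a region of interest
#'
#' @param frame numeric matrix.
#' @param roi a [roi_spec()] lying fully inside the frame.
#' @return the exact (`height` x `width`) sub-matrix.
#' @export
crop_roi <- function(frame, roi) {
  if (roi$x0 + roi$width > ncol(frame) || roi$y0 + roi$height > nrow(frame))
    stop("ROI exceeds frame bounds", call. = FALSE)
  frame[(roi$y0 + 1L):(roi$y0 + roi$height),
        (roi$x0 + 1L):(roi$x0 + roi$width), drop = FALSE]
}

#' Delta image: signed difference from the neutral frame
#'
#' @param frame_roi,neutral_roi numeric matrices of equal shape.
#' @return `frame_roi - neutral_roi` (signed, in \[-255, 255\] for 8-bit
#'   input).
#' @export
delta_image <- function(frame_roi, neutral_roi) {
  if (!identical(dim(frame_roi), dim(neutral_roi)))
    stop("shape mismatch between frame and neutral ROI", call. = FALSE)
  frame_roi - neutral_roi
}

flatten_image <- function(m) as.vector(t(m))

unflatten_image <- function(v, shape) {
  matrix(v, nrow = shape[1], ncol = shape[2], byrow = TRUE)
}

#' Build a flat delta-image database for one facial region
#'
#' For every video: the optimal neutral frame's ROI is subtracted from each
#' frame's ROI, and frames whose region class is in `class_filter` contribute
#' one row-major flattened row. Row order is deterministic: video order, then
#' frame order.
#'
#' @param videos list of aligned [labeled_video()] objects.
#' @param roi a [roi_spec()].
#' @param class_filter classes to keep (default: the region's three target
#'   classes).
#' @param neutral_overrides optional named list video_id -> 0-based frame
#'   index of a manually chosen neutral frame.
#' @return object of class `image_database`: list with `matrix` (n x p),
#'   `meta` (data frame: `video_id`, `frame_index`, `subject_id`, `class`),
#'   `region`, `roi_shape` (`c(height, width)`).
#' @export
build_database <- function(videos, roi,
                           class_filter = au_target_classes(roi$region),
                           neutral_overrides = NULL) {
  region <- roi$region
  mats <- list(); metas <- list()
  for (v in videos) {
    nf <- select_optimal_neutral(v, neutral_overrides[[v$video_id]])
    neutral_roi <- crop_roi(v$frames[[nf + 1L]], roi)
    keep <- which(v$labels[[region]] %in% class_filter)
    if (!length(keep)) next
    rows <- t(vapply(keep, function(i)
      flatten_image(delta_image(crop_roi(v$frames[[i]], roi), neutral_roi)),
      numeric(roi$width * roi$height)))
    mats[[length(mats) + 1L]] <- rows
    metas[[length(metas) + 1L]] <- data.frame(
      video_id = v$video_id, frame_index = keep - 1L,
      subject_id = v$subject_id, class = v$labels[[region]][keep],
      stringsAsFactors = FALSE)
  }
  if (!length(mats))
    stop("no frames match the class filter", call. = FALSE)
  structure(list(matrix = do.call(rbind, mats),
                 meta = do.call(rbind, metas),
                 region = region,
                 roi_shape = c(roi$height, roi$width)),
            class = "image_database")
}

#' @export
print.image_database <- function(x, ...) {
  cat(sprintf("<image_database %s> %d delta-images of %dx%d (%d px), %d videos\n",
              x$region, nrow(x$matrix), x$roi_shape[1], x$roi_shape[2],
              ncol(x$matrix), length(unique(x$meta$video_id))))
  print(table(x$meta$class))
  invisible(x)
}

#' Save / load an image database
#'
#' The pixel matrix goes into a binary array container (RDS) and the row
#' metadata into a sidecar delimited-text table next to it.
#'
#' @param db an `image_database`.
#' @param prefix path prefix; writes `<prefix>_matrix.rds` and
#'   `<prefix>_meta.csv`.
#' @return `save_database`: the prefix, invisibly. `load_database`: the
#'   database.
#' @export
save_database <- function(db, prefix) {
  saveRDS(list(matrix = db$matrix, region = db$region,
               roi_shape = db$roi_shape), paste0(prefix, "_matrix.rds"))
  utils::write.csv(cbind(row = seq_len(nrow(db$meta)), db$meta),
                   paste0(prefix, "_meta.csv"), row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname save_database
#' @export
load_database <- function(prefix) {
  core <- readRDS(paste0(prefix, "_matrix.rds"))
  meta <- utils::read.csv(paste0(prefix, "_meta.csv"), stringsAsFactors = FALSE)
  structure(list(matrix = core$matrix, meta = meta[-1],
                 region = core$region, roi_shape = core$roi_shape),
            class = "image_database")
}
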