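#' Construct a labeled video
#'
#' A labeled video bundles an ordered frame sequence (2-D intensity matrices
#' on the native 0--255 float scale) with per-frame harmonized action-unit
#' classes for the upper and lower face and subject/species metadata.
#'
#' @param video_id,subject_id character identifiers.
#' @param species one of `"rhesus"`, `"fascicularis"`, `"synthetic"`.
#' @param frames list of numeric matrices, all with identical dimensions.
#' @param fps frames per second.
#' @param labels data frame with columns `frame` (0-based), `upper`, `lower`
#'   (class names); one row per frame. Defaults to all-neutral.
#' @return an object of class `labeled_video`.
#' @export
labeled_video <- function(video_id, subject_id, species, frames, fps = 30,
                          labels = NULL) {
  if (!length(frames)) stop("a video needs at least one frame", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent frame sizes within video ", video_id, call. = FALSE)
  n <- length(frames)
  if (is.null(labels))
    labels <- data.frame(frame = seq_len(n) - 1L,
                         upper = "UpperNone", lower = "LowerNone",
                         stringsAsFactors = FALSE)
  stopifnot(nrow(labels) == n, all(labels$frame == seq_len(n) - 1L))
  bad_u <- setdiff(labels$upper, au_all_classes("upper"))
  bad_l <- setdiff(labels$lower, au_all_classes("lower"))
  if (length(bad_u) || length(bad_l))
    stop("unknown class label(s): ", paste(c(bad_u, bad_l), collapse = ", "),
         call. = FALSE)
  structure(list(video_id = video_id, subject_id = subject_id,
                 species = species, frames = frames, fps = fps,
                 labels = labels),
            class = "labeled_video")
}

#' @export
print.labeled_video <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<labeled_video %s> subject %s (%s), %d frames of %dx%d @ %g fps\n",
              x$video_id, x$subject_id, x$species, length(x$frames),
              d[1], d[2], x$fps))
  invisible(x)
}

#' Bundle labeled videos into a dataset
#'
#' @param videos list of [labeled_video()] objects with unique `video_id`s.
#' @return an object of class `au_dataset`.
#' @export
au_dataset <- function(videos) {
  ids <- vapply(videos, `[[`, "", "video_id")
  if (anyDuplicated(ids)) stop("duplicate video_id", call. = FALSE)
  names(videos) <- ids
  structure(list(videos = videos,
                 subjects = unique(vapply(videos, `[[`, "", "subject_id")),
                 species = unique(vapply(videos, `[[`, "", "species"))),
            class = "au_dataset")
}

#' Convert an RGB frame to grayscale
#'
#' Uses the fixed luma weights 0.299, 0.587, 0.114. Grayscale input (a plain
#' matrix, or an array with one channel) is returned unchanged.
#'
#' @param frame numeric matrix (h x w) or array (h x w x 1 or h x w x 3),
#'   values on the 0--255 scale.
#' @return numeric matrix (h x w).
#' @export
to_grayscale <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (length(dim(frame)) != 3L || !dim(frame)[3] %in% c(1L, 3L))
    stop("frame must have 1 or 3 channels", call. = FALSE)
  d <- dim(frame)
  if (d[3] == 1L) return(matrix(frame[, , 1], d[1], d[2]))
  matrix(0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3],
         d[1], d[2])
}

read_frame_file <- function(path) {
  img <- tryCatch({
    if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
    else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) tiff::readTIFF(path)
    else stop("unsupported image format")
  }, error = function(e) stop("cannot decode frame ", basename(path), ": ",
                              conditionMessage(e), call. = FALSE))
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  to_grayscale(img * 255)
}

#' Read a manifest of video metadata
#'
#' Plain `key: value` (or `key=value`) text with at least `video_id`,
#' `subject_id`, `species`, `fps`.
#'
#' @param path manifest file.
#' @return named list of character values (`fps` converted to numeric).
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "[:=]", perl = TRUE)
  out <- lapply(kv, function(x) trimws(paste(x[-1], collapse = ":")))
  names(out) <- vapply(kv, function(x) trimws(x[1]), "")
  if (!is.null(out$fps)) out$fps <- as.numeric(out$fps)
  out
}

#' Load a video from an image sequence directory
#'
#' Reads all PNG/TIFF files in `path` in lexicographic order, decodes them to
#' float intensity matrices (0--255) and converts RGB frames to grayscale.
#' Labels are attached afterwards with [attach_labels()].
#'
#' @param path directory holding the frame images.
#' @param manifest named list (or path to a manifest file) with `video_id`,
#'   `subject_id`, `species`, `fps`.
#' @return a [labeled_video()] with all-neutral labels.
#' @export
load_image_sequence <- function(path, manifest) {
  if (is.character(manifest) && length(manifest) == 1L && file.exists(manifest))
    manifest <- read_manifest(manifest)
  files <- sort(list.files(path, pattern = "\\.(png|tiff?)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop("no frame images found in ", path, call. = FALSE)
  frames <- lapply(files, read_frame_file)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
    stop("frame ", basename(files[bad]), " has inconsistent size", call. = FALSE)
  }
  labeled_video(manifest$video_id, manifest$subject_id, manifest$species,
                frames, fps = manifest$fps %||% 30)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a per-frame action-unit label table
#'
#' Delimited text (comma) with a header row and columns `video_id`,
#' `frame_index` (0-based), `region` (`upper`/`lower`), `codes` ("+"-joined
#' raw codes, empty for neutral) and optionally `intensity`. One row per
#' frame per region; frames absent from the table are treated downstream as
#' neutral. The intensity column is parsed but not used by classification.
#'
#' @param path file path.
#' @return data frame with one row per (video, frame, region).
#' @export
read_label_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L)
    return(data.frame(video_id = character(0), frame_index = integer(0),
                      region = character(0), codes = character(0),
                      intensity = character(0), stringsAsFactors = FALSE))
  need <- c("video_id", "frame_index", "region", "codes")
  if (!all(need %in% names(df)))
    stop("label table missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  if (is.null(df$intensity)) df$intensity <- ""
  df$frame_index <- suppressWarnings(as.integer(df$frame_index))
  bad <- which(is.na(df$frame_index) | df$frame_index < 0L)
  if (length(bad))
    stop("invalid frame_index at line ", bad[1] + 1L, call. = FALSE)
  bad <- which(!df$region %in% c("upper", "lower"))
  if (length(bad))
    stop("unknown region \"", df$region[bad[1]], "\" at line ", bad[1] + 1L,
         call. = FALSE)
  df$codes[is.na(df$codes)] <- ""
  df[c("video_id", "frame_index", "region", "codes", "intensity")]
}

#' Write a per-frame label table
#'
#' Inverse of [read_label_table()] for its documented schema.
#'
#' @param labels data frame as returned by [read_label_table()].
#' @param path output file.
#' @export
write_label_table <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expand coded events into per-frame label rows
#'
#' Behavioural coding software exports events as (start, stop) frame
#' intervals; the classifier needs one row per frame. Intervals are
#' closed-open on frame indices: frames `start_frame` to `stop_frame - 1`.
#'
#' @param events data frame with columns `video_id`, `start_frame`,
#'   `stop_frame`, `region`, `codes` and optionally `intensity`.
#' @return per-frame label table (see [read_label_table()]).
#' @export
expand_label_events <- function(events) {
  if (!nrow(events))
    return(data.frame(video_id = character(0), frame_index = integer(0),
                      region = character(0), codes = character(0),
                      intensity = character(0), stringsAsFactors = FALSE))
  if (is.null(events$intensity)) events$intensity <- ""
  rows <- lapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    if (e$stop_frame <= e$start_frame) return(NULL)
    data.frame(video_id = e$video_id,
               frame_index = seq.int(e$start_frame, e$stop_frame - 1L),
               region = e$region, codes = e$codes, intensity = e$intensity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Attach harmonized labels from a label table to a video
#'
#' Rows of `label_table` matching the video's id are harmonized per frame and
#' region with [harmonize_labels()]; frames without a row get the region's
#' neutral class. Multiple rows for one (frame, region) contribute the union
#' of their codes.
#'
#' @param video a [labeled_video()].
#' @param label_table data frame from [read_label_table()].
#' @param drop_codes raw codes to delete globally before harmonization (e.g.
#'   `"AU45"` when blink annotations are unreliable for a corpus). Default:
#'   keep everything.
#' @return the video with its `labels` replaced.
#' @export
attach_labels <- function(video, label_table, drop_codes = character(0)) {
  n <- length(video$frames)
  tab <- label_table[label_table$video_id == video$video_id &
                       label_table$frame_index < n, , drop = FALSE]
  lab <- data.frame(frame = seq_len(n) - 1L,
                    upper = "UpperNone", lower = "LowerNone",
                    stringsAsFactors = FALSE)
  for (region in c("upper", "lower")) {
    sub <- tab[tab$region == region, , drop = FALSE]
    if (!nrow(sub)) next
    by_frame <- split(sub$codes, sub$frame_index)
    for (fi in names(by_frame)) {
      codes <- unique(unlist(lapply(by_frame[[fi]], parse_au_codes)))
      codes <- setdiff(codes, drop_codes)
      lab[[region]][as.integer(fi) + 1L] <- harmonize_labels(codes, region)
    }
  }
  video$labels <- lab
  video
}
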