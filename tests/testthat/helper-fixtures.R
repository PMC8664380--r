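# shared small fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

balanced_freqs <- function() {
  list(upper = c("UpperNone" = 0.4, "AU43_5" = 0.3, "AU1+2" = 0.3),
       lower = c("LowerNone" = 0.34, "AU25+26" = 0.22,
                 "AU25+26+18i" = 0.22, "AU25+26+16" = 0.22))
}

small_config <- function(...) {
  synthetic_config(image_size = c(64, 56), n_subjects = 2L,
                   videos_per_subject = 2L, frames_per_video = 40L,
                   class_frequencies = balanced_freqs(),
                   noise_sd = 0, seed = 42L, ...)
}

# aligned small synthetic dataset, cached
small_aligned <- function() {
  if (is.null(.fixture_env$small)) {
    g <- generate_dataset(small_config())
    .fixture_env$small <- list(
      raw = g$dataset, truth = g$truth,
      aligned = align_dataset(g$dataset, g$truth$landmarks),
      config = small_config())
  }
  .fixture_env$small
}

# a tiny database with arbitrary class counts (1-pixel images) for
# undersampling / partition logic tests
stub_database <- function(counts_by_class, region = "upper",
                          subject_id = "S01", video_id = "v1") {
  classes <- rep(names(counts_by_class), times = counts_by_class)
  n <- length(classes)
  structure(list(matrix = matrix(seq_len(n), ncol = 1),
                 meta = data.frame(video_id = rep(video_id, n),
                                   frame_index = seq_len(n) - 1L,
                                   subject_id = rep(subject_id, n),
                                   class = classes,
                                   stringsAsFactors = FALSE),
                 region = region, roi_shape = c(1L, 1L)),
            class = "image_database")
}

# smooth gradient image for warp round-trip tests
gradient_image <- function(h, w) {
  outer(seq_len(h), seq_len(w), function(r, c) 50 + r * 1.5 + c * 0.8 +
          10 * sin(r / 5) * cos(c / 7))
}

brute_force_knn <- function(train, labels, probe, k, metric, class_set) {
  d <- apply(train, 1, function(row) feature_distance(probe, row, metric))
  ord <- order(d, seq_along(d))
  nb <- ord[seq_len(k)]
  counts <- sapply(class_set, function(cl) sum(labels[nb] == cl))
  top <- which(counts == max(counts))
  if (length(top) > 1) {
    sums <- sapply(class_set[top], function(cl) sum(d[nb[labels[nb] == cl]]))
    top <- top[sums == min(sums)]
  }
  class_set[top[1]]
}
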