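#' Align every video of a dataset using annotated landmarks
#'
#' @param dataset an [au_dataset()].
#' @param landmarks named list of [landmark_set()]s, one per video id.
#' @return the dataset with all videos aligned.
#' @export
align_dataset <- function(dataset, landmarks) {
  dataset$videos <- lapply(dataset$videos, function(v)
    align_video(v, landmarks[[v$video_id]]))
  dataset
}

#' Run the full recognition pipeline on one region and score it per subject
#'
#' Convenience driver covering the standard evaluation path: build the
#' region's delta-image database from aligned videos, undersample balanced
#' training sets, form the requested cross-validation partitions, fit
#' eigenfaces per (balanced set, partition), classify with fixed
#' hyperparameters, and aggregate to a subject-level report. Intended for
#' end-to-end checks and small studies; use [grid_search()] for tuning.
#'
#' @param aligned_videos list of aligned [labeled_video()]s.
#' @param roi a [roi_spec()].
#' @param design `"across_subject"` or `"within_subject"`.
#' @param k,pc_expl_var,metric KNN hyperparameters.
#' @param n_sets number of balanced training sets.
#' @param seed seed for the undersampling.
#' @param min_train,min_test per-class inclusion thresholds for partitions.
#' @param eigenvalue_threshold passed to [fit_eigenfaces()].
#' @return list with `subject_report` (see [subject_level_report()]),
#'   `reports` (per partition x balanced set), `partitions`, `db`.
#' @export
evaluate_region_pipeline <- function(aligned_videos, roi,
                                     design = c("across_subject",
                                                "within_subject"),
                                     k = 3L, pc_expl_var = 90,
                                     metric = "euclidean",
                                     n_sets = 3L, seed = 1L,
                                     min_train = 20L, min_test = 5L,
                                     eigenvalue_threshold = 1e-6) {
  design <- match.arg(design)
  db <- build_database(aligned_videos, roi)
  classes <- au_target_classes(db$region)
  partitions <- if (design == "across_subject")
    make_across_subject_partitions(db, min_train, min_test)
  else make_within_subject_partitions(db, min_train, min_test)
  if (!length(partitions))
    stop("no partition satisfies the inclusion thresholds", call. = FALSE)
  balanced <- undersample_balanced(db, n_sets = n_sets, seed = seed)
  reports <- list(); subjects <- character(0)
  for (part in partitions) {
    for (bal in balanced) {
      train_rows <- intersect(bal$row_indices, part$train_rows)
      if (any(class_counts(db$meta, train_rows, classes) < 1L)) next
      model <- fit_eigenfaces(db$matrix[train_rows, , drop = FALSE],
                              eigenvalue_threshold)
      N <- select_num_components(model, pc_expl_var)
      Wtr <- project_faces(model, db$matrix[train_rows, , drop = FALSE], N)
      Wte <- project_faces(model, db$matrix[part$test_rows, , drop = FALSE], N)
      clf <- train_classifier(Wtr, db$meta$class[train_rows],
                              classifier_config("knn", k = k, metric = metric),
                              class_set = classes)
      rep <- evaluate_predictions(stats::predict(clf, Wte),
                                  db$meta$class[part$test_rows], classes)
      reports[[length(reports) + 1L]] <- rep
      subjects <- c(subjects,
                    db$meta$subject_id[part$test_rows[1]])
    }
  }
  if (!length(reports))
    stop("no evaluable (partition, balanced set) pair", call. = FALSE)
  list(subject_report = subject_level_report(subjects, reports),
       reports = reports, partitions = partitions, db = db)
}
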