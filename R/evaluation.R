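derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(index) * 7919) %% 2147483647)
}

#' Build class-balanced training sets by random undersampling
#'
#' The per-class size equals the smallest class count in the database: every
#' row of the smallest class is kept, and each larger class contributes a
#' uniform random sample without replacement of that size. Sets are drawn
#' independently; set `i` is fully determined by `(seed, i)`.
#'
#' @param db an `image_database` whose `meta$class` holds the three target
#'   classes.
#' @param n_sets number of balanced sets (the study protocol used 3--10
#'   depending on data volume).
#' @param seed integer seed.
#' @param classes the classes to balance over (default: all present).
#' @return list of `balanced_training_set` objects: `row_indices` (sorted),
#'   `per_class_count`, `seed`, `set_index`.
#' @export
undersample_balanced <- function(db, n_sets = 3L, seed = 1L,
                                 classes = NULL) {
  meta <- db$meta
  if (is.null(classes)) classes <- sort(unique(meta$class))
  by_class <- lapply(classes, function(cl) which(meta$class == cl))
  names(by_class) <- classes
  counts <- lengths(by_class)
  if (any(counts == 0L))
    stop("class with zero rows: ",
         paste(classes[counts == 0L], collapse = ", "), call. = FALSE)
  m <- min(counts)
  lapply(seq_len(n_sets), function(i) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(derive_seed(seed, i))
    idx <- unlist(lapply(by_class, function(rows)
      if (length(rows) == m) rows else sample(rows, m)))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    structure(list(row_indices = sort(unname(idx)), per_class_count = m,
                   seed = seed, set_index = i),
              class = "balanced_training_set")
  })
}

new_partition <- function(design, held_out, train_rows, test_rows,
                          split_id = NA_integer_) {
  structure(list(design = design, held_out_unit = held_out,
                 train_rows = train_rows, test_rows = test_rows,
                 split_id = split_id),
            class = "cv_partition")
}

class_counts <- function(meta, rows, classes) {
  vapply(classes, function(cl) sum(meta$class[rows] == cl), 0L)
}

#' Leave-one-video-out partitions within each subject
#'
#' For every subject, each of their videos is held out in turn; the training
#' pool is the subject's remaining videos. A partition is emitted only if
#' every target class has at least `min_train` training frames and at least
#' `min_test` frames in the held-out video.
#'
#' @param db an `image_database` restricted to the target classes.
#' @param min_train,min_test per-class inclusion thresholds (defaults 20
#'   and 5, the within-subject protocol values).
#' @return list of `cv_partition` objects (possibly empty).
#' @export
make_within_subject_partitions <- function(db, min_train = 20L, min_test = 5L) {
  meta <- db$meta
  classes <- au_target_classes(db$region)
  out <- list()
  for (subj in unique(meta$subject_id)) {
    vids <- unique(meta$video_id[meta$subject_id == subj])
    if (length(vids) < 2L) next
    for (v in vids) {
      test <- which(meta$video_id == v)
      train <- which(meta$subject_id == subj & meta$video_id != v)
      if (all(class_counts(meta, train, classes) >= min_train) &&
          all(class_counts(meta, test, classes) >= min_test))
        out[[length(out) + 1L]] <- new_partition("within_subject", v,
                                                 train, test)
    }
  }
  out
}

#' Leave-one-subject-out partitions
#'
#' Each subject is held out in turn; the training pool is all other
#' subjects' frames. Inclusion requires at least `min_train` training and
#' `min_test` test frames per class (defaults 150 and 50, the
#' across-subject protocol values).
#'
#' @inheritParams make_within_subject_partitions
#' @return list of `cv_partition` objects.
#' @export
make_across_subject_partitions <- function(db, min_train = 150L,
                                           min_test = 50L) {
  meta <- db$meta
  classes <- au_target_classes(db$region)
  out <- list()
  for (subj in unique(meta$subject_id)) {
    test <- which(meta$subject_id == subj)
    train <- which(meta$subject_id != subj)
    if (all(class_counts(meta, train, classes) >= min_train) &&
        all(class_counts(meta, test, classes) >= min_test))
      out[[length(out) + 1L]] <- new_partition("across_subject", subj,
                                               train, test)
  }
  out
}

largest_remainder_counts <- function(class_n, fraction) {
  target <- round(sum(class_n) * fraction)
  exact <- class_n * fraction
  base <- floor(exact)
  short <- target - sum(base)
  if (short > 0) {
    ord <- order(exact - base, decreasing = TRUE)   # stable: ties by position
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1L
  } else if (short < 0) {
    ord <- order(exact - base)
    base[ord[seq_len(-short)]] <- base[ord[seq_len(-short)]] - 1L
  }
  as.integer(base)
}

#' Repeated stratified holdout splits
#'
#' Splits a set of labelled rows `n_splits` times into a validation set
#' (1 - `test_fraction` of the data) and a test set (`test_fraction`),
#' stratified by class. Per-class test counts follow largest-remainder
#' rounding so the global test fraction is hit exactly whenever divisible.
#'
#' @param rows integer row indices into a database.
#' @param classes character class label per row.
#' @param n_splits number of random splits (the across-species protocol
#'   uses 100).
#' @param test_fraction fraction of rows in the test set (default 0.2).
#' @param seed integer seed; split `i` is determined by `(seed, i)`.
#' @return list of `cv_partition` objects (design `"holdout"`,
#'   `train_rows` = validation rows).
#' @export
make_holdout_splits <- function(rows, classes, n_splits = 100L,
                                test_fraction = 0.2, seed = 1L) {
  classes <- as.character(classes)
  stopifnot(length(rows) == length(classes))
  lev <- sort(unique(classes))
  per_class <- lapply(lev, function(cl) rows[classes == cl])
  n_cl <- lengths(per_class)
  if (any(n_cl < 5L))
    stop("class too small to stratify: ",
         paste(lev[n_cl < 5L], collapse = ", "), call. = FALSE)
  test_n <- largest_remainder_counts(n_cl, test_fraction)
  lapply(seq_len(n_splits), function(i) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(derive_seed(seed, i))
    test <- unlist(lapply(seq_along(lev), function(j)
      sample(per_class[[j]], test_n[j])))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    new_partition("holdout", NA_character_, sort(setdiff(rows, test)),
                  sort(test), split_id = i)
  })
}

#' Score predictions against ground truth
#'
#' Builds the 3 x 3 confusion matrix (rows = predicted, columns = true),
#' per-class sensitivity (true positive rate: diagonal over column sum),
#' their mean (the model-selection criterion), and overall accuracy
#' (trace over total). A class absent from the truth has undefined
#' sensitivity; it is reported as `NA` and excluded from the mean with a
#' warning.
#'
#' @param predicted,truth character vectors of equal positive length.
#' @param class_order the classes, in fixed order.
#' @return object of class `performance_report`: `confusion`,
#'   `per_class_tpr`, `avg_tpr`, `accuracy`, `n_test`.
#' @export
evaluate_predictions <- function(predicted, truth,
                                 class_order = sort(unique(truth))) {
  if (length(predicted) != length(truth) || !length(truth))
    stop("predicted and truth must have equal positive length", call. = FALSE)
  if (!all(c(predicted, truth) %in% class_order))
    stop("label outside class_order", call. = FALSE)
  pf <- factor(predicted, levels = class_order)
  tf <- factor(truth, levels = class_order)
  confusion <- table(predicted = pf, true = tf)
  col_n <- colSums(confusion)
  tpr <- ifelse(col_n > 0, diag(confusion) / col_n, NA_real_)
  if (anyNA(tpr))
    warning("class(es) absent from truth excluded from avg TPR: ",
            paste(class_order[is.na(tpr)], collapse = ", "), call. = FALSE)
  structure(list(confusion = unclass(confusion),
                 per_class_tpr = stats::setNames(tpr, class_order),
                 avg_tpr = mean(tpr, na.rm = TRUE),
                 accuracy = sum(diag(confusion)) / length(truth),
                 n_test = length(truth)),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> n = %d, accuracy %.3f, avg TPR %.3f\n",
              x$n_test, x$accuracy, x$avg_tpr))
  print(round(x$confusion, 2))
  invisible(x)
}

#' Hyperparameter grid for classifier tuning
#'
#' @param k_values KNN neighbour counts (default 1..12).
#' @param pc_expl_var_values cumulative explained-variance targets in percent
#'   (default 50..95 by 5).
#' @param metrics distance metrics to try.
#' @param set_indices balanced-set indices to try (default: all supplied).
#' @return object of class `parameter_grid`.
#' @export
parameter_grid <- function(k_values = 1:12,
                           pc_expl_var_values = seq(50, 95, by = 5),
                           metrics = c("euclidean", "cosine"),
                           set_indices = NULL) {
  structure(list(k_values = as.integer(k_values),
                 pc_expl_var_values = pc_expl_var_values,
                 metrics = metrics, set_indices = set_indices),
            class = "parameter_grid")
}

# Evaluate one (balanced set, partition) eigenspace across the grid.
# Returns rows of the performance surface.
grid_eval_cell <- function(db, bal, part, grid, classifier_kind,
                           eigenvalue_threshold) {
  classes <- au_target_classes(db$region)
  train_rows <- intersect(bal$row_indices, part$train_rows)
  if (any(class_counts(db$meta, train_rows, classes) < 1L) ||
      length(train_rows) < 2L)
    return(NULL)
  model <- fit_eigenfaces(db$matrix[train_rows, , drop = FALSE],
                          eigenvalue_threshold)
  train_lab <- db$meta$class[train_rows]
  test_lab <- db$meta$class[part$test_rows]
  full_train <- project_faces(model, db$matrix[train_rows, , drop = FALSE])
  full_test <- project_faces(model, db$matrix[part$test_rows, , drop = FALSE])
  rows <- list()
  for (pc in grid$pc_expl_var_values) {
    N <- select_num_components(model, pc)
    Wtr <- full_train$weights[, seq_len(N), drop = FALSE]
    Wte <- full_test$weights[, seq_len(N), drop = FALSE]
    if (classifier_kind == "svm") {
      clf <- train_classifier(Wtr, train_lab,
                              classifier_config("svm"), class_set = classes)
      rep <- evaluate_predictions(stats::predict(clf, Wte), test_lab, classes)
      rows[[length(rows) + 1L]] <- data.frame(
        set_index = bal$set_index, pc_expl_var = pc, metric = "linear",
        k = NA_integer_, n_components = N, avg_tpr = rep$avg_tpr,
        accuracy = rep$accuracy, stringsAsFactors = FALSE)
      next
    }
    for (metric in grid$metrics) {
      D <- distance_matrix(Wte, Wtr, metric)
      ks <- grid$k_values[grid$k_values <= nrow(Wtr)]
      votes <- knn_votes(D, train_lab, ks, classes)
      for (j in seq_along(ks)) {
        rep <- evaluate_predictions(votes[, j], test_lab, classes)
        rows[[length(rows) + 1L]] <- data.frame(
          set_index = bal$set_index, pc_expl_var = pc, metric = metric,
          k = ks[j], n_components = N, avg_tpr = rep$avg_tpr,
          accuracy = rep$accuracy, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Grid search over eigenspace and classifier hyperparameters
#'
#' For every balanced training set and grid point, eigenfaces are refitted
#' on the balanced training rows that fall inside each partition's training
#' pool, the dimensionality is chosen by the explained-variance target, a
#' classifier is trained and scored on the partition's test rows, and the
#' score is the mean average TPR over partitions. The winner is the grid
#' point with the highest score; ties break toward smaller `k`, then smaller
#' `pc_expl_var`, then euclidean before cosine, then smaller set index.
#'
#' @param db an `image_database`.
#' @param balanced_sets list from [undersample_balanced()].
#' @param partitions list of `cv_partition`s.
#' @param grid a [parameter_grid()].
#' @param classifier_kind `"knn"` or `"svm"`.
#' @param eigenvalue_threshold passed to [fit_eigenfaces()].
#' @return list with `best` (named list: `k`, `pc_expl_var`, `metric`,
#'   `set_index`, `score`) and `surface` (data frame of all grid points,
#'   score averaged over partitions).
#' @export
grid_search <- function(db, balanced_sets, partitions,
                        grid = parameter_grid(),
                        classifier_kind = c("knn", "svm"),
                        eigenvalue_threshold = 1e-6) {
  classifier_kind <- match.arg(classifier_kind)
  if (!length(partitions)) stop("no partitions supplied", call. = FALSE)
  sets <- balanced_sets
  if (!is.null(grid$set_indices))
    sets <- sets[vapply(sets, `[[`, 0L, "set_index") %in% grid$set_indices]
  cells <- list()
  for (bal in sets)
    for (part in partitions) {
      cell <- grid_eval_cell(db, bal, part, grid, classifier_kind,
                             eigenvalue_threshold)
      if (!is.null(cell)) cells[[length(cells) + 1L]] <- cell
    }
  if (!length(cells)) stop("no evaluable grid cells", call. = FALSE)
  all_rows <- do.call(rbind, cells)
  all_rows$k[is.na(all_rows$k)] <- 0L           # svm: k not applicable
  surface <- stats::aggregate(cbind(avg_tpr, accuracy) ~
                                set_index + pc_expl_var + metric + k,
                              data = all_rows, FUN = mean)
  metric_rank <- match(surface$metric, c("euclidean", "cosine", "linear"))
  ord <- order(-surface$avg_tpr, surface$k, surface$pc_expl_var, metric_rank,
               surface$set_index)
  surface <- surface[ord, c("set_index", "pc_expl_var", "metric", "k",
                            "avg_tpr", "accuracy")]
  rownames(surface) <- NULL
  best <- surface[1, ]
  list(best = list(k = best$k, pc_expl_var = best$pc_expl_var,
                   metric = best$metric, set_index = best$set_index,
                   score = best$avg_tpr),
       surface = surface)
}

#' Aggregate video-level reports to subject level
#'
#' Generalization results are reported per subject: video-level metrics are
#' first averaged (unweighted) within each subject, then summarized across
#' subjects as mean and standard error. Confusion matrices are averaged the
#' same way.
#'
#' @param subject_ids character vector, one per report.
#' @param reports list of `performance_report`s, parallel to `subject_ids`.
#' @return list with `per_subject` (data frame: subject, avg_tpr, accuracy),
#'   `mean_avg_tpr`, `se_avg_tpr`, `mean_accuracy`, `se_accuracy`,
#'   `mean_confusion`.
#' @export
subject_level_report <- function(subject_ids, reports) {
  stopifnot(length(subject_ids) == length(reports), length(reports) >= 1L)
  subjects <- unique(subject_ids)
  per <- lapply(subjects, function(s) {
    rs <- reports[subject_ids == s]
    list(avg_tpr = mean(vapply(rs, `[[`, 0, "avg_tpr")),
         accuracy = mean(vapply(rs, `[[`, 0, "accuracy")),
         confusion = Reduce(`+`, lapply(rs, `[[`, "confusion")) / length(rs))
  })
  avg_tpr <- vapply(per, `[[`, 0, "avg_tpr")
  accuracy <- vapply(per, `[[`, 0, "accuracy")
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  list(per_subject = data.frame(subject_id = subjects, avg_tpr = avg_tpr,
                                accuracy = accuracy, stringsAsFactors = FALSE),
       mean_avg_tpr = mean(avg_tpr), se_avg_tpr = se(avg_tpr),
       mean_accuracy = mean(accuracy), se_accuracy = se(accuracy),
       mean_confusion = Reduce(`+`, lapply(per, `[[`, "confusion")) /
         length(per))
}

#' Save a performance report (with provenance) as structured text
#'
#' @param report a `performance_report`.
#' @param path JSON file path.
#' @param config optional named list of configuration/seed provenance.
#' @export
save_report <- function(report, path, config = list()) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite required to serialize reports", call. = FALSE)
  out <- list(confusion = report$confusion,
              per_class_tpr = as.list(report$per_class_tpr),
              avg_tpr = report$avg_tpr, accuracy = report$accuracy,
              n_test = report$n_test, config = config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
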