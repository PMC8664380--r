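test_that("balanced sets keep the smallest class whole and sample the rest", {
  db <- stub_database(c("AU1+2" = 8L, "AU43_5" = 30L, "UpperNone" = 50L))
  sets <- undersample_balanced(db, n_sets = 4, seed = 7)
  small_rows <- which(db$meta$class == "AU1+2")
  for (s in sets) {
    expect_identical(s$per_class_count, 8L)
    expect_length(s$row_indices, 24L)
    expect_false(anyDuplicated(s$row_indices) > 0)
    counts <- table(db$meta$class[s$row_indices])
    expect_true(all(counts == 8L))
    expect_true(all(small_rows %in% s$row_indices))
  }
  # seed reproducibility, set-wise
  again <- undersample_balanced(db, n_sets = 4, seed = 7)
  for (i in 1:4)
    expect_identical(sets[[i]]$row_indices, again[[i]]$row_indices)
  different <- undersample_balanced(db, n_sets = 1, seed = 8)
  expect_false(identical(sets[[1]]$row_indices, different[[1]]$row_indices))
  # already balanced: every row kept
  db2 <- stub_database(c(A = 5L, B = 5L, C = 5L))
  expect_identical(undersample_balanced(db2, 2, 1)[[1]]$row_indices, 1:15)
  expect_error(undersample_balanced(stub_database(c(A = 3L)), 1, 1,
                                    classes = c("A", "B")), "zero rows")
})

test_that("undersampling draws do not disturb the global RNG stream", {
  db <- stub_database(c(A = 3L, B = 9L, C = 9L))
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(undersample_balanced(db, 2, 1))
  expect_identical(stats::runif(1), before)
})

test_that("within-subject partitions hold out one video with thresholds", {
  meta <- rbind(
    stub_database(c("UpperNone" = 30L, "AU1+2" = 30L, "AU43_5" = 30L),
                  video_id = "a1")$meta,
    stub_database(c("UpperNone" = 30L, "AU1+2" = 30L, "AU43_5" = 30L),
                  video_id = "a2")$meta)
  db <- stub_database(c(A = 1L)); db$meta <- meta
  db$matrix <- matrix(0, nrow(meta), 1)
  parts <- make_within_subject_partitions(db)
  expect_length(parts, 2L)  # each video once, enumerated threshold check
  for (p in parts) {
    expect_length(intersect(p$train_rows, p$test_rows), 0L)
    expect_true(all(db$meta$video_id[p$test_rows] == p$held_out_unit))
  }
  # held-out video with 4 frames of one class is excluded (min_test = 5),
  # while the other two videos still clear both thresholds
  meta3 <- rbind(meta,
                 stub_database(c("UpperNone" = 30L, "AU1+2" = 30L,
                                 "AU43_5" = 4L), video_id = "a3")$meta)
  db$meta <- meta3; db$matrix <- matrix(0, nrow(meta3), 1)
  parts <- make_within_subject_partitions(db)
  expect_identical(sort(sapply(parts, `[[`, "held_out_unit")),
                   c("a1", "a2"))
  # single-video subjects produce no partitions
  db3 <- stub_database(c("UpperNone" = 30L, "AU1+2" = 30L, "AU43_5" = 30L))
  expect_length(make_within_subject_partitions(db3), 0L)
})

test_that("across-subject partitions reproduce brute-force threshold checks", {
  counts <- list(S1 = c(200L, 200L, 200L), S2 = c(200L, 200L, 200L),
                 S3 = c(200L, 49L, 200L), S4 = c(160L, 160L, 160L))
  classes <- au_target_classes("upper")
  meta <- do.call(rbind, lapply(names(counts), function(s) {
    cc <- counts[[s]]; names(cc) <- classes
    stub_database(cc, subject_id = s, video_id = paste0(s, "_v"))$meta
  }))
  db <- stub_database(c(A = 1L)); db$meta <- meta
  db$matrix <- matrix(0, nrow(meta), 1)
  parts <- make_across_subject_partitions(db)
  # brute-force oracle over subjects
  want <- Filter(function(s) {
    test <- meta$subject_id == s
    all(sapply(classes, function(cl) sum(test & meta$class == cl)) >= 50) &&
      all(sapply(classes, function(cl) sum(!test & meta$class == cl)) >= 150)
  }, names(counts))
  expect_identical(sapply(parts, `[[`, "held_out_unit"), want)
  expect_false("S3" %in% sapply(parts, `[[`, "held_out_unit"))
  for (p in parts)
    expect_length(intersect(p$train_rows, p$test_rows), 0L)
})

test_that("stratified holdout splits use largest-remainder class counts", {
  rows <- 1:50
  classes <- rep(c("A", "B", "C"), times = c(25, 15, 10))
  splits <- make_holdout_splits(rows, classes, n_splits = 5, seed = 3)
  for (sp in splits) {
    expect_length(sp$test_rows, 10L)
    expect_identical(sort(c(sp$train_rows, sp$test_rows)), rows)
    expect_length(intersect(sp$train_rows, sp$test_rows), 0L)
    tc <- table(classes[sp$test_rows])
    expect_identical(as.integer(tc[c("A", "B", "C")]), c(5L, 3L, 2L))
  }
  # determinism given the seed
  again <- make_holdout_splits(rows, classes, n_splits = 5, seed = 3)
  expect_identical(splits[[2]]$test_rows, again[[2]]$test_rows)
  # indivisible case still hits the rounded global fraction
  classes2 <- rep(c("A", "B", "C"), times = c(26, 14, 9))
  sp2 <- make_holdout_splits(1:49, classes2, n_splits = 1, seed = 1)[[1]]
  expect_length(sp2$test_rows, round(49 * 0.2))
  expect_error(make_holdout_splits(1:6, rep(c("A", "B"), c(4, 2)),
                                   n_splits = 1), "too small")
})

test_that("performance reports match hand-counted confusion arithmetic", {
  classes <- c("A", "B", "C")
  # confusion (pred x true) [[5,1,2],[0,4,0],[0,0,3]]
  truth <- c(rep("A", 5), "B", rep("C", 2), rep("B", 4), rep("C", 3))
  pred <- c(rep("A", 8), rep("B", 4), rep("C", 3))
  rep1 <- evaluate_predictions(pred, truth, classes)
  expect_identical(unclass(rep1$confusion)[1, ], c(A = 5L, B = 1L, C = 2L))
  expect_equal(unname(rep1$per_class_tpr), c(1.0, 0.8, 0.6))
  expect_equal(rep1$avg_tpr, 0.8)
  expect_equal(rep1$accuracy, 12 / 15)
  # perfect predictions
  perf <- evaluate_predictions(rep(classes, each = 5), rep(classes, each = 5),
                               classes)
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$avg_tpr, 1)
  expect_equal(diag(perf$confusion), c(A = 5L, B = 5L, C = 5L))
  # column sums equal true class counts
  expect_equal(colSums(rep1$confusion), c(A = 5, B = 5, C = 5))
  # missing true class is excluded from the mean with a warning
  expect_warning(r2 <- evaluate_predictions(c("A", "B"), c("A", "A"),
                                            classes), "absent")
  expect_true(is.na(r2$per_class_tpr["B"]))
  expect_equal(r2$avg_tpr, mean(c(0.5), na.rm = TRUE))
  expect_error(evaluate_predictions("A", c("A", "B"), classes), "length")
})

test_that("uniform random predictions on balanced data approach 1/3", {
  set.seed(123)
  classes <- c("A", "B", "C")
  n <- 30000
  truth <- rep(classes, each = n / 3)
  pred <- sample(classes, n, replace = TRUE)
  r <- evaluate_predictions(pred, truth, classes)
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(r$accuracy - 1 / 3), 3 * se)
})

test_that("grid search scores every point and breaks ties toward smaller k", {
  fx <- small_aligned()
  db <- build_database(fx$aligned$videos, synthetic_rois(fx$config)$upper)
  bal <- undersample_balanced(db, n_sets = 2, seed = 1)
  parts <- make_within_subject_partitions(db, min_train = 3, min_test = 2)
  expect_gt(length(parts), 0)
  grid <- parameter_grid(k_values = c(1L, 3L), pc_expl_var_values = c(60, 90),
                         metrics = "euclidean")
  res <- grid_search(db, bal, parts, grid, "knn")
  expect_identical(nrow(res$surface), 2L * 2L * 2L)  # k x pcvar x sets
  expect_true(all(res$surface$avg_tpr >= 0 & res$surface$avg_tpr <= 1))
  # the returned best equals independent re-evaluation via the surface
  expect_equal(res$best$score, max(res$surface$avg_tpr))
  top <- res$surface[res$surface$avg_tpr == res$best$score, ]
  expect_identical(res$best$k, min(top$k))
  # single-point grid returns that point
  one <- grid_search(db, bal[1], parts,
                     parameter_grid(k_values = 1L, pc_expl_var_values = 90,
                                    metrics = "euclidean"), "knn")
  expect_identical(nrow(one$surface), 1L)
  expect_identical(one$best$k, 1L)
})

test_that("subject-level aggregation averages videos before subjects", {
  conf <- matrix(c(5L, 0L, 0L, 0L, 5L, 0L, 0L, 0L, 5L), 3, 3)
  mk <- function(acc, tpr) structure(
    list(confusion = conf, per_class_tpr = rep(tpr, 3), avg_tpr = tpr,
         accuracy = acc, n_test = 15L), class = "performance_report")
  out <- subject_level_report(c("s1", "s1", "s2"),
                              list(mk(0.6, 0.5), mk(0.8, 0.7), mk(1, 1)))
  expect_equal(out$per_subject$accuracy, c(0.7, 1))
  expect_equal(out$mean_accuracy, 0.85)
  expect_equal(out$mean_avg_tpr, mean(c(0.6, 1)))
  # permutation invariance
  out2 <- subject_level_report(c("s2", "s1", "s1"),
                               list(mk(1, 1), mk(0.8, 0.7), mk(0.6, 0.5)))
  expect_equal(out2$mean_accuracy, out$mean_accuracy)
  # one video per subject: subject report equals the video report
  out3 <- subject_level_report("s1", list(mk(0.6, 0.5)))
  expect_equal(out3$per_subject$avg_tpr, 0.5)
})

test_that("grid-search training pools never leak test rows", {
  fx <- small_aligned()
  db <- build_database(fx$aligned$videos, synthetic_rois(fx$config)$lower)
  bal <- undersample_balanced(db, n_sets = 2, seed = 2)
  within <- make_within_subject_partitions(db, min_train = 3, min_test = 2)
  across <- make_across_subject_partitions(db, min_train = 5, min_test = 5)
  hold <- make_holdout_splits(seq_len(nrow(db$meta)), db$meta$class,
                              n_splits = 3, seed = 1)
  for (p in c(within, across, hold)) {
    expect_length(intersect(p$train_rows, p$test_rows), 0L)
    for (b in bal)
      expect_length(intersect(intersect(b$row_indices, p$train_rows),
                              p$test_rows), 0L)
  }
})
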