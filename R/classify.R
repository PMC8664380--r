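#' Classifier configuration
#'
#' @param kind `"knn"` or `"svm"`.
#' @param k number of nearest neighbours (KNN only; the tuning grid uses
#'   1--12).
#' @param metric `"euclidean"` or `"cosine"` (KNN only).
#' @param cost regularization constant of the linear SVM (one-vs-one
#'   multiclass).
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(kind = c("knn", "svm"), k = 1L,
                              metric = c("euclidean", "cosine"), cost = 1) {
  kind <- match.arg(kind)
  metric <- match.arg(metric)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  structure(list(kind = kind, k = as.integer(k), metric = metric, cost = cost),
            class = "classifier_config")
}

#' Distance between feature vectors
#'
#' `euclidean`: the L2 norm of the difference. `cosine`: one minus the cosine
#' of the angle, `1 - (u . v) / (||u|| ||v||)`; both vectors must have
#' nonzero norm.
#'
#' @param u,v numeric vectors of equal length.
#' @param metric `"euclidean"` or `"cosine"`.
#' @return non-negative scalar.
#' @export
feature_distance <- function(u, v, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (length(u) != length(v)) stop("length mismatch", call. = FALSE)
  if (metric == "euclidean") return(sqrt(sum((u - v)^2)))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine distance undefined for a zero vector", call. = FALSE)
  1 - sum(u * v) / (nu * nv)
}

# n_test x n_train distance matrix, vectorized
distance_matrix <- function(probes, train, metric) {
  if (metric == "euclidean") {
    d2 <- outer(rowSums(probes^2), rowSums(train^2), `+`) -
      2 * tcrossprod(probes, train)
    sqrt(pmax(d2, 0))
  } else {
    np <- sqrt(rowSums(probes^2)); nt <- sqrt(rowSums(train^2))
    if (any(np == 0) || any(nt == 0))
      stop("cosine distance undefined for a zero vector", call. = FALSE)
    1 - tcrossprod(probes / np, train / nt)
  }
}

#' Train an action-unit classifier on eigenspace features
#'
#' KNN stores the training set verbatim. The SVM standardizes features by
#' the training mean/SD and fits linear one-vs-one decision functions
#' (through \pkg{e1071}), which is deterministic for a fixed training set.
#' All three target classes of the region must be represented.
#'
#' @param features a `projected_features` (or n x N weight matrix).
#' @param labels character vector of n class labels.
#' @param config a [classifier_config()].
#' @param class_set the classes the classifier distinguishes, in fixed
#'   tie-break order (default: the distinct labels in the order of
#'   [au_target_classes()] if they match a region, else sorted).
#' @param eigen_ref optional [model_fingerprint()] of the eigenface model the
#'   features came from; checked at prediction time when supplied.
#' @return object of class `trained_classifier`.
#' @export
train_classifier <- function(features, labels, config = classifier_config(),
                             class_set = NULL, eigen_ref = NULL) {
  W <- if (inherits(features, "projected_features")) features$weights
       else as.matrix(features)
  labels <- as.character(labels)
  if (nrow(W) != length(labels))
    stop("feature/label length mismatch", call. = FALSE)
  if (is.null(class_set)) {
    for (r in c("upper", "lower"))
      if (setequal(unique(labels), au_target_classes(r)))
        class_set <- au_target_classes(r)
    if (is.null(class_set)) class_set <- sort(unique(labels))
  }
  missing <- setdiff(class_set, labels)
  if (length(missing))
    stop("class(es) absent from training labels: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (config$kind == "knn" && nrow(W) < config$k)
    stop("fewer training rows than k", call. = FALSE)
  fit <- NULL
  scale_mu <- scale_sd <- NULL
  if (config$kind == "svm") {
    scale_mu <- colMeans(W)
    scale_sd <- apply(W, 2, stats::sd)
    scale_sd[scale_sd == 0] <- 1
    Ws <- sweep(sweep(W, 2, scale_mu), 2, scale_sd, "/")
    fit <- e1071::svm(Ws, factor(labels, levels = class_set),
                      kernel = "linear", cost = config$cost, scale = FALSE)
  }
  structure(list(config = config, train_features = W, train_labels = labels,
                 class_set = class_set, eigen_ref = eigen_ref, svm_fit = fit,
                 scale_mu = scale_mu, scale_sd = scale_sd),
            class = "trained_classifier")
}

# KNN votes for several k at once; returns n_probes x length(ks) label matrix.
# Neighbour ties at the k-th radius are included by smallest training index
# (the order() secondary key); class vote ties are broken by smallest summed
# distance among the tied classes, then by fixed class_set order.
knn_votes <- function(D, train_labels, ks, class_set) {
  n <- nrow(D)
  out <- matrix(NA_character_, n, length(ks))
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_along(train_labels))
    for (j in seq_along(ks)) {
      nb <- ord[seq_len(ks[j])]
      lab <- train_labels[nb]
      counts <- vapply(class_set, function(cl) sum(lab == cl), 0L)
      top <- which(counts == max(counts))
      if (length(top) > 1L) {
        sums <- vapply(class_set[top], function(cl) {
          s <- sum(D[i, nb[lab == cl]])
          if (counts[cl] == 0L) Inf else s
        }, 0)
        top <- top[sums == min(sums)]
      }
      out[i, j] <- class_set[top[1]]
    }
  }
  out
}

#' Predict action-unit classes for probe features
#'
#' KNN takes a majority vote among the k nearest training rows under the
#' configured metric; vote ties are broken by the smallest summed distance
#' among the tied classes, then by the fixed class order. The SVM uses
#' one-vs-one voting.
#'
#' @param object a `trained_classifier`.
#' @param probes a `projected_features` (or matrix) with the same width as
#'   the training features.
#' @param eigen_model optional `eigen_model`; when both this and the stored
#'   `eigen_ref` are present, prediction refuses to run on a mismatching
#'   model.
#' @param ... unused.
#' @return character vector of predicted classes.
#' @export
predict.trained_classifier <- function(object, probes, eigen_model = NULL, ...) {
  W <- if (inherits(probes, "projected_features")) probes$weights
       else as.matrix(probes)
  if (ncol(W) != ncol(object$train_features))
    stop("probe width does not match training features", call. = FALSE)
  if (!is.null(eigen_model) && !is.null(object$eigen_ref) &&
      !identical(model_fingerprint(eigen_model), object$eigen_ref))
    stop("eigenface model fingerprint mismatch", call. = FALSE)
  if (object$config$kind == "knn") {
    D <- distance_matrix(W, object$train_features, object$config$metric)
    return(drop(knn_votes(D, object$train_labels, object$config$k,
                          object$class_set)))
  }
  Ws <- sweep(sweep(W, 2, object$scale_mu), 2, object$scale_sd, "/")
  as.character(stats::predict(object$svm_fit, Ws))
}

#' Save / load a trained classifier
#'
#' Binary container holding features, labels, config and the eigenface model
#' fingerprint.
#'
#' @param clf a `trained_classifier`.
#' @param path RDS file path.
#' @export
save_classifier <- function(clf, path) {
  saveRDS(clf, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) readRDS(path)
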