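#' Fit an eigenface model to a delta-image database
#'
#' Snapshot PCA: the rows are zero-meaned and the eigendecomposition is taken
#' of the n x n Gram matrix (divided by n - 1, the unbiased sample-covariance
#' convention) whenever n < p, which is the usual regime for face images.
#' Eigenvectors are mapped back to pixel space, normalized to unit length,
#' and components whose eigenvalue falls below `eigenvalue_threshold` are
#' eliminated. Pixel values are kept on the native 0--255 scale, so the
#' default threshold is meaningful on that scale. The sign of each component
#' is fixed by making its largest-magnitude element positive, so serialized
#' models are comparable across platforms.
#'
#' @param db an `image_database` (or a plain n x p matrix), n >= 2.
#' @param eigenvalue_threshold components with eigenvalue below this are
#'   dropped (default `1e-6`).
#' @return object of class `eigen_model`: `mean_vector` (length p),
#'   `components` (m x p, rows orthonormal, descending eigenvalue),
#'   `eigenvalues`, `explained_ratio` (normalized over the retained
#'   components), `region`, `roi_shape`.
#' @export
fit_eigenfaces <- function(db, eigenvalue_threshold = 1e-6) {
  X <- if (inherits(db, "image_database")) db$matrix else as.matrix(db)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 images to fit eigenfaces", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (n < p) {
    G <- tcrossprod(Xc) / (n - 1)
    e <- eigen(G, symmetric = TRUE)
    keep <- which(e$values >= eigenvalue_threshold)
    if (!length(keep))
      stop("degenerate data: all eigenvalues below threshold", call. = FALSE)
    comps <- crossprod(Xc, e$vectors[, keep, drop = FALSE])
    comps <- sweep(comps, 2, sqrt(colSums(comps^2)), "/")
    vals <- e$values[keep]
  } else {
    S <- crossprod(Xc) / (n - 1)
    e <- eigen(S, symmetric = TRUE)
    keep <- which(e$values >= eigenvalue_threshold)
    if (!length(keep))
      stop("degenerate data: all eigenvalues below threshold", call. = FALSE)
    comps <- e$vectors[, keep, drop = FALSE]
    vals <- e$values[keep]
  }
  comps <- t(comps)                               # m x p
  flip <- apply(comps, 1, function(r) sign(r[which.max(abs(r))]))
  comps <- comps * flip
  structure(list(mean_vector = mu,
                 components = comps,
                 eigenvalues = vals,
                 explained_ratio = vals / sum(vals),
                 region = if (inherits(db, "image_database")) db$region else NA,
                 roi_shape = if (inherits(db, "image_database")) db$roi_shape
                             else NULL,
                 threshold = eigenvalue_threshold),
            class = "eigen_model")
}

#' @export
print.eigen_model <- function(x, ...) {
  cat(sprintf("<eigen_model %s> %d components over %d pixels; top eigenvalue %.4g\n",
              x$region, nrow(x$components), ncol(x$components),
              x$eigenvalues[1]))
  invisible(x)
}

#' Number of components needed for a cumulative explained variance
#'
#' @param model an `eigen_model`.
#' @param pc_expl_var target cumulative explained variance, in percent
#'   (`(0, 100]`; the hyperparameter grid uses 50--95).
#' @return the smallest N whose leading components cumulatively explain at
#'   least `pc_expl_var` percent of the retained variance.
#' @export
select_num_components <- function(model, pc_expl_var) {
  if (pc_expl_var <= 0 || pc_expl_var > 100)
    stop("pc_expl_var must be in (0, 100]", call. = FALSE)
  cum <- cumsum(model$explained_ratio)
  which(cum >= pc_expl_var / 100 - 1e-12)[1]
}

#' Project images onto the leading eigenfaces
#'
#' @param model an `eigen_model`.
#' @param images n x p matrix of flattened images (or an `image_database`).
#' @param n_components number of leading components N (<= model size).
#' @return object of class `projected_features`: `weights` (n x N) and
#'   `component_count`.
#' @export
project_faces <- function(model, images, n_components = nrow(model$components)) {
  X <- if (inherits(images, "image_database")) images$matrix else
    if (is.matrix(images)) images else matrix(images, nrow = 1)
  m <- nrow(model$components)
  if (n_components > m) stop("n_components exceeds model size", call. = FALSE)
  if (ncol(X) != ncol(model$components))
    stop("image row length does not match model", call. = FALSE)
  W <- sweep(X, 2, model$mean_vector) %*%
    t(model$components[seq_len(n_components), , drop = FALSE])
  structure(list(weights = W, component_count = n_components),
            class = "projected_features")
}

#' Reconstruct images from eigenface weights
#'
#' @param model an `eigen_model`.
#' @param features a `projected_features` (or plain weight matrix).
#' @return n x p matrix `mean + weights %*% components[1..N, ]`.
#' @export
reconstruct_faces <- function(model, features) {
  W <- if (inherits(features, "projected_features")) features$weights
       else as.matrix(features)
  if (ncol(W) > nrow(model$components))
    stop("feature width exceeds model size", call. = FALSE)
  sweep(W %*% model$components[seq_len(ncol(W)), , drop = FALSE],
        2, model$mean_vector, `+`)
}

#' Visualize what one eigenface encodes by sweeping its weight
#'
#' For each step s, the image `mean + (mean_weight + s * sd_weight) *
#' component` is formed, where `mean_weight` and `sd_weight` are the mean and
#' standard deviation of the training weights on that component. The
#' resulting sequence morphs the mean face along the chosen component.
#'
#' @param model an `eigen_model` with a known `roi_shape`.
#' @param pc_index 1-based component index.
#' @param training_features `projected_features` of the training set
#'   (covering at least `pc_index` components).
#' @param sd_steps weight offsets in SD units (default -3..+3, step 1).
#' @return list of images (matrices of `roi_shape`), one per step.
#' @export
eigenface_sweep <- function(model, pc_index, training_features,
                            sd_steps = -3:3) {
  if (pc_index < 1 || pc_index > nrow(model$components))
    stop("pc_index out of range", call. = FALSE)
  w <- training_features$weights[, pc_index]
  mw <- mean(w); sdw <- stats::sd(w)
  comp <- model$components[pc_index, ]
  lapply(sd_steps, function(s)
    unflatten_image(model$mean_vector + (mw + s * sdw) * comp,
                    model$roi_shape))
}

#' Fingerprint of an eigenface model
#'
#' A cheap deterministic checksum used to tie trained classifiers to the
#' model whose eigenspace their features live in.
#'
#' @param model an `eigen_model`.
#' @return character scalar.
#' @export
model_fingerprint <- function(model) {
  paste(nrow(model$components), ncol(model$components),
        formatC(sum(model$eigenvalues), format = "g", digits = 12),
        formatC(sum(model$mean_vector), format = "g", digits = 12),
        sep = ":")
}

#' Save / load an eigenface model
#'
#' Binary array container (RDS) with a plain-text header alongside stating
#' region, ROI shape, threshold and fingerprint.
#'
#' @param model an `eigen_model`.
#' @param prefix path prefix; writes `<prefix>_model.rds`, `<prefix>_model.txt`.
#' @export
save_eigen_model <- function(model, prefix) {
  saveRDS(unclass(model), paste0(prefix, "_model.rds"))
  writeLines(c(paste0("region: ", model$region),
               paste0("roi_shape: ", paste(model$roi_shape, collapse = "x")),
               paste0("threshold: ", model$threshold),
               paste0("fingerprint: ", model_fingerprint(model))),
             paste0(prefix, "_model.txt"))
  invisible(prefix)
}

#' @rdname save_eigen_model
#' @export
load_eigen_model <- function(prefix) {
  structure(readRDS(paste0(prefix, "_model.rds")), class = "eigen_model")
}
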