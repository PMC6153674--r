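# Classical baseline: joint HSV colour histograms -> PCA -> Gaussian-kernel
# SVM. Establishes that ablation detection is not solved by global colour
# statistics alone.

#' Joint HSV colour histogram of a frame
#'
#' Converts the frame to HSV (each channel scaled to \[0, 1\]), quantises
#' every channel into `levels` equal bins, and counts pixels in the joint
#' 3-D histogram, flattened H-major (H varies slowest). At the default 16
#' levels per channel the feature has 16^3 = 4096 bins. By default only
#' pixels inside the scope disc are counted — the black border would
#' otherwise dominate the histogram.
#'
#' @param frame A [new_frame()] object.
#' @param levels Bins per channel (>= 2).
#' @param masked Count only scope-disc pixels (default `TRUE`).
#' @param drop_v Reserved flag for an intensity-invariant variant that
#'   discards the V channel; it performed worse in the clinical comparison
#'   and is deliberately not implemented — `TRUE` errors.
#' @return Integer vector of length `levels^3`, with attribute `n_pixels`
#'   (the number of counted pixels; also the histogram's sum).
#' @export
hsv_histogram <- function(frame, levels = 16L, masked = TRUE,
                          drop_v = FALSE) {
  if (isTRUE(drop_v)) {
    stop("The V-channel-removed histogram variant is not implemented ",
         "(it underperformed the full HSV histogram).", call. = FALSE)
  }
  if (levels < 2) stop("levels must be >= 2.", call. = FALSE)
  levels <- as.integer(levels)
  px <- frame$pixels
  d <- dim(px)
  if (length(d) != 3 || d[3] != 3) {
    stop("hsv_histogram() needs a 3-channel frame.", call. = FALSE)
  }
  keep <- if (masked) as.vector(frame$mask) else rep(TRUE, d[1] * d[2])
  r <- as.vector(px[, , 1])[keep]
  g <- as.vector(px[, , 2])[keep]
  b <- as.vector(px[, , 3])[keep]
  hsv <- grDevices::rgb2hsv(r, g, b, maxColorValue = 1)
  qz <- function(v) pmin(floor(v * levels), levels - 1L)
  hb <- qz(hsv[1, ]); sb <- qz(hsv[2, ]); vb <- qz(hsv[3, ])
  idx <- hb * levels^2 + sb * levels + vb + 1L
  counts <- tabulate(idx, nbins = levels^3)
  structure(counts, n_pixels = length(r), levels = levels)
}

#' Fit a PCA projection on histogram features
#'
#' Centres the feature matrix and keeps the `n_components` directions of
#' largest variance. The effective dimension is capped by the data rank,
#' `min(n_components, n_samples - 1, n_features)`, and recorded on the
#' returned projection (with a warning when the cap bites).
#'
#' @param features Numeric matrix, one row per frame (e.g. stacked
#'   [hsv_histogram()] vectors).
#' @param n_components Target dimensionality (default 1000).
#' @return A `feto_pca` object with elements `rotation`, `center`, `dim`,
#'   `sdev`.
#' @export
fit_pca <- function(features, n_components = 1000L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2) stop("PCA needs at least 2 samples.", call. = FALSE)
  eff <- min(n_components, n - 1L, ncol(features))
  if (eff < n_components) {
    warning("Effective PCA dimension capped at ", eff, " (rank bound).",
            call. = FALSE)
  }
  pr <- stats::prcomp(features, center = TRUE, scale. = FALSE, rank. = eff)
  structure(
    list(rotation = pr$rotation[, seq_len(eff), drop = FALSE],
         center = pr$center, dim = as.integer(eff),
         sdev = pr$sdev[seq_len(eff)]),
    class = "feto_pca"
  )
}

#' Project features through a fitted PCA
#'
#' @param pca A `feto_pca` from [fit_pca()].
#' @param features Numeric matrix (or vector) in the original feature space.
#' @return Projected matrix with `pca$dim` columns; the training mean maps
#'   to the zero vector.
#' @export
project_pca <- function(pca, features) {
  stopifnot(inherits(pca, "feto_pca"))
  x <- if (is.null(dim(features))) matrix(features, nrow = 1) else
    as.matrix(features)
  sweep(x, 2, pca$center) %*% pca$rotation
}

#' Train a Gaussian-kernel SVM on projected features
#'
#' Radial-basis-function SVM via \pkg{e1071}, with Platt-scaled class
#' probabilities fitted so the decision can be swept for precision-recall
#' analysis. Kernel width defaults to `1/n_features` and cost to 1 (library
#' defaults); a grid search is available but off by default.
#'
#' @param x Numeric feature matrix (one row per frame).
#' @param labels Logical vector (`TRUE` = ablation).
#' @param cost,gamma SVM hyperparameters (`NULL` gamma = `1/ncol(x)`).
#' @param tune Cross-validated grid search over cost/gamma (slow; default
#'   `FALSE`).
#' @return A `feto_svm` object.
#' @export
train_svm <- function(x, labels, cost = 1, gamma = NULL, tune = FALSE) {
  x <- as.matrix(x)
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) {
    stop("SVM training needs both classes present.", call. = FALSE)
  }
  gamma <- gamma %||% (1 / ncol(x))
  yf <- factor(ifelse(labels, "ablation", "not_ablation"),
               levels = c("not_ablation", "ablation"))
  if (tune) {
    tn <- e1071::tune.svm(x, yf, cost = 2^(-1:3), gamma = gamma * 4^(-1:1),
                          kernel = "radial", probability = TRUE)
    fit <- tn$best.model
  } else {
    fit <- e1071::svm(x, yf, kernel = "radial", cost = cost, gamma = gamma,
                      probability = TRUE)
  }
  structure(list(fit = fit), class = "feto_svm")
}

#' Predict with a trained SVM
#'
#' @param svm A `feto_svm`.
#' @param x Feature matrix (rows = frames) in the same space as training.
#' @return A tibble with `label` (logical, `TRUE` = ablation), `score`
#'   (Platt probability of ablation, in \[0, 1\]) and `decision` (raw
#'   decision value, positive towards ablation).
#' @export
predict_svm <- function(svm, x) {
  stopifnot(inherits(svm, "feto_svm"))
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  pr <- stats::predict(svm$fit, x, decision.values = TRUE,
                       probability = TRUE)
  prob <- attr(pr, "probabilities")[, "ablation"]
  dec <- as.numeric(attr(pr, "decision.values"))
  flip <- grepl("^not_ablation", colnames(attr(pr, "decision.values"))[1])
  tibble::tibble(
    label = pr == "ablation",
    score = as.numeric(prob),
    decision = if (flip) -dec else dec
  )
}

#' End-to-end histogram/PCA/SVM baseline
#'
#' Convenience bundle: computes masked HSV histograms for the training
#' frames, fits the PCA projection and the Gaussian-kernel SVM on the
#' projected features.
#'
#' @param train_set Dataset tibble (class-balanced recommended).
#' @param levels Histogram bins per channel.
#' @param n_components PCA target dimension.
#' @param ... Passed to [train_svm()].
#' @return A `feto_svm_pipeline` with elements `pca`, `svm`, `levels`.
#' @export
train_svm_baseline <- function(train_set, levels = 16L,
                               n_components = 1000L, ...) {
  feats <- t(vapply(train_set$frame, function(f) {
    as.numeric(hsv_histogram(f, levels = levels))
  }, numeric(levels^3)))
  pca <- suppressWarnings(fit_pca(feats, n_components = n_components))
  proj <- project_pca(pca, feats)
  svm <- train_svm(proj, train_set$binary, ...)
  structure(list(pca = pca, svm = svm, levels = as.integer(levels)),
            class = "feto_svm_pipeline")
}

#' @rdname train_svm_baseline
#' @param pipeline A `feto_svm_pipeline`.
#' @param frames Dataset tibble, list of frames or single frame.
#' @export
predict_svm_baseline <- function(pipeline, frames) {
  stopifnot(inherits(pipeline, "feto_svm_pipeline"))
  fl <- if (inherits(frames, "feto_frame")) {
    list(frames)
  } else if (is.data.frame(frames)) {
    frames$frame
  } else {
    frames
  }
  feats <- t(vapply(fl, function(f) {
    as.numeric(hsv_histogram(f, levels = pipeline$levels))
  }, numeric(pipeline$levels^3)))
  predict_svm(pipeline$svm, project_pca(pipeline$pca, feats))
}
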