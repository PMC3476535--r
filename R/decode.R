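#' Reduce spectrogram resolution by block averaging
#'
#' Non-overlapping `factor x factor` block means in time and frequency;
#' trailing partial blocks are averaged over the cells available.
#'
#' @param spec A `spectrogram` (any kind).
#' @param factor Reduction factor.
#' @return A `spectrogram` whose `times`/`freqs` are block centres.
#' @export
reduce_resolution <- function(spec, factor = 10) {
  v <- spec$values
  nt <- nrow(v); nf <- ncol(v)
  bt <- ceiling(nt / factor); bf <- ceiling(nf / factor)
  gi <- rep(seq_len(bt), each = factor)[seq_len(nt)]
  gj <- rep(seq_len(bf), each = factor)[seq_len(nf)]
  ## block means via two grouped averages
  vm <- rowsum(v, gi) / as.vector(table(gi))
  vm <- t(rowsum(t(vm), gj) / as.vector(table(gj)))
  dimnames(vm) <- NULL
  spec$values <- vm
  spec$times <- as.vector(rowsum(spec$times, gi) / as.vector(table(gi)))
  spec$freqs <- as.vector(rowsum(spec$freqs, gj) / as.vector(table(gj)))
  if (!is.null(spec$baseline_spectrum))
    spec$baseline_spectrum <- as.vector(
      rowsum(spec$baseline_spectrum, gj) / as.vector(table(gj)))
  spec$reduced_by <- factor
  spec
}

#' Build single-trial feature vectors from masked reduced spectrograms
#'
#' For each condition, identifies the significant points of the reduced
#' spectrograms across the condition's trials ([bootstrap_mask()]); the
#' feature set is the union of significant points over the four
#' conditions, per component cluster.  Each trial's feature vector is its
#' dB values at those points, concatenated across clusters.
#'
#' @param specs_by_cluster Named list (one element per component cluster)
#'   of lists of reduced normalised `spectrogram`s, one per trial, all on
#'   a common grid.
#' @param labels Character vector of condition labels, one per trial.
#' @param alpha,n_boot,seed Passed to [bootstrap_mask()].
#' @param exclude Cluster names to drop (e.g. a visual-cortex cluster
#'   excluded for gaze-control reasons).
#' @return List with `features` (trials x features matrix), `spec`
#'   (per-cluster logical masks = the feature coordinates), `labels`.
#' @export
build_features <- function(specs_by_cluster, labels, alpha = 0.05,
                           n_boot = 200, seed = 1, exclude = character(0)) {
  keep <- setdiff(names(specs_by_cluster), exclude)
  if (!length(keep)) stop("no clusters left after exclusion")
  specs_by_cluster <- specs_by_cluster[keep]
  conds <- sort(unique(labels))
  feats <- list()
  fspec <- list()
  for (cl in keep) {
    specs <- specs_by_cluster[[cl]]
    stopifnot(length(specs) == length(labels))
    sel <- matrix(FALSE, nrow(specs[[1]]$values), ncol(specs[[1]]$values))
    for (cn in conds) {
      mk <- bootstrap_mask(specs[labels == cn], alpha = alpha,
                           n_boot = n_boot, seed = seed)
      sel <- sel | mk$mask
    }
    if (any(sel)) {
      fm <- t(vapply(specs, function(s) s$values[sel],
                     numeric(sum(sel))))
      feats[[cl]] <- fm
      fspec[[cl]] <- sel
    }
  }
  if (!length(feats))
    stop("no significant time-frequency points; lower alpha or increase ",
         "the signal-to-noise ratio")
  list(features = do.call(cbind, feats), spec = fspec, labels = labels)
}

#' Train a linear (pooled-variance) Gaussian naive Bayes classifier
#'
#' Gaussian naive Bayes with per-class feature means and a single
#' per-feature variance pooled across classes, which makes the decision
#' boundaries linear.  Priors are the training class frequencies.
#' Variances are floored at `1e-6` times the overall feature variance.
#'
#' @param x Trials x features matrix.
#' @param y Class labels.
#' @param pooled Use pooled variances (`TRUE`, linear boundaries); when
#'   `FALSE`, per-class variances (quadratic boundaries).
#' @return An object of class `nb_model`.
#' @export
train_nb <- function(x, y, pooled = TRUE) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  nf <- ncol(x)
  means <- matrix(0, length(classes), nf,
                  dimnames = list(classes, colnames(x)))
  vars <- matrix(0, length(classes), nf)
  for (k in seq_along(classes)) {
    xi <- x[y == classes[k], , drop = FALSE]
    means[k, ] <- colMeans(xi)
    v <- apply(xi, 2, stats::var)
    vars[k, ] <- ifelse(is.finite(v), v, 0)   # singleton class
  }
  nk <- as.vector(table(factor(y, classes)))
  pooled_var <- colSums(vars * (nk - 1)) /
    max(1, nrow(x) - length(classes))
  floor_v <- 1e-6 * pmax(apply(x, 2, stats::var), .Machine$double.eps)
  pooled_var <- pmax(pooled_var, floor_v)
  vars <- pmax(vars, rep(floor_v, each = length(classes)))
  structure(list(classes = classes, means = means,
                 variances = if (pooled)
                   matrix(pooled_var, length(classes), nf, byrow = TRUE)
                 else vars,
                 pooled = pooled,
                 priors = nk / sum(nk)),
            class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf(
    "%s Gaussian naive Bayes: %d classes, %d features\n",
    if (x$pooled) "Linear (pooled-variance)" else "Quadratic",
    length(x$classes), ncol(x$means)))
  cat("  priors:", paste(sprintf("%s=%.3f", x$classes, x$priors),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Predict from a naive Bayes model
#'
#' @param object An `nb_model`.
#' @param newdata Trials x features matrix.
#' @param ... Unused.
#' @return List with `class` (argmax labels) and `posterior`
#'   (trials x classes, softmax-normalised in the log domain).
#' @export
predict.nb_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  K <- length(object$classes)
  lp <- matrix(0, nrow(x), K)
  for (k in seq_len(K)) {
    mu <- object$means[k, ]
    v <- object$variances[k, ]
    lp[, k] <- log(object$priors[k]) -
      0.5 * rowSums(sweep(sweep(x, 2, mu)^2, 2, v, "/")) -
      0.5 * sum(log(2 * pi * v))
  }
  mx <- apply(lp, 1, max)
  post <- exp(lp - mx)
  post <- post / rowSums(post)
  colnames(post) <- object$classes
  list(class = object$classes[max.col(lp, ties.method = "first")],
       posterior = post)
}

#' Stratified k-fold cross-validation of the naive Bayes decoder
#'
#' Splits trials into `k` stratified folds (seeded), trains on `k - 1`
#' folds and tests on the held-out fold.  When `x` is a feature matrix the
#' features are fixed (the subject-level mask selection); when `x` is a
#' list of per-cluster reduced spectrograms the significance masks and
#' features are recomputed inside each training fold
#' ([build_features()]), so no test-trial information enters the feature
#' selection (the leakage-free default of [decode_study()]).
#'
#' @param x Trials x features matrix, or named list of per-cluster lists
#'   of reduced spectrograms.
#' @param y Class labels, one per trial.
#' @param k Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @param alpha,n_boot Mask parameters when features are recomputed.
#' @param exclude Cluster names to drop.
#' @return List with `confusion` (per-fold count matrices), `folds`
#'   (fold id per trial), `accuracy` (overall), `predicted`.
#' @export
crossvalidate <- function(x, y, k = 10, seed = 1, alpha = 0.05,
                          n_boot = 200, exclude = character(0)) {
  y <- as.character(y)
  n <- length(y)
  classes <- sort(unique(y))
  if (min(table(y)) < k)
    stop("each class needs at least k trials for stratified k-fold CV")
  set.seed(seed)
  folds <- integer(n)
  for (cl in classes) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fixed <- is.matrix(x)
  if (fixed) stopifnot(nrow(x) == n)
  predicted <- character(n)
  conf <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    te <- !tr
    if (fixed) {
      mod <- train_nb(x[tr, , drop = FALSE], y[tr])
      pred <- predict(mod, x[te, , drop = FALSE])$class
    } else {
      bf <- build_features(lapply(x, function(sl) sl[tr]), y[tr],
                           alpha = alpha, n_boot = n_boot, seed = seed,
                           exclude = exclude)
      mod <- train_nb(bf$features, y[tr])
      xte <- do.call(cbind, lapply(names(bf$spec), function(cl) {
        t(vapply(x[[cl]][te], function(s) s$values[bf$spec[[cl]]],
                 numeric(sum(bf$spec[[cl]]))))
      }))
      pred <- predict(mod, xte)$class
    }
    predicted[te] <- pred
    conf[[f]] <- table(factor(y[te], classes), factor(pred, classes))
  }
  list(confusion = conf, folds = folds, predicted = predicted,
       accuracy = mean(predicted == y), classes = classes, seed = seed)
}

#' Grand-average normalized confusion matrix
#'
#' Sums per-fold (and per-subject) confusion counts and normalises so the
#' cells sum to 100 percent; row sums then reflect class prevalence.
#'
#' @param confusions List of confusion count matrices (or of
#'   [crossvalidate()] results).
#' @return An object of class `confusion_matrix` with `counts`,
#'   `normalized` (percent), `accuracy`.
#' @export
aggregate_confusion <- function(confusions) {
  mats <- lapply(confusions, function(cm) {
    if (is.list(cm) && !is.null(cm$confusion))
      Reduce(`+`, lapply(cm$confusion, unclass)) else unclass(cm)
  })
  counts <- Reduce(`+`, mats)
  normalized <- 100 * counts / sum(counts)
  structure(list(counts = counts, normalized = normalized,
                 accuracy = sum(diag(as.matrix(normalized))) / 100),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 1, ...) {
  cat("Grand average normalized confusion matrix (% of all trials):\n")
  print(round(x$normalized, digits))
  cat(sprintf("accuracy: %.1f%%\n", 100 * x$accuracy))
  invisible(x)
}
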