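#' Training-fold imputation and standardization
#'
#' Learns column means (over non-missing training values), imputation values
#' and SDs from the training rows only, then applies mean imputation and
#' z-scoring. The returned transform can be reused on held-out rows without
#' leaking their statistics. Zero-variance features get SD 1.
#'
#' @param x Numeric matrix or data frame (rows = dyads).
#' @param training_rows Integer indices of the training rows.
#' @return List: \code{x} (transformed full matrix) and \code{transform}
#'   (for [apply_transform()]).
#' @export
impute_and_standardize <- function(x, training_rows = seq_len(nrow(x))) {
  x <- as.matrix(x)
  if (length(training_rows) == 0) stop("empty training set", call. = FALSE)
  tr <- x[training_rows, , drop = FALSE]
  center <- colMeans(tr, na.rm = TRUE)
  center[is.nan(center)] <- 0
  scale <- apply(tr, 2, stats::sd, na.rm = TRUE)
  zero <- is.na(scale) | scale < 1e-12
  if (any(zero)) {
    dyad_log("%d zero-variance feature(s); SD set to 1", sum(zero))
    scale[zero] <- 1
  }
  transform <- list(center = center, scale = scale)
  list(x = apply_transform(transform, x), transform = transform)
}

#' @rdname impute_and_standardize
#' @param transform A transform from [impute_and_standardize()].
#' @export
apply_transform <- function(transform, x) {
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- transform$center[j]
  }
  sweep(sweep(x, 2, transform$center), 2, transform$scale, "/")
}

#' Fit a PCA projection retaining a target explained variance
#'
#' Principal components of an already standardized table; keeps the smallest
#' number of components whose cumulative explained variance reaches
#' \code{variance_kept}. Component signs follow a deterministic convention:
#' the largest-magnitude loading of each kept component is positive.
#'
#' @param x Standardized numeric matrix (n x p), n >= 2.
#' @param variance_kept Fraction of variance to retain. Default 0.95.
#' @return List of class \code{"pca_projection"}: \code{rotation} (p x k),
#'   \code{k}, \code{eigenvalues}, \code{explained} (cumulative fractions).
#' @export
fit_pca <- function(x, variance_kept = 0.95) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 rows", call. = FALSE)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev / sum(ev)
  cum <- cumsum(ev)
  k <- which(cum >= variance_kept - 1e-12)[1]
  if (is.na(k)) k <- length(ev)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(rotation = rot, k = k, eigenvalues = pc$sdev^2,
                 explained = cum),
            class = "pca_projection")
}

#' @rdname fit_pca
#' @param projection A \code{pca_projection}.
#' @export
project_pca <- function(projection, x) {
  as.matrix(x) %*% projection$rotation
}

#' Fit a decision stump (one-feature threshold classifier)
#'
#' Exhaustive search over every feature, every candidate threshold (the
#' midpoints of consecutive distinct sorted values) and both polarities,
#' minimizing 0-1 training error. Ties are broken deterministically: lower
#' feature index, then lower threshold, then the "greater" polarity.
#' Single-class input yields a constant classifier.
#'
#' @param x Numeric matrix (n x p), no missing values.
#' @param y Binary labels (factor, or coercible to one with 2 levels).
#' @return A list of class \code{"stump_model"}: \code{feature},
#'   \code{threshold}, \code{polarity} ("greater" or "lessOrEqual" mapping
#'   to the second class level), \code{classes}, \code{training_error}.
#' @export
fit_stump <- function(x, y) {
  x <- as.matrix(x)
  y <- as.factor(y)
  classes <- levels(y)
  if (length(classes) == 1) {
    return(structure(list(feature = NA_integer_, threshold = NA_real_,
                          polarity = "constant", constant = classes[1],
                          classes = classes, training_error = 0L),
                     class = "stump_model"))
  }
  stopifnot(length(classes) == 2)
  y1 <- as.integer(y == classes[2])
  n <- nrow(x)
  majority <- classes[which.max(tabulate(as.integer(y), 2))]
  best <- list(err = sum(y1 != (majority == classes[2])) + 1L)
  for (j in seq_len(ncol(x))) {
    vals <- sort(unique(x[, j]))
    if (length(vals) < 2) next
    thrs <- (vals[-1] + vals[-length(vals)]) / 2
    for (thr in thrs) {
      gt <- x[, j] > thr
      err_greater <- sum(y1 != as.integer(gt))
      err_leq <- n - err_greater
      for (pol in c("greater", "lessOrEqual")) {
        err <- if (pol == "greater") err_greater else err_leq
        if (err < best$err) {
          best <- list(err = err, feature = j, threshold = thr,
                       polarity = pol)
        }
      }
    }
  }
  if (is.null(best$feature)) {
    return(structure(list(feature = NA_integer_, threshold = NA_real_,
                          polarity = "constant", constant = majority,
                          classes = classes,
                          training_error = best$err - 1L),
                     class = "stump_model"))
  }
  structure(list(feature = best$feature, threshold = best$threshold,
                 polarity = best$polarity, constant = majority,
                 classes = classes, training_error = best$err),
            class = "stump_model")
}

#' @rdname fit_stump
#' @param model A \code{stump_model}.
#' @param newx Numeric matrix of rows to classify.
#' @export
predict_stump <- function(model, newx) {
  newx <- as.matrix(newx)
  if (model$polarity == "constant") {
    return(factor(rep(model$constant, nrow(newx)), levels = model$classes))
  }
  v <- newx[, model$feature]
  hit <- if (model$polarity == "greater") v > model$threshold
         else v <= model$threshold
  factor(ifelse(hit, model$classes[2], model$classes[1]),
         levels = model$classes)
}

#' Leave-one-out evaluation of the PCA + decision-stump pipeline
#'
#' For each dyad in turn, the imputation/standardization transform, the PCA
#' projection and the stump are fit on the remaining dyads only, and the
#' held-out dyad is predicted; predictions are assembled into a confusion
#' matrix. Setting \code{config$pca_outside_loo} fits the PCA once on the
#' full standardized table instead (the laxer protocol);
#' \code{config$classify_on = "raw"} skips the PCA.
#'
#' @param features Numeric data frame or matrix of features (rows = dyads;
#'   may contain \code{NA}).
#' @param labels Binary labels, one per row.
#' @param config A [run_config()].
#' @param dyad_id Optional row identifiers.
#' @return A list of class \code{"classification_result"}: per-dyad
#'   \code{predicted} and \code{truth}, \code{confusion} (truth in rows),
#'   \code{accuracy}, \code{classes}.
#' @export
loo_evaluate <- function(features, labels, config = run_config(),
                         dyad_id = NULL) {
  x <- as.matrix(features)
  y <- as.factor(labels)
  n <- nrow(x)
  if (n < 3) stop("leave-one-out needs at least 3 rows", call. = FALSE)
  stopifnot(length(y) == n)
  if (is.null(dyad_id)) dyad_id <- sprintf("row%03d", seq_len(n))
  if (config$missing_policy == "drop_incomplete") {
    keep <- stats::complete.cases(x)
    dyad_log("dropping %d incomplete row(s)", sum(!keep))
    x <- x[keep, , drop = FALSE]; y <- droplevels(y[keep])
    dyad_id <- dyad_id[keep]
    n <- nrow(x)
  }
  global_pca <- NULL
  if (config$pca_outside_loo && config$classify_on == "pca") {
    std_all <- impute_and_standardize(x)
    global_pca <- fit_pca(std_all$x, config$pca_variance_kept)
  }
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    std <- impute_and_standardize(x, train)
    xtr <- std$x[train, , drop = FALSE]
    xte <- std$x[i, , drop = FALSE]
    if (config$classify_on == "pca") {
      proj <- if (is.null(global_pca)) fit_pca(xtr, config$pca_variance_kept)
              else global_pca
      xtr <- project_pca(proj, xtr)
      xte <- project_pca(proj, xte)
    }
    stump <- fit_stump(xtr, y[train])
    pred[i] <- predict_stump(stump, xte)
  }
  confusion <- table(truth = y, predicted = pred)
  confusion <- matrix(as.integer(confusion), nrow = nlevels(y),
                      dimnames = list(levels(y), levels(y)))
  structure(list(dyad_id = dyad_id, truth = as.character(y),
                 predicted = as.character(pred),
                 confusion = confusion,
                 accuracy = mean(pred == y),
                 classes = levels(y)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("Leave-one-out classification: accuracy %.2f%% (n = %d)\n",
              100 * x$accuracy, length(x$truth)))
  print(x$confusion)
  invisible(x)
}

#' Point-biserial feature-class correlations, ranked
#'
#' Pearson correlation between each raw feature and the binary class
#' (coded 0/1), computed over the rows where the feature is non-missing,
#' with the two-sided p-value from the t distribution; features are ranked
#' by \code{|r|}. Raw p-values are reported alongside a Benjamini-Hochberg
#' adjusted column. Constant features are excluded.
#'
#' @param features Numeric data frame or matrix (rows = dyads).
#' @param labels Binary labels.
#' @param modality Optional character vector tagging each feature's
#'   modality; inferred from the name prefix ("stt_" = audio, "hm_" =
#'   video) when \code{NULL}.
#' @return Data frame \code{feature, modality, r, p, p_bh, n}, sorted by
#'   decreasing \code{|r|}.
#' @export
feature_class_correlations <- function(features, labels, modality = NULL) {
  x <- as.matrix(features)
  y <- as.factor(labels)
  stopifnot(nlevels(y) == 2)
  y01 <- as.integer(y == levels(y)[2])
  nm <- colnames(x)
  if (is.null(nm)) nm <- sprintf("f%d", seq_len(ncol(x)))
  if (is.null(modality)) {
    modality <- ifelse(startsWith(nm, "stt_"), "audio",
                       ifelse(startsWith(nm, "hm_"), "video", "other"))
  }
  rows <- list()
  for (j in seq_len(ncol(x))) {
    ok <- !is.na(x[, j])
    v <- x[ok, j]
    if (length(v) < 3 || stats::sd(v) < 1e-12 ||
        length(unique(y01[ok])) < 2) {
      dyad_log("excluding constant/degenerate feature '%s'", nm[j])
      next
    }
    ct <- stats::cor.test(v, y01[ok], method = "pearson")
    rows[[length(rows) + 1]] <- data.frame(
      feature = nm[j], modality = modality[j],
      r = unname(ct$estimate), p = ct$p.value, n = length(v),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(feature = character(), modality = character(),
                      r = numeric(), p = numeric(), p_bh = numeric(),
                      n = integer()))
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(-abs(out$r)), c("feature", "modality", "r", "p",
                                   "p_bh", "n")]
  rownames(out) <- NULL
  out
}

#' Accuracy percentage from error counts
#'
#' @param n_total Number of classified cases (> 0).
#' @param n_errors Number of misclassifications.
#' @return \code{100 * (n_total - n_errors) / n_total}, rounded to 2
#'   decimals (e.g. 12 errors among 51 dyads give 76.47).
#' @export
accuracy_from_counts <- function(n_total, n_errors) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  if (n_errors < 0 || n_errors > n_total) {
    stop("n_errors must lie in [0, n_total]", call. = FALSE)
  }
  round(100 * (n_total - n_errors) / n_total, 2)
}
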