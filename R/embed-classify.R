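#' Two-dimensional embedding of a feature table (PCA + t-SNE)
#'
#' Reduces the feature matrix to its leading principal components (default
#' 10) and embeds those scores in two dimensions with t-SNE (default
#' perplexity 15). Both steps are seeded and reproducible.
#'
#' @param ft A [feature_table()].
#' @param n_components Number of principal components kept before t-SNE.
#' @param perplexity t-SNE perplexity; must satisfy
#'   `perplexity < (n_samples - 1) / 3`.
#' @param seed Integer seed.
#' @param n_iter t-SNE gradient-descent iterations.
#' @return A `slide_embedding` tibble with columns `sample_id`, `x`, `y`,
#'   `label`.
#' @export
embed_features <- function(ft, n_components = 10L, perplexity = 15,
                           seed = 1L, n_iter = 500L) {
  X <- feature_matrix(ft)
  n <- nrow(X)
  if (n_components > min(dim(X))) {
    stop("n_components exceeds min(samples, features)", call. = FALSE)
  }
  if (perplexity >= (n - 1) / 3) {
    stop("too few samples for this perplexity (need perplexity < (n-1)/3)",
      call. = FALSE
    )
  }
  pcs <- stats::prcomp(X, center = TRUE, scale. = FALSE)$x[,
    seq_len(n_components),
    drop = FALSE
  ]
  Y <- tsne_embed(pcs, perplexity = perplexity, seed = seed, n_iter = n_iter)
  out <- tibble::tibble(
    sample_id = ft$sample_id, x = Y[, 1], y = Y[, 2], label = ft$label
  )
  class(out) <- c("slide_embedding", class(out))
  out
}

#' @export
autoplot.slide_embedding <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$x, y = .data$y,
    colour = .data$label
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = NULL) +
    ggplot2::theme_minimal()
}

make_stratified_folds <- function(labels, folds, seed) {
  assignment <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

standardize_train_test <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  list(
    train = sweep(sweep(train, 2, mu), 2, sd, "/"),
    test = sweep(sweep(test, 2, mu), 2, sd, "/")
  )
}

fold_auc <- function(truth, score, neg, pos) {
  as.numeric(pROC::auc(
    factor(truth, levels = c(neg, pos)), score,
    levels = c(neg, pos), direction = "<", quiet = TRUE
  ))
}

average_precision <- function(truth, score, positive) {
  ord <- order(score, decreasing = TRUE)
  hits <- truth[ord] == positive
  n_pos <- sum(hits)
  if (n_pos == 0L) {
    return(NA_real_)
  }
  precision_at_hit <- cumsum(hits)[hits] / which(hits)
  mean(precision_at_hit)
}

#' Cross-validated linear-SVM classification of a feature table
#'
#' Stratified k-fold cross-validation (default 6 folds) of a linear
#' maximum-margin classifier (cost parameter `C`, default 1). Features are
#' standardized with train-fold statistics before fitting. Reports per-fold
#' ROC AUC on held-out samples, their mean, and average precision from the
#' pooled out-of-fold decision scores.
#'
#' @param ft A [feature_table()].
#' @param labels Two-class labels; defaults to `ft$label`. The
#'   alphabetically larger class is treated as positive (so with
#'   tumor/normal labels, tumor is positive).
#' @param folds Number of folds (default 6).
#' @param cost SVM cost parameter `C` (default 1).
#' @param seed Seed for the fold assignment.
#' @return A `classification_report`: `fold_aucs`, `mean_auc`,
#'   `average_precision`, `fold_count`, `regularization_c`, the fold
#'   assignment and the pooled out-of-fold `scores` tibble.
#' @export
classify_cv <- function(ft, labels = NULL, folds = 6L, cost = 1, seed = 1L) {
  X <- feature_matrix(ft)
  if (is.null(labels)) labels <- ft$label
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop("classification requires exactly two classes", call. = FALSE)
  }
  if (min(table(labels)) < folds) {
    stop("each class needs at least `folds` members", call. = FALSE)
  }
  neg <- classes[1]
  pos <- classes[2]
  assignment <- make_stratified_folds(labels, folds, seed)
  oof <- rep(NA_real_, length(labels))
  fold_aucs <- numeric(folds)
  for (k in seq_len(folds)) {
    te <- assignment == k
    std <- standardize_train_test(X[!te, , drop = FALSE], X[te, , drop = FALSE])
    fit <- e1071::svm(std$train, factor(labels[!te], levels = c(neg, pos)),
      kernel = "linear", cost = cost, scale = FALSE
    )
    dv <- attr(
      stats::predict(fit, std$test, decision.values = TRUE),
      "decision.values"
    )
    score <- as.numeric(dv[, 1])
    # libsvm's decision value is positive for the class named first in the
    # column label; orient scores so that higher means `pos`
    first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
    if (first != pos) score <- -score
    oof[te] <- score
    fold_aucs[k] <- fold_auc(labels[te], score, neg, pos)
  }
  structure(
    list(
      fold_aucs = fold_aucs,
      mean_auc = mean(fold_aucs),
      average_precision = average_precision(labels, oof, pos),
      fold_count = folds,
      regularization_c = cost,
      positive_class = pos,
      fold_assignment = assignment,
      scores = tibble::tibble(
        sample_id = ft$sample_id, label = labels,
        fold = assignment, score = oof
      )
    ),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> %d-fold CV, mean AUC %.3f, AP %.3f\n",
    x$fold_count, x$mean_auc, x$average_precision
  ))
  invisible(x)
}

#' @export
tidy.classification_report <- function(x, ...) {
  tibble::tibble(fold = seq_len(x$fold_count), auc = x$fold_aucs)
}

#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(
    mean_auc = x$mean_auc, average_precision = x$average_precision,
    fold_count = x$fold_count, regularization_c = x$regularization_c
  )
}

#' @export
autoplot.classification_report <- function(object, ...) {
  roc <- pROC::roc(
    factor(object$scores$label), object$scores$score,
    direction = "<", quiet = TRUE,
    levels = c(
      setdiff(sort(unique(object$scores$label)), object$positive_class),
      object$positive_class
    )
  )
  df <- tibble::tibble(
    fpr = 1 - roc$specificities,
    tpr = roc$sensitivities
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey") +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Pooled out-of-fold ROC (mean AUC %.3f)", object$mean_auc)
    ) +
    ggplot2::theme_minimal()
}

#' Classification performance on random feature subsets
#'
#' For each subset size, draws `repeats` random column subsets, runs
#' [classify_cv()] on each, and reports the mean cross-validated AUC per
#' size.
#'
#' @param ft A [feature_table()].
#' @param sizes Subset sizes (default `c(10, 25, 50, 100)`).
#' @param repeats Random subsets per size (default 3).
#' @param folds,cost,seed Passed to [classify_cv()].
#' @param labels Optional labels (defaults to `ft$label`).
#' @return Tibble with one row per size: `size`, `mean_auc`; the per-run
#'   results are attached as the `"runs"` attribute.
#' @export
feature_subset_experiment <- function(ft, sizes = c(10L, 25L, 50L, 100L),
                                      repeats = 3L, folds = 6L, cost = 1,
                                      seed = 1L, labels = NULL) {
  fcols <- feature_col_names(ft)
  if (max(sizes) > length(fcols)) {
    stop("largest subset size exceeds the feature count", call. = FALSE)
  }
  runs <- purrr::map_dfr(seq_along(sizes), function(si) {
    purrr::map_dfr(seq_len(repeats), function(r) {
      cols <- withr::with_seed(
        seed + 1000L * si + r,
        sample(fcols, sizes[si])
      )
      sub <- feature_table(
        as.matrix(ft[, cols, drop = FALSE]), ft$sample_id, ft$label,
        extractor_name = attr(ft, "extractor_name"),
        crop_size = attr(ft, "crop_size")
      )
      rep <- classify_cv(sub,
        labels = labels, folds = folds, cost = cost,
        seed = seed
      )
      tibble::tibble(size = sizes[si], repeat_index = r, mean_auc = rep$mean_auc)
    })
  })
  out <- dplyr::summarise(dplyr::group_by(runs, .data$size),
    mean_auc = mean(.data$mean_auc), .groups = "drop"
  )
  attr(out, "runs") <- runs
  out
}
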