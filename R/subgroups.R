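#' Davies-Bouldin index of a clustering
#'
#' Mean over clusters of the highest ratio of summed within-cluster scatter
#' to centroid separation; lower values indicate a better partition.
#'
#' @param X Numeric sample x feature matrix.
#' @param labels Integer cluster assignment.
#' @return Non-negative scalar.
#' @export
davies_bouldin <- function(X, labels) {
  ks <- sort(unique(labels))
  centroids <- t(vapply(
    ks, function(k) colMeans(X[labels == k, , drop = FALSE]),
    numeric(ncol(X))
  ))
  scatter <- vapply(seq_along(ks), function(i) {
    diff <- sweep(X[labels == ks[i], , drop = FALSE], 2, centroids[i, ])
    mean(sqrt(rowSums(diff^2)))
  }, numeric(1))
  K <- length(ks)
  ratios <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (i != j) {
        m <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
        ratios[i, j] <- (scatter[i] + scatter[j]) / m
      }
    }
  }
  mean(apply(ratios, 1, max))
}

#' K-means scan over candidate cluster counts
#'
#' Standardizes the chosen feature columns, runs multi-start K-means for
#' each K in `k_min:k_max`, and scores each partition with the mean
#' silhouette coefficient and the Davies-Bouldin index. The chosen K
#' maximizes silhouette; the Davies-Bouldin index (lower wins) breaks ties.
#'
#' @param ft A [feature_table()] or a numeric sample x feature matrix.
#' @param features Optional character vector restricting `ft` to selected
#'   columns (e.g. the survival-significant features).
#' @param k_min,k_max Candidate range (defaults 2 and 12).
#' @param seed Seed for the K-means starts.
#' @param n_init Random starts per K (default 10).
#' @return A `cluster_scan`: `metrics` tibble (`k`, `silhouette`,
#'   `davies_bouldin`), `labels_per_k`, `chosen_k` and the chosen `labels`.
#' @export
cluster_scan <- function(ft, features = NULL, k_min = 2L, k_max = 12L,
                         seed = 1L, n_init = 10L) {
  X <- if (is.matrix(ft)) ft else feature_matrix(ft)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  if (all(sds < 1e-12)) {
    stop("degenerate clustering input: all points identical", call. = FALSE)
  }
  X <- sweep(sweep(X, 2, colMeans(X)), 2, pmax(sds, 1e-12), "/")
  n <- nrow(X)
  if (n <= k_max) {
    warning("fewer samples than k_max; clipping the K range", call. = FALSE)
    k_max <- n - 1L
  }
  ks <- k_min:k_max
  d <- stats::dist(X)
  labels_per_k <- list()
  metrics <- purrr::map_dfr(ks, function(k) {
    cl <- withr::with_seed(
      seed + k,
      stats::kmeans(X, centers = k, nstart = n_init, iter.max = 100L)
    )
    labels_per_k[[as.character(k)]] <<- cl$cluster
    sil <- mean(cluster::silhouette(cl$cluster, d)[, "sil_width"])
    tibble::tibble(
      k = k, silhouette = sil, davies_bouldin = davies_bouldin(X, cl$cluster)
    )
  })
  best_sil <- max(metrics$silhouette)
  cand <- metrics[abs(metrics$silhouette - best_sil) < 1e-12, ]
  chosen_k <- cand$k[which.min(cand$davies_bouldin)]
  structure(
    list(
      metrics = metrics,
      labels_per_k = labels_per_k,
      chosen_k = chosen_k,
      labels = stats::setNames(
        labels_per_k[[as.character(chosen_k)]],
        rownames(X)
      )
    ),
    class = "cluster_scan"
  )
}

#' @export
print.cluster_scan <- function(x, ...) {
  cat(sprintf(
    "<cluster_scan> K in %d..%d, chosen K = %d (silhouette %.3f)\n",
    min(x$metrics$k), max(x$metrics$k), x$chosen_k,
    x$metrics$silhouette[x$metrics$k == x$chosen_k]
  ))
  invisible(x)
}

#' @export
tidy.cluster_scan <- function(x, ...) {
  x$metrics
}

#' @export
glance.cluster_scan <- function(x, ...) {
  tibble::tibble(
    chosen_k = x$chosen_k,
    silhouette = x$metrics$silhouette[x$metrics$k == x$chosen_k],
    davies_bouldin = x$metrics$davies_bouldin[x$metrics$k == x$chosen_k]
  )
}

#' @export
autoplot.cluster_scan <- function(object, ...) {
  df <- tidyr::pivot_longer(object$metrics, -"k",
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(
      xintercept = object$chosen_k, linetype = "dashed",
      colour = "grey40"
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Number of clusters K", y = NULL) +
    ggplot2::theme_minimal()
}

km_area <- function(survival) {
  fit <- survival::survfit(survival::Surv(survival$time, survival$event) ~ 1)
  t <- c(0, fit$time)
  s <- c(1, fit$surv)
  sum(diff(t) * s[-length(s)])
}

#' Survival comparison between discovered subgroups
#'
#' Fits a Cox model on the subgroup indicator, computes the log-rank test
#' and per-group Kaplan-Meier curves. Groups are relabeled 1, 2, ... in
#' increasing order of Kaplan-Meier area, so the highest-numbered group has
#' the best survival (subgroup 2 of 2 is the better-prognosis group).
#'
#' @param groups Tibble with `subject_id` and `group`, or a vector of
#'   group labels named by subject id.
#' @param survival Survival-record tibble.
#' @param endpoint `"OS"` or `"DFS"`.
#' @return A `subgroup_survival`: relabeled `groups` tibble, `c_index`,
#'   `logrank_p`, and the `km` ([kaplan_meier()]) result.
#' @export
subgroup_survival <- function(groups, survival, endpoint = "OS") {
  if (!is.data.frame(groups)) {
    groups <- tibble::tibble(
      subject_id = names(groups),
      group = as.vector(groups)
    )
  }
  sv <- survival[survival$endpoint == endpoint, , drop = FALSE]
  ids <- intersect(groups$subject_id, sv$subject_id)
  if (length(ids) == 0L) stop("no shared subjects", call. = FALSE)
  sv <- sv[match(ids, sv$subject_id), , drop = FALSE]
  g <- groups$group[match(ids, groups$subject_id)]
  if (length(unique(g)) < 2L) {
    stop("need at least two subgroups", call. = FALSE)
  }
  if (sum(sv$event) == 0L) stop("no events in the cohort", call. = FALSE)
  areas <- vapply(
    split(seq_along(g), g),
    function(ix) km_area(sv[ix, , drop = FALSE]), numeric(1)
  )
  relabel <- stats::setNames(order(order(areas)), names(areas))
  g2 <- unname(relabel[as.character(g)])
  fit <- survival::coxph(
    survival::Surv(sv$time, sv$event) ~ factor(g2),
    ties = "efron"
  )
  km <- kaplan_meier(sv, groups = as.character(g2))
  structure(
    list(
      groups = tibble::tibble(subject_id = ids, group = g2),
      c_index = unname(summary(fit)$concordance[1]),
      logrank_p = km$logrank_p,
      endpoint = endpoint,
      km = km
    ),
    class = "subgroup_survival"
  )
}

#' @export
print.subgroup_survival <- function(x, ...) {
  cat(sprintf(
    "<subgroup_survival> %s: %d groups, C-index %.3f, log-rank p %.3g\n",
    x$endpoint, length(unique(x$groups$group)), x$c_index, x$logrank_p
  ))
  invisible(x)
}

#' @export
glance.subgroup_survival <- function(x, ...) {
  tibble::tibble(
    endpoint = x$endpoint,
    n_groups = length(unique(x$groups$group)),
    c_index = x$c_index, logrank_p = x$logrank_p
  )
}

#' Cross-model subgroup overlap table
#'
#' Counts samples per combination of subgroup labels assigned by different
#' models. All label sets must cover the same samples.
#'
#' @param label_sets Named list; each element is a tibble with
#'   `subject_id`/`group` columns or a vector of labels named by subject
#'   id.
#' @return Tibble with one column per model plus `n`, one row per observed
#'   label combination; `sum(n)` equals the number of samples.
#' @export
overlap_table <- function(label_sets) {
  stopifnot(length(label_sets) >= 2L, !is.null(names(label_sets)))
  tabs <- lapply(label_sets, function(ls) {
    if (!is.data.frame(ls)) {
      ls <- tibble::tibble(subject_id = names(ls), group = as.vector(ls))
    }
    ls
  })
  ids <- sort(tabs[[1]]$subject_id)
  for (tb in tabs) {
    if (!identical(sort(tb$subject_id), ids)) {
      stop("label sets cover different samples", call. = FALSE)
    }
  }
  wide <- tibble::tibble(subject_id = ids)
  for (nm in names(tabs)) {
    tb <- tabs[[nm]]
    wide[[nm]] <- tb$group[match(ids, tb$subject_id)]
  }
  dplyr::count(wide, dplyr::across(dplyr::all_of(names(tabs))), name = "n")
}
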