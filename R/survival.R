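#' Build a table of survival records
#'
#' One row per subject per endpoint: positive follow-up time in days, a
#' binary event indicator (1 = event observed, 0 = censored) and the
#' endpoint tag (`"OS"` overall survival or `"DFS"` disease-free survival).
#'
#' @param subject_id Character subject ids.
#' @param time Positive times in days.
#' @param event 0/1 event indicators.
#' @param endpoint `"OS"` or `"DFS"` (recycled).
#' @return A tibble of survival records.
#' @export
survival_records <- function(subject_id, time, event, endpoint = "OS") {
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  if (!all(event %in% c(0, 1))) {
    stop("event must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  tb <- tibble::tibble(
    subject_id = as.character(subject_id),
    time = as.numeric(time), event = as.integer(event),
    endpoint = as.character(endpoint)
  )
  if (anyDuplicated(tb[, c("subject_id", "endpoint")])) {
    stop("each subject may appear at most once per endpoint", call. = FALSE)
  }
  tb
}

#' Read survival records from CSV
#'
#' Expects columns `subject_id`, `time_days`, `event`, `endpoint`.
#' @param path CSV path.
#' @return A survival-record tibble.
#' @export
read_survival_csv <- function(path) {
  tb <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    time_days = readr::col_double(),
    event = readr::col_integer(),
    endpoint = readr::col_character()
  ))
  survival_records(tb$subject_id, tb$time_days, tb$event, tb$endpoint)
}

align_survival <- function(ft, survival, endpoint) {
  sv <- survival[survival$endpoint == endpoint, , drop = FALSE]
  ids <- intersect(ft$sample_id, sv$subject_id)
  if (length(ids) == 0L) {
    stop("no subjects shared between features and survival records",
      call. = FALSE
    )
  }
  sv <- sv[match(ids, sv$subject_id), , drop = FALSE]
  list(
    X = feature_matrix(ft)[match(ids, ft$sample_id), , drop = FALSE],
    survival = sv
  )
}

#' Univariate Cox proportional hazards fit for one feature
#'
#' Maximizes the Cox partial likelihood (Efron tie handling) with the
#' feature as sole covariate; significance is the score (log-rank) test.
#'
#' @param feature Numeric per-subject covariate values.
#' @param survival Survival-record tibble aligned with `feature`.
#' @return One-row tibble: `coefficient`, `hazard_ratio`, `logrank_p`,
#'   `c_index`.
#' @export
fit_univariate_cox <- function(feature, survival) {
  if (sum(survival$event) < 2L) {
    stop("need at least 2 events for a Cox fit", call. = FALSE)
  }
  if (stats::var(feature) < 1e-12) {
    stop("feature is (near-)constant", call. = FALSE)
  }
  fit <- survival::coxph(
    survival::Surv(survival$time, survival$event) ~ feature,
    ties = "efron"
  )
  sm <- summary(fit)
  tibble::tibble(
    coefficient = unname(stats::coef(fit)[1]),
    hazard_ratio = exp(unname(stats::coef(fit)[1])),
    logrank_p = unname(sm$sctest["pvalue"]),
    c_index = unname(sm$concordance[1])
  )
}

#' Screen all features for univariate survival association
#'
#' Fits [fit_univariate_cox()] per feature and flags features with score
#' test p-value at or below `threshold` (default 0.05). Near-constant
#' features (variance below 1e-12) are excluded with a warning.
#'
#' @param ft A [feature_table()].
#' @param survival Survival-record tibble.
#' @param endpoint `"OS"` or `"DFS"`.
#' @param threshold Selection p-value threshold.
#' @return A `feature_screen` tibble (one row per tested feature:
#'   `feature`, `coefficient`, `hazard_ratio`, `logrank_p`, `c_index`,
#'   `significant`) with attributes `percent_selected`, `endpoint`,
#'   `threshold`.
#' @export
screen_features <- function(ft, survival, endpoint = "OS", threshold = 0.05) {
  al <- align_survival(ft, survival, endpoint)
  X <- al$X
  variances <- apply(X, 2, stats::var)
  constant <- variances < 1e-12
  if (any(constant)) {
    warning(
      sum(constant), " near-constant feature(s) excluded from screening",
      call. = FALSE
    )
  }
  cols <- colnames(X)[!constant]
  res <- purrr::map_dfr(cols, function(cn) {
    dplyr::bind_cols(
      tibble::tibble(feature = cn),
      fit_univariate_cox(X[, cn], al$survival)
    )
  })
  res$significant <- res$logrank_p <= threshold
  attr(res, "percent_selected") <- 100 * mean(res$significant)
  attr(res, "endpoint") <- endpoint
  attr(res, "threshold") <- threshold
  class(res) <- c("feature_screen", class(res))
  res
}

#' Features significant for every listed endpoint
#'
#' @param screens List of `feature_screen` results (e.g. OS and DFS).
#' @return Character vector of feature names significant in all screens.
#' @export
intersect_significant <- function(screens) {
  Reduce(intersect, lapply(screens, function(s) s$feature[s$significant]))
}

#' Elastic-net-penalized Cox proportional hazards model
#'
#' Coordinate-descent penalized Cox regression over a log-spaced lambda
#' path with mixing parameter `alpha` (default 0.5, equal lasso and ridge
#' weight). Lambda is chosen to minimize the mean cross-validated partial
#' likelihood deviance (default 10 folds). The concordance index is
#' computed on prevalidated (out-of-fold) linear predictors, and the
#' reported log-rank p-value compares subjects above versus below the
#' median out-of-fold risk score.
#'
#' @param ft A [feature_table()].
#' @param survival Survival-record tibble.
#' @param endpoint `"OS"` or `"DFS"`.
#' @param alpha Elastic-net mixing parameter in `[0, 1]`.
#' @param folds Cross-validation folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param lambda Optional fixed lambda overriding cross-validated
#'   selection.
#' @param nlambda Path length (default 100).
#' @return An `encox_fit` object: nonzero `coefficients` tibble,
#'   `alpha`, `lambda_selected`, `cv_folds`, `c_index`,
#'   `c_index_folds` (per-fold C on out-of-fold predictors), `logrank_p`,
#'   and the per-subject `risk` tibble.
#' @export
fit_elasticnet_cox <- function(ft, survival, endpoint = "OS", alpha = 0.5,
                               folds = 10L, seed = 1L, lambda = NULL,
                               nlambda = 100L) {
  al <- align_survival(ft, survival, endpoint)
  X <- al$X
  sv <- al$survival
  if (sum(sv$event) < folds) {
    stop("fewer events than cross-validation folds", call. = FALSE)
  }
  y <- survival::Surv(sv$time, sv$event)
  foldid <- make_stratified_folds(as.character(sv$event), folds, seed)
  if (is.null(lambda)) {
    cv <- withr::with_seed(seed, glmnet::cv.glmnet(X, y,
      family = "cox", alpha = alpha, foldid = foldid,
      type.measure = "deviance", nlambda = nlambda, keep = TRUE,
      standardize = TRUE
    ))
    lambda_sel <- cv$lambda.min
    idx <- which.min(abs(cv$lambda - lambda_sel))
    oof_lp <- as.numeric(cv$fit.preval[, idx])
    final <- cv$glmnet.fit
  } else {
    lambda_sel <- lambda
    oof_lp <- numeric(nrow(X))
    for (k in seq_len(folds)) {
      te <- foldid == k
      fit_k <- glmnet::glmnet(X[!te, , drop = FALSE], y[!te],
        family = "cox", alpha = alpha, standardize = TRUE
      )
      oof_lp[te] <- as.numeric(
        stats::predict(fit_k, X[te, , drop = FALSE], s = lambda_sel)
      )
    }
    final <- glmnet::glmnet(X, y,
      family = "cox", alpha = alpha,
      standardize = TRUE
    )
  }
  beta <- as.numeric(stats::predict(final, s = lambda_sel, type = "coefficients"))
  nz <- which(beta != 0)
  c_overall <- concordance_index(oof_lp, sv)
  c_folds <- vapply(seq_len(folds), function(k) {
    sub <- sv[foldid == k, , drop = FALSE]
    tryCatch(concordance_index(oof_lp[foldid == k], sub),
      error = function(e) NA_real_
    )
  }, numeric(1))
  high <- oof_lp > stats::median(oof_lp)
  logrank_p <- if (length(unique(high)) == 2L) {
    sd <- survival::survdiff(survival::Surv(sv$time, sv$event) ~ high)
    stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  } else {
    NA_real_
  }
  structure(
    list(
      coefficients = tibble::tibble(
        feature = colnames(X)[nz], coefficient = beta[nz]
      ),
      n_features = ncol(X),
      alpha = alpha, lambda_selected = lambda_sel, cv_folds = folds,
      c_index = c_overall,
      c_index_folds = c_folds,
      logrank_p = logrank_p,
      endpoint = endpoint,
      risk = tibble::tibble(
        subject_id = sv$subject_id, oof_linear_predictor = oof_lp,
        time = sv$time, event = sv$event
      )
    ),
    class = "encox_fit"
  )
}

#' @export
print.encox_fit <- function(x, ...) {
  cat(sprintf(
    "<encox_fit> %s: %d/%d nonzero features, lambda %.4g, C-index %.3f, log-rank p %.3g\n",
    x$endpoint, nrow(x$coefficients), x$n_features, x$lambda_selected,
    x$c_index, x$logrank_p
  ))
  invisible(x)
}

#' @export
tidy.encox_fit <- function(x, ...) {
  x$coefficients
}

#' @export
glance.encox_fit <- function(x, ...) {
  ok <- !is.na(x$c_index_folds)
  tibble::tibble(
    endpoint = x$endpoint,
    n_nonzero = nrow(x$coefficients),
    alpha = x$alpha,
    lambda_selected = x$lambda_selected,
    c_index = x$c_index,
    c_index_fold_mean = mean(x$c_index_folds[ok]),
    c_index_fold_sd = stats::sd(x$c_index_folds[ok]),
    logrank_p = x$logrank_p
  )
}

#' Harrell's concordance index
#'
#' The fraction of comparable subject pairs whose risk scores order their
#' event times correctly; risk ties count one half. 0.5 is chance level,
#' 1 is perfect concordance of higher risk with shorter survival.
#'
#' @param risk Numeric per-subject risk scores (higher = worse prognosis).
#' @param survival Survival-record tibble aligned with `risk`.
#' @return Scalar C-index in `[0, 1]`.
#' @export
concordance_index <- function(risk, survival) {
  cc <- survival::concordance(
    survival::Surv(survival$time, survival$event) ~ risk,
    reverse = TRUE
  )
  counts <- cc$count
  comparable <- counts["concordant"] + counts["discordant"] + counts["tied.x"]
  if (comparable == 0) {
    stop("no comparable pairs: concordance undefined", call. = FALSE)
  }
  unname(cc$concordance)
}

#' Kaplan-Meier curves with a log-rank group comparison
#'
#' Product-limit survival estimate per group; with two or more groups a
#' two-sided log-rank test is reported.
#'
#' @param survival Survival-record tibble.
#' @param groups Optional group labels aligned with `survival`; omitted or
#'   single-valued gives one curve and no test.
#' @return A `km_result`: `curves` tibble (`group`, `time`, `n_risk`,
#'   `n_event`, `survival`), `logrank_p` (NA for a single group) and the
#'   underlying `survfit` object.
#' @export
kaplan_meier <- function(survival, groups = NULL) {
  y <- survival::Surv(survival$time, survival$event)
  if (is.null(groups)) groups <- rep("all", nrow(survival))
  groups <- as.character(groups)
  if (any(table(groups) == 0L)) stop("empty group", call. = FALSE)
  df <- data.frame(time = survival$time, event = survival$event, group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- if (is.null(fit$strata)) {
    rep(unique(groups), length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  curves <- tibble::tibble(
    group = strata, time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, survival = fit$surv
  )
  logrank_p <- if (length(unique(groups)) >= 2L) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    stats::pchisq(sd$chisq,
      df = length(unique(groups)) - 1L,
      lower.tail = FALSE
    )
  } else {
    NA_real_
  }
  structure(
    list(curves = curves, logrank_p = logrank_p, survfit = fit),
    class = "km_result"
  )
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf(
    "<km_result> %d group(s), log-rank p %s\n",
    length(unique(x$curves$group)),
    ifelse(is.na(x$logrank_p), "n/a", format(signif(x$logrank_p, 3)))
  ))
  invisible(x)
}

#' @export
autoplot.km_result <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(
    split(object$curves, object$curves$group),
    function(g) {
      tibble::tibble(
        group = g$group[1],
        time = c(0, g$time), survival = c(1, g$survival)
      )
    }
  ))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time, y = .data$survival,
    colour = .data$group
  )) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Days", y = "Survival probability", colour = NULL,
      subtitle = if (!is.na(object$logrank_p)) {
        sprintf("log-rank p = %.3g", object$logrank_p)
      } else {
        NULL
      }
    ) +
    ggplot2::theme_minimal()
}
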