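#' Integrated pathway level (IPL) matrix
#'
#' Pathway-entity by sample activity matrix in the Firehose PARADIGM
#' dialect. Entity ids have the form `"<pathwayIndex>_<concept>"`
#' (e.g. `"19_EPHB3"`): a non-negative integer pathway index, an
#' underscore, then the concept (gene or complex) name.
#'
#' @param values Numeric entities x samples matrix.
#' @param entity_ids Character entity ids (unique, parseable).
#' @param sample_ids Character sample ids.
#' @return An `ipl_matrix` with `values`, and an `entities` tibble
#'   (`entity_id`, `pathway_index`, `concept`).
#' @export
ipl_matrix <- function(values, entity_ids, sample_ids) {
  values <- as.matrix(values)
  stopifnot(
    nrow(values) == length(entity_ids),
    ncol(values) == length(sample_ids)
  )
  if (anyDuplicated(entity_ids)) {
    stop("duplicate entity ids", call. = FALSE)
  }
  entities <- parse_entity_ids(entity_ids)
  dimnames(values) <- list(entity_ids, sample_ids)
  structure(
    list(values = values, entities = entities, sample_ids = sample_ids),
    class = "ipl_matrix"
  )
}

parse_entity_ids <- function(entity_ids) {
  m <- regmatches(entity_ids, regexec("^([0-9]+)_(.+)$", entity_ids))
  bad <- which(lengths(m) != 3L)
  if (length(bad) > 0L) {
    stop(
      "entity id without integer pathway prefix at row ", bad[1], ": '",
      entity_ids[bad[1]], "'",
      call. = FALSE
    )
  }
  tibble::tibble(
    entity_id = entity_ids,
    pathway_index = as.integer(vapply(m, `[`, character(1), 2L)),
    concept = vapply(m, `[`, character(1), 3L)
  )
}

#' @export
print.ipl_matrix <- function(x, ...) {
  cat(sprintf(
    "<ipl_matrix> %d entities x %d samples, %d pathways\n",
    nrow(x$values), ncol(x$values),
    length(unique(x$entities$pathway_index))
  ))
  invisible(x)
}

#' Read / write an IPL matrix (tab-delimited Firehose dialect)
#'
#' First column is the entity id, remaining columns are samples.
#'
#' @param path TSV path.
#' @return `parse_ipl()` returns an [ipl_matrix()]; `write_ipl()` returns
#'   `path` invisibly.
#' @export
parse_ipl <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  tb[[1]] <- as.character(tb[[1]])
  ipl_matrix(
    as.matrix(tb[, -1, drop = FALSE]),
    entity_ids = tb[[1]], sample_ids = names(tb)[-1]
  )
}

#' @rdname parse_ipl
#' @param ipl An [ipl_matrix()].
#' @export
write_ipl <- function(ipl, path) {
  stopifnot(inherits(ipl, "ipl_matrix"))
  tb <- tibble::as_tibble(ipl$values, rownames = "entity_id")
  readr::write_tsv(tb, path)
  invisible(path)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @return Adjusted values, monotone in rank and capped at 1.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Correlate image features with pathway-entity activities
#'
#' Pearson correlation and two-sided p-value for every (feature, entity)
#' pair over the samples shared between the feature table and the IPL
#' matrix, with Benjamini-Hochberg adjustment pooled across all pairs.
#'
#' @param ft A [feature_table()].
#' @param ipl An [ipl_matrix()].
#' @param features Optional character vector restricting to selected
#'   feature columns (e.g. the survival-significant ones).
#' @param threshold Adjusted-p significance threshold (default 0.05).
#' @return Tibble (`feature`, `entity_id`, `r`, `p`, `p_adjusted`,
#'   `significant`) with attributes `n_samples` and
#'   `fraction_features_significant` (share of tested features with at
#'   least one significant pair).
#' @export
correlate_features_ipl <- function(ft, ipl, features = NULL,
                                   threshold = 0.05) {
  stopifnot(inherits(ipl, "ipl_matrix"))
  X <- feature_matrix(ft)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  shared <- intersect(rownames(X), ipl$sample_ids)
  if (length(shared) < 3L) {
    stop("need at least 3 shared samples to correlate", call. = FALSE)
  }
  Xs <- X[shared, , drop = FALSE]
  E <- t(ipl$values[, shared, drop = FALSE])
  n <- length(shared)
  r <- stats::cor(Xs, E)
  r_cl <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r_cl * sqrt((n - 2) / (1 - r_cl^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out <- tibble::tibble(
    feature = rep(colnames(Xs), times = ncol(E)),
    entity_id = rep(colnames(E), each = ncol(Xs)),
    r = as.vector(r),
    p = as.vector(p)
  )
  out$p_adjusted <- bh_adjust(out$p)
  out$significant <- out$p_adjusted <= threshold
  attr(out, "n_samples") <- n
  sig_features <- unique(out$feature[out$significant])
  attr(out, "fraction_features_significant") <-
    length(sig_features) / ncol(Xs)
  out
}

# Newton inversion of the trigamma function (solves trigamma(x) = y).
trigamma_inverse <- function(y) {
  if (y > 1e7) {
    return(1 / sqrt(y))
  }
  if (y < 1e-6) {
    return(1 / y)
  }
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

# Empirical-Bayes fit of a scaled F distribution to sample variances:
# estimates the prior variance s0^2 and prior degrees of freedom d0 by
# matching moments of log(s^2).
fit_variance_prior <- function(s2, df1) {
  s2 <- pmax(s2, 1e-12)
  z <- log(s2)
  e <- z - digamma(df1 / 2) + log(df1 / 2)
  evar <- stats::var(e) - trigamma(df1 / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    # no excess dispersion beyond sampling noise: complete shrinkage
    df_prior <- Inf
    s2_prior <- mean(s2)
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

# Variance squeezing and the moderated t: each entity's pooled variance is
# shrunk toward the prior with weight df_prior, and the statistic gains
# df_prior degrees of freedom. df_prior -> 0 recovers the ordinary pooled t.
moderated_t_stats <- function(effect, s2, n1, n2, df_resid, df_prior,
                              s2_prior) {
  s2_post <- if (is.finite(df_prior)) {
    (df_prior * s2_prior + df_resid * s2) / (df_prior + df_resid)
  } else {
    rep(s2_prior, length(s2))
  }
  tstat <- effect / sqrt(s2_post * (1 / n1 + 1 / n2))
  df_total <- min(df_resid + df_prior, 1e6)
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = df_total))
}

#' Differential pathway activity between two subgroups
#'
#' Per-entity two-group test with empirical-Bayes variance moderation: the
#' residual variances of all entities inform a scaled inverse-chi-squared
#' prior (moments fit on log variances), each entity's variance is shrunk
#' toward the prior, and the moderated t-statistic is referred to a t
#' distribution with augmented degrees of freedom. A plain Welch t-test is
#' available as `method = "welch"`.
#'
#' @param ipl An [ipl_matrix()].
#' @param groups Two-group labels: a tibble with `subject_id` and `group`,
#'   or a vector named by sample id, or an unnamed vector aligned with the
#'   IPL samples.
#' @param threshold BH-adjusted significance threshold (default 0.1).
#' @param method `"moderated"` (default) or `"welch"`.
#' @return Tibble (`entity_id`, `pathway_index`, `concept`, `effect`
#'   = mean(group 1) - mean(group 2), `t`, `p`, `p_adjusted`,
#'   `significant`) with the prior parameters as attributes.
#' @export
differential_ipl <- function(ipl, groups, threshold = 0.1,
                             method = c("moderated", "welch")) {
  method <- match.arg(method)
  stopifnot(inherits(ipl, "ipl_matrix"))
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$subject_id)
  }
  if (!is.null(names(groups))) {
    shared <- intersect(ipl$sample_ids, names(groups))
    V <- ipl$values[, shared, drop = FALSE]
    g <- as.character(groups[shared])
  } else {
    stopifnot(length(groups) == ncol(ipl$values))
    V <- ipl$values
    g <- as.character(groups)
  }
  lv <- sort(unique(g))
  if (length(lv) != 2L) stop("need exactly two groups", call. = FALSE)
  i1 <- g == lv[1]
  i2 <- g == lv[2]
  n1 <- sum(i1)
  n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  m1 <- rowMeans(V[, i1, drop = FALSE])
  m2 <- rowMeans(V[, i2, drop = FALSE])
  effect <- m1 - m2
  if (method == "moderated") {
    v1 <- apply(V[, i1, drop = FALSE], 1, stats::var)
    v2 <- apply(V[, i2, drop = FALSE], 1, stats::var)
    df_resid <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df_resid
    prior <- fit_variance_prior(s2, df_resid)
    mod <- moderated_t_stats(
      effect, s2, n1, n2, df_resid,
      prior$df_prior, prior$s2_prior
    )
    tstat <- mod$t
    p <- mod$p
  } else {
    tt <- apply(V, 1, function(v) {
      ht <- stats::t.test(v[i1], v[i2])
      c(ht$statistic, ht$p.value)
    })
    tstat <- tt[1, ]
    p <- tt[2, ]
    prior <- list(df_prior = NA_real_, s2_prior = NA_real_)
  }
  out <- tibble::tibble(
    entity_id = rownames(V),
    pathway_index = ipl$entities$pathway_index[
      match(rownames(V), ipl$entities$entity_id)
    ],
    concept = ipl$entities$concept[
      match(rownames(V), ipl$entities$entity_id)
    ],
    effect = unname(effect), t = unname(tstat), p = unname(p)
  )
  out$p_adjusted <- bh_adjust(out$p)
  out$significant <- out$p_adjusted <= threshold
  attr(out, "df_prior") <- prior$df_prior
  attr(out, "s2_prior") <- prior$s2_prior
  out
}
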