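#' Simulate a two-stain H&E-like image with known ground truth
#'
#' Renders a Beer-Lambert image through a known stain matrix: randomly
#' placed nucleus disks carry high hematoxylin and low eosin concentration,
#' the surrounding cytoplasm carries eosin with little hematoxylin, and a
#' left-hand strip of `background_fraction` of the columns is stain-free
#' (full intensity). Gaussian noise is added in concentration space.
#'
#' @param width,height Image dimensions in pixels.
#' @param stain_model Ground-truth [stain_model()].
#' @param nucleus_count Number of nucleus disks.
#' @param nucleus_radius_range Length-2 integer range of disk radii.
#' @param background_fraction Fraction of columns that are background.
#' @param noise_sd Concentration noise standard deviation.
#' @param seed Integer seed; output is bit-reproducible.
#' @param subject_id,sample_type Metadata for the output image.
#' @return List: `image` ([slide_image()]), `stain_model` (ground truth,
#'   with `max_density` filled from the realized concentrations),
#'   `concentrations` (`h x w x 2` array).
#' @export
simulate_he_image <- function(width = 200L, height = 200L,
                              stain_model = reference_stain_model(),
                              nucleus_count = 40L,
                              nucleus_radius_range = c(4L, 10L),
                              background_fraction = 0.2,
                              noise_sd = 0.02, seed = 1L,
                              subject_id = NA_character_,
                              sample_type = "tumor") {
  stopifnot(width >= 1L, height >= 1L, noise_sd >= 0)
  if (max(nucleus_radius_range) * 2 > min(width, height)) {
    stop("nucleus radius exceeds the image", call. = FALSE)
  }
  withr::with_seed(seed, {
    conc <- array(0, dim = c(height, width, 2L))
    n_bg_cols <- round(background_fraction * width)
    tissue_cols <- setdiff(seq_len(width), seq_len(n_bg_cols))
    if (length(tissue_cols) > 0L) {
      # cytoplasm: eosin-dominated with faint hematoxylin
      nt <- height * length(tissue_cols)
      conc[, tissue_cols, 1] <- stats::runif(nt, 0, 0.08)
      conc[, tissue_cols, 2] <- stats::runif(nt, 0.3, 1.0)
      # nuclei: hematoxylin-dominated disks
      cgrid <- expand.grid(row = seq_len(height), col = tissue_cols)
      for (k in seq_len(nucleus_count)) {
        r <- sample(nucleus_radius_range[1]:nucleus_radius_range[2], 1L)
        cr <- sample(seq_len(height), 1L)
        cc <- sample(tissue_cols, 1L)
        rows <- max(1L, cr - r):min(height, cr + r)
        cols <- max(1L, cc - r):min(width, cc + r)
        for (j in cols) {
          dy <- rows - cr
          inside <- rows[dy^2 + (j - cc)^2 <= r^2]
          if (length(inside) > 0L && j > n_bg_cols) {
            conc[inside, j, 1] <- stats::runif(length(inside), 0.6, 1.2)
            conc[inside, j, 2] <- stats::runif(length(inside), 0, 0.08)
          }
        }
      }
      if (noise_sd > 0) {
        noise <- array(stats::rnorm(length(conc), sd = noise_sd), dim(conc))
        noise[, seq_len(n_bg_cols), ] <- 0
        conc <- conc + noise
      }
      conc[conc < 0] <- 0
    }
    image <- render_concentrations(conc, stain_model,
      subject_id = subject_id, sample_type = sample_type
    )
    truth <- stain_model
    cm <- matrix(conc, ncol = 2L)
    tissue_px <- rowSums(cm) > 0
    truth$max_density <- if (any(tissue_px)) {
      apply(cm[tissue_px, , drop = FALSE], 2, stats::quantile,
        probs = 0.99, names = FALSE
      )
    } else {
      c(1, 1)
    }
    list(image = image, stain_model = truth, concentrations = conc)
  })
}

# Solves for the uniform-censoring horizon c such that the expected
# censoring fraction E[P(C < T)] over subjects matches the target.
censoring_horizon <- function(rates, censor_fraction) {
  if (censor_fraction <= 0) {
    return(Inf)
  }
  expected_cens <- function(cc) {
    mean((1 - exp(-rates * cc)) / (rates * cc)) - censor_fraction
  }
  lo <- 1e-9 / max(rates)
  hi <- 1e9 / min(rates)
  stats::uniroot(expected_cens, c(lo, hi), tol = 1e-10, extendInt = "downX")$root
}

#' Simulate a cohort with planted class, cluster and survival structure
#'
#' Features are standard Gaussian. Tumor samples are shifted by
#' `class_shift` (in sd units) on a random feature subspace; tumor samples
#' additionally carry `n_clusters` planted mean-shift clusters on a second
#' random subspace. Survival times for tumor subjects follow an exponential
#' Cox model — hazard `baseline_hazard * exp(x' beta)` — with independent
#' uniform censoring on `(0, c)`, `c` solved numerically so the expected
#' censoring fraction matches `censor_fraction`. DFS times are generated
#' the same way from `dfs_beta`.
#'
#' @param n_tumor,n_normal Sample counts.
#' @param n_features Feature count.
#' @param class_shift Tumor-vs-normal mean shift (sd units) on
#'   `n_class_features` random features.
#' @param n_class_features,n_cluster_features Subspace sizes (default 10).
#' @param n_clusters Planted clusters among tumor samples (default 2).
#' @param cluster_shift Between-cluster mean shift in sd units.
#' @param survival_beta Length-`n_features` Cox coefficient vector for OS
#'   (default: 1 on the first five features, 0 elsewhere).
#' @param dfs_beta Coefficients for DFS (default: `survival_beta`
#'   reversed).
#' @param censor_fraction Target censoring fraction in `[0, 1)`.
#' @param baseline_hazard Baseline event rate per day.
#' @param seed Integer seed.
#' @return List: `features` ([feature_table()] with tumor/normal labels),
#'   `survival` (OS and DFS records for tumor subjects), and `truth`
#'   (planted class features, cluster assignment and features, betas,
#'   censoring horizons).
#' @export
simulate_cohort <- function(n_tumor = 60L, n_normal = 20L, n_features = 50L,
                            class_shift = 2, n_class_features = 10L,
                            n_clusters = 2L, cluster_shift = 2,
                            n_cluster_features = 10L,
                            survival_beta = NULL, dfs_beta = NULL,
                            censor_fraction = 0.25,
                            baseline_hazard = 1 / 1000, seed = 1L) {
  stopifnot(
    n_tumor > 0L, n_normal >= 0L, n_features > 0L,
    censor_fraction >= 0, censor_fraction < 1
  )
  if (is.null(survival_beta)) {
    survival_beta <- rep(0, n_features)
    survival_beta[seq_len(min(5L, n_features))] <- 1
  }
  stopifnot(length(survival_beta) == n_features)
  if (is.null(dfs_beta)) dfs_beta <- rev(survival_beta)
  withr::with_seed(seed, {
    n <- n_tumor + n_normal
    X <- matrix(stats::rnorm(n * n_features), n, n_features)
    is_tumor <- c(rep(TRUE, n_tumor), rep(FALSE, n_normal))
    class_features <- sample.int(
      n_features,
      min(n_class_features, n_features)
    )
    X[is_tumor, class_features] <- X[is_tumor, class_features] + class_shift
    cluster_assignment <- rep_len(seq_len(n_clusters), n_tumor)
    cluster_features <- sample.int(
      n_features,
      min(n_cluster_features, n_features)
    )
    offsets <- (seq_len(n_clusters) - (n_clusters + 1) / 2) * cluster_shift
    X[is_tumor, cluster_features] <-
      X[is_tumor, cluster_features] + offsets[cluster_assignment]
    ids <- sprintf("S%04d", seq_len(n))
    labels <- ifelse(is_tumor, "tumor", "normal")
    draw_endpoint <- function(beta, endpoint) {
      lp <- as.numeric(X[is_tumor, , drop = FALSE] %*% beta)
      rates <- baseline_hazard * exp(lp)
      t_event <- stats::rexp(n_tumor, rate = rates)
      horizon <- censoring_horizon(rates, censor_fraction)
      c_time <- if (is.finite(horizon)) {
        stats::runif(n_tumor, 0, horizon)
      } else {
        rep(Inf, n_tumor)
      }
      survival_records(
        ids[is_tumor],
        pmin(t_event, c_time),
        as.integer(t_event <= c_time),
        endpoint
      )
    }
    os <- draw_endpoint(survival_beta, "OS")
    dfs <- draw_endpoint(dfs_beta, "DFS")
    list(
      features = feature_table(X, ids, labels,
        extractor_name = "simulated"
      ),
      survival = dplyr::bind_rows(os, dfs),
      truth = list(
        class_features = sort(class_features),
        cluster_assignment = stats::setNames(
          cluster_assignment,
          ids[is_tumor]
        ),
        cluster_features = sort(cluster_features),
        survival_beta = survival_beta,
        dfs_beta = dfs_beta
      )
    )
  })
}

#' Simulate an IPL matrix coupled to chosen image features
#'
#' Each coupled entity is built as `r * z(feature) + sqrt(1 - r^2) * noise`
#' so its correlation with the feature equals the target in expectation;
#' all remaining entities are independent standard Gaussian noise. Entity
#' ids follow the `"<pathwayIndex>_<concept>"` dialect.
#'
#' @param ft A [feature_table()] supplying the samples and features.
#' @param n_entities Total entity count.
#' @param coupled_pairs Tibble with columns `feature` (column name of `ft`)
#'   and `r` (target correlation, strictly inside (-1, 1)); pair `i` is
#'   coupled to entity `i`.
#' @param seed Integer seed.
#' @return List: `ipl` ([ipl_matrix()]) and `truth` tibble
#'   (`feature`, `entity_id`, `target_r`).
#' @export
simulate_ipl <- function(ft, n_entities = 100L, coupled_pairs = NULL,
                         seed = 1L) {
  if (is.null(coupled_pairs)) {
    coupled_pairs <- tibble::tibble(feature = character(), r = numeric())
  }
  if (nrow(coupled_pairs) > 0 && any(abs(coupled_pairs$r) >= 1)) {
    stop("target correlations must lie strictly inside (-1, 1)",
      call. = FALSE
    )
  }
  stopifnot(nrow(coupled_pairs) <= n_entities)
  X <- feature_matrix(ft)
  n <- nrow(X)
  withr::with_seed(seed, {
    V <- matrix(stats::rnorm(n_entities * n), n_entities, n)
    entity_ids <- sprintf(
      "%d_G%04d",
      seq_len(n_entities) %% 20L, seq_len(n_entities)
    )
    for (i in seq_len(nrow(coupled_pairs))) {
      x <- as.numeric(scale(X[, coupled_pairs$feature[i]]))
      r <- coupled_pairs$r[i]
      V[i, ] <- r * x + sqrt(1 - r^2) * stats::rnorm(n)
    }
    truth <- tibble::tibble(
      feature = coupled_pairs$feature,
      entity_id = entity_ids[seq_len(nrow(coupled_pairs))],
      target_r = coupled_pairs$r
    )
    list(
      ipl = ipl_matrix(V, entity_ids, rownames(X)),
      truth = truth
    )
  })
}
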