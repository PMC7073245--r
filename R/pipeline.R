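# Polynomial rolling hash over serialized bytes; used for config/result
# digests (stability across runs, not cryptographic strength).
fnv1a_hex <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 5381
  for (b in bytes) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

stage_seed <- function(master_seed, stage) {
  (as.integer(master_seed) + sum(utf8ToInt(stage)) * 7919L) %% 2147483647L
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated
#' object. Per-stage seeds are derived deterministically from
#' `master_seed`, so a rerun with an identical configuration and inputs is
#' reproducible.
#'
#' @param images Path to a cohort manifest CSV (`subject_id`, `path`,
#'   `sample_type`), or `NULL`.
#' @param survival Path to a survival CSV (`subject_id`, `time_days`,
#'   `event`, `endpoint`), or `NULL`.
#' @param ipl Path to an IPL TSV, or `NULL`.
#' @param simulate `NULL`, or a named list of [simulate_cohort()] /
#'   [simulate_he_image()] arguments (`n_images` selects how many H&E
#'   images to simulate); when set, all inputs are generated.
#' @param output_dir Optional directory for result files.
#' @param augmentation_count,multiplier_low,multiplier_high Stain
#'   augmentation policy (defaults 50 and 0.95-1.05).
#' @param crop_size Crop side length, 256 or 512 unless
#'   `allow_any_size = TRUE`.
#' @param crop_count Crops per augmented image (default 20).
#' @param min_tissue_fraction Crop tissue filter (default 0.5).
#' @param extractor Feature extractor backend name.
#' @param classifier_folds,classifier_cost Linear-SVM cross-validation
#'   parameters (defaults 6 and 1).
#' @param screen_threshold Univariate Cox selection p-value (default 0.05).
#' @param enet_alpha,enet_folds Elastic-net Cox parameters (defaults 0.5
#'   and 10).
#' @param k_min,k_max K-means scan range (defaults 2 and 12).
#' @param correlation_threshold BH threshold for feature-IPL correlation
#'   (default 0.05).
#' @param differential_threshold BH threshold for differential pathway
#'   activity (default 0.1).
#' @param master_seed Master seed for all stages.
#' @param allow_any_size Permit non-standard crop sizes.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(images = NULL, survival = NULL, ipl = NULL,
                            simulate = NULL, output_dir = NULL,
                            augmentation_count = 50L,
                            multiplier_low = 0.95, multiplier_high = 1.05,
                            crop_size = 256L, crop_count = 20L,
                            min_tissue_fraction = 0.5,
                            extractor = "histogram",
                            classifier_folds = 6L, classifier_cost = 1,
                            screen_threshold = 0.05,
                            enet_alpha = 0.5, enet_folds = 10L,
                            k_min = 2L, k_max = 12L,
                            correlation_threshold = 0.05,
                            differential_threshold = 0.1,
                            master_seed = 1L, allow_any_size = FALSE) {
  cfg <- list(
    images = images, survival = survival, ipl = ipl, simulate = simulate,
    output_dir = output_dir,
    augmentation_count = as.integer(augmentation_count),
    multiplier_low = multiplier_low, multiplier_high = multiplier_high,
    crop_size = as.integer(crop_size), crop_count = as.integer(crop_count),
    min_tissue_fraction = min_tissue_fraction,
    extractor = extractor,
    classifier_folds = as.integer(classifier_folds),
    classifier_cost = classifier_cost,
    screen_threshold = screen_threshold,
    enet_alpha = enet_alpha, enet_folds = as.integer(enet_folds),
    k_min = as.integer(k_min), k_max = as.integer(k_max),
    correlation_threshold = correlation_threshold,
    differential_threshold = differential_threshold,
    master_seed = as.integer(master_seed),
    allow_any_size = isTRUE(allow_any_size)
  )
  for (th in c(
    "screen_threshold", "correlation_threshold",
    "differential_threshold"
  )) {
    if (cfg[[th]] <= 0 || cfg[[th]] >= 1) {
      stop(th, " must lie in (0, 1)", call. = FALSE)
    }
  }
  if (cfg$crop_count < 1L) stop("crop_count must be >= 1", call. = FALSE)
  if (!cfg$allow_any_size && !cfg$crop_size %in% c(256L, 512L)) {
    stop("crop_size must be 256 or 512 (set allow_any_size to override)",
      call. = FALSE
    )
  }
  if (cfg$enet_alpha < 0 || cfg$enet_alpha > 1) {
    stop("enet_alpha must lie in [0, 1]", call. = FALSE)
  }
  cfg$hash <- fnv1a_hex(cfg[setdiff(names(cfg), "hash")])
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      call. = FALSE
    )
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input acquisition (files or simulation), stain
#' normalization and augmentation, crop sampling, per-crop feature
#' extraction with median aggregation to subjects, 2-D embedding,
#' cross-validated tumor/normal classification, univariate Cox screening
#' for OS and DFS, elastic-net Cox modelling, K-means subgroup discovery
#' on the doubly-significant features, subgroup survival comparison, and
#' feature-pathway correlation plus differential pathway activity between
#' subgroups. Every stage is seeded from `master_seed`; outputs carry the
#' configuration hash.
#'
#' With simulated inputs the image branch runs on the synthetic H&E
#' images (yielding `image_features`), while the cohort-level analyses run
#' on the simulated cohort feature table, whose planted structure is
#' known.
#'
#' @param config A [pipeline_config()].
#' @return A result bundle (list) with elements `config`, `image_features`,
#'   `features`, `embedding`, `classification`, `screen_os`, `screen_dfs`,
#'   `significant_both`, `enet_os`, `cluster_scan`, `subgroups`,
#'   `correlations`, `differential`, and `digest` (hash of the key
#'   numeric results).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  bundle <- list(config = config)

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    n_images <- sim_args$n_images %||% 4L
    n_entities <- sim_args$n_entities %||% 100L
    sim_args$n_images <- NULL
    sim_args$n_entities <- NULL
    cohort <- run_stage("simulate", do.call(simulate_cohort, c(
      sim_args,
      list(seed = stage_seed(config$master_seed, "cohort"))
    )))
    ft <- cohort$features
    surv <- cohort$survival
    truth <- cohort$truth
    images <- run_stage("simulate", lapply(seq_len(n_images), function(i) {
      simulate_he_image(
        width = max(config$crop_size + 8L, 200L),
        height = max(config$crop_size + 8L, 200L),
        background_fraction = 0.1,
        seed = stage_seed(config$master_seed, paste0("image", i)),
        subject_id = sprintf("IMG%03d", i),
        sample_type = if (i %% 2L == 1L) "tumor" else "normal"
      )$image
    }))
    ipl_sim <- run_stage("simulate", simulate_ipl(
      ft,
      n_entities = n_entities,
      coupled_pairs = tibble::tibble(
        feature = feature_col_names(ft)[1:2], r = c(0.7, -0.6)
      ),
      seed = stage_seed(config$master_seed, "ipl")
    ))
    ipl <- ipl_sim$ipl
    bundle$truth <- truth
  } else {
    images <- if (!is.null(config$images)) {
      run_stage("load", read_cohort_manifest(config$images)$images)
    } else {
      list()
    }
    surv <- if (!is.null(config$survival)) {
      run_stage("load", read_survival_csv(config$survival))
    } else {
      NULL
    }
    ipl <- if (!is.null(config$ipl)) {
      run_stage("load", parse_ipl(config$ipl))
    } else {
      NULL
    }
    ft <- NULL
  }

  # --- image branch: normalize, augment, crop, extract, aggregate ---------
  if (length(images) > 0L) {
    extractor <- feature_extractor(config$extractor)
    policy <- augmentation_policy(
      count = config$augmentation_count,
      multiplier_low = config$multiplier_low,
      multiplier_high = config$multiplier_high,
      seed = stage_seed(config$master_seed, "augment")
    )
    per_image <- run_stage("extract", lapply(seq_along(images), function(i) {
      norm <- normalize_to_reference(images[[i]])
      extract_image_features(norm, extractor,
        policy = policy,
        crop_size = config$crop_size, crop_count = config$crop_count,
        seed = stage_seed(config$master_seed, paste0("crops", i)),
        min_tissue_fraction = config$min_tissue_fraction
      )$features
    }))
    by_subject <- split(
      per_image,
      vapply(images, function(im) im$subject_id, character(1))
    )
    subject_vectors <- lapply(by_subject, aggregate_to_subject)
    subject_labels <- vapply(
      split(
        vapply(images, function(im) im$sample_type, character(1)),
        vapply(images, function(im) im$subject_id, character(1))
      ),
      function(x) x[1], character(1)
    )
    bundle$image_features <- feature_table(
      do.call(rbind, subject_vectors),
      names(subject_vectors), subject_labels,
      extractor_name = extractor$name, crop_size = config$crop_size
    )
    if (is.null(ft)) ft <- bundle$image_features
  }
  if (is.null(ft)) stop("no feature table: provide images or simulate", call. = FALSE)
  bundle$features <- ft

  # --- embedding and classification ---------------------------------------
  n <- nrow(ft)
  perp <- min(15, floor((n - 2) / 3))
  if (perp >= 2) {
    bundle$embedding <- run_stage("embed", embed_features(
      ft,
      n_components = min(10L, nrow(ft) - 1L, length(feature_col_names(ft))),
      perplexity = perp, seed = stage_seed(config$master_seed, "embed")
    ))
  }
  if (length(unique(stats::na.omit(ft$label))) == 2L) {
    bundle$classification <- run_stage("classify", classify_cv(
      ft,
      folds = config$classifier_folds, cost = config$classifier_cost,
      seed = stage_seed(config$master_seed, "classify")
    ))
  }

  # --- survival analyses ---------------------------------------------------
  if (!is.null(surv)) {
    bundle$screen_os <- run_stage("screen", suppressWarnings(screen_features(
      ft, surv,
      endpoint = "OS", threshold = config$screen_threshold
    )))
    bundle$screen_dfs <- run_stage("screen", suppressWarnings(screen_features(
      ft, surv,
      endpoint = "DFS", threshold = config$screen_threshold
    )))
    bundle$significant_both <- intersect_significant(
      list(bundle$screen_os, bundle$screen_dfs)
    )
    bundle$enet_os <- run_stage("enet", fit_elasticnet_cox(
      ft, surv,
      endpoint = "OS", alpha = config$enet_alpha,
      folds = config$enet_folds,
      seed = stage_seed(config$master_seed, "enet")
    ))

    # --- subgroup discovery on doubly-significant features ---------------
    cluster_cols <- if (length(bundle$significant_both) >= 2L) {
      bundle$significant_both
    } else {
      feature_col_names(ft)
    }
    tumor_ids <- intersect(
      ft$sample_id[is.na(ft$label) | ft$label == "tumor"],
      surv$subject_id
    )
    tumor_ft <- ft[match(tumor_ids, ft$sample_id), , drop = FALSE]
    bundle$cluster_scan <- run_stage("cluster", cluster_scan(
      feature_matrix(tumor_ft)[, cluster_cols, drop = FALSE],
      k_min = config$k_min,
      k_max = min(config$k_max, length(tumor_ids) - 1L),
      seed = stage_seed(config$master_seed, "cluster")
    ))
    bundle$subgroups <- run_stage("subgroups", subgroup_survival(
      bundle$cluster_scan$labels, surv,
      endpoint = "OS"
    ))

    # --- pathway correlation and differential activity -------------------
    if (!is.null(ipl)) {
      bundle$correlations <- run_stage("correlate", correlate_features_ipl(
        ft, ipl,
        features = cluster_cols,
        threshold = config$correlation_threshold
      ))
      bundle$differential <- run_stage("differential", differential_ipl(
        ipl, bundle$subgroups$groups,
        threshold = config$differential_threshold
      ))
    }
  }

  bundle$digest <- fnv1a_hex(list(
    config_hash = config$hash,
    features = round(unname(feature_matrix(ft)), 10),
    mean_auc = bundle$classification$mean_auc,
    chosen_k = bundle$cluster_scan$chosen_k,
    c_index = bundle$enet_os$c_index
  ))

  if (!is.null(config$output_dir)) {
    write_bundle(bundle, config$output_dir)
  }
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(bundle$features, file.path(dir, "features.tsv"))
  summary <- list(config_hash = bundle$config$hash, digest = bundle$digest)
  if (!is.null(bundle$classification)) {
    summary$classification <- as.list(glance(bundle$classification))
  }
  if (!is.null(bundle$enet_os)) {
    summary$enet_os <- as.list(glance(bundle$enet_os))
  }
  if (!is.null(bundle$cluster_scan)) {
    summary$chosen_k <- bundle$cluster_scan$chosen_k
  }
  if (!is.null(bundle$subgroups)) {
    summary$subgroups <- as.list(glance(bundle$subgroups))
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
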