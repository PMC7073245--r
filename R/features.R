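#' Per-crop feature extractors
#'
#' All extractors shipped with the package are deterministic and
#' weights-free: a crop is summarized by per-channel intensity histograms
#' (plus per-channel means and standard deviations) which are passed through
#' a fixed random projection seeded by the extractor name. The named
#' backends differ only in their output dimension, which follows the channel
#' arithmetic of the corresponding convolutional architecture:
#'
#' * `"vgg16"`: the four late convolutional stages contribute
#'   128 + 256 + 512 + 512 = 1408 channels, one pooled scalar each;
#' * `"inception_v3"`, `"resnet50"`: the globally pooled final convolutional
#'   block has 2048 channels;
#' * `"histogram"`: a compact generic backend (default 64 dimensions).
#'
#' Identical crops always map to identical vectors, so the full pipeline is
#' reproducible bit-for-bit. Pretrained-weight extraction is out of scope;
#' any external extractor can be plugged in by constructing the same object
#' with its own `extract_fun`.
#'
#' @param name Backend name.
#' @param output_dim Output dimension; defaults to the backend's
#'   architecture-determined value.
#' @param bins Histogram bins per channel (default 32).
#' @param extract_fun Optional custom function `crop -> numeric(output_dim)`.
#' @return A `feature_extractor` object with fields `name`, `output_dim`,
#'   `deterministic`.
#' @export
feature_extractor <- function(name = c(
                                "histogram", "vgg16", "inception_v3",
                                "resnet50"
                              ),
                              output_dim = NULL, bins = 32L,
                              extract_fun = NULL) {
  name <- match.arg(name)
  if (is.null(output_dim)) {
    output_dim <- switch(name,
      vgg16 = 128L + 256L + 512L + 512L,
      inception_v3 = 2048L,
      resnet50 = 2048L,
      histogram = 64L
    )
  }
  output_dim <- as.integer(output_dim)
  stopifnot(output_dim >= 1L)
  in_dim <- 3L * bins + 6L
  seed <- sum(utf8ToInt(name)) %% 100000L
  projection <- withr::with_seed(
    seed,
    matrix(stats::rnorm(output_dim * in_dim), nrow = output_dim) /
      sqrt(in_dim)
  )
  structure(
    list(
      name = name, output_dim = output_dim, bins = as.integer(bins),
      projection = projection, deterministic = TRUE,
      extract_fun = extract_fun
    ),
    class = "feature_extractor"
  )
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat(sprintf(
    "<feature_extractor> %s, %d features (deterministic)\n",
    x$name, x$output_dim
  ))
  invisible(x)
}

#' Extract the feature vector of a single crop
#'
#' @param crop A crop from [sample_crops()], or any `slide_image`-like
#'   object with a `pixels` field.
#' @param extractor A [feature_extractor()].
#' @return Numeric vector of length `extractor$output_dim`.
#' @export
extract_crop_features <- function(crop, extractor) {
  stopifnot(inherits(extractor, "feature_extractor"))
  if (!is.null(extractor$extract_fun)) {
    v <- extractor$extract_fun(crop)
    if (length(v) != extractor$output_dim) {
      stop("custom extractor returned wrong dimension", call. = FALSE)
    }
    return(as.numeric(v))
  }
  px <- crop$pixels
  if (nrow(px) < 8L || ncol(px) < 8L) {
    stop("crop too small for feature extraction (minimum 8 x 8)",
      call. = FALSE
    )
  }
  breaks <- seq(0, 255, length.out = extractor$bins + 1L)
  desc <- unlist(lapply(1:3, function(ch) {
    v <- as.vector(px[, , ch])
    h <- graphics::hist(pmin(v, 255), breaks = breaks, plot = FALSE)$counts
    c(h / length(v), mean(v) / 255, stats::sd(v) / 255)
  }))
  as.numeric(extractor$projection %*% desc)
}

#' Median-aggregate per-crop feature vectors to one per-image vector
#'
#' The elementwise median across all crops of all augmentations of an
#' image; permutation-invariant and monotone in every coordinate.
#'
#' @param vectors A numeric matrix (rows = vectors) or list of equal-length
#'   numeric vectors.
#' @return A single numeric vector of medians.
#' @export
aggregate_to_image <- function(vectors) {
  if (is.list(vectors)) {
    if (length(vectors) == 0L) stop("no vectors to aggregate", call. = FALSE)
    lens <- lengths(vectors)
    if (length(unique(lens)) != 1L) {
      stop("vectors have differing lengths", call. = FALSE)
    }
    vectors <- do.call(rbind, vectors)
  }
  if (!is.matrix(vectors) || nrow(vectors) == 0L) {
    stop("no vectors to aggregate", call. = FALSE)
  }
  apply(vectors, 2, stats::median)
}

#' Median-aggregate per-image vectors to one per-subject vector
#'
#' Subjects with multiple images are represented by the elementwise median
#' of their per-image vectors.
#'
#' @inheritParams aggregate_to_image
#' @return A single numeric vector of medians.
#' @export
aggregate_to_subject <- function(vectors) {
  aggregate_to_image(vectors)
}

#' Extract aggregated features for one image
#'
#' Runs the full per-image branch: stain-space augmentation, random crop
#' sampling from every augmented image, per-crop feature extraction, and
#' median aggregation across all crops of all augmentations.
#'
#' @param image A [slide_image()].
#' @param extractor A [feature_extractor()].
#' @param policy An [augmentation_policy()].
#' @param crop_size,crop_count Crop parameters (defaults 256 and 20).
#' @param seed Seed for crop sampling.
#' @param min_tissue_fraction Passed to [sample_crops()].
#' @return List with `features` (aggregated vector) and `per_crop`
#'   (matrix of all per-crop vectors, retained for inspection).
#' @export
extract_image_features <- function(image, extractor,
                                   policy = augmentation_policy(),
                                   crop_size = 256L, crop_count = 20L,
                                   seed = 1L, min_tissue_fraction = 0.5) {
  augmented <- augment_image(image, policy)
  per_crop <- do.call(rbind, lapply(seq_along(augmented), function(a) {
    crops <- sample_crops(augmented[[a]], crop_size,
      count = crop_count,
      seed = seed + a, min_tissue_fraction = min_tissue_fraction,
      augmentation_index = a
    )
    do.call(rbind, lapply(crops, extract_crop_features, extractor = extractor))
  }))
  list(features = aggregate_to_image(per_crop), per_crop = per_crop)
}

#' Build a feature table
#'
#' The cohort-level container for downstream analysis: a tibble with one
#' row per sample, columns `sample_id`, `label` and one numeric column per
#' feature (`f1`, `f2`, ...). Extractor name and crop size travel along as
#' attributes.
#'
#' @param values Numeric samples x features matrix (no missing values).
#' @param sample_ids Character vector of unique sample ids.
#' @param labels Optional `"tumor"`/`"normal"` labels.
#' @param extractor_name,crop_size Provenance strings/ints.
#' @return A `feature_table` tibble.
#' @export
feature_table <- function(values, sample_ids, labels = NULL,
                          extractor_name = NA_character_,
                          crop_size = NA_integer_) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(sample_ids))
  if (anyNA(values)) stop("feature table cannot contain NA", call. = FALSE)
  if (anyDuplicated(sample_ids)) {
    stop("sample ids must be unique", call. = FALSE)
  }
  if (is.null(labels)) labels <- rep(NA_character_, nrow(values))
  colnames(values) <- paste0("f", seq_len(ncol(values)))
  ft <- tibble::as_tibble(values)
  ft <- tibble::add_column(ft,
    sample_id = as.character(sample_ids),
    label = as.character(labels), .before = 1
  )
  attr(ft, "extractor_name") <- extractor_name
  attr(ft, "crop_size") <- crop_size
  class(ft) <- c("feature_table", class(ft))
  ft
}

#' Extract the numeric feature matrix from a feature table
#'
#' @param ft A [feature_table()].
#' @return Numeric matrix with sample ids as row names.
#' @export
feature_matrix <- function(ft) {
  m <- as.matrix(ft[, grep("^f[0-9]+$", names(ft), value = TRUE),
    drop = FALSE
  ])
  storage.mode(m) <- "double"
  rownames(m) <- ft$sample_id
  m
}

feature_col_names <- function(ft) {
  grep("^f[0-9]+$", names(ft), value = TRUE)
}

#' Write / read a feature table as TSV plus JSON sidecar
#'
#' @param ft A [feature_table()].
#' @param path TSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` a [feature_table()].
#' @export
write_feature_table <- function(ft, path) {
  readr::write_tsv(tibble::as_tibble(ft), path)
  jsonlite::write_json(
    list(
      extractor_name = attr(ft, "extractor_name"),
      crop_size = attr(ft, "crop_size"),
      n_samples = nrow(ft), n_features = length(feature_col_names(ft))
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), label = readr::col_character(),
    .default = readr::col_double()
  ))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) {
    jsonlite::read_json(side, simplifyVector = TRUE)
  } else {
    list(extractor_name = NA_character_, crop_size = NA_integer_)
  }
  feature_table(
    as.matrix(tb[, grep("^f[0-9]+$", names(tb)), drop = FALSE]),
    tb$sample_id, tb$label,
    extractor_name = meta$extractor_name, crop_size = meta$crop_size
  )
}
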