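#' Reference summaries of the TCGA-LIHC cohort analysis
#'
#' Bundled summary tables from a published prognostic analysis of the
#' TCGA-LIHC diagnostic-slide cohort (421 tumor and 105 adjacent-normal
#' samples), used for arithmetic consistency checks: counts of
#' univariately survival-significant features per extractor backend and
#' crop size, and the cross-backend subgroup overlap counts.
#'
#' @return `univariate_significance_table()`: tibble with `model`,
#'   `feature_number`, `crop_size`, `os_significant`, `dfs_significant`.
#' @export
univariate_significance_table <- function() {
  tibble::tribble(
    ~model, ~feature_number, ~crop_size, ~os_significant, ~dfs_significant,
    "vgg16", 1408L, 256L, 272L, 219L,
    "inception_v3", 2048L, 256L, 574L, 294L,
    "resnet50", 2048L, 256L, 522L, 385L,
    "vgg16", 1408L, 512L, 300L, 201L,
    "inception_v3", 2048L, 512L, 356L, 290L,
    "resnet50", 2048L, 512L, 347L, 390L
  )
}

#' @rdname univariate_significance_table
#' @return `subgroup_overlap_counts()`: tibble with one row per
#'   combination of subgroup labels (`inception_v3`, `vgg16`, `resnet50`)
#'   and the sample count `n`; counts sum to the 421 tumor samples.
#' @export
subgroup_overlap_counts <- function() {
  tibble::tribble(
    ~inception_v3, ~vgg16, ~resnet50, ~n,
    1L, 1L, 1L, 176L,
    1L, 1L, 2L, 18L,
    1L, 2L, 1L, 20L,
    1L, 2L, 2L, 4L,
    2L, 1L, 1L, 48L,
    2L, 1L, 2L, 109L,
    2L, 2L, 1L, 16L,
    2L, 2L, 2L, 30L
  )
}

#' @rdname univariate_significance_table
#' @return `lihc_median_image_size()`: named vector with the cohort's
#'   median level-3 image `width` and `height` in pixels.
#' @export
lihc_median_image_size <- function() {
  c(width = 5601, height = 2249.5)
}
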