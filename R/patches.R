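#' Randomly sample square crops from a slide image
#'
#' Origins are drawn uniformly (with replacement) over all valid 0-based
#' positions. Crops whose tissue fraction — the share of pixels with mean
#' optical density above `od_threshold` — falls below `min_tissue_fraction`
#' are rejected and redrawn up to 100 times each; if no draw passes, the
#' best-seen crop is kept and a warning is emitted. Set
#' `min_tissue_fraction = 0` to disable the filter.
#'
#' @param image A [slide_image()] at least `size x size` pixels.
#' @param size Crop side length in pixels (the standard sizes are 256
#'   and 512).
#' @param count Number of crops (default 20).
#' @param seed Integer seed; identical seeds reproduce the crops.
#' @param min_tissue_fraction Minimum tissue fraction per crop (default 0.5).
#' @param od_threshold Mean-OD threshold defining tissue pixels
#'   (default 0.15).
#' @return List of `crop` objects, each with `pixels` (`size x size x 3`),
#'   0-based `origin_row`/`origin_col`, `size`, `tissue_fraction` and
#'   provenance fields `source_image_id`, `augmentation_index`.
#' @export
sample_crops <- function(image, size, count = 20L, seed = 1L,
                         min_tissue_fraction = 0.5, od_threshold = 0.15,
                         augmentation_index = NA_integer_) {
  stopifnot(inherits(image, "slide_image"))
  size <- as.integer(size)
  if (size > image$height || size > image$width) {
    stop(sprintf(
      "crop size %d exceeds image dimensions %d x %d",
      size, image$height, image$width
    ), call. = FALSE)
  }
  mean_od <- apply(rgb_to_od(image), c(1, 2), mean)
  n_row <- image$height - size + 1L
  n_col <- image$width - size + 1L
  crops <- withr::with_seed(seed, {
    low_tissue <- 0L
    out <- vector("list", count)
    for (i in seq_len(count)) {
      best <- NULL
      for (attempt in 1:100) {
        r0 <- sample.int(n_row, 1L) - 1L
        c0 <- sample.int(n_col, 1L) - 1L
        tf <- mean(mean_od[(r0 + 1L):(r0 + size), (c0 + 1L):(c0 + size)] >
          od_threshold)
        if (is.null(best) || tf > best$tissue_fraction) {
          best <- list(origin_row = r0, origin_col = c0, tissue_fraction = tf)
        }
        if (tf >= min_tissue_fraction) break
      }
      if (best$tissue_fraction < min_tissue_fraction) {
        low_tissue <- low_tissue + 1L
      }
      out[[i]] <- best
    }
    if (low_tissue > 0L) {
      warning(sprintf(
        "%d of %d crops fell below the tissue fraction %.2f; best-seen crops kept",
        low_tissue, count, min_tissue_fraction
      ), call. = FALSE)
    }
    out
  })
  lapply(seq_along(crops), function(i) {
    cr <- crops[[i]]
    rows <- (cr$origin_row + 1L):(cr$origin_row + size)
    cols <- (cr$origin_col + 1L):(cr$origin_col + size)
    structure(
      list(
        pixels = image$pixels[rows, cols, , drop = FALSE],
        origin_row = cr$origin_row, origin_col = cr$origin_col,
        size = size, tissue_fraction = cr$tissue_fraction,
        source_image_id = image$subject_id,
        augmentation_index = augmentation_index
      ),
      class = "crop"
    )
  })
}

#' @export
print.crop <- function(x, ...) {
  cat(sprintf(
    "<crop> %dpx at (%d, %d), tissue %.2f\n",
    x$size, x$origin_row, x$origin_col, x$tissue_fraction
  ))
  invisible(x)
}

#' Fraction of image pixels covered by a crop set, in percent
#'
#' `100 * count * size^2 / (width * height)`; overlaps between crops are not
#' deduplicated, matching the average-coverage arithmetic used to describe
#' random crop sampling.
#'
#' @param image_width,image_height Source dimensions in pixels.
#' @param size Crop side length.
#' @param count Number of crops.
#' @return Coverage percentage.
#' @export
crop_coverage_percent <- function(image_width, image_height, size, count) {
  stopifnot(image_width > 0, image_height > 0, size > 0, count > 0)
  100 * count * size^2 / (image_width * image_height)
}

#' Crop manifest as a tibble
#'
#' @param crops List of crops from [sample_crops()].
#' @return Tibble with one row per crop: image id, augmentation index,
#'   origin, size and tissue fraction.
#' @export
crop_manifest <- function(crops) {
  purrr::map_dfr(crops, function(cr) {
    tibble::tibble(
      image_id = cr$source_image_id,
      augmentation_index = cr$augmentation_index,
      origin_row = cr$origin_row, origin_col = cr$origin_col,
      size = cr$size, tissue_fraction = cr$tissue_fraction
    )
  })
}
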