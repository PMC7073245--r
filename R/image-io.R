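#' Slide image objects
#'
#' A `slide_image` is an 8-bit RGB raster (stored as a numeric
#' `height x width x 3` array with values in `[0, 255]`) together with the
#' subject it came from, its sample type (tumor or adjacent normal) and,
#' optionally, the pyramid level it was read from.
#'
#' @param pixels Numeric array `height x width x 3`, values in `[0, 255]`.
#' @param subject_id Subject identifier (string).
#' @param sample_type `"tumor"` or `"normal"`.
#' @param source_level Integer pyramid level the raster came from, or `NA`.
#' @return A `slide_image` object.
#' @export
slide_image <- function(pixels, subject_id = NA_character_,
                        sample_type = c("tumor", "normal"),
                        source_level = NA_integer_) {
  sample_type <- match.arg(sample_type)
  pixels <- as_pixel_array(pixels)
  structure(
    list(
      pixels = pixels,
      width = ncol(pixels),
      height = nrow(pixels),
      subject_id = subject_id,
      sample_type = sample_type,
      source_level = source_level
    ),
    class = "slide_image"
  )
}

as_pixel_array <- function(pixels) {
  if (length(dim(pixels)) == 2L) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] >= 3L)
  pixels <- pixels[, , 1:3, drop = FALSE]
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  pixels
}

#' @export
print.slide_image <- function(x, ...) {
  cat(sprintf(
    "<slide_image> %d x %d px, subject %s (%s)\n",
    x$width, x$height,
    ifelse(is.na(x$subject_id), "?", x$subject_id), x$sample_type
  ))
  invisible(x)
}

#' @export
dim.slide_image <- function(x) c(x$height, x$width, 3L)

#' Read a slide-derived RGB image, optionally downsampling
#'
#' Reads an 8-bit RGB PNG or TIFF and reduces it by an integer factor using
#' block-mean (area) averaging, the semantic equivalent of moving down a
#' slide pyramid level. Output dimensions are `ceiling(original / factor)`
#' per axis, so partial edge blocks are averaged rather than discarded.
#'
#' @param path Path to a PNG or TIFF file (8-bit RGB or RGBA; alpha dropped).
#' @param downsample_factor Positive integer; 1 returns the image unchanged.
#' @inheritParams slide_image
#' @return A [slide_image()].
#' @export
load_image <- function(path, downsample_factor = 1L,
                       subject_id = NA_character_,
                       sample_type = c("tumor", "normal")) {
  sample_type <- match.arg(sample_type)
  if (!file.exists(path)) {
    stop("image file does not exist: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      stop("unsupported image format: .", ext, call. = FALSE)
    ),
    error = function(e) {
      stop("failed to decode image '", path, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  img <- slide_image(as_pixel_array(raw * 255),
    subject_id = subject_id, sample_type = sample_type
  )
  downsample_image(img, downsample_factor)
}

#' Downsample a slide image by block averaging
#'
#' @param image A [slide_image()].
#' @param factor Positive integer reduction factor.
#' @return A [slide_image()] of dimension `ceiling(dim / factor)`.
#' @export
downsample_image <- function(image, factor) {
  stopifnot(inherits(image, "slide_image"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) {
    stop("downsample factor must be a positive integer", call. = FALSE)
  }
  if (factor == 1L) {
    return(image)
  }
  px <- image$pixels
  grp_r <- ceiling(seq_len(nrow(px)) / factor)
  grp_c <- ceiling(seq_len(ncol(px)) / factor)
  out <- array(0, dim = c(max(grp_r), max(grp_c), 3L))
  cnt_r <- tabulate(grp_r)
  cnt_c <- tabulate(grp_c)
  for (ch in 1:3) {
    m <- rowsum(px[, , ch], grp_r) / cnt_r
    m <- t(rowsum(t(m), grp_c) / cnt_c)
    out[, , ch] <- m
  }
  slide_image(out,
    subject_id = image$subject_id, sample_type = image$sample_type,
    source_level = image$source_level
  )
}

#' Write a slide image to PNG
#'
#' @param image A [slide_image()].
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "slide_image"))
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns `subject_id`, `path` and
#' `sample_type`; each row names one image file belonging to a subject.
#' Subjects may own multiple images.
#'
#' @param path Manifest CSV path.
#' @param downsample_factor Passed to [load_image()] for every file.
#' @return A list with `images` (list of [slide_image()]) and the manifest
#'   tibble.
#' @export
read_cohort_manifest <- function(path, downsample_factor = 1L) {
  manifest <- readr::read_csv(path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      path = readr::col_character(),
      sample_type = readr::col_character()
    )
  )
  images <- purrr::pmap(manifest, function(subject_id, path, sample_type) {
    load_image(path, downsample_factor,
      subject_id = subject_id, sample_type = sample_type
    )
  })
  list(images = images, manifest = manifest)
}

#' Group cohort images by subject
#'
#' @param images List of [slide_image()] objects.
#' @return Named list of image lists, one element per subject, ordered by
#'   subject id.
#' @export
group_by_subject <- function(images) {
  if (length(images) == 0L) {
    return(stats::setNames(list(), character()))
  }
  ids <- vapply(images, function(im) im$subject_id, character(1))
  split(images, factor(ids, levels = sort(unique(ids))))
}
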