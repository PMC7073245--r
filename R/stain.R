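#' Stain model: optical-density vectors and concentration maxima
#'
#' A two-stain (hematoxylin and eosin) model of an H&E image under the
#' Beer-Lambert law. `matrix` holds one unit-norm 3-vector of per-channel
#' optical-density absorption per column (column 1 = hematoxylin, column 2 =
#' eosin); `max_density` holds a robust per-stain concentration maximum used
#' to match stain intensity between images.
#'
#' @param matrix 3 x 2 numeric matrix; columns are normalized to unit
#'   Euclidean norm and must be non-negative and more than 1 degree apart.
#' @param max_density Length-2 positive numeric vector, or `NA` when not yet
#'   estimated.
#' @return A `stain_model` object.
#' @export
stain_model <- function(matrix, max_density = c(NA_real_, NA_real_)) {
  matrix <- as.matrix(matrix)
  stopifnot(nrow(matrix) == 3L, ncol(matrix) == 2L)
  if (any(matrix < -1e-8)) {
    stop("stain vectors must be non-negative", call. = FALSE)
  }
  matrix[matrix < 0] <- 0
  matrix <- sweep(matrix, 2, sqrt(colSums(matrix^2)), "/")
  if (stain_angle(matrix[, 1], matrix[, 2]) <= 1) {
    stop("stain vectors are collinear (angle <= 1 degree)", call. = FALSE)
  }
  structure(
    list(matrix = matrix, max_density = as.numeric(max_density)),
    class = "stain_model"
  )
}

#' @export
print.stain_model <- function(x, ...) {
  cat("<stain_model>\n")
  m <- round(x$matrix, 4)
  dimnames(m) <- list(c("R", "G", "B"), c("hematoxylin", "eosin"))
  print(m)
  cat("max_density:", signif(x$max_density, 4), "\n")
  invisible(x)
}

#' Angle in degrees between two stain vectors
#' @param a,b Numeric 3-vectors.
#' @return Angle in degrees.
#' @export
stain_angle <- function(a, b) {
  ct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Classical published H&E reference stain model
#'
#' Standard literature optical-density vectors, H = (0.65, 0.70, 0.29) and
#' E = (0.07, 0.99, 0.11), column-normalized.
#'
#' @param max_density Per-stain reference concentration maxima.
#' @return A [stain_model()].
#' @export
reference_stain_model <- function(max_density = c(1.9705, 1.0308)) {
  stain_model(
    cbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11)),
    max_density = max_density
  )
}

#' RGB to optical density
#'
#' Per channel, `OD = -log10(max(I, 1) / background_intensity)` under the
#' Beer-Lambert law; stain contributions add linearly in OD space.
#'
#' @param image A [slide_image()] or a `h x w x 3` pixel array in `[0, 255]`.
#' @param background_intensity Transmitted intensity of stain-free
#'   background; must be positive (default 255).
#' @return Numeric `h x w x 3` array of optical densities.
#' @export
rgb_to_od <- function(image, background_intensity = 255) {
  if (background_intensity <= 0) {
    stop("background_intensity must be positive", call. = FALSE)
  }
  px <- if (inherits(image, "slide_image")) image$pixels else image
  -log10(pmax(px, 1) / background_intensity)
}

#' Render stain concentrations back to RGB
#'
#' Inverse Beer-Lambert: `I_c = background * 10^-(M %*% conc)_c`.
#'
#' @param concentrations `h x w x 2` non-negative array (hematoxylin,
#'   eosin channels).
#' @param model A [stain_model()].
#' @param background_intensity Background intensity (default 255).
#' @param subject_id,sample_type Metadata for the output image.
#' @return A [slide_image()] (continuous intensities, clamped to `[0, 255]`).
#' @export
render_concentrations <- function(concentrations, model,
                                  background_intensity = 255,
                                  subject_id = NA_character_,
                                  sample_type = "tumor") {
  stopifnot(inherits(model, "stain_model"))
  d <- dim(concentrations)
  cmat <- matrix(concentrations, ncol = 2L)
  od <- cmat %*% t(model$matrix)
  px <- background_intensity * 10^(-od)
  px <- pmin(pmax(px, 0), 255)
  slide_image(array(px, dim = c(d[1], d[2], 3L)),
    subject_id = subject_id, sample_type = sample_type
  )
}

od_pixel_matrix <- function(od) {
  matrix(od, ncol = 3L)
}

#' Estimate an image-specific stain matrix (Macenko procedure)
#'
#' Projects tissue-pixel optical densities onto the plane of their top two
#' principal directions and takes the extreme-angle directions (the
#' `angle_percentile` and `100 - angle_percentile` percentiles) as the two
#' stain vectors. The hematoxylin column is the one with the larger
#' red-channel OD component. Per-stain concentration maxima are taken as the
#' 99th percentile of tissue-pixel concentrations.
#'
#' @param x A [slide_image()] or an OD array from [rgb_to_od()].
#' @param od_min Tissue threshold: pixels with OD Euclidean norm below this
#'   are treated as background (default 0.15).
#' @param angle_percentile Extreme-angle percentile (default 1, i.e. the 1st
#'   and 99th percentile angles).
#' @return A [stain_model()] with estimated `matrix` and `max_density`.
#' @export
estimate_stain_matrix <- function(x, od_min = 0.15, angle_percentile = 1) {
  od <- if (inherits(x, "slide_image")) rgb_to_od(x) else x
  P <- od_pixel_matrix(od)
  tissue <- P[sqrt(rowSums(P^2)) > od_min, , drop = FALSE]
  if (nrow(tissue) < 100L) {
    stop("insufficient tissue: fewer than 100 pixels above the OD threshold",
      call. = FALSE
    )
  }
  sv <- svd(tissue, nu = 0, nv = 3)
  if (sv$d[2] <= 0 || sv$d[1] / sv$d[2] > 50) {
    stop("degenerate stain structure: input is effectively single-stain",
      call. = FALSE
    )
  }
  V <- sv$v[, 1:2, drop = FALSE]
  proj <- tissue %*% V
  for (j in 1:2) {
    if (sum(proj[, j]) < 0) {
      V[, j] <- -V[, j]
      proj[, j] <- -proj[, j]
    }
  }
  phi <- atan2(proj[, 2], proj[, 1])
  lo <- stats::quantile(phi, angle_percentile / 100, names = FALSE)
  hi <- stats::quantile(phi, 1 - angle_percentile / 100, names = FALSE)
  v1 <- V %*% c(cos(lo), sin(lo))
  v2 <- V %*% c(cos(hi), sin(hi))
  fix_sign <- function(v) if (sum(v) < 0) -v else v
  v1 <- fix_sign(v1)
  v2 <- fix_sign(v2)
  cand <- cbind(v1, v2)
  cand[cand < 0] <- 0
  # hematoxylin absorbs strongly in red; deterministic column order
  if (cand[1, 1] < cand[1, 2]) cand <- cand[, 2:1, drop = FALSE]
  model <- stain_model(cand)
  conc <- matrix(nnls_two_column(tissue, model$matrix), ncol = 2L)
  model$max_density <- apply(conc, 2, stats::quantile,
    probs = 0.99, names = FALSE
  )
  model$max_density <- pmax(model$max_density, 1e-6)
  model
}

# Closed-form non-negative least squares onto two unit-norm columns.
# Takes an n x 3 OD matrix, returns an n x 2 concentration matrix.
nnls_two_column <- function(P, M) {
  proj <- P %*% M # n x 2 inner products
  g <- sum(M[, 1] * M[, 2])
  Ginv <- solve(matrix(c(1, g, g, 1), 2))
  Cu <- proj %*% Ginv
  ok <- Cu[, 1] >= -1e-12 & Cu[, 2] >= -1e-12
  out <- Cu
  if (any(!ok)) {
    # on the boundary the best single-stain fit is the larger clamped
    # projection (residual^2 = |y|^2 - max(0, proj)^2 for unit columns)
    a1 <- pmax(0, proj[!ok, 1])
    a2 <- pmax(0, proj[!ok, 2])
    pick1 <- a1 >= a2
    sub <- cbind(ifelse(pick1, a1, 0), ifelse(pick1, 0, a2))
    out[!ok, ] <- sub
  }
  out[out < 0] <- 0
  out
}

#' Deconvolve an OD raster into stain concentrations
#'
#' Per-pixel non-negative least-squares fit of the optical density onto the
#' two stain columns.
#'
#' @inheritParams estimate_stain_matrix
#' @param model A [stain_model()].
#' @return List with `concentrations` (`h x w x 2` array, hematoxylin then
#'   eosin) and `model`.
#' @export
compute_concentrations <- function(x, model) {
  stopifnot(inherits(model, "stain_model"))
  od <- if (inherits(x, "slide_image")) rgb_to_od(x) else x
  d <- dim(od)
  conc <- nnls_two_column(od_pixel_matrix(od), model$matrix)
  list(
    concentrations = array(conc, dim = c(d[1], d[2], 2L)),
    model = model
  )
}

#' Normalize an image's stain appearance to a reference model
#'
#' Estimates the source stain model, deconvolves into concentrations,
#' rescales each stain by `reference$max_density / source$max_density` and
#' re-renders through the reference stain matrix.
#'
#' @param image A [slide_image()].
#' @param reference Target [stain_model()]; defaults to the classical
#'   published H&E vectors.
#' @param od_min,angle_percentile Passed to [estimate_stain_matrix()].
#' @return A [slide_image()] with the reference stain appearance.
#' @export
normalize_to_reference <- function(image,
                                   reference = reference_stain_model(),
                                   od_min = 0.15, angle_percentile = 1) {
  stopifnot(inherits(image, "slide_image"), inherits(reference, "stain_model"))
  src <- estimate_stain_matrix(image, od_min, angle_percentile)
  conc <- compute_concentrations(image, src)$concentrations
  scale <- reference$max_density / src$max_density
  conc[, , 1] <- conc[, , 1] * scale[1]
  conc[, , 2] <- conc[, , 2] * scale[2]
  render_concentrations(conc, reference,
    subject_id = image$subject_id, sample_type = image$sample_type
  )
}

#' Color augmentation policy
#'
#' @param count Number of augmentations to generate (default 50).
#' @param multiplier_low,multiplier_high Bounds of the uniform per-stain
#'   concentration multiplier (defaults 0.95 and 1.05).
#' @param seed Integer seed; identical seeds give identical augmentations.
#' @return An `augmentation_policy` object.
#' @export
augmentation_policy <- function(count = 50L, multiplier_low = 0.95,
                                multiplier_high = 1.05, seed = 1L) {
  if (count < 1L) stop("count must be positive", call. = FALSE)
  if (!(multiplier_low > 0 && multiplier_low <= multiplier_high)) {
    stop("need 0 < multiplier_low <= multiplier_high", call. = FALSE)
  }
  structure(
    list(
      count = as.integer(count), multiplier_low = multiplier_low,
      multiplier_high = multiplier_high, seed = as.integer(seed)
    ),
    class = "augmentation_policy"
  )
}

#' Stain-space color augmentation
#'
#' Deconvolves the image through its estimated stain matrix, then for each
#' augmentation multiplies the two concentration channels by independent
#' Uniform(multiplier_low, multiplier_high) draws and re-renders through the
#' same stain matrix.
#'
#' @param image A [slide_image()].
#' @param policy An [augmentation_policy()].
#' @param od_min,angle_percentile Passed to [estimate_stain_matrix()].
#' @return List of `policy$count` augmented [slide_image()]s; the drawn
#'   multipliers are attached as the `"multipliers"` attribute
#'   (`count x 2` matrix).
#' @export
augment_image <- function(image, policy = augmentation_policy(),
                          od_min = 0.15, angle_percentile = 1) {
  stopifnot(inherits(image, "slide_image"), inherits(policy, "augmentation_policy"))
  src <- estimate_stain_matrix(image, od_min, angle_percentile)
  conc <- compute_concentrations(image, src)$concentrations
  mult <- withr::with_seed(
    policy$seed,
    matrix(
      stats::runif(
        2L * policy$count, policy$multiplier_low,
        policy$multiplier_high
      ),
      ncol = 2L, byrow = TRUE
    )
  )
  out <- lapply(seq_len(policy$count), function(i) {
    ci <- conc
    ci[, , 1] <- ci[, , 1] * mult[i, 1]
    ci[, , 2] <- ci[, , 2] * mult[i, 2]
    render_concentrations(ci, src,
      subject_id = image$subject_id, sample_type = image$sample_type
    )
  })
  attr(out, "multipliers") <- mult
  out
}

#' Serialize / read a stain model as JSON
#'
#' @param model A [stain_model()].
#' @param path JSON file path.
#' @return `write_stain_model()` returns `path` invisibly;
#'   `read_stain_model()` returns a [stain_model()].
#' @export
write_stain_model <- function(model, path) {
  stopifnot(inherits(model, "stain_model"))
  jsonlite::write_json(
    list(
      matrix = as.vector(t(model$matrix)), # row-major
      max_density = model$max_density
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_stain_model
#' @export
read_stain_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stain_model(
    matrix(obj$matrix, nrow = 3, byrow = TRUE),
    max_density = obj$max_density
  )
}
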