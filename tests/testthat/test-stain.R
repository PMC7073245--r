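test_that("optical density transform matches the elementwise Beer-Lambert formula", {
  white <- constant_image(4, 4, rgb = c(255, 255, 255))
  expect_equal(max(abs(rgb_to_od(white))), 0)

  tenth <- constant_image(4, 4, rgb = c(25.5, 25.5, 25.5))
  expect_equal(rgb_to_od(tenth)[1, 1, ], rep(1, 3))

  px <- withr::with_seed(2, array(runif(5 * 5 * 3, 1, 255), c(5, 5, 3)))
  od <- rgb_to_od(slide_image(px))
  oracle <- array(vapply(
    seq_along(px),
    function(i) -log10(max(px[i], 1) / 255), numeric(1)
  ), dim(px))
  expect_equal(od, oracle)

  expect_error(rgb_to_od(white, background_intensity = 0), "positive")
})

test_that("stain-matrix estimation recovers known stain vectors within 2 degrees", {
  H <- c(0.65, 0.70, 0.29)
  E <- c(0.07, 0.99, 0.11)
  syn <- render_synthetic_stains(H, E, seed = 11)
  m <- estimate_stain_matrix(syn$image)
  expect_lt(stain_angle(m$matrix[, 1], syn$H), 2)
  expect_lt(stain_angle(m$matrix[, 2], syn$E), 2)
  # hematoxylin column carries the larger red-channel OD
  expect_gt(m$matrix[1, 1], m$matrix[1, 2])

  # the two columns explain >= 90% of thresholded OD variance
  od <- rgb_to_od(syn$image)
  P <- matrix(od, ncol = 3)
  P <- P[sqrt(rowSums(P^2)) > 0.15, ]
  fitted <- compute_concentrations(
    array(P, c(nrow(P), 1, 3)), m
  )$concentrations
  recon <- matrix(fitted, ncol = 2) %*% t(m$matrix)
  expect_gte(1 - sum((P - recon)^2) / sum(P^2), 0.9)
})

test_that("degenerate inputs raise the documented stain errors", {
  expect_error(
    estimate_stain_matrix(constant_image(50, 50, c(255, 255, 255))),
    "insufficient tissue"
  )
  # single stain: all pixels proportional to one OD vector
  H <- c(0.65, 0.70, 0.29) / sqrt(sum(c(0.65, 0.70, 0.29)^2))
  conc <- withr::with_seed(4, runif(900, 0.2, 1.2))
  px <- 255 * 10^(-outer(conc, H))
  expect_error(
    estimate_stain_matrix(slide_image(array(px, c(30, 30, 3)))),
    "single-stain"
  )
})

test_that("stain estimation is invariant to pixel order", {
  syn <- render_synthetic_stains(c(0.6, 0.7, 0.3), c(0.1, 0.9, 0.2), seed = 7)
  m1 <- estimate_stain_matrix(syn$image)
  px <- matrix(syn$image$pixels, ncol = 3)
  shuffled <- withr::with_seed(8, px[sample(nrow(px)), ])
  m2 <- estimate_stain_matrix(
    slide_image(array(shuffled, dim(syn$image$pixels)))
  )
  expect_lt(stain_angle(m1$matrix[, 1], m2$matrix[, 1]), 0.5)
  expect_lt(stain_angle(m1$matrix[, 2], m2$matrix[, 2]), 0.5)
})

test_that("concentration deconvolution solves the per-pixel NNLS problem", {
  model <- reference_stain_model()
  C <- withr::with_seed(9, matrix(runif(100 * 2, 0, 1.5), ncol = 2))
  od <- array(C %*% t(model$matrix), c(10, 10, 3))
  got <- matrix(compute_concentrations(od, model)$concentrations, ncol = 2)
  expect_equal(got, C, tolerance = 1e-7)

  zero <- compute_concentrations(array(0, c(2, 2, 3)), model)$concentrations
  expect_equal(max(abs(zero)), 0)

  # random (infeasible) OD against an independent constrained solver
  od_rand <- withr::with_seed(10, array(runif(60, 0, 1), c(4, 5, 3)))
  got_r <- matrix(
    compute_concentrations(od_rand, model)$concentrations,
    ncol = 2
  )
  P <- matrix(od_rand, ncol = 3)
  oracle <- t(apply(P, 1, function(y) {
    pracma::lsqnonneg(model$matrix, y)$x
  }))
  expect_equal(got_r, oracle, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("normalization maps an image onto the reference stain appearance", {
  syn <- render_synthetic_stains(c(0.65, 0.7, 0.29), c(0.07, 0.99, 0.11),
    seed = 12
  )
  # reference equal to the image's own model: near identity
  own <- estimate_stain_matrix(syn$image)
  self_norm <- normalize_to_reference(syn$image, own)
  expect_lt(mean(abs(self_norm$pixels - syn$image$pixels)), 2)

  # idempotence
  ref <- reference_stain_model()
  once <- normalize_to_reference(syn$image, ref)
  twice <- normalize_to_reference(once, ref)
  expect_lt(mean(abs(twice$pixels - once$pixels)), 1)

  # stains perturbed ~10 degrees from the reference normalize back within 5
  rot <- function(v, deg) {
    u <- c(v[2], -v[1], 0)
    u <- u / sqrt(sum(u^2))
    w <- v * cos(deg * pi / 180) + u * sin(deg * pi / 180)
    abs(w) / sqrt(sum(w^2))
  }
  syn2 <- render_synthetic_stains(
    rot(c(0.65, 0.7, 0.29), 10), rot(c(0.07, 0.99, 0.11), 10),
    seed = 13
  )
  norm2 <- normalize_to_reference(syn2$image, ref)
  m2 <- estimate_stain_matrix(norm2)
  expect_lt(stain_angle(m2$matrix[, 1], ref$matrix[, 1]), 5)
  expect_lt(stain_angle(m2$matrix[, 2], ref$matrix[, 2]), 5)
})

test_that("augmentation draws seeded per-stain multipliers in density space", {
  syn <- render_synthetic_stains(c(0.6, 0.75, 0.3), c(0.08, 0.95, 0.15),
    seed = 14
  )
  aug <- augment_image(syn$image, augmentation_policy(count = 50, seed = 3))
  expect_length(aug, 50)
  aug_b <- augment_image(syn$image, augmentation_policy(count = 50, seed = 3))
  expect_identical(aug[[7]]$pixels, aug_b[[7]]$pixels)

  # unit multipliers reproduce the stain-reconstructed input exactly
  ident <- augment_image(syn$image, augmentation_policy(
    count = 3, multiplier_low = 1, multiplier_high = 1, seed = 1
  ))
  src <- estimate_stain_matrix(syn$image)
  recon <- render_concentrations(
    compute_concentrations(syn$image, src)$concentrations, src
  )
  expect_equal(ident[[2]]$pixels, recon$pixels, tolerance = 1e-12)

  # a multiplier m scales that stain's OD contribution linearly
  pol <- augmentation_policy(
    count = 1, multiplier_low = 0.8,
    multiplier_high = 1.3, seed = 5
  )
  one <- augment_image(syn$image, pol)
  mult <- attr(one, "multipliers")[1, ]
  conc <- matrix(
    compute_concentrations(syn$image, src)$concentrations,
    ncol = 2
  )
  expected_od <- (conc %*% diag(mult)) %*% t(src$matrix)
  got_od <- matrix(rgb_to_od(one[[1]]), ncol = 3)
  keep <- matrix(one[[1]]$pixels, ncol = 3) > 1.5 # away from the clamp
  expect_equal(got_od[rowSums(keep) == 3, ], expected_od[rowSums(keep) == 3, ],
    tolerance = 1e-6
  )
})

test_that("render/deconvolve round trip preserves concentrations", {
  model <- reference_stain_model()
  C <- withr::with_seed(15, matrix(runif(400, 0, 1.2), ncol = 2))
  img <- render_concentrations(array(C, c(20, 10, 2)), model)
  back <- compute_concentrations(img, model)$concentrations
  expect_equal(matrix(back, ncol = 2), C, tolerance = 1e-3)
})

test_that("recovery stays below 3 degrees on average over random stain pairs", {
  errs <- c()
  withr::with_seed(20, {
    made <- 0
    while (made < 20) {
      H <- random_stain_vector()
      E <- random_stain_vector()
      if (stain_angle(H, E) < 15) next
      made <- made + 1
      syn <- render_synthetic_stains(H, E, seed = sample.int(1e6, 1))
      m <- estimate_stain_matrix(syn$image)
      # estimated columns are ordered by red OD, the generator's are not:
      # score the column assignment that matches best
      direct <- c(
        stain_angle(m$matrix[, 1], H),
        stain_angle(m$matrix[, 2], E)
      )
      swapped <- c(
        stain_angle(m$matrix[, 1], E),
        stain_angle(m$matrix[, 2], H)
      )
      errs <- c(errs, if (sum(direct) <= sum(swapped)) direct else swapped)
    }
  })
  expect_lt(mean(errs), 3)
})

test_that("stain models serialize to JSON and back", {
  m <- reference_stain_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_stain_model(m, path)
  m2 <- read_stain_model(path)
  expect_equal(m2$matrix, m$matrix, tolerance = 1e-12)
  expect_equal(m2$max_density, m$max_density)
})
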