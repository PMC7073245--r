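# Fixtures and independent oracles shared across the suite.

# Constant-color test image.
constant_image <- function(h, w, rgb = c(200, 120, 180)) {
  px <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  slide_image(px)
}

# Brute-force block-mean downsampling oracle (double loop, ceiling blocks).
block_mean_oracle <- function(px, f) {
  oh <- ceiling(nrow(px) / f)
  ow <- ceiling(ncol(px) / f)
  out <- array(0, dim = c(oh, ow, 3L))
  for (i in seq_len(oh)) {
    for (j in seq_len(ow)) {
      rows <- ((i - 1) * f + 1):min(i * f, nrow(px))
      cols <- ((j - 1) * f + 1):min(j * f, ncol(px))
      for (ch in 1:3) out[i, j, ch] <- mean(px[rows, cols, ch])
    }
  }
  out
}

# Beer-Lambert rendering of random two-stain concentrations; the pixel mix
# includes near-pure pixels of each stain so extreme-angle estimation is
# well posed.
render_synthetic_stains <- function(H, E, n_pixels = 2000L, seed = 1L) {
  withr::with_seed(seed, {
    kind <- sample(1:3, n_pixels, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    c1 <- ifelse(kind == 1, runif(n_pixels, 0.4, 1.2),
      ifelse(kind == 3, runif(n_pixels, 0.2, 0.8), runif(n_pixels, 0, 0.05))
    )
    c2 <- ifelse(kind == 2, runif(n_pixels, 0.4, 1.2),
      ifelse(kind == 3, runif(n_pixels, 0.2, 0.8), runif(n_pixels, 0, 0.05))
    )
    M <- cbind(H / sqrt(sum(H^2)), E / sqrt(sum(E^2)))
    od <- cbind(c1, c2) %*% t(M)
    px <- 255 * 10^(-od)
    h <- 40L
    w <- ceiling(n_pixels / h)
    pad <- h * w - n_pixels
    px <- rbind(px, matrix(255, pad, 3))
    list(
      image = slide_image(array(px, dim = c(h, w, 3L))),
      H = M[, 1], E = M[, 2],
      concentrations = cbind(c1, c2)
    )
  })
}

# A random unit-norm non-negative stain vector.
random_stain_vector <- function() {
  v <- abs(stats::rnorm(3)) + 0.05
  v / sqrt(sum(v^2))
}

# Brute-force Benjamini-Hochberg step-up oracle.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Textbook Pearson correlation, evaluated term by term.
pearson_oracle <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Two well-separated Gaussian classes as a feature table.
gaussian_two_class_ft <- function(n_per_class = 30L, p = 10L, shift = 10,
                                  seed = 1L) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(2 * n_per_class * p), ncol = p)
    X[seq_len(n_per_class), ] <- X[seq_len(n_per_class), ] + shift
    feature_table(
      X, sprintf("s%03d", seq_len(2 * n_per_class)),
      rep(c("tumor", "normal"), each = n_per_class)
    )
  })
}
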