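# Exact t-SNE (O(n^2)), sufficient at cohort scale (hundreds of samples).
# Perplexity calibration by per-point bisection on the Gaussian precision;
# standard early exaggeration + momentum gradient descent with adaptive
# gains (Kullback-Leibler objective between input and embedding affinities).

tsne_affinities <- function(X, perplexity) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  diag(D2) <- Inf
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta_lo <- 0
    beta_hi <- Inf
    beta <- 1
    di <- D2[i, -i]
    for (iter in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) {
        entropy <- 0
      } else {
        p <- w / sw
        entropy <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(entropy - target) < 1e-5) break
      if (entropy > target) {
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- (beta + beta_lo) / 2
      }
    }
    w <- exp(-di * beta)
    P[i, -i] <- w / max(sum(w), .Machine$double.eps)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

tsne_embed <- function(X, perplexity = 15, n_iter = 500L, seed = 1L,
                       eta = 200) {
  n <- nrow(X)
  P <- tsne_affinities(X, perplexity)
  withr::with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    inc <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    exaggeration_until <- 100L
    P_ex <- P * 12
    for (iter in seq_len(n_iter)) {
      Pit <- if (iter <= exaggeration_until) P_ex else P
      sqy <- rowSums(Y^2)
      num <- 1 / (1 + outer(sqy, sqy, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pit - Q) * num
      grad <- 4 * (diag(rowSums(L)) %*% Y - L %*% Y)
      momentum <- if (iter < 250L) 0.5 else 0.8
      gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      inc <- momentum * inc - eta * gains * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}
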