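make_test_ipl <- function(n_entities = 50, n_samples = 20, seed = 70) {
  withr::with_seed(seed, {
    V <- matrix(rnorm(n_entities * n_samples), n_entities, n_samples)
    ipl_matrix(
      V, sprintf("%d_G%03d", seq_len(n_entities) %% 7, seq_len(n_entities)),
      paste0("smp", seq_len(n_samples))
    )
  })
}

test_that("entity ids parse into pathway index and concept", {
  ent <- histoprog:::parse_entity_ids("19_EPHB3")
  expect_identical(ent$pathway_index, 19L)
  expect_identical(ent$concept, "EPHB3")

  ipl <- make_test_ipl(n_entities = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ipl(ipl, path)
  ipl2 <- parse_ipl(path)
  expect_equal(ipl2$values, ipl$values, tolerance = 1e-12)
  expect_identical(ipl2$entities, ipl$entities)

  expect_error(
    ipl_matrix(matrix(0, 1, 2), "EPHB3", c("a", "b")),
    "without integer pathway prefix"
  )
  expect_error(
    ipl_matrix(matrix(0, 2, 2), c("1_A", "1_A"), c("a", "b")),
    "duplicate"
  )
})

test_that("feature-entity correlation matches the textbook formula and flags identity", {
  ft <- withr::with_seed(71, feature_table(
    matrix(rnorm(20 * 4), 20, 4), paste0("smp", 1:20)
  ))
  ipl <- make_test_ipl(n_entities = 6, n_samples = 20, seed = 72)
  ipl$values[1, ] <- feature_matrix(ft)[ipl$sample_ids, "f1"]
  res <- correlate_features_ipl(ft, ipl)
  ident <- res[res$feature == "f1" & res$entity_id == ipl$entities$entity_id[1], ]
  expect_equal(ident$r, 1, tolerance = 1e-12)
  expect_lte(ident$p_adjusted, 0.05)
  expect_true(all(res$p_adjusted >= res$p))
  expect_identical(nrow(res), 24L)

  x <- c(1.2, -0.5, 3.1, 0.4, -2.2)
  y <- c(0.3, 0.8, -1.1, 2.0, 0.5)
  ft5 <- feature_table(matrix(x, 5, 1), paste0("smp", 1:5))
  ipl5 <- ipl_matrix(matrix(y, 1, 5), "3_ABC", paste0("smp", 1:5))
  res5 <- correlate_features_ipl(ft5, ipl5, threshold = 0.05)
  expect_equal(res5$r, pearson_oracle(x, y), tolerance = 1e-12)
})

test_that("correlation is symmetric in which matrix plays the feature role", {
  ft <- withr::with_seed(73, feature_table(
    matrix(rnorm(15 * 3), 15, 3), paste0("smp", 1:15)
  ))
  ipl <- make_test_ipl(n_entities = 4, n_samples = 15, seed = 74)
  fwd <- correlate_features_ipl(ft, ipl)
  ft_swap <- feature_table(
    t(ipl$values[, paste0("smp", 1:15)]), paste0("smp", 1:15)
  )
  ipl_swap <- ipl_matrix(
    t(feature_matrix(ft)), paste0("1_F", 1:3), ft$sample_id
  )
  bwd <- correlate_features_ipl(ft_swap, ipl_swap)
  expect_equal(sort(fwd$r), sort(bwd$r), tolerance = 1e-12)
})

test_that("correlation requires at least three shared samples", {
  ft <- feature_table(matrix(rnorm(4), 2, 2), c("smp1", "smp2"))
  ipl <- make_test_ipl(n_entities = 3, n_samples = 20)
  expect_error(correlate_features_ipl(ft, ipl), "at least 3 shared")
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  p <- withr::with_seed(75, runif(50))
  adj <- bh_adjust(p)
  expect_true(all(adj >= p & adj <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("planted differential entities are detected and null entities are not", {
  ipl <- make_test_ipl(n_entities = 200, n_samples = 40, seed = 76)
  g <- stats::setNames(rep(c("g1", "g2"), each = 20), ipl$sample_ids)
  ipl$values[1, g[ipl$sample_ids] == "g1"] <-
    ipl$values[1, g[ipl$sample_ids] == "g1"] + 5
  res <- differential_ipl(ipl, g, threshold = 0.1)
  expect_true(res$significant[1])
  expect_lte(sum(res$significant[-1]), 2)
  expect_equal(res$effect[1], mean(ipl$values[1, 1:20]) - mean(ipl$values[1, 21:40]))

  flat <- ipl
  flat$values[2, ] <- rep(c(1, 2), 20) # equal means, equal spread per group
  res2 <- differential_ipl(flat, g)
  expect_equal(res2$t[2], 0)
  expect_error(
    differential_ipl(ipl, stats::setNames(
      c("a", "b", rep("c", 38)),
      ipl$sample_ids
    )),
    "two groups"
  )
})

test_that("the moderated t reproduces the reference empirical-Bayes implementation", {
  V <- withr::with_seed(77, matrix(rnorm(300 * 24), 300, 24) *
    sqrt(stats::rchisq(300, 4) / 4))
  ipl <- ipl_matrix(
    V, sprintf("%d_T%03d", 1:300 %% 5, 1:300),
    paste0("smp", 1:24)
  )
  g <- stats::setNames(rep(c("a", "b"), each = 12), ipl$sample_ids)
  res <- differential_ipl(ipl, g)
  design <- cbind(1, rep(c(1, 0), each = 12))
  fit <- limma::eBayes(limma::lmFit(V, design))
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-10)
  expect_equal(attr(res, "df_prior"), fit$df.prior, tolerance = 1e-8)
})

test_that("moderation reduces to the ordinary pooled t as the prior df vanishes", {
  withr::with_seed(78, {
    n1 <- 10
    n2 <- 12
    effect <- rnorm(50)
    s2 <- rchisq(50, 5) / 5
  })
  df_resid <- n1 + n2 - 2
  mod <- histoprog:::moderated_t_stats(
    effect, s2, n1, n2, df_resid,
    df_prior = 1e-12, s2_prior = 4
  )
  pooled_t <- effect / sqrt(s2 * (1 / n1 + 1 / n2))
  expect_equal(mod$t, pooled_t, tolerance = 1e-9)
  expect_equal(mod$p, 2 * stats::pt(-abs(pooled_t), df = df_resid),
    tolerance = 1e-9
  )
  # and strong variance heterogeneity drives the fitted prior df down
  V <- withr::with_seed(78, matrix(rnorm(400 * 20), 400, 20) *
    exp(rnorm(400, sd = 3)))
  ipl <- ipl_matrix(
    V, sprintf("%d_U%03d", 1:400 %% 3, 1:400),
    paste0("smp", 1:20)
  )
  g <- stats::setNames(rep(c("a", "b"), each = 10), ipl$sample_ids)
  res <- differential_ipl(ipl, g)
  expect_lt(attr(res, "df_prior"), 1.5)
})

test_that("a fully null matrix rarely produces BH discoveries", {
  withr::with_seed(79, {
    any_hit <- vapply(seq_len(50), function(i) {
      V <- matrix(rnorm(2000 * 40), 2000, 40)
      ipl <- ipl_matrix(
        V, sprintf("%d_N%04d", 1:2000 %% 9, 1:2000),
        paste0("smp", 1:40)
      )
      g <- stats::setNames(rep(c("a", "b"), each = 20), ipl$sample_ids)
      any(differential_ipl(ipl, g, threshold = 0.1)$significant)
    }, logical(1))
  })
  expect_lte(mean(any_hit), 0.2)
})
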