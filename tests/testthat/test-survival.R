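test_that("a perfectly concordant feature yields positive coefficient and C = 1", {
  sv <- survival_records(paste0("s", 1:4), c(1, 2, 3, 4), rep(1, 4))
  res <- suppressWarnings(fit_univariate_cox(-rank(sv$time), sv))
  expect_gt(res$coefficient, 0)
  expect_equal(res$c_index, 1)
  expect_equal(res$hazard_ratio, exp(res$coefficient))
})

test_that("univariate Cox recovers a known coefficient from simulation", {
  co <- simulate_cohort(
    n_tumor = 300, n_normal = 0, n_features = 1,
    class_shift = 0, cluster_shift = 0, survival_beta = 1,
    censor_fraction = 0.25, seed = 50
  )
  os <- co$survival[co$survival$endpoint == "OS", ]
  x <- feature_matrix(co$features)[os$subject_id, 1]
  res <- fit_univariate_cox(x, os)
  expect_lt(abs(res$coefficient - 1), 0.25)
  expect_lt(res$logrank_p, 0.001)
  expect_gt(res$c_index, 0.6)
})

test_that("the score statistic matches the hand-evaluated two-subject partial likelihood", {
  # two subjects, both events, distinct covariates x1, x2, times t1 < t2:
  # U = (x1 - x2)/2, I = (x1 - x2)^2 / 4, so the score chi-square is 1
  sv <- survival_records(c("a", "b"), c(1, 2), c(1, 1))
  fit <- suppressWarnings(survival::coxph(
    survival::Surv(sv$time, sv$event) ~ x,
    data = data.frame(x = c(2, 5)), ties = "efron"
  ))
  expect_equal(unname(summary(fit)$sctest["test"]), 1)
  res <- suppressWarnings(fit_univariate_cox(c(2, 5), sv))
  expect_equal(res$logrank_p, stats::pchisq(1, 1, lower.tail = FALSE))
})

test_that("degenerate survival inputs raise the documented errors", {
  sv <- survival_records(paste0("s", 1:4), 1:4, c(1, 1, 0, 0))
  expect_error(fit_univariate_cox(rep(2, 4), sv), "constant")
  sv0 <- survival_records(paste0("s", 1:4), 1:4, c(1, 0, 0, 0))
  expect_error(fit_univariate_cox(rnorm(4), sv0), "2 events")
  expect_error(survival_records("a", -1, 1), "positive")
  expect_error(survival_records("a", 1, 2), "0 .* or 1")
  expect_error(survival_records(c("a", "a"), c(1, 2), c(1, 1)), "at most once")
})

test_that("feature screening reports selection counts, fractions and exclusions", {
  co <- simulate_cohort(
    n_tumor = 80, n_normal = 0, n_features = 10,
    class_shift = 0, cluster_shift = 0,
    survival_beta = c(2, rep(0, 9)), seed = 51
  )
  X <- feature_matrix(co$features)
  X <- cbind(X, f11 = 1) # constant column
  ft <- feature_table(X, co$features$sample_id)
  expect_warning(
    sc <- screen_features(ft, co$survival, "OS"),
    "near-constant"
  )
  expect_identical(nrow(sc), 10L)
  expect_true(sc$significant[sc$feature == "f1"])
  expect_equal(
    attr(sc, "percent_selected"),
    100 * mean(sc$significant)
  )
  sc0 <- suppressWarnings(
    screen_features(ft, co$survival, "OS", threshold = 0)
  )
  expect_identical(sum(sc0$significant), 0L)
})

test_that("null univariate Cox p-values are approximately uniform", {
  co <- simulate_cohort(
    n_tumor = 200, n_normal = 0, n_features = 200,
    class_shift = 0, cluster_shift = 0,
    survival_beta = rep(0, 200), censor_fraction = 0.25, seed = 52
  )
  sc <- screen_features(co$features, co$survival, "OS")
  ks <- stats::ks.test(sc$logrank_p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("an overwhelming penalty empties the elastic-net model", {
  co <- simulate_cohort(
    n_tumor = 100, n_normal = 0, n_features = 20,
    class_shift = 0, cluster_shift = 0, seed = 53
  )
  en <- fit_elasticnet_cox(co$features, co$survival,
    endpoint = "OS",
    lambda = 1e6, seed = 1
  )
  expect_identical(nrow(en$coefficients), 0L)
  expect_equal(en$c_index, 0.5)
  expect_equal(en$alpha, 0.5)
})

test_that("the elastic-net model enforces its preconditions", {
  co <- simulate_cohort(
    n_tumor = 12, n_normal = 0, n_features = 5,
    class_shift = 0, cluster_shift = 0,
    censor_fraction = 0.6, seed = 54
  )
  expect_error(
    fit_elasticnet_cox(co$features, co$survival, folds = 12),
    "fewer events"
  )
})

test_that("concordance matches pair enumeration and its exchange identity", {
  sv <- survival_records(paste0("s", 1:3), c(1, 2, 3), c(1, 1, 1))
  expect_equal(concordance_index(c(3, 1, 2), sv), 2 / 3, tolerance = 1e-12)
  expect_equal(concordance_index(c(3, 2, 1), sv), 1)

  svr <- withr::with_seed(55, survival_records(
    paste0("s", 1:40), rexp(40, 0.01) + 0.1, rbinom(40, 1, 0.7)
  ))
  r <- withr::with_seed(56, rnorm(40))
  expect_equal(
    concordance_index(r, svr) + concordance_index(-r, svr), 1,
    tolerance = 1e-12
  )
  all_censored <- survival_records(c("a", "b"), c(1, 2), c(0, 0))
  expect_error(concordance_index(c(1, 2), all_censored), "no comparable")
})

test_that("Kaplan-Meier estimates follow the product-limit construction", {
  sv <- survival_records(paste0("s", 1:4), c(1, 2, 3, 4), c(1, 0, 0, 0))
  km <- kaplan_meier(sv)
  expect_equal(km$curves$survival[km$curves$time == 1], 0.75)
  expect_true(is.na(km$logrank_p))

  none <- survival_records(paste0("s", 1:5), 1:5, rep(0, 5))
  expect_true(all(kaplan_meier(none)$curves$survival == 1))

  hr3 <- withr::with_seed(57, {
    survival_records(
      paste0("s", 1:200),
      c(rexp(100, 0.003), rexp(100, 0.001)),
      rep(1, 200)
    )
  })
  km2 <- kaplan_meier(hr3, groups = rep(c("high", "low"), each = 100))
  expect_lt(km2$logrank_p, 0.01)
  expect_identical(sort(unique(km2$curves$group)), c("high", "low"))
})
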