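planted_two_cluster_matrix <- function(n = 200, p = 10, sep = 10, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    X[seq_len(n / 2), ] <- X[seq_len(n / 2), ] + sep
    rownames(X) <- sprintf("s%03d", seq_len(n))
    X
  })
}

test_that("the scan picks the planted number of clusters with strong silhouette", {
  X <- planted_two_cluster_matrix(seed = 60)
  scan <- cluster_scan(X, k_min = 2, k_max = 8, seed = 1)
  expect_identical(scan$chosen_k, 2L)
  expect_gt(scan$metrics$silhouette[scan$metrics$k == 2], 0.8)
  expect_true(all(scan$metrics$silhouette >= -1 & scan$metrics$silhouette <= 1))
  expect_true(all(scan$metrics$davies_bouldin >= 0))
  expect_identical(tidy(scan), scan$metrics)
  expect_identical(glance(scan)$chosen_k, 2L)
})

test_that("the scan validates degenerate input and clips infeasible K", {
  X <- matrix(1, 20, 3)
  expect_error(cluster_scan(X), "degenerate")
  X2 <- planted_two_cluster_matrix(n = 8, seed = 61)
  expect_warning(scan <- cluster_scan(X2, k_min = 2, k_max = 12, seed = 1),
    "clipping"
  )
  expect_lte(max(scan$metrics$k), 7)
})

test_that("the scan covers the default K range 2 through 12", {
  X <- planted_two_cluster_matrix(n = 60, p = 5, sep = 6, seed = 62)
  scan <- cluster_scan(X, seed = 2, n_init = 3)
  expect_identical(scan$metrics$k, 2:12)
})

test_that("Davies-Bouldin agrees with the two-cluster hand calculation", {
  # two singleton-pair clusters on a line: scatter 0.5 each, separation 10
  X <- matrix(c(0, 0, 1, 0, 10, 0, 11, 0), ncol = 2, byrow = TRUE)
  labels <- c(1, 1, 2, 2)
  expect_equal(davies_bouldin(X, labels), (0.5 + 0.5) / 10)
})

test_that("cluster assignment is invariant to sample and feature order", {
  X <- planted_two_cluster_matrix(n = 60, p = 6, sep = 8, seed = 63)
  scan <- cluster_scan(X, k_min = 2, k_max = 4, seed = 3)
  perm <- withr::with_seed(64, sample(nrow(X)))
  scan_p <- cluster_scan(X[perm, rev(seq_len(ncol(X)))],
    k_min = 2, k_max = 4, seed = 3
  )
  agree <- table(scan$labels[perm], scan_p$labels)
  # labels may be permuted; every original cluster maps to exactly one new
  expect_true(all(rowSums(agree > 0) == 1))
  expect_identical(scan_p$chosen_k, scan$chosen_k)
})

test_that("subgroups with different hazards are detected and ordered by prognosis", {
  withr::with_seed(65, {
    times <- c(rexp(150, 0.0025), rexp(150, 0.001))
    sv <- survival_records(sprintf("s%03d", 1:300), times, rep(1, 300))
    g <- stats::setNames(
      rep(c("worse", "better"), each = 150),
      sv$subject_id
    )
  })
  res <- subgroup_survival(g, sv)
  expect_lt(res$logrank_p, 0.01)
  expect_gt(res$c_index, 0.55)
  # group 2 is the better-prognosis group by construction of the relabeling
  better_ids <- names(g)[g == "better"]
  expect_true(all(res$groups$group[res$groups$subject_id %in% better_ids] == 2))

  perm <- withr::with_seed(66, sample(300))
  res_p <- subgroup_survival(
    tibble::tibble(subject_id = sv$subject_id[perm], group = g[perm]),
    sv
  )
  expect_equal(res_p$logrank_p, res$logrank_p)
})

test_that("equal-hazard subgroups reject at the nominal rate", {
  reps <- 500
  pvals <- withr::with_seed(67, vapply(seq_len(reps), function(i) {
    sv <- survival_records(
      paste0("s", 1:60), rexp(60, 0.002),
      rbinom(60, 1, 0.8)
    )
    kaplan_meier(sv, groups = rep(c("a", "b"), 30))$logrank_p
  }, numeric(1)))
  rate <- mean(pvals <= 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("overlap tables count every sample exactly once", {
  ref <- subgroup_overlap_counts()
  expect_identical(sum(ref$n), 421L)
  by_first <- tapply(ref$n, ref$inception_v3, sum)
  expect_identical(as.integer(by_first), c(218L, 203L))

  ids <- paste0("s", 1:10)
  a <- stats::setNames(rep(1:2, each = 5), ids)
  b <- a
  tab <- overlap_table(list(m1 = a, m2 = b))
  expect_true(all(tab$m1 == tab$m2))
  expect_identical(sum(tab$n), 10L)

  names(b)[1] <- "zother"
  expect_error(overlap_table(list(m1 = a, m2 = b)), "different samples")
})
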