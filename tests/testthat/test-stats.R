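span_tbl <- function(ids, mins, maxs) {
  tibble::tibble(reaction_id = ids, min_flux = mins, max_flux = maxs)
}

test_that("flux matrix assembly applies zero snap, retention, and id checks", {
  spans <- list(
    s1 = span_tbl(c("r1", "r2", "r3"), c(0, 1e-12, 2), c(1, 1e-12, 5)),
    s2 = span_tbl(c("r1", "r2"), c(0, 0), c(0, 0))
  )
  fm <- collect_flux_matrix(spans)
  # r2 is zero everywhere (after snapping) -> dropped entirely
  expect_false(any(grepl("r2", fm$feature_id)))
  # r3 is absent from s2 -> recorded as zero there, retained
  r3 <- fm[fm$feature_id == "max|r3", ]
  expect_equal(r3$s2, 0)
  expect_equal(r3$s1, 5)
  # min|r1 is zero in both -> dropped; max|r1 retained
  expect_false("min|r1" %in% fm$feature_id)
  expect_true("max|r1" %in% fm$feature_id)
  # structural bound: at most 2 rows per reaction
  expect_lte(nrow(fm), 2 * 3)
  dup <- spans; names(dup) <- c("s1", "s1")
  expect_error(collect_flux_matrix(dup), "duplicated")
  expect_error(collect_flux_matrix(unname(spans)), "named")
})

test_that("rank-sum exact p matches full enumeration for small groups", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  set.seed(17)
  for (rep in 1:12) {
    na <- sample(2:5, 1); nb <- sample(2:6, 1)
    a <- sample(seq(1, 100), na)  # distinct integers: tie-free
    b <- sample(setdiff(seq(1, 100), a), nb)
    mine <- rank_sum_test(a, b)
    expect_identical(mine$method, "exact")
    expect_equal(mine$p_value, enumerate_ranksum_p(a, b), tolerance = 1e-12,
                 info = paste(rep))
  }
  expect_error(rank_sum_test(numeric(0), 1), "empty")
})

test_that("identical constant groups give p = 1", {
  res <- rank_sum_test(rep(2, 5), rep(2, 7))
  expect_equal(res$p_value, 1)
})

test_that("the normal approximation agrees with a permutation oracle", {
  set.seed(5)
  a <- rnorm(15); b <- rnorm(20, 0.4)
  mine <- rank_sum_test(a, b)
  expect_identical(mine$method, "normal")
  pool <- c(a, b); na <- length(a)
  r <- rank(pool)
  obs <- abs(sum(r[1:na]) - na * (length(pool) + 1) / 2)
  perm <- replicate(20000, {
    idx <- sample(length(pool), na)
    abs(sum(r[idx]) - na * (length(pool) + 1) / 2)
  })
  p_perm <- mean(perm >= obs - 1e-9)
  expect_lt(abs(mine$p_value - p_perm), 0.02)
})

test_that("exact and approximate p agree near the crossover size on tie-free data", {
  set.seed(9)
  a <- sample(1:1000, 8); b <- sample(setdiff(1:1000, a), 8)
  exact <- rank_sum_test(a, b)$p_value
  approx <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  )
  expect_lt(abs(exact - approx), 0.01)
})

test_that("BH adjustment matches the direct step-up formula and honours exclusion", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(2)
  p <- runif(40)
  expect_equal(adjust_fdr(p), oracle_bh(p), tolerance = 1e-12)
  # excluded features get NA and do not count toward m
  p4 <- c(0.01, 0.02, 0.03, 0.001)
  excl <- c(FALSE, FALSE, FALSE, TRUE)
  q <- adjust_fdr(p4, exclude = excl)
  expect_true(is.na(q[4]))
  expect_equal(q[1:3], adjust_fdr(p4[1:3]))
  # storey variant stays within [0, 1] and is monotone in p
  qs <- adjust_fdr(p, method = "storey")
  expect_true(all(qs >= 0 & qs <= 1))
  expect_true(all(diff(qs[order(p)]) > -1e-12))
})

test_that("compare_groups is label-symmetric and rejects unknown labels", {
  set.seed(12)
  mat <- tibble::tibble(
    feature_id = paste0("max|r", 1:6), type = "max"
  )
  meta <- tibble::tibble(sample_id = paste0("s", 1:12),
                         group = rep(c("control", "mut0"), each = 6))
  for (s in meta$sample_id) {
    mat[[s]] <- runif(6) + ifelse(meta$group[meta$sample_id == s] == "mut0",
                                  c(1, 0, 0, 0, 0, 0), 0)
  }
  class(mat) <- c("flux_matrix", class(mat))
  res <- compare_groups(mat, meta, "control-vs-mut0")
  # swap group labels: p and q preserved, direction flipped
  meta2 <- meta
  meta2$group <- ifelse(meta$group == "control", "mut0", "control")
  res2 <- compare_groups(mat, meta2, "control-vs-mut0")
  m1 <- res[order(res$feature_id), ]
  m2 <- res2[order(res2$feature_id), ]
  expect_equal(m1$p_value, m2$p_value, tolerance = 1e-12)
  expect_equal(m1$q_value, m2$q_value, tolerance = 1e-12)
  flip <- c(higher_in_control = "higher_in_mut0",
            higher_in_mut0 = "higher_in_control",
            tied_medians = "tied_medians")
  expect_identical(unname(flip[m1$direction]), m2$direction)
  expect_error(compare_groups(mat, meta, "mutant-vs-alien"), "unknown comparison")
})

test_that("identical groups produce no significant features", {
  mat <- tibble::tibble(feature_id = paste0("max|r", 1:5), type = "max")
  for (s in paste0("s", 1:10)) mat[[s]] <- c(1, 2, 3, 4, 5)
  class(mat) <- c("flux_matrix", class(mat))
  meta <- tibble::tibble(sample_id = paste0("s", 1:10),
                         group = rep(c("control", "mut0"), each = 5))
  res <- compare_groups(mat, meta, "control-vs-mut0")
  # all features constant across the union -> all excluded, none significant
  expect_true(all(res$excluded))
  expect_false(any(res$significant, na.rm = TRUE))
  g <- glance(res)
  expect_identical(g$n_tested, 0L)
})

test_that("q-values are a monotone step-up transform of p-values per comparison", {
  set.seed(77)
  mat <- tibble::tibble(feature_id = paste0("max|r", 1:30), type = "max")
  for (s in paste0("s", 1:16)) mat[[s]] <- rnorm(30)
  class(mat) <- c("flux_matrix", class(mat))
  meta <- tibble::tibble(sample_id = paste0("s", 1:16),
                         group = rep(c("control", "other"), each = 8))
  res <- compare_groups(mat, meta, "control-vs-other")
  keep <- !res$excluded
  o <- order(res$p_value[keep])
  expect_true(all(diff(res$q_value[keep][o]) > -1e-12))
})

test_that("symptom association respects the minimum carrier rule", {
  set.seed(3)
  n <- 20
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:n), group = rep(c("mut0", "mutminus"), 10),
    rare = c(rep(1L, 7), rep(0L, n - 7)),
    common = rep(c(1L, 0L), each = 10)
  )
  mat <- tibble::tibble(feature_id = paste0("max|r", 1:8), type = "max")
  for (s in meta$sample_id) mat[[s]] <- rnorm(8)
  class(mat) <- c("flux_matrix", class(mat))
  expect_message(
    res <- associate_symptoms(mat, meta, "mut", min_carriers = 8),
    "skipping symptom 'rare'"
  )
  expect_identical(attr(res, "skipped"), "rare")
  expect_setequal(unique(res$symptom), "common")
  g <- glance(res)
  expect_identical(g$n_symptoms_skipped, 1L)
})
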