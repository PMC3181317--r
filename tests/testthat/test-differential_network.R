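test_that("the permutation null is reproducible bit-for-bit from the seed", {
  ds <- toy_dataset(15, 10, m = 3, seed = 4)
  d1 <- permutation_null(ds, n_perm = 1, seed = 99)
  d2 <- permutation_null(ds, n_perm = 1, seed = 99)
  expect_identical(d1[1, ], d2[1, ])
  expect_equal(dim(d1), c(1L, 3L))
  d3 <- permutation_null(ds, n_perm = 5, seed = 100)
  expect_false(identical(d1[1, ], d3[1, ]))
  expect_error(permutation_null(ds, n_perm = 0), "positive")
})

test_that("the null matrix is laid out pair-per-column with metadata", {
  ds <- toy_dataset(12, 12, m = 4, seed = 8)
  d <- permutation_null(ds, n_perm = 7, seed = 2)
  expect_equal(dim(d), c(7L, 6L))
  pairs <- attr(d, "pairs")
  expect_equal(nrow(pairs), 6)
  expect_true(all(pairs$variable_i != pairs$variable_j))
  expect_true(all(d >= 0))
  expect_equal(attr(d, "seed"), 2L)
})

test_that("exchangeable groups make observed and permuted d comparable", {
  # both groups from one model: mean_perm d* ~ mean_pairs d_obs
  ds <- toy_dataset(40, 40, m = 5, seed = 12)
  d_null <- permutation_null(ds, n_perm = 500, seed = 5)
  fa <- fit_group(ds, "A")
  fb <- fit_group(ds, "B")
  ut <- upper.tri(fa$pcor)
  d_obs <- abs(fa$pcor[ut] - fb$pcor[ut])
  # per-permutation mean-over-pairs d* forms the reference distribution;
  # the observed mean d is one more exchangeable draw from it
  perm_means <- rowMeans(d_null)
  expect_lt(abs(mean(d_obs) - mean(perm_means)), 3 * sd(perm_means))
})

test_that("the sampled null matches exhaustive label enumeration", {
  set.seed(33)
  vals <- matrix(rnorm(12), ncol = 2, dimnames = list(NULL, c("x", "y")))
  ds <- grouped_dataset(vals, rep(c("A", "B"), each = 3))
  ex <- permutation_null(ds, method = "exhaustive")
  expect_equal(nrow(ex), choose(6, 3))  # all 20 assignments
  # every sampled d* must be one of the enumerated values
  sm <- permutation_null(ds, n_perm = 50, seed = 6)
  expect_true(all(sapply(sm[, 1], function(v) {
    any(abs(v - ex[, 1]) < 1e-12)
  })))
  # exhaustive p-value within 1/(B+1) of the exact enumeration p-value
  fa <- fit_group(ds, "A")
  fb <- fit_group(ds, "B")
  d_obs <- abs(fa$pcor[1, 2] - fb$pcor[1, 2])
  p_pkg <- permutation_pvalues(d_obs, ex)
  p_exact <- mean(ex[, 1] >= d_obs)
  expect_lt(abs(p_pkg - p_exact), 1 / (nrow(ex) + 1) + 1e-12)
})

test_that("add-one p-values follow the counting definition", {
  null1 <- matrix(runif(99), ncol = 1)
  expect_equal(permutation_pvalues(0, null1), 1)       # every d* >= 0
  expect_equal(permutation_pvalues(2, null1), 0.01)    # 1/(99+1)
  expect_true(all(permutation_pvalues(runif(3), matrix(runif(30), 10)) > 0))
  expect_error(permutation_pvalues(c(0, 0), matrix(0, 2, 3)), "per null")
})

test_that("change classification follows the reference-group rules", {
  expect_equal(classify_change(0.20, -0.15, TRUE), "sign_change")
  expect_equal(classify_change(0.10, 0.30, TRUE), "increase")
  expect_equal(classify_change(0.10, 0.30, FALSE), "none")
  expect_equal(classify_change(0.30, 0.10, TRUE), "decrease")
  # noise-level flips are not sign changes; the magnitude rule applies
  expect_equal(classify_change(0.02, -0.30, TRUE), "increase")
  expect_equal(classify_change(0.02, -0.30, TRUE, min_magnitude = 0.01),
               "sign_change")
  # vectorized
  expect_equal(
    classify_change(c(0.2, 0.1, 0.1), c(-0.15, 0.3, 0.3), c(TRUE, TRUE, FALSE)),
    c("sign_change", "increase", "none"))
})

test_that("p-values are invariant to swapping the group labels", {
  ds <- toy_dataset(20, 15, m = 4, seed = 44)
  dn1 <- build_differential_network(ds, n_perm = 50, seed = 9)
  swapped <- grouped_dataset(
    ds$values,
    factor(ds$group_labels, levels = rev(levels(ds$group_labels))))
  dn2 <- build_differential_network(swapped, n_perm = 50, seed = 9)
  # d is symmetric in the groups and sizes map deterministically:
  # the permutation draws differ (sizes swap roles) but the observed d and
  # the exhaustive-style identity d(r_A, r_B) = d(r_B, r_A) must hold
  expect_equal(dn2$pairs$d_obs, dn1$pairs$d_obs, tolerance = 1e-12)
  expect_equal(dn2$pairs$r_A, dn1$pairs$r_B, tolerance = 1e-12)
  # with equal group sizes the sampled null is identical too
  ds_eq <- toy_dataset(18, 18, m = 3, seed = 45)
  sw_eq <- grouped_dataset(
    ds_eq$values,
    factor(ds_eq$group_labels, levels = c("B", "A")))
  n1 <- permutation_null(ds_eq, n_perm = 40, seed = 3)
  n2 <- permutation_null(sw_eq, n_perm = 40, seed = 3)
  expect_equal(n1, n2, ignore_attr = TRUE)
})

test_that("differential p-values are roughly uniform under the global null", {
  # pairs within one dataset share the two fitted pcor matrices, so their
  # p-values are dependent; pool over replicate datasets before comparing
  # the empirical distribution with the uniform
  p <- unlist(lapply(1:12, function(r) {
    ds <- toy_dataset(60, 60, m = 5, seed = 70 + r)
    dn <- build_differential_network(ds, n_perm = 200, seed = 11 + r)
    dn$pairs$p_perm
  }))
  grid <- seq(0.1, 0.9, by = 0.2)
  emp <- sapply(grid, function(q) mean(p <= q))
  # one-sided: not stochastically smaller than uniform, up to MC noise
  expect_true(all(emp <= grid + 0.12))
  expect_true(all(p > 0 & p <= 1))
})

test_that("detection power rises with the planted effect size", {
  base <- function(delta, seed) {
    spec <- simulation_spec(
      block_sizes = c(3, 3),
      within_block_pcor = 0.2,
      cross_block_edges = data.frame(i = integer(), j = integer(),
                                     pcor = numeric()),
      differential_edges = data.frame(i = 1, j = 4, pcor_B = delta,
                                      category = "increase"),
      n_A = 300, n_B = 300, seed = seed)
    ds <- sample_dataset(spec)
    dn <- build_differential_network(ds, n_perm = 120, seed = seed)
    pair <- dn$pairs$variable_i == "B01.1" & dn$pairs$variable_j == "B02.1"
    dn$pairs$p_perm[pair] <= 0.05
  }
  n_rep <- 30
  rates <- sapply(c(0.1, 0.2, 0.4), function(delta) {
    mean(sapply(seq_len(n_rep), function(r) base(delta, 500 + r)))
  })
  expect_true(all(diff(rates) >= -1 / n_rep))  # non-decreasing up to MC noise
  expect_gt(rates[3], rates[1])
})

test_that("the full differential build composes and gates correctly", {
  ds <- toy_dataset(25, 25, m = 4, seed = 90)
  dn <- build_differential_network(ds, n_perm = 99, alpha = 0.2, seed = 13)
  expect_s3_class(dn, "diff_edge_set")
  expect_equal(nrow(dn$pairs), 6)
  expect_true(all(dn$pairs$d_obs >= 0))
  expect_true(all(dn$pairs$p_perm > 0 & dn$pairs$p_perm <= 1))
  # category != none exactly when significant
  expect_equal(dn$pairs$category != "none", dn$pairs$p_perm <= dn$alpha)
  expect_error(build_differential_network(ds, n_perm = 0), "positive")
  expect_error(build_differential_network(ds, n_perm = 10, alpha = 0),
               "alpha")
  # bonferroni flag tightens the cut-off
  dnb <- build_differential_network(ds, n_perm = 99, alpha = 0.2, seed = 13,
                                    bonferroni = TRUE)
  expect_equal(dnb$alpha, 0.2 / 6)
})
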