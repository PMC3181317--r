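pcor_fixture <- function(vals, vars = NULL) {
  m <- (1 + sqrt(1 + 8 * length(vals))) / 2
  p <- diag(m)
  p[upper.tri(p)] <- vals
  p <- p + t(p) - diag(m)
  diag(p) <- 1
  if (is.null(vars)) vars <- paste0("V", seq_len(m))
  dimnames(p) <- list(vars, vars)
  p
}

test_that("edge p-values follow the analytic null tail", {
  p <- pcor_fixture(c(0, 0.5, 1))
  tab <- edge_pvalues(p, kappa = 5)
  expect_equal(tab$p_value[tab$statistic == 0], 1)     # null value
  expect_equal(tab$p_value[tab$statistic == 1], 0)     # boundary
  # kappa = 5: tail of (1-r^2)^1 normalized on [-1,1]
  expect_equal(tab$p_value[tab$statistic == 0.5],
               oracle_null_tail(0.5, 5), tolerance = 1e-8)
  expect_equal(oracle_null_tail(0.5, 5), 0.3125, tolerance = 1e-8)
  # several kappa / r combinations against the integration oracle
  for (kappa in c(4.5, 10, 60)) {
    for (r in c(0.1, -0.3, 0.7)) {
      tab <- edge_pvalues(pcor_fixture(c(r, 0, 0)), kappa = kappa)
      expect_equal(tab$p_value[1], oracle_null_tail(r, kappa),
                   tolerance = 1e-7)
    }
  }
  expect_error(edge_pvalues(p, kappa = 3), "> 3")
  expect_error(edge_pvalues(p, kappa = 2.5), "> 3")
})

test_that("the edge table covers each unordered pair exactly once", {
  ds <- toy_dataset(50, 40, m = 6, seed = 2)
  tab <- edge_pvalues(fit_group(ds, "A"))
  expect_equal(nrow(tab), 15)
  key <- paste(pmin(tab$variable_i, tab$variable_j),
               pmax(tab$variable_i, tab$variable_j))
  expect_false(any(duplicated(key)))
  expect_false(any(tab$variable_i == tab$variable_j))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_true(is.numeric(attr(tab, "kappa")) && attr(tab, "kappa") > 3)
})

test_that("maximum-likelihood kappa recovers the generating value", {
  set.seed(17)
  kappa_true <- 40
  r2 <- rbeta(3000, 0.5, (kappa_true - 1) / 2)
  r <- sqrt(r2) * sample(c(-1, 1), 3000, replace = TRUE)
  kap <- diffpcor:::estimate_kappa(r)
  expect_equal(kap, kappa_true, tolerance = 0.1)
})

test_that("Bonferroni arithmetic matches the stated thresholds", {
  expect_equal(bonferroni_threshold(0.05, 60), 8.3333e-4, tolerance = 1e-4)
  expect_equal(bonferroni_threshold(0.05, 60 * 59 / 2), 2.8249e-5,
               tolerance = 1e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
})

test_that("network assembly keeps isolated nodes and respects the threshold", {
  p <- pcor_fixture(rep(0, 10), vars = paste0("m", 1:5))
  tab <- edge_pvalues(p, kappa = 10)
  net0 <- build_network(tab, 0.01)
  expect_equal(nrow(net0$edges), 0)
  expect_equal(length(net0$nodes), 5)
  expect_equal(net0$K, 10)
  net1 <- build_network(tab, 1)  # saturation: every tabled pair is an edge
  expect_equal(nrow(net1$edges), 10)
  expect_true(all(net0$edges$p_value <= net0$alpha_corrected))
  expect_error(build_network(tab, 0), "threshold")
})

test_that("edge sets are monotone in the threshold", {
  ds <- toy_dataset(80, 60, m = 6, seed = 5)
  tab <- edge_pvalues(fit_group(ds, "A"))
  thresholds <- sort(runif(5))
  prev <- character(0)
  for (t in thresholds) {
    net <- build_network(tab, t)
    cur <- paste(net$edges$variable_i, net$edges$variable_j)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("connected and isolated node counts always sum to the panel size", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- matrix(rnorm(300 * 10), ncol = 10)
    colnames(x) <- paste0("V", 1:10)
    rc <- shrink_correlation(x)
    tab <- edge_pvalues(partial_correlations(rc), kappa = "auto",
                        n = nrow(x))
    net <- build_network(tab, bonferroni_threshold(0.05, 45))
    topo <- global_summary(net)
    expect_equal(topo$n_connected + topo$n_isolated, 10)
  }
})

test_that("family-wise error is controlled on identity-precision data", {
  # no true edges: expected number of Bonferroni-significant edges <= alpha
  n_rep <- 100
  edge_counts <- numeric(n_rep)
  m <- 20
  k <- m * (m - 1) / 2
  thr <- bonferroni_threshold(0.05, k)
  for (r in seq_len(n_rep)) {
    set.seed(3000 + r)
    x <- matrix(rnorm(500 * m), ncol = m)
    fitp <- partial_correlations(shrink_correlation(x))
    tab <- edge_pvalues(fitp, kappa = "auto", n = 500)
    edge_counts[r] <- sum(tab$p_value <= thr)
  }
  expect_lte(mean(edge_counts), 0.05)
})

test_that("strong planted within-block edges are recovered", {
  # four planted blocks of 3 inside a 30-variable panel (signal pairs kept
  # sparse so the ML null-df fit stays close to the true null), n = 2000
  spec <- simulation_spec(block_sizes = c(3, 3, 3, 3, rep(1, 18)),
                          within_block_pcor = 0.3,
                          cross_block_edges = data.frame(i = integer(),
                                                         j = integer(),
                                                         pcor = numeric()),
                          differential_edges = data.frame(
                            i = integer(), j = integer(),
                            pcor_B = numeric(), category = character()),
                          n_A = 2000, n_B = 2000, seed = 1)
  prec <- build_precision(spec, "A")
  planted <- which(abs(prec$realized_pcor) > 0.1 &
                     upper.tri(prec$realized_pcor), arr.ind = TRUE)
  hits <- 0
  total <- 0
  for (r in 1:10) {
    ds <- sample_dataset(spec, seed = 100 + r)
    fit <- fit_group(ds, "A")
    tab <- edge_pvalues(fit)
    net <- build_network(tab, bonferroni_threshold(0.05, nrow(tab)))
    edge_key <- paste(net$edges$variable_i, net$edges$variable_j)
    vars <- spec$variable_names
    planted_key <- paste(vars[planted[, 1]], vars[planted[, 2]])
    hits <- hits + sum(planted_key %in% edge_key)
    total <- total + length(planted_key)
  }
  expect_gte(hits / total, 0.95)
})
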