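#' Two-sided edge p-values for partial correlations
#'
#' Tests, for every unordered variable pair, the null hypothesis that the
#' partial correlation is zero. Under the null the partial correlation r is
#' modelled by the density p0(r) proportional to (1 - r^2)^((kappa - 3) / 2)
#' on \[-1, 1\], with kappa the effective degree of freedom. The two-sided
#' p-value is P(|R| >= |r|) under p0, computed as
#' 1 - pbeta(r^2, 1/2, (kappa - 1)/2).
#'
#' With `kappa = "auto"` the degree of freedom is estimated by maximum
#' likelihood on the observed off-diagonal partial correlations. Since pairs
#' with real associations would bias a naive fit, the likelihood is
#' restricted to the null bulk (values within 4 null standard deviations of
#' a robust MAD-based initial scale) with the correspondingly truncated
#' normalizer. If the optimizer fails or runs to its boundary, the fallback
#' kappa = max(n - M - 1, 4) is used. The kappa actually applied is
#' attached as attribute `"kappa"`.
#'
#' @param result A `shrinkage_pcor` fit from [fit_group()], or a bare
#'   symmetric pcor matrix (then `n` is required for the fallback).
#' @param kappa Positive degree of freedom (> 3), or `"auto"`.
#' @param n Sample count, only needed when `result` is a bare matrix.
#' @return Data frame (class `edge_table`) with one row per unordered pair
#'   i < j in the canonical variable order: `variable_i`, `variable_j`,
#'   `statistic` (the partial correlation), `p_value`, `annotation`.
#' @export
edge_pvalues <- function(result, kappa = "auto", n = NULL) {
  if (inherits(result, "shrinkage_pcor")) {
    pcor <- result$pcor
    n <- result$n
  } else {
    pcor <- as.matrix(result)
  }
  m <- ncol(pcor)
  vars <- colnames(pcor)
  if (is.null(vars)) vars <- paste0("V", seq_len(m))
  ut <- upper.tri(pcor)
  r <- pcor[ut]
  if (identical(kappa, "auto")) {
    kappa <- estimate_kappa(r, n = n, m = m)
  } else {
    if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 3) {
      stop("`kappa` must be a single number > 3 or \"auto\"", call. = FALSE)
    }
  }
  idx <- which(ut, arr.ind = TRUE)
  tab <- data.frame(
    variable_i = vars[idx[, "row"]],
    variable_j = vars[idx[, "col"]],
    statistic = r,
    p_value = pcor_null_pvalue(r, kappa),
    annotation = "",
    stringsAsFactors = FALSE
  )
  class(tab) <- c("edge_table", "data.frame")
  attr(tab, "kappa") <- kappa
  attr(tab, "nodes") <- vars
  tab
}

# Two-sided tail probability of |R| >= |r| under p0(r) ~ (1-r^2)^((k-3)/2).
pcor_null_pvalue <- function(r, kappa) {
  r2 <- pmin(r^2, 1)
  stats::pbeta(r2, shape1 = 0.5, shape2 = (kappa - 1) / 2, lower.tail = FALSE)
}

# ML estimate of the null degree of freedom kappa from observed partial
# correlations. Truly associated pairs would drag a naive fit over all
# pairs far below the null value, so the likelihood is restricted to the
# null bulk: a robust initial scale (MAD of r; null r is approximately
# N(0, 1/kappa) for large kappa) defines a window of 4 null SDs, and kappa
# maximizes the correctly truncated likelihood of the retained pairs,
# log L = sum (k-3)/2 log(1-r^2) - N log int_{-c}^{c} (1-t^2)^((k-3)/2) dt.
estimate_kappa <- function(r, n = NULL, m = NULL) {
  fallback <- if (!is.null(n) && !is.null(m)) max(n - m - 1, 4) else 4
  upper <- 1e7
  med <- stats::median(abs(r))
  if (!is.finite(med) || med <= 0) {
    return(if (is.numeric(fallback)) fallback else 4)
  }
  kappa0 <- max(4, (stats::qnorm(0.75) / med)^2)
  cut <- min(1 - 1e-9, 4 / sqrt(kappa0))
  keep <- abs(r) <= cut
  if (sum(keep) < 3L) {
    keep <- rep(TRUE, length(r))
    cut <- 1 - 1e-9
  }
  r2 <- pmin(r[keep]^2, 1 - 1e-12)
  slog <- sum(log1p(-r2))
  nn <- length(r2)
  c2 <- cut^2
  negll <- function(k) {
    lnorm <- stats::pbeta(c2, 0.5, (k - 1) / 2, log.p = TRUE) +
      lbeta(0.5, (k - 1) / 2)
    -((k - 3) / 2 * slog - nn * lnorm)
  }
  opt <- tryCatch(
    stats::optimize(negll, interval = c(3 + 1e-6, upper)),
    error = function(e) NULL
  )
  if (is.null(opt) || !is.finite(opt$minimum) || opt$minimum >= upper * 0.99) {
    return(fallback)
  }
  opt$minimum
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param n_tests Number of tests (e.g. M variables for the concentration
#'   screen, or K = M(M-1)/2 pairs for edge tests).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(n_tests) || length(n_tests) != 1L || n_tests < 1) {
    stop("`n_tests` must be a positive integer", call. = FALSE)
  }
  alpha / n_tests
}

#' Build a binary association network from edge p-values
#'
#' Draws an edge between every pair whose p-value is at or below the
#' threshold (typically the Bonferroni-corrected alpha / K); all remaining
#' variables stay in the node set as isolated nodes, so the graph always has
#' the full panel of M nodes.
#'
#' @param pvals An `edge_table` from [edge_pvalues()].
#' @param threshold Inclusion threshold in (0, 1\]; pairs with
#'   `p_value <= threshold` become edges.
#' @param nodes Optional character vector fixing the node set and order;
#'   defaults to the variables seen when the table was built.
#' @return Object of class `assoc_network`: list with `nodes`, `edges`
#'   (data frame `variable_i`, `variable_j`, `pcor`, `p_value`),
#'   `alpha_corrected` (the threshold), and `K` (total pair count).
#' @export
build_network <- function(pvals, threshold, nodes = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  }
  if (is.null(nodes)) nodes <- attr(pvals, "nodes")
  if (is.null(nodes)) nodes <- unique(c(pvals$variable_i, pvals$variable_j))
  keep <- pvals$p_value <= threshold
  edges <- data.frame(
    variable_i = pvals$variable_i[keep],
    variable_j = pvals$variable_j[keep],
    pcor = pvals$statistic[keep],
    p_value = pvals$p_value[keep],
    stringsAsFactors = FALSE
  )
  m <- length(nodes)
  structure(
    list(
      nodes = nodes,
      edges = edges,
      alpha_corrected = threshold,
      K = m * (m - 1) / 2,
      kappa = attr(pvals, "kappa")
    ),
    class = "assoc_network"
  )
}

#' @export
print.assoc_network <- function(x, ...) {
  cat("Association network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges (p <=", format(x$alpha_corrected, digits = 4),
      "of", x$K, "pairs)\n")
  invisible(x)
}
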