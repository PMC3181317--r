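#' Permutation null distribution of the partial-correlation difference
#'
#' Pools the samples of both groups, repeatedly permutes the group labels
#' preserving the two group sizes, refits the shrinkage partial correlations
#' in each pseudo-group (the shrinkage intensity is re-estimated every time)
#' and records d* = |r*_A - r*_B| for every unordered variable pair. One
#' shared pool of permutations serves all pairs, mirroring a protocol that
#' permutes whole datasets rather than individual pairs, so the per-pair
#' null samples are dependent across pairs.
#'
#' With `method = "exhaustive"` all choose(n, n_A) assignments of samples to
#' the first group are enumerated instead of sampled; `n_perm` is ignored.
#' This is only feasible for very small groups and is mainly useful for
#' validating the sampled null.
#'
#' @param data A [grouped_dataset()].
#' @param n_perm Number of label permutations (the reference protocol uses
#'   100,000; reduce for exploratory runs).
#' @param seed Integer seed; permutations use R's Mersenne-Twister generator
#'   and are fully reproducible given the seed.
#' @param method `"sample"` (default) or `"exhaustive"`.
#' @return Numeric matrix with one row per permutation and one column per
#'   unordered pair (columns ordered as the upper triangle of the pcor
#'   matrix, i < j), with attributes `pairs` (data frame of variable names),
#'   `seed`, and `method`.
#' @export
permutation_null <- function(data, n_perm, seed = 1L,
                             method = c("sample", "exhaustive")) {
  stopifnot(inherits(data, "grouped_dataset"))
  method <- match.arg(method)
  if (method == "sample" &&
      (!is.numeric(n_perm) || length(n_perm) != 1L || n_perm < 1)) {
    stop("`n_perm` must be a positive integer", call. = FALSE)
  }
  x <- data$values
  n_tot <- nrow(x)
  n_a <- data$group_sizes[[1L]]
  m <- ncol(x)
  ut <- upper.tri(diag(m))
  if (method == "exhaustive") {
    assign_a <- utils::combn(n_tot, n_a)
    n_perm <- ncol(assign_a)
  } else {
    n_perm <- as.integer(n_perm)
  }
  d_star <- matrix(NA_real_, nrow = n_perm, ncol = sum(ut))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  for (b in seq_len(n_perm)) {
    idx_a <- if (method == "exhaustive") {
      assign_a[, b]
    } else {
      sample.int(n_tot, n_a)
    }
    p_a <- pcor_fit_fast(x[idx_a, , drop = FALSE])
    p_b <- pcor_fit_fast(x[-idx_a, , drop = FALSE])
    d_star[b, ] <- abs(p_a[ut] - p_b[ut])
  }
  idx <- which(ut, arr.ind = TRUE)
  vars <- data$variable_names
  attr(d_star, "pairs") <- data.frame(
    variable_i = vars[idx[, "row"]],
    variable_j = vars[idx[, "col"]],
    stringsAsFactors = FALSE
  )
  attr(d_star, "seed") <- as.integer(seed)
  attr(d_star, "method") <- method
  d_star
}

#' Permutation p-values for observed partial-correlation differences
#'
#' Uses the add-one estimator p = (1 + #\{d* >= d_obs\}) / (1 + B), which
#' counts the observed statistic as one realization of the null and can
#' therefore never return zero.
#'
#' @param d_obs Numeric vector of observed absolute differences, one per
#'   pair (same pair order as the null matrix columns).
#' @param null_samples Matrix from [permutation_null()] (permutations in
#'   rows, pairs in columns).
#' @return Numeric vector of p-values in (0, 1\].
#' @export
permutation_pvalues <- function(d_obs, null_samples) {
  null_samples <- as.matrix(null_samples)
  if (length(d_obs) != ncol(null_samples)) {
    stop("`d_obs` must have one entry per null-sample column", call. = FALSE)
  }
  b <- nrow(null_samples)
  if (b < 1L) stop("need at least one null sample per pair", call. = FALSE)
  exceed <- colSums(null_samples >= rep(d_obs, each = b))
  (1 + exceed) / (1 + b)
}

#' Classify how a partial correlation changed between groups
#'
#' Change categories are defined with respect to the first (reference)
#' group: `sign_change` when the two group-wise partial correlations have
#' opposite signs and both magnitudes reach `min_magnitude` (guarding
#' against noise-level sign flips around zero); otherwise `increase` when
#' the magnitude grew, `decrease` when it shrank. Non-significant pairs are
#' always `none`.
#'
#' @param r_A,r_B Partial correlations in the reference and comparison
#'   group (vectors of equal length).
#' @param significant Logical vector; only significant pairs get a category.
#' @param min_magnitude Minimum |r| in both groups for `sign_change`
#'   (default 0.05).
#' @return Character vector in `c("increase", "decrease", "sign_change",
#'   "none")`.
#' @export
classify_change <- function(r_A, r_B, significant, min_magnitude = 0.05) {
  stopifnot(length(r_A) == length(r_B),
            length(significant) %in% c(1L, length(r_A)))
  significant <- rep_len(as.logical(significant), length(r_A))
  out <- rep("none", length(r_A))
  flip <- r_A * r_B < 0 & abs(r_A) >= min_magnitude & abs(r_B) >= min_magnitude
  grew <- abs(r_B) > abs(r_A)
  out[significant & grew] <- "increase"
  out[significant & !grew] <- "decrease"
  out[significant & flip] <- "sign_change"
  out
}

#' Differential network from a two-group dataset
#'
#' Full differential analysis: fits shrinkage partial correlations per
#' group, computes the observed d = |r_A - r_B| for every pair, builds the
#' permutation null with re-estimated shrinkage in every pseudo-group,
#' derives add-one permutation p-values and classifies the significant
#' changes. Significance uses the uncorrected `alpha` on the two-tailed
#' permutation p-value by default: for a fixed sample size the power to
#' detect a change in correlation is lower than for a change in a single
#' variable's level, so a per-pair cut-off is retained; set
#' `bonferroni = TRUE` to divide `alpha` by the pair count instead.
#'
#' @inheritParams permutation_null
#' @param alpha Per-pair significance level for the differential edges
#'   (default 0.05, uncorrected).
#' @param min_magnitude Passed to [classify_change()].
#' @param bonferroni If `TRUE`, use `alpha / K` with K = M(M-1)/2.
#' @return Object of class `diff_edge_set`: list with `pairs` (data frame
#'   `variable_i`, `variable_j`, `r_A`, `r_B`, `d_obs`, `p_perm`,
#'   `category`), `nodes`, `groups`, `n_permutations`, `seed`, `alpha`
#'   (the cut-off actually applied), `min_magnitude`, and the per-group
#'   shrinkage intensities `lambda`.
#' @export
build_differential_network <- function(data, n_perm = 1e5, alpha = 0.05,
                                       seed = 1L, min_magnitude = 0.05,
                                       bonferroni = FALSE,
                                       method = c("sample", "exhaustive")) {
  stopifnot(inherits(data, "grouped_dataset"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  method <- match.arg(method)
  groups <- levels(data$group_labels)
  fit_a <- fit_group(data, groups[1L])
  fit_b <- fit_group(data, groups[2L])
  ut <- upper.tri(fit_a$pcor)
  r_a <- fit_a$pcor[ut]
  r_b <- fit_b$pcor[ut]
  d_obs <- abs(r_a - r_b)
  null_d <- permutation_null(data, n_perm = n_perm, seed = seed,
                             method = method)
  p_perm <- permutation_pvalues(d_obs, null_d)
  m <- length(data$variable_names)
  k_pairs <- m * (m - 1) / 2
  cutoff <- if (bonferroni) alpha / k_pairs else alpha
  signif <- p_perm <= cutoff
  pairs <- attr(null_d, "pairs")
  pairs$r_A <- r_a
  pairs$r_B <- r_b
  pairs$d_obs <- d_obs
  pairs$p_perm <- p_perm
  pairs$category <- classify_change(r_a, r_b, signif, min_magnitude)
  structure(
    list(
      pairs = pairs,
      nodes = data$variable_names,
      groups = groups,
      n_permutations = nrow(null_d),
      seed = as.integer(seed),
      alpha = cutoff,
      min_magnitude = min_magnitude,
      lambda = stats::setNames(c(fit_a$lambda, fit_b$lambda), groups)
    ),
    class = "diff_edge_set"
  )
}

#' Significant subset of a differential edge set
#'
#' @param x A `diff_edge_set`.
#' @return Data frame of the pairs with `category != "none"` (the edges of
#'   the differential network).
#' @export
differential_edges <- function(x) {
  stopifnot(inherits(x, "diff_edge_set"))
  x$pairs[x$pairs$category != "none", , drop = FALSE]
}

#' @export
print.diff_edge_set <- function(x, ...) {
  sig <- differential_edges(x)
  connected <- unique(c(sig$variable_i, sig$variable_j))
  cat("Differential network:", x$groups[1L], "vs", x$groups[2L], "\n")
  cat("  pairs tested:", nrow(x$pairs), " permutations:", x$n_permutations,
      " cut-off p <=", format(x$alpha, digits = 4), "\n")
  cat("  differential edges:", nrow(sig), "\n")
  if (nrow(sig) > 0) {
    tab <- table(factor(sig$category,
                        levels = c("increase", "decrease", "sign_change")))
    cat("   ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  }
  cat("  differentially connected variables:", length(connected),
      " unconnected:", length(x$nodes) - length(connected), "\n")
  invisible(x)
}
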