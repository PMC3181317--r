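#' Ledoit-Wolf optimal shrinkage intensity on the correlation scale
#'
#' Computes the analytic optimal mixing weight lambda for the linear
#' shrinkage estimator U* = lambda T + (1 - lambda) U, where U is the sample
#' correlation matrix and the target T is the identity (unit diagonal,
#' off-diagonals shrunk to zero):
#'
#'   lambda* = sum_{i != j} Var-hat(r_ij) / sum_{i != j} r_ij^2,
#'
#' clipped to \[0, 1\]. Var-hat(r_ij) is the unbiased small-sample estimate
#' n / (n - 1)^3 * sum_k (w_kij - w-bar_ij)^2 over the per-sample products
#' w_kij of values standardized with the (n - 1)-denominator variance. A zero
#' denominator (empirical correlations all exactly zero) yields lambda = 1:
#' the data are indistinguishable from the target. With fewer than 3 samples
#' the variance of the correlations cannot be estimated and lambda = 1 is
#' returned, so that estimation degenerates gracefully to the target.
#'
#' @param data Numeric samples x variables matrix, at least 2 columns, each
#'   with nonzero variance.
#' @return Shrinkage intensity in \[0, 1\].
#' @references Ledoit & Wolf (2003) J. Multivariate Anal.; Schafer &
#'   Strimmer (2005) Stat. Appl. Genet. Mol. Biol.
#' @export
estimate_lambda <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (ncol(data) < 2L) stop("need at least 2 variables", call. = FALSE)
  check_nonconstant(data)
  if (n < 3L) {
    return(1)
  }
  xs <- standardize_cols(data)
  r <- crossprod(xs) / (n - 1)
  # Var-hat(r_ij) via sums of squared standardized products:
  # sum_k (w - wbar)^2 = sum_k w^2 - n * wbar^2 with wbar = r (n-1)/n
  s2 <- crossprod(xs^2)
  wbar <- r * (n - 1) / n
  vhat <- n / (n - 1)^3 * (s2 - n * wbar^2)
  diag(vhat) <- 0
  roff <- r
  diag(roff) <- 0
  denom <- sum(roff^2)
  if (denom <= 0) {
    return(1)
  }
  min(1, max(0, sum(vhat) / denom))
}

#' Regularized correlation matrix by linear shrinkage to the identity
#'
#' Returns U* = lambda I + (1 - lambda) U where U is the sample correlation
#' matrix of `data`. For lambda > 0 the result is symmetric positive
#' definite even when variables outnumber samples.
#'
#' @inheritParams estimate_lambda
#' @param lambda Shrinkage intensity in \[0, 1\], or `"auto"` to use
#'   [estimate_lambda()].
#' @return M x M regularized correlation matrix with unit diagonal; the
#'   intensity used is attached as attribute `"lambda"`.
#' @export
shrink_correlation <- function(data, lambda = "auto") {
  data <- as.matrix(data)
  if (identical(lambda, "auto")) {
    lambda <- estimate_lambda(data)
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("`lambda` must be a single value in [0, 1] or \"auto\"", call. = FALSE)
  }
  check_nonconstant(data)
  n <- nrow(data)
  xs <- standardize_cols(data)
  r <- crossprod(xs) / (n - 1)
  ustar <- (1 - lambda) * r
  diag(ustar) <- 1
  dimnames(ustar) <- list(colnames(data), colnames(data))
  attr(ustar, "lambda") <- lambda
  ustar
}

#' Partial correlations from a (regularized) correlation matrix
#'
#' Inverts the correlation matrix to the precision matrix Omega and scales:
#' pcor_ij = -Omega_ij / sqrt(Omega_ii Omega_jj). The diagonal is set to 1.
#' The partial correlation measures the linear association between two
#' variables conditioning on all remaining ones, so under a Gaussian
#' graphical model a zero entry encodes conditional independence.
#'
#' @param regularized_correlation Symmetric positive-definite matrix (e.g.
#'   from [shrink_correlation()]).
#' @return Symmetric matrix of partial correlations with unit diagonal.
#' @export
partial_correlations <- function(regularized_correlation) {
  rc <- as.matrix(regularized_correlation)
  if (!isSymmetric(unname(rc), tol = 1e-8)) {
    stop("input must be a symmetric matrix", call. = FALSE)
  }
  omega <- tryCatch(
    chol2inv(chol(rc)),
    error = function(e) {
      stop("correlation matrix is numerically singular; use shrinkage ",
           "intensity lambda > 0", call. = FALSE)
    }
  )
  d <- sqrt(diag(omega))
  pcor <- -omega / tcrossprod(d)
  pcor <- (pcor + t(pcor)) / 2
  diag(pcor) <- 1
  dimnames(pcor) <- dimnames(rc)
  pcor
}

#' Shrinkage partial-correlation fit for one group
#'
#' Convenience composition: extracts the rows of one group, estimates the
#' shrinkage intensity, forms the regularized correlation matrix and derives
#' the partial correlations.
#'
#' @param data A [grouped_dataset()].
#' @param group One of the two group labels.
#' @param lambda Shrinkage intensity or `"auto"` (default).
#' @return Object of class `shrinkage_pcor`: list with `lambda` (intensity
#'   used), `regularized_correlation`, `pcor`, `n` (samples used), `group`.
#' @export
fit_group <- function(data, group, lambda = "auto") {
  x <- group_values(data, group)
  rc <- shrink_correlation(x, lambda = lambda)
  structure(
    list(
      lambda = attr(rc, "lambda"),
      regularized_correlation = rc,
      pcor = partial_correlations(rc),
      n = nrow(x),
      group = as.character(group)
    ),
    class = "shrinkage_pcor"
  )
}

#' @export
print.shrinkage_pcor <- function(x, ...) {
  cat("Shrinkage partial-correlation fit",
      if (!is.null(x$group)) paste0("(group '", x$group, "')"), "\n")
  cat("  variables:", ncol(x$pcor), " samples:", x$n, "\n")
  cat("  shrinkage intensity lambda:", format(x$lambda, digits = 4), "\n")
  off <- x$pcor[upper.tri(x$pcor)]
  cat("  |pcor| range:", format(min(abs(off)), digits = 3), "-",
      format(max(abs(off)), digits = 3), "\n")
  invisible(x)
}

# ---- internal helpers ------------------------------------------------------

# Column standardization with the (n-1)-denominator variance estimator.
standardize_cols <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  xc <- x - rep(m, each = n)
  s <- sqrt(colSums(xc^2) / (n - 1))
  xc / rep(s, each = n)
}

check_nonconstant <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  ss <- colSums((x - rep(m, each = n))^2)
  if (any(ss == 0)) {
    bad <- colnames(x)[ss == 0]
    if (is.null(bad)) bad <- which(ss == 0)
    stop("zero-variance column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Fast path used inside the permutation loop: shrinkage pcor matrix from a
# plain matrix, lambda re-estimated, minimal validation.
pcor_fit_fast <- function(x) {
  n <- nrow(x)
  xs <- standardize_cols(x)
  r <- crossprod(xs) / (n - 1)
  s2 <- crossprod(xs^2)
  wbar <- r * (n - 1) / n
  vhat <- n / (n - 1)^3 * (s2 - n * wbar^2)
  diag(vhat) <- 0
  roff <- r
  diag(roff) <- 0
  denom <- sum(roff^2)
  lam <- if (denom <= 0 || n < 3) 1 else min(1, max(0, sum(vhat) / denom))
  ustar <- (1 - lam) * r
  diag(ustar) <- 1
  omega <- chol2inv(chol(ustar))
  d <- sqrt(diag(omega))
  pcor <- -omega / tcrossprod(d)
  diag(pcor) <- 1
  pcor
}
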