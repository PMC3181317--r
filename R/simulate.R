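#' Specification of a two-group block-structured simulation
#'
#' Describes a pair of Gaussian graphical models sharing a block-diagonal
#' partial-correlation backbone (blocks standing in for panels of closely
#' related measures such as lipoprotein subclasses) plus optional
#' cross-block links, identical between the two groups except for a chosen
#' set of differential pairs whose group-B partial correlation is
#' overridden (increased, decreased, or sign-flipped).
#'
#' The defaults emulate a lipoprotein-subclass panel: 14 blocks of 4-5
#' measures (M = 60 variables), moderate within-block partial correlation,
#' a chain of cross-block links (the lipoprotein cascade runs across
#' subclass sizes), group sizes 4406 and 531, and three planted
#' differential pairs covering the three change categories.
#'
#' @param block_sizes Integer partition of the variable count into blocks.
#' @param within_block_pcor Target partial correlation between all pairs
#'   inside a block (must satisfy |pcor| < 1).
#' @param cross_block_edges Data frame with columns `i`, `j` (variable
#'   indices) and `pcor`: additional shared links.
#' @param differential_edges Data frame with columns `i`, `j`, `pcor_B`
#'   (the group-B override) and `category` (the intended change type).
#' @param n_A,n_B Group sample sizes (each at least 2).
#' @param group_labels Two labels, first = reference group.
#' @param seed Integer seed for [sample_dataset()].
#' @return Object of class `sim_spec`.
#' @export
simulation_spec <- function(block_sizes = c(rep(5L, 4), rep(4L, 10)),
                            within_block_pcor = 0.2,
                            cross_block_edges = NULL,
                            differential_edges = NULL,
                            n_A = 4406L, n_B = 531L,
                            group_labels = c("A", "B"),
                            seed = 1L) {
  block_sizes <- as.integer(block_sizes)
  if (any(block_sizes < 1L)) stop("block sizes must be >= 1", call. = FALSE)
  m <- sum(block_sizes)
  if (abs(within_block_pcor) >= 1) {
    stop("|within_block_pcor| must be < 1", call. = FALSE)
  }
  block_start <- cumsum(c(1L, utils::head(block_sizes, -1L)))
  if (is.null(cross_block_edges) && length(block_sizes) > 1L) {
    # chain consecutive block heads
    cross_block_edges <- data.frame(
      i = block_start[-length(block_start)],
      j = block_start[-1L],
      pcor = 0.2
    )
  }
  if (is.null(differential_edges)) {
    differential_edges <- default_differential_edges(block_start, block_sizes)
  }
  check_edge_frame <- function(df, value_col) {
    if (is.null(df)) return(invisible(NULL))
    stopifnot(all(c("i", "j", value_col) %in% names(df)))
    if (any(df$i < 1 | df$i > m | df$j < 1 | df$j > m | df$i == df$j)) {
      stop("edge indices must be distinct and in 1..M", call. = FALSE)
    }
    if (any(abs(df[[value_col]]) >= 1)) {
      stop("all target partial correlations must satisfy |pcor| < 1",
           call. = FALSE)
    }
  }
  check_edge_frame(cross_block_edges, "pcor")
  check_edge_frame(differential_edges, "pcor_B")
  if (length(group_labels) != 2L || anyDuplicated(group_labels)) {
    stop("`group_labels` must be two distinct labels", call. = FALSE)
  }
  if (n_A < 2L || n_B < 2L) {
    stop("group sizes `n_A` and `n_B` must be at least 2", call. = FALSE)
  }
  block_id <- rep(seq_along(block_sizes), block_sizes)
  variable_names <- paste0("B", sprintf("%02d", block_id), ".",
                           unlist(lapply(block_sizes, seq_len)))
  structure(
    list(
      M = m,
      block_sizes = block_sizes,
      within_block_pcor = within_block_pcor,
      cross_block_edges = cross_block_edges,
      differential_edges = differential_edges,
      n_A = as.integer(n_A),
      n_B = as.integer(n_B),
      group_labels = as.character(group_labels),
      variable_names = variable_names,
      seed = as.integer(seed)
    ),
    class = "sim_spec"
  )
}

# One planted change per category: a sign flip and a weakening on existing
# cross-block links, plus a newly strengthened cross-block pair.
default_differential_edges <- function(block_start, block_sizes) {
  nb <- length(block_sizes)
  if (nb < 7L || any(block_sizes[c(3, 5)] < 2L)) {
    return(data.frame(i = integer(), j = integer(), pcor_B = numeric(),
                      category = character()))
  }
  data.frame(
    i = c(block_start[1L], block_start[3L] + 1L, block_start[6L]),
    j = c(block_start[2L], block_start[5L] + 1L, block_start[7L]),
    pcor_B = c(-0.2, 0.3, 0.05),
    category = c("sign_change", "increase", "decrease")
  )
}

#' Precision matrix of one simulated group
#'
#' Builds the unit-diagonal partial-correlation pattern implied by the
#' simulation spec (with group-B overrides applied when `group = "B"`),
#' converts it to a precision matrix (off-diagonal Omega_ij = -pcor_ij),
#' and enforces positive definiteness by diagonal inflation: the smallest
#' delta in \{0, 0.05, 0.1, ...\} such that Omega + delta I has minimum
#' eigenvalue >= 1e-6 is added, then the matrix is re-standardized to unit
#' diagonal. Inflation attenuates the requested partial correlations, so
#' the realized values are recomputed from the final matrix and returned
#' alongside it; tests and recovery rates should always be read against the
#' realized values.
#'
#' @param spec A [simulation_spec()].
#' @param group `"A"` or `"B"` (position, not label text).
#' @return Object of class `precision_model`: list with `omega` (precision
#'   matrix), `realized_pcor`, `delta` (inflation used), `group`.
#' @export
build_precision <- function(spec, group = c("A", "B")) {
  stopifnot(inherits(spec, "sim_spec"))
  group <- match.arg(group)
  m <- spec$M
  p <- diag(1, m)
  block_id <- rep(seq_along(spec$block_sizes), spec$block_sizes)
  same_block <- outer(block_id, block_id, "==")
  p[same_block & !diag(m)] <- spec$within_block_pcor
  set_pair <- function(mat, i, j, v) {
    mat[cbind(i, j)] <- v
    mat[cbind(j, i)] <- v
    mat
  }
  ce <- spec$cross_block_edges
  if (!is.null(ce) && nrow(ce) > 0) {
    p <- set_pair(p, ce$i, ce$j, ce$pcor)
  }
  if (group == "B") {
    de <- spec$differential_edges
    if (!is.null(de) && nrow(de) > 0) {
      p <- set_pair(p, de$i, de$j, de$pcor_B)
    }
  }
  omega <- -p
  diag(omega) <- 1
  delta <- 0
  repeat {
    ev <- min(eigen(omega + delta * diag(m), symmetric = TRUE,
                    only.values = TRUE)$values)
    if (ev >= 1e-6) break
    delta <- delta + 0.05
    if (delta > 2) {
      stop("requested partial-correlation pattern cannot be repaired to a ",
           "positive-definite precision matrix (inflation cap exceeded)",
           call. = FALSE)
    }
  }
  omega <- omega + delta * diag(m)
  d <- sqrt(diag(omega))
  omega <- omega / tcrossprod(d)
  realized <- -omega / tcrossprod(sqrt(diag(omega)))
  diag(realized) <- 1
  dimnames(omega) <- dimnames(realized) <-
    list(spec$variable_names, spec$variable_names)
  structure(
    list(omega = omega, realized_pcor = realized, delta = delta,
         group = group),
    class = "precision_model"
  )
}

#' Draw a two-group dataset from a simulation spec
#'
#' Samples `n_A` + `n_B` rows from the two zero-mean multivariate Gaussians
#' whose covariances are the inverses of the constructed precision
#' matrices, attaches the group labels, and returns a [grouped_dataset()].
#' Fully reproducible from `spec$seed` (pass `seed` to override).
#'
#' @param spec A [simulation_spec()].
#' @param seed Optional integer overriding `spec$seed`.
#' @return A [grouped_dataset()] with attribute `"sim_spec"` set to `spec`.
#' @export
sample_dataset <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  seed <- if (is.null(seed)) spec$seed else as.integer(seed)
  prec_a <- build_precision(spec, "A")
  prec_b <- build_precision(spec, "B")
  sigma_a <- chol2inv(chol(prec_a$omega))
  sigma_b <- chol2inv(chol(prec_b$omega))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  xa <- MASS::mvrnorm(spec$n_A, mu = rep(0, spec$M), Sigma = sigma_a)
  xb <- MASS::mvrnorm(spec$n_B, mu = rep(0, spec$M), Sigma = sigma_b)
  values <- rbind(xa, xb)
  colnames(values) <- spec$variable_names
  ds <- grouped_dataset(
    values,
    factor(rep(spec$group_labels, c(spec$n_A, spec$n_B)),
           levels = spec$group_labels)
  )
  attr(ds, "sim_spec") <- spec
  ds
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("Simulation spec: M =", x$M, "variables in", length(x$block_sizes),
      "blocks\n")
  cat("  within-block pcor:", x$within_block_pcor,
      " cross-block links:", NROW(x$cross_block_edges), "\n")
  cat("  differential pairs:", NROW(x$differential_edges),
      " group sizes:", x$n_A, "/", x$n_B, " seed:", x$seed, "\n")
  invisible(x)
}
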