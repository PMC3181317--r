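#' Per-variable two-group Mann-Whitney screen
#'
#' Runs the non-parametric two-sample Mann-Whitney (Wilcoxon rank-sum) test
#' on every variable, two-sided, and flags significance both at the
#' Bonferroni-corrected threshold alpha / M and at the uncorrected alpha.
#' Exact-distribution p-values are used when the smaller group has at most
#' 8 samples and the pooled values carry no ties; otherwise the normal
#' approximation with tie and continuity correction is applied. A variable
#' that is constant across both groups gets p = 1 and a warning flag.
#'
#' @param data A [grouped_dataset()].
#' @param alpha Family-wise significance level (default 0.05).
#' @return Data frame with one row per variable: `variable`, `statistic`
#'   (the Mann-Whitney U of the first group), `p_value`,
#'   `significant_bonferroni`, `significant_uncorrected`, `flag`
#'   (`"constant"` for degenerate variables, otherwise `""`). The
#'   Bonferroni threshold alpha / M is attached as attribute
#'   `"bonferroni_threshold"`.
#' @export
mann_whitney_screen <- function(data, alpha = 0.05) {
  stopifnot(inherits(data, "grouped_dataset"))
  groups <- levels(data$group_labels)
  xa <- group_values(data, groups[1L])
  xb <- group_values(data, groups[2L])
  m <- length(data$variable_names)
  thr <- bonferroni_threshold(alpha, m)
  res <- lapply(seq_len(m), function(j) {
    a <- xa[, j]
    b <- xb[, j]
    pooled <- c(a, b)
    if (length(unique(pooled)) == 1L) {
      return(data.frame(statistic = length(a) * length(b) / 2, p_value = 1,
                        flag = "constant", stringsAsFactors = FALSE))
    }
    exact <- min(length(a), length(b)) <= 8 && !anyDuplicated(pooled)
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                         correct = TRUE)
    )
    data.frame(statistic = unname(wt$statistic), p_value = wt$p.value,
               flag = "", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    variable = data$variable_names,
    statistic = res$statistic,
    p_value = res$p_value,
    significant_bonferroni = res$p_value <= thr,
    significant_uncorrected = res$p_value <= alpha,
    flag = res$flag,
    stringsAsFactors = FALSE
  )
  if (any(out$flag == "constant")) {
    warning("constant variable(s): ",
            paste(out$variable[out$flag == "constant"], collapse = ", "),
            call. = FALSE)
  }
  attr(out, "bonferroni_threshold") <- thr
  attr(out, "alpha") <- alpha
  out
}
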