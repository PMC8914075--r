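#' Uniform container for test statistics
#'
#' All inference operations in the package (paired t, rank correlation,
#' repeated-measures ANOVA effects) return this light-weight structure.
#'
#' @param statistic Test statistic value.
#' @param df Degrees of freedom; a scalar or a numerator/denominator pair.
#' @param p Two-sided p value in `[0, 1]` (may be `NA` for degenerate input).
#' @param effect Named list of descriptive summaries (means, SDs, n, ...).
#' @param method Human-readable description of the test.
#' @return An object of class `stat_result`.
#' @export
stat_result <- function(statistic, df, p, effect = list(), method = "") {
  if (is.finite(p) && (p < 0 || p > 1)) stop("p must lie in [0, 1]")
  structure(list(statistic = statistic, df = df, p = p,
                 effect = effect, method = method),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = (%s), p = %.4g\n",
              if (nzchar(x$method)) x$method else "stat_result",
              x$statistic, dfs, x$p))
  if (length(x$effect)) {
    for (nm in names(x$effect)) {
      v <- x$effect[[nm]]
      if (is.numeric(v) && length(v) <= 4)
        cat(sprintf("  %s: %s\n", nm, paste(format(v, digits = 4), collapse = " ")))
    }
  }
  invisible(x)
}
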