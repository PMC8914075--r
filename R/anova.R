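# Repeated-measures ANOVA on within-subject cell means via orthonormal
# contrasts: for each effect, subjects' cell means are projected onto the
# effect's contrast space; the univariate F compares the mean projection
# against its within-subject scatter. This is the summary-statistics
# approach to group inference (per-subject contrast images in, subject as
# the random factor).

# Orthonormalised Helmert contrasts for a factor with k levels (k x (k-1)).
orthonormal_contrasts <- function(k) {
  H <- stats::contr.helmert(k)
  sweep(H, 2, sqrt(colSums(H^2)), "/")
}

#' Within-subject (repeated-measures) ANOVA
#'
#' Fully within-subject factorial ANOVA on per-subject cell means. Each
#' main effect and interaction gets its own error term (the
#' subject-by-effect scatter); sphericity is uncorrected by default, with
#' a Greenhouse-Geisser option.
#'
#' @param data Long data frame with a subject column, one column per
#'   factor, and a value column. Subjects with incomplete cells are
#'   excluded (reported in each result's `effect$n_excluded`).
#' @param dv Name of the value column (default `"value"`).
#' @param subject Name of the subject column (default `"subject"`).
#' @param factors Character vector of within-subject factor column names.
#' @param gg Apply the Greenhouse-Geisser sphericity correction.
#' @return Named list of [stat_result()]s, one per main effect and
#'   interaction (names like `"condition"`, `"condition:roi"`).
#' @export
rm_anova <- function(data, factors, dv = "value", subject = "subject",
                     gg = FALSE) {
  stopifnot(all(c(factors, dv, subject) %in% names(data)))
  for (f in factors) data[[f]] <- factor(data[[f]])
  levs <- lapply(data[factors], levels)
  cells <- expand.grid(levs, KEEP.OUT.ATTRS = FALSE)  # first factor fastest
  cell_key <- interaction(cells, drop = FALSE, lex.order = FALSE)
  data_key <- interaction(data[factors], drop = FALSE, lex.order = FALSE)

  subjects <- unique(data[[subject]])
  Y <- matrix(NA_real_, length(subjects), nrow(cells))
  for (i in seq_along(subjects)) {
    rows <- data[[subject]] == subjects[i]
    agg <- tapply(data[[dv]][rows], data_key[rows], mean)
    Y[i, ] <- as.numeric(agg[as.character(cell_key)])
  }
  complete <- stats::complete.cases(Y)
  n_excluded <- sum(!complete)
  Y <- Y[complete, , drop = FALSE]
  n <- nrow(Y)
  if (n < 2L) stop("need at least 2 subjects with complete cells")

  effects <- unlist(lapply(seq_along(factors), function(k)
    utils::combn(factors, k, simplify = FALSE)), recursive = FALSE)
  out <- list()
  for (eff in effects) {
    # Kronecker over factors in expand.grid order (first factor varies
    # fastest => it is the rightmost kronecker term).
    M <- matrix(1, 1, 1)
    for (f in factors) {
      k <- length(levs[[f]])
      Mf <- if (f %in% eff) orthonormal_contrasts(k)
            else matrix(1 / sqrt(k), k, 1)
      M <- Mf %x% M
    }
    Z <- Y %*% M
    zbar <- colMeans(Z)
    k_eff <- ncol(Z)
    ss_eff <- n * sum(zbar^2)
    ss_err <- sum(sweep(Z, 2, zbar)^2)
    df1 <- k_eff
    df2 <- k_eff * (n - 1L)
    eps <- 1
    if (gg && k_eff > 1L) {
      S <- stats::cov(Z)
      eps <- sum(diag(S))^2 / (k_eff * sum(S^2))
      eps <- min(1, max(eps, 1 / k_eff))
    }
    Fv <- if (ss_err > 0) (ss_eff / df1) / (ss_err / df2) else
      ifelse(ss_eff > 0, Inf, 0)
    p <- if (is.finite(Fv)) stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
         else as.numeric(Fv == 0)
    out[[paste(eff, collapse = ":")]] <-
      stat_result(statistic = Fv, df = c(df1 * eps, df2 * eps), p = p,
                  effect = list(ss_effect = ss_eff, ss_error = ss_err,
                                n_subjects = n, n_excluded = n_excluded,
                                gg_epsilon = eps),
                  method = paste0("rm-ANOVA ", paste(eff, collapse = " x ")))
  }
  out
}

#' 2x2 repeated-measures interaction: DW position x condition
#'
#' Within-subject interaction between degraded-pseudoword position (DW1,
#' DW2) and clear-pseudoword condition (match, mismatch). With one degree
#' of freedom the interaction F equals the squared paired t on each
#' subject's difference-of-differences
#' `(DW2_match - DW1_match) - (DW2_mismatch - DW1_mismatch)`.
#'
#' @param data Long data frame with columns `subject`, `position` (levels
#'   dw1/dw2), `condition` (match/mismatch) and `value`.
#' @return A [stat_result()] with `df = (1, n - 1)`; `effect` carries the
#'   four cell means and the mean interaction contrast.
#' @export
rm_anova_2x2 <- function(data) {
  stopifnot(all(c("subject", "position", "condition", "value") %in% names(data)))
  cell <- function(s, pos, cond)
    mean(data$value[data$subject == s & data$position == pos &
                    data$condition == cond])
  subjects <- unique(data$subject)
  d <- vapply(subjects, function(s)
    (cell(s, "dw2", "match") - cell(s, "dw1", "match")) -
    (cell(s, "dw2", "mismatch") - cell(s, "dw1", "mismatch")), numeric(1))
  keep <- is.finite(d)
  d <- d[keep]
  n <- length(d)
  if (n < 2L) stop("need at least 2 subjects with complete cells")
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    Fv <- if (mean(d) == 0) 0 else Inf
    p <- as.numeric(Fv == 0)
  } else {
    tv <- mean(d) / (sd_d / sqrt(n))
    Fv <- tv^2
    p <- stats::pf(Fv, 1, n - 1L, lower.tail = FALSE)
  }
  means <- c(dw1_match = mean(data$value[data$position == "dw1" &
                                         data$condition == "match"]),
             dw2_match = mean(data$value[data$position == "dw2" &
                                         data$condition == "match"]),
             dw1_mismatch = mean(data$value[data$position == "dw1" &
                                            data$condition == "mismatch"]),
             dw2_mismatch = mean(data$value[data$position == "dw2" &
                                            data$condition == "mismatch"]))
  stat_result(statistic = Fv, df = c(1, n - 1L), p = p,
              effect = list(cell_means = means, mean_interaction = mean(d),
                            n_subjects = n, n_excluded = sum(!keep)),
              method = "rm-ANOVA position x condition interaction")
}

#' 2x3x2 repeated-measures ANOVA over PAC ROI betas
#'
#' Factorial within-subject ANOVA with factors condition (match,
#' mismatch), ROI (Te1.0, Te1.1, Te1.2) and hemisphere (left, right), on
#' per-subject mean betas averaged over DW position.
#'
#' @param table An ROI beta table (see [roi_mean_betas()]) or any long data
#'   frame with columns `subject`, `condition`, `roi`, `hemisphere` and a
#'   value column.
#' @param dv Value column name (default `"mean_beta"`).
#' @param gg Greenhouse-Geisser correction flag, passed to [rm_anova()].
#' @return Named list of [stat_result()]s for the three main effects and
#'   all interactions.
#' @export
rm_anova_2x3x2 <- function(table, dv = "mean_beta", gg = FALSE) {
  rm_anova(table, factors = c("condition", "roi", "hemisphere"), dv = dv,
           gg = gg)
}
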