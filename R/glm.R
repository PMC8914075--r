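#' Fit the voxelwise GLM
#'
#' Ordinary least squares of every voxel time course on the design matrix.
#' Rank-deficient designs are handled by the Moore-Penrose pseudo-inverse
#' with a warning; the residual degrees of freedom are
#' `scans - rank(design)`.
#'
#' @param bold A `bold_dataset`, or a plain scans-by-voxels matrix.
#' @param design A [build_design()] matrix (rows must match scan count).
#' @return A `glm_fit`: list with `betas` (regressors x voxels), `sigma2`
#'   (residual variance per voxel), `df_residual`, `rank`, `cov_unscaled`
#'   (`(X'X)^-` matrix), `design`, and `event_cols`.
#' @export
fit_glm <- function(bold, design) {
  Y <- if (inherits(bold, "bold_dataset")) bold$data else as.matrix(bold)
  X <- unclass(design)
  if (nrow(Y) != nrow(X)) stop("design rows must match scan count")
  qr_x <- qr(X)
  rank <- qr_x$rank
  p <- ncol(X)
  if (rank < p) {
    warning("rank-deficient design (rank ", rank, " < ", p,
            "); using pseudo-inverse")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    pinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    betas <- pinv %*% Y
    cov_unscaled <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$v[, pos, drop = FALSE]) / sv$d[pos]^2)
  } else {
    cov_unscaled <- chol2inv(chol(crossprod(X)))
    betas <- cov_unscaled %*% crossprod(X, Y)
  }
  rownames(betas) <- colnames(X)
  dimnames(cov_unscaled) <- list(colnames(X), colnames(X))
  res <- Y - X %*% betas
  df <- nrow(Y) - rank
  sigma2 <- colSums(res^2) / df
  structure(list(betas = betas, sigma2 = sigma2, df_residual = df,
                 rank = rank, cov_unscaled = cov_unscaled, design = X,
                 event_cols = attr(design, "event_cols")),
            class = "glm_fit")
}

#' Statistic map container
#'
#' @param stat Per-voxel statistic.
#' @param p Per-voxel p values.
#' @param df Degrees of freedom (scalar for t, pair for F).
#' @param type `"t"` or `"F"`.
#' @param dim Optional spatial dimensions of the voxel grid.
#' @return A `stat_map` list.
#' @export
stat_map <- function(stat, p, df, type = "F", dim = NULL) {
  stopifnot(length(stat) == length(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  structure(list(stat = stat, p = p, df = df, type = type, dim = dim),
            class = "stat_map")
}

# Resolve a contrast given as a weight matrix/vector or regressor names.
resolve_contrast <- function(fit, contrast) {
  p <- nrow(fit$betas)
  if (is.character(contrast)) {
    idx <- match(contrast, rownames(fit$betas))
    if (anyNA(idx)) stop("unknown regressor: ",
                         paste(contrast[is.na(idx)], collapse = ", "))
    C <- matrix(0, length(idx), p)
    C[cbind(seq_along(idx), idx)] <- 1
  } else {
    C <- rbind(contrast)
    if (ncol(C) != p) stop("contrast has ", ncol(C), " columns; design has ", p)
  }
  if (any(rowSums(abs(C)) == 0)) stop("contrast contains an all-zero row")
  C
}

#' Voxelwise F contrast
#'
#' Extra-sum-of-squares F test of `C beta = 0` with numerator df equal to
#' the number of contrast rows and denominator df the residual df.
#'
#' @param fit A [fit_glm()] result.
#' @param contrast Weight matrix (rows = constraints, columns = regressors)
#'   or a character vector of regressor names (tests them jointly against 0).
#' @param dim Optional spatial dimensions to attach to the map.
#' @return A `stat_map` of type `"F"`.
#' @export
f_contrast <- function(fit, contrast, dim = NULL) {
  stopifnot(inherits(fit, "glm_fit"))
  C <- resolve_contrast(fit, contrast)
  q <- nrow(C)
  CB <- C %*% fit$betas
  M <- C %*% fit$cov_unscaled %*% t(C)
  Mi <- solve(M)
  quad <- colSums(CB * (Mi %*% CB))
  Fstat <- quad / (q * fit$sigma2)
  stat_map(Fstat, stats::pf(Fstat, q, fit$df_residual, lower.tail = FALSE),
           df = c(q, fit$df_residual), type = "F", dim = dim)
}

#' Voxelwise t contrast
#'
#' @param fit A [fit_glm()] result.
#' @param contrast Numeric weight vector over regressors, or a single
#'   regressor name.
#' @param dim Optional spatial dimensions.
#' @return A `stat_map` of type `"t"` (two-sided p).
#' @export
t_contrast <- function(fit, contrast, dim = NULL) {
  stopifnot(inherits(fit, "glm_fit"))
  C <- resolve_contrast(fit, contrast)
  if (nrow(C) != 1L) stop("t contrast must be a single row")
  cb <- drop(C %*% fit$betas)
  se <- sqrt(drop(C %*% fit$cov_unscaled %*% t(C)) * fit$sigma2)
  tstat <- cb / se
  stat_map(tstat, 2 * stats::pt(abs(tstat), fit$df_residual, lower.tail = FALSE),
           df = fit$df_residual, type = "t", dim = dim)
}

#' Conjunction-null analysis over statistic maps
#'
#' Minimum-statistic conjunction: a voxel passes only if every contributing
#' map is individually significant at `alpha`, i.e. the conjunction p value
#' is the voxelwise maximum of the component p values.
#'
#' @param maps List of `stat_map`s sharing geometry.
#' @param alpha Component significance level (default 0.05).
#' @return A `stat_map` carrying the minimum statistic and maximum p, with
#'   attribute `pass`: logical vector of jointly significant voxels.
#' @export
conjunction_null <- function(maps, alpha = 0.05) {
  stopifnot(length(maps) >= 1L, all(vapply(maps, inherits, TRUE, "stat_map")))
  n <- length(maps[[1]]$stat)
  if (!all(vapply(maps, function(m) length(m$stat) == n, TRUE)))
    stop("maps do not share geometry")
  stat_min <- do.call(pmin, lapply(maps, `[[`, "stat"))
  p_max <- do.call(pmax, lapply(maps, `[[`, "p"))
  out <- stat_map(stat_min, p_max, df = maps[[1]]$df, type = maps[[1]]$type,
                  dim = maps[[1]]$dim)
  attr(out, "pass") <- p_max < alpha
  out
}
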