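# ROI beta extraction with effects-of-interest voxel selection, BH FDR
# correction, and FDR-corrected post-hoc paired t-tests.

#' Benjamini-Hochberg FDR correction
#'
#' Step-up rejections at level `q`.
#'
#' @param pvals Numeric p values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `reject` (logical), `p_adjusted` (BH-adjusted p) and
#'   `q`.
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  adj <- stats::p.adjust(pvals, method = "BH")
  list(reject = !is.na(adj) & adj <= q, p_adjusted = adj, q = q)
}

# Split "Te1.0_L" style labels into roi and hemisphere parts.
split_roi_label <- function(labels) {
  parts <- strsplit(labels, "_", fixed = TRUE)
  data.frame(roi = vapply(parts, function(p) paste(p[-length(p)], collapse = "_"),
                          character(1)),
             hemisphere = vapply(parts, function(p) p[length(p)], character(1)),
             stringsAsFactors = FALSE)
}

#' Extract per-ROI mean betas with effects-of-interest selection
#'
#' For each subject, voxels within each ROI are kept if the
#' effects-of-interest F contrast (all event regressors jointly against
#' baseline) is significant at `selection_p` (uncorrected) - keeping
#' condition-unbiased voxels that show any task modulation - and the betas
#' of the DW1/DW2 match/mismatch regressors are averaged over the kept
#' voxels.
#'
#' @param fits List of [fit_glm()] results, one per subject (voxel columns
#'   aligned with `atlas`).
#' @param atlas A [make_roi_atlas()] label array (or per-voxel label vector).
#' @param selection_p Voxel-selection threshold on the F-contrast p value
#'   (default 0.001; `1` keeps every ROI voxel).
#' @param positions Named list mapping DW positions to regressor names per
#'   condition.
#' @return An `roi_beta_table` data frame: `subject`, `roi`, `hemisphere`,
#'   `condition`, `position`, `mean_beta`, `sd_beta`, `n_voxels`; empty
#'   selections yield `NA` means.
#' @export
roi_mean_betas <- function(fits, atlas, selection_p = 0.001,
                           positions = list(
                             dw1 = c(match = "dw1_match", mismatch = "dw1_mismatch"),
                             dw2 = c(match = "dw2_match", mismatch = "dw2_mismatch"))) {
  labels <- as.vector(atlas)
  rois <- sort(setdiff(unique(labels), ""))
  if (!length(rois)) stop("atlas contains no labeled ROI voxels")
  rows <- list()
  for (s in seq_along(fits)) {
    fit <- fits[[s]]
    if (ncol(fit$betas) != length(labels))
      stop("fit voxel count does not match atlas")
    sel_map <- f_contrast(fit, fit$event_cols)
    keep <- sel_map$p < selection_p
    for (rl in rois) {
      voxels <- which(labels == rl & keep)
      hemi <- split_roi_label(rl)
      for (pos in names(positions)) {
        for (cond in names(positions[[pos]])) {
          reg <- positions[[pos]][[cond]]
          b <- if (length(voxels)) fit$betas[reg, voxels] else numeric(0)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = s, roi = hemi$roi, hemisphere = hemi$hemisphere,
            condition = cond, position = pos,
            mean_beta = if (length(b)) mean(b) else NA_real_,
            sd_beta = if (length(b) > 1) stats::sd(b) else NA_real_,
            n_voxels = length(b), stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(do.call(rbind, rows), class = c("roi_beta_table", "data.frame"))
}

#' Average an ROI beta table over DW position
#'
#' Produces the per-subject condition x ROI x hemisphere cell means used by
#' the factorial rm-ANOVA and the post-hoc tests.
#'
#' @param table An `roi_beta_table` from [roi_mean_betas()].
#' @return Data frame `subject`, `roi`, `hemisphere`, `condition`,
#'   `mean_beta`.
#' @export
average_positions <- function(table) {
  agg <- stats::aggregate(mean_beta ~ subject + roi + hemisphere + condition,
                          data = table, FUN = mean, na.action = stats::na.pass)
  agg[order(agg$subject, agg$roi, agg$hemisphere, agg$condition), ,
      drop = FALSE]
}

#' FDR-corrected post-hoc paired t-tests per ROI
#'
#' For every ROI x hemisphere cell, a paired t-test of match versus
#' mismatch mean betas (averaged over DW position) across subjects, with
#' Benjamini-Hochberg correction over the set of ROIs.
#'
#' @param table An `roi_beta_table` (position-resolved; averaged internally)
#'   or an already position-averaged table.
#' @param q FDR level (default 0.05).
#' @return Data frame with one row per ROI x hemisphere: `roi`,
#'   `hemisphere`, `t`, `df`, `p`, `p_adjusted`, `reject`,
#'   `mean_match`, `mean_mismatch`.
#' @export
posthoc_paired_t <- function(table, q = 0.05) {
  tab <- if ("position" %in% names(table)) average_positions(table) else table
  cells <- unique(tab[, c("roi", "hemisphere")])
  cells <- cells[order(cells$roi, cells$hemisphere), , drop = FALSE]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- tab[tab$roi == cells$roi[i] & tab$hemisphere == cells$hemisphere[i], ]
    wide <- merge(sub[sub$condition == "match", c("subject", "mean_beta")],
                  sub[sub$condition == "mismatch", c("subject", "mean_beta")],
                  by = "subject", suffixes = c("_match", "_mismatch"))
    wide <- wide[stats::complete.cases(wide), ]
    if (nrow(wide) < 2L)
      stop("post-hoc paired t needs at least 2 subjects per ROI")
    st <- paired_t(wide$mean_beta_match, wide$mean_beta_mismatch)
    data.frame(roi = cells$roi[i], hemisphere = cells$hemisphere[i],
               t = st$statistic, df = st$df, p = st$p,
               mean_match = mean(wide$mean_beta_match),
               mean_mismatch = mean(wide$mean_beta_mismatch),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  fdr <- fdr_correct(out$p, q)
  out$p_adjusted <- fdr$p_adjusted
  out$reject <- fdr$reject
  out
}
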