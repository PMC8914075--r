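#' Simulate a multi-subject BOLD study and extract ROI betas
#'
#' End-to-end synthetic replication harness: for each subject a seeded
#' trial schedule is generated, a BOLD session simulated from the given
#' effect map, the voxelwise GLM fitted (with the subject's motion-like
#' nuisance series and drift basis), and the PAC ROI beta table extracted
#' with effects-of-interest voxel selection.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param atlas ROI atlas (default [make_roi_atlas()]).
#' @param effects Effect map (default [default_effect_map()]; pass
#'   `dw2_match_boost = 0` upstream for a null study).
#' @param noise_sd,ar_coef Noise parameters for [simulate_bold()].
#' @param schedule_args List of overrides for [generate_schedule()].
#' @param selection_p Voxel-selection threshold for [roi_mean_betas()].
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return List with `roi_table` (position-resolved beta table), `fits`
#'   (per-subject `glm_fit`s), `schedules`, `atlas`, `effects`.
#' @export
simulate_glm_study <- function(n_subjects = 20L, atlas = make_roi_atlas(),
                               effects = default_effect_map(atlas),
                               noise_sd = 1, ar_coef = 0.3,
                               schedule_args = list(), selection_p = 0.001,
                               seed = 1L) {
  fits <- vector("list", n_subjects)
  schedules <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sub_seed <- (as.integer(seed) * 1000L + s) %% .Machine$integer.max
    schedules[[s]] <- do.call(generate_schedule,
                              c(schedule_args, list(seed = sub_seed)))
    bold <- simulate_bold(schedules[[s]], atlas = atlas, effects = effects,
                          noise_sd = noise_sd, ar_coef = ar_coef,
                          seed = sub_seed + 1L)
    X <- build_design(schedules[[s]], nuisance = bold$nuisance)
    fits[[s]] <- fit_glm(bold, X)
  }
  roi_table <- roi_mean_betas(fits, atlas, selection_p = selection_p)
  list(roi_table = roi_table, fits = fits, schedules = schedules,
       atlas = atlas, effects = effects)
}

#' Run the group-level ROI analysis chain
#'
#' From a position-resolved ROI beta table: the 2x2 position-by-condition
#' interaction rm-ANOVA (on betas averaged over ROIs), the 2x3x2
#' condition x ROI x hemisphere rm-ANOVA (on betas averaged over DW
#' position), and the FDR-corrected post-hoc paired t-tests per ROI.
#'
#' @param roi_table An `roi_beta_table` from [roi_mean_betas()].
#' @param q FDR level for the post-hoc tests.
#' @param gg Greenhouse-Geisser flag for the factorial ANOVA.
#' @return List with `interaction_2x2` ([stat_result()]), `anova_2x3x2`
#'   (list of [stat_result()]s) and `posthoc` (data frame).
#' @export
analyze_roi_study <- function(roi_table, q = 0.05, gg = FALSE) {
  pos_tab <- stats::aggregate(mean_beta ~ subject + position + condition,
                              data = roi_table, FUN = mean)
  names(pos_tab)[names(pos_tab) == "mean_beta"] <- "value"
  list(interaction_2x2 = rm_anova_2x2(pos_tab),
       anova_2x3x2 = rm_anova_2x3x2(average_positions(roi_table), gg = gg),
       posthoc = posthoc_paired_t(roi_table, q = q))
}
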