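#' Build a synthetic ROI atlas on a small lattice
#'
#' Places the six primary-auditory-cortex subregion ROIs (Te1.0, Te1.1,
#' Te1.2 in each hemisphere) as disjoint voxel blocks on a 3D lattice;
#' remaining voxels are unlabeled background. The geometry is abstract
#' (no anatomical registration): left-hemisphere ROIs sit in the low-x
#' half, right-hemisphere ROIs in the high-x half.
#'
#' @param dim Lattice dimensions (default `c(20, 20, 12)`).
#' @param roi_size Block size per ROI (default `c(3, 3, 2)`).
#' @return A `roi_atlas`: character 3D array of labels (`""` = background)
#'   with attribute `roi_names`.
#' @export
make_roi_atlas <- function(dim = c(20, 20, 12), roi_size = c(3, 3, 2)) {
  stopifnot(length(dim) == 3, length(roi_size) == 3, all(roi_size <= dim))
  labels <- array("", dim = dim)
  rois <- c("Te1.0", "Te1.1", "Te1.2")
  y_starts <- round(seq(1, dim[2] - roi_size[2] + 1, length.out = 3))
  z0 <- max(1L, (dim[3] - roi_size[3]) %/% 2L)
  for (h in c("L", "R")) {
    x0 <- if (h == "L") 1L else dim[1] - roi_size[1] + 1L
    for (k in seq_along(rois)) {
      labels[x0:(x0 + roi_size[1] - 1L),
             y_starts[k]:(y_starts[k] + roi_size[2] - 1L),
             z0:(z0 + roi_size[3] - 1L)] <- paste0(rois[k], "_", h)
    }
  }
  structure(labels, class = "roi_atlas",
            roi_names = paste0(rep(rois, 2), "_", rep(c("L", "R"), each = 3)))
}

#' Condition-dependent BOLD amplitudes per ROI
#'
#' Ground-truth event amplitudes for the simulator: every labeled ROI
#' responds to all pseudoword events with `base_amp`, the DW2 response in
#' the match condition is raised by `dw2_match_boost`, and DW1 amplitudes
#' are equal across conditions by construction (the trial type is unknown
#' at DW1 time). The defaults reproduce ROI condition means near 2.27
#' (match) and 1.58 (mismatch) when betas are averaged over DW1 and DW2.
#' Background voxels have zero amplitude.
#'
#' @param atlas A [make_roi_atlas()] result (or character vector of ROI names).
#' @param base_amp Stimulus-event amplitude in all ROIs.
#' @param dw2_match_boost Added amplitude for DW2 on match trials.
#' @param resp_amp Amplitude of the verbal-response regressors.
#' @return An `effect_map`: numeric matrix ROIs x event types.
#' @export
default_effect_map <- function(atlas, base_amp = 1.58, dw2_match_boost = 1.38,
                               resp_amp = 0.5) {
  rois <- if (is.character(atlas) && is.null(dim(atlas))) atlas
          else attr(atlas, "roi_names")
  A <- matrix(base_amp, length(rois), length(EVENT_TYPES),
              dimnames = list(rois, EVENT_TYPES))
  A[, "dw2_match"] <- base_amp + dw2_match_boost
  A[, c("resp_match", "resp_mismatch")] <- resp_amp
  stopifnot(all(A[, "dw1_match"] == A[, "dw1_mismatch"]))
  structure(A, class = "effect_map")
}

#' Simulate a preprocessed BOLD session
#'
#' Voxel time series are the HRF-convolved event regressors weighted by the
#' voxel ROI's amplitudes, plus low-frequency drift, plus AR(1) Gaussian
#' noise; six motion-like nuisance series (scaled random walks) are
#' generated alongside. Deterministic for a given seed.
#'
#' @param schedule An [generate_schedule()] result.
#' @param atlas A [make_roi_atlas()] label array.
#' @param effects An [default_effect_map()] matrix (ROIs x event types).
#' @param noise_sd Innovation SD of the AR(1) noise.
#' @param ar_coef AR(1) coefficient in `[0, 1)`.
#' @param drift_sd SD of random DCT drift coefficients (0 = no drift).
#' @param seed Integer seed.
#' @return A `bold_dataset`: list with `data` (scans x voxels matrix),
#'   `atlas`, `labels` (per-voxel ROI label vector), `nuisance`
#'   (scans x 6), `tr`, `n_scans`, `dim`, and the noise parameters.
#' @export
simulate_bold <- function(schedule, atlas = make_roi_atlas(),
                          effects = default_effect_map(atlas),
                          noise_sd = 1, ar_coef = 0.3, drift_sd = 0,
                          seed = 1L) {
  stopifnot(inherits(schedule, "event_schedule"))
  labels <- as.vector(atlas)
  rois <- rownames(effects)
  if (!all(setdiff(unique(labels), "") %in% rois))
    stop("atlas contains ROI labels missing from the effect map")
  tr <- attr(schedule, "tr")
  n_scans <- attr(schedule, "n_scans")
  scan_times <- (seq_len(n_scans) - 1L) * tr
  Xe <- event_regressors(schedule, scan_times)
  A <- matrix(0, ncol(Xe), length(labels))       # event type x voxel amplitude
  in_roi <- labels != ""
  A[, in_roi] <- t(effects[labels[in_roi], colnames(Xe), drop = FALSE])
  set.seed(as.integer(seed))
  Y <- Xe %*% A
  if (drift_sd > 0) {
    B <- dct_basis(n_scans, tr)
    if (ncol(B) > 0)
      Y <- Y + B %*% matrix(stats::rnorm(ncol(B) * ncol(Y), 0, drift_sd), ncol(B))
  }
  if (noise_sd > 0) {
    eps <- matrix(stats::rnorm(n_scans * ncol(Y), 0, noise_sd), n_scans)
    if (ar_coef != 0)
      eps <- apply(eps, 2, function(e)
        as.numeric(stats::filter(e, ar_coef, method = "recursive")))
    Y <- Y + eps
  }
  nuis <- apply(matrix(stats::rnorm(n_scans * 6L, 0, 0.05), n_scans), 2, cumsum)
  colnames(nuis) <- paste0("motion", 1:6)
  structure(list(data = Y, atlas = atlas, labels = labels, nuisance = nuis,
                 tr = tr, n_scans = n_scans, dim = dim(atlas),
                 noise_sd = noise_sd, ar_coef = ar_coef, seed = seed),
            class = "bold_dataset")
}

#' Generate spatially smooth Gaussian noise fields
#'
#' Samples stationary Gaussian random fields with an isotropic Gaussian
#' autocorrelation, emulating the spatial smoothness of preprocessed BOLD
#' contrast maps. White noise is filtered in the frequency domain with a
#' Gaussian transfer function and rescaled to unit marginal variance.
#'
#' @param n Number of fields (e.g. subjects).
#' @param dim Field dimensions (length 3).
#' @param fwhm Smoothness as full-width-at-half-maximum in voxels; the
#'   default matches an 8 mm kernel on 3 mm voxels.
#' @param seed Integer seed.
#' @return An `n x prod(dim)` matrix; each row is one vectorised field.
#' @export
smooth_noise_fields <- function(n, dim, fwhm = 8 / 3, seed = 1L) {
  stopifnot(length(dim) == 3, fwhm > 0, n >= 1)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  H <- 1
  for (k in 1:3) {
    f <- fft_axis(dim[k], 1)                      # cycles per voxel
    hk <- exp(-2 * pi^2 * sigma^2 * f^2)
    shape <- c(1, 1, 1); shape[k] <- dim[k]
    H <- H * array(rep(hk, each = prod(dim[seq_len(k - 1)])), dim)
  }
  set.seed(as.integer(seed))
  out <- matrix(0, n, prod(dim))
  for (i in seq_len(n)) {
    w <- array(stats::rnorm(prod(dim)), dim)
    sm <- Re(stats::fft(stats::fft(w) * H, inverse = TRUE)) / prod(dim)
    out[i, ] <- as.vector(sm)
  }
  out / sqrt(mean(apply(out, 2, stats::var)))
}

#' Write a BOLD dataset as a 4D NIfTI volume
#'
#' Requires the `RNifti` package.
#'
#' @param bold A `bold_dataset`.
#' @param path Output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(bold, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required to write NIfTI volumes")
  vol <- array(t(bold$data), dim = c(bold$dim, bold$n_scans))
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(3, 3, 3, bold$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI volume into a scans-by-voxels matrix
#'
#' @param path NIfTI file path.
#' @return A `bold_dataset` without atlas labels (all background).
#' @export
read_bold_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required to read NIfTI volumes")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  stopifnot(length(d) == 4)
  Y <- t(matrix(img, prod(d[1:3]), d[4]))
  tr <- RNifti::pixdim(img)[4]
  structure(list(data = Y, atlas = NULL, labels = rep("", prod(d[1:3])),
                 nuisance = NULL, tr = tr, n_scans = d[4], dim = d[1:3],
                 noise_sd = NA, ar_coef = NA, seed = NA),
            class = "bold_dataset")
}
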