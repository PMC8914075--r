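# Connected-component labeling and permutation (sign-flip) cluster-extent
# family-wise error correction for group statistic maps.

# Label connected suprathreshold components of a logical 3D array.
# connectivity: 6 (faces), 18 (faces+edges) or 26 (all neighbours).
label_clusters <- function(mask, connectivity = 26) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  dist <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[dist == 1, , drop = FALSE],
                 "18" = offs[dist >= 1 & rowSums(offs != 0) <= 2, , drop = FALSE],
                 "26" = offs[dist >= 1, , drop = FALSE],
                 stop("connectivity must be 6, 18 or 26"))
  labels <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(structure(labels, sizes = integer(0)))
  coords <- arrayInd(idx, d)
  lin <- function(co) co[, 1] + d[1] * (co[, 2] - 1L) + d[1] * d[2] * (co[, 3] - 1L)
  cur <- 0L
  sizes <- integer(0)
  for (v in seq_along(idx)) {
    if (labels[idx[v]] != 0L) next
    cur <- cur + 1L
    queue <- idx[v]
    labels[idx[v]] <- cur
    size <- 1L
    while (length(queue)) {
      co <- arrayInd(queue, d)
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
        cbind(co[, 1] + offs[k, 1], co[, 2] + offs[k, 2], co[, 3] + offs[k, 3])))
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nbl <- unique(lin(nb[ok, , drop = FALSE]))
      nbl <- nbl[mask[nbl] & labels[nbl] == 0L]
      labels[nbl] <- cur
      size <- size + length(nbl)
      queue <- nbl
    }
    sizes[cur] <- size
  }
  structure(labels, sizes = sizes)
}

# One-sample t statistics for columns of an n x V matrix, given precomputed
# column sums of squares (invariant under sign flips).
col_t <- function(signs, data, ss, n) {
  m <- drop(signs %*% data) / n
  v <- (ss - n * m^2) / (n - 1)
  m / sqrt(v / n)
}

#' Permutation cluster-extent correction
#'
#' Group-level cluster inference on per-subject contrast images via
#' sign-flipping: the observed one-sample t map is thresholded at the
#' two-sided `voxel_p` cluster-forming threshold, suprathreshold voxels are
#' grouped into connected clusters, and each cluster's extent is compared
#' with the permutation null distribution of the maximum cluster extent
#' obtained by randomly flipping subject signs. Exact under exchangeability
#' of subject contrast signs (symmetric null).
#'
#' @param data Subjects x voxels matrix of contrast values.
#' @param dim Spatial dimensions, `prod(dim) == ncol(data)`.
#' @param voxel_p Two-sided voxel-level cluster-forming p (default 0.001).
#' @param n_perm Number of sign-flip permutations (default 1000; fewer than
#'   100 triggers a warning).
#' @param seed Integer seed.
#' @param connectivity Neighbourhood for clustering: 6, 18 or 26 (default).
#' @param alpha Cluster-level FWE threshold used for the `significant` flag.
#' @return A data frame with one row per observed cluster (`cluster`,
#'   `size`, `peak_stat`, `p_fwe`, `significant`), with attributes `labels`
#'   (3D cluster-label array), `tmap`, `threshold` and `null_max_size`.
#' @export
cluster_correct <- function(data, dim, voxel_p = 0.001, n_perm = 1000L,
                            seed = 1L, connectivity = 26, alpha = 0.05) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (prod(dim) != ncol(data)) stop("prod(dim) must equal the voxel count")
  if (n < 2L) stop("need at least 2 subjects")
  if (n_perm < 100L) warning("fewer than 100 permutations: p values are coarse")
  ss <- colSums(data^2)
  thr <- stats::qt(1 - voxel_p / 2, df = n - 1)
  tmap <- col_t(rep(1, n), data, ss, n)
  obs_mask <- array(abs(tmap) > thr & is.finite(tmap), dim = dim)
  labels <- label_clusters(obs_mask, connectivity)
  sizes <- attr(labels, "sizes")

  set.seed(as.integer(seed))
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    tp <- col_t(s, data, ss, n)
    m <- array(abs(tp) > thr & is.finite(tp), dim = dim)
    null_max[b] <- if (any(m)) max(attr(label_clusters(m, connectivity), "sizes")) else 0
  }
  if (length(sizes)) {
    p_fwe <- vapply(sizes, function(k) (1 + sum(null_max >= k)) / (n_perm + 1),
                    numeric(1))
    peak <- vapply(seq_along(sizes), function(k) max(abs(tmap)[labels == k]),
                   numeric(1))
    out <- data.frame(cluster = seq_along(sizes), size = sizes,
                      peak_stat = peak, p_fwe = p_fwe,
                      significant = p_fwe < alpha)
  } else {
    out <- data.frame(cluster = integer(0), size = integer(0),
                      peak_stat = numeric(0), p_fwe = numeric(0),
                      significant = logical(0))
  }
  structure(out, labels = labels, tmap = tmap, threshold = thr,
            null_max_size = null_max)
}
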