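# design construction, voxelwise GLM, contrasts, conjunction, clusters,
# repeated-measures ANOVAs, ROI extraction, FDR.

test_that("design matrix columns follow the HRF and superpose linearly", {
  empty <- generate_schedule(n_match = 0, n_mismatch = 0, n_catch = 0, seed = 1)
  Xe <- build_design(empty, n_scans = 50, tr = 2)
  expect_length(attr(Xe, "event_cols"), 0)
  expect_true(all(colnames(Xe) %in% c(paste0("drift", 1:10), "intercept")))

  # single event at t = 0: column equals the HRF sampled at TR
  sch1 <- structure(
    data.frame(onset = 0, duration = 0.8, trial_type = "dw1_match",
               trial = 1L, condition = "match"),
    class = c("event_schedule", "data.frame"), tr = 2, n_scans = 40L)
  X1 <- build_design(sch1)
  expect_equal(unname(X1[, "dw1_match"]), canonical_hrf((0:39) * 2),
               tolerance = 1e-12)

  # two events 2 s apart: superposition of shifted HRFs
  sch2 <- structure(
    data.frame(onset = c(0, 2), duration = 0.8,
               trial_type = "dw1_match", trial = 1:2, condition = "match"),
    class = c("event_schedule", "data.frame"), tr = 2, n_scans = 40L)
  X2 <- build_design(sch2)
  expect_equal(unname(X2[, "dw1_match"]),
               canonical_hrf((0:39) * 2) + canonical_hrf((0:39) * 2 - 2),
               tolerance = 1e-12)

  dup <- sch1
  dup <- rbind(dup, dup[1, ])
  class(dup) <- c("event_schedule", "data.frame")
  attr(dup, "tr") <- 2; attr(dup, "n_scans") <- 40L
  expect_error(build_design(dup), "duplicate")
})

test_that("high-pass drift basis has the right size and orthonormality", {
  B <- dct_basis(200, 2, cutoff = 128)
  expect_identical(ncol(B), as.integer(floor(2 * 200 * 2 / 128)))
  expect_equal(crossprod(B), diag(ncol(B)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("GLM estimates match the normal-equations oracle", {
  set.seed(20)
  X <- cbind(1, rnorm(6), c(0, 1, 0, 1, 1, 0))
  colnames(X) <- c("a", "b", "c")
  Y <- matrix(rnorm(12), 6, 2)
  Xd <- structure(X, class = c("design_matrix", "matrix"), event_cols = "b")
  fit <- fit_glm(Y, Xd)
  beta_hand <- solve(t(X) %*% X) %*% t(X) %*% Y
  expect_equal(unclass(fit$betas), beta_hand, tolerance = 1e-10,
               ignore_attr = TRUE)
  res <- Y - X %*% fit$betas
  expect_lt(max(abs(t(X) %*% res)), 1e-8)
  expect_identical(fit$df_residual, 3L)
  expect_equal(fit$sigma2, colSums(res^2) / 3, tolerance = 1e-12)
})

test_that("rank-deficient designs fall back to the pseudo-inverse", {
  X <- cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8))
  colnames(X) <- c("i", "x", "x2")
  Xd <- structure(X, class = c("design_matrix", "matrix"), event_cols = "x")
  expect_warning(fit <- fit_glm(matrix(rnorm(8), 4), Xd), "rank-deficient")
  expect_identical(fit$rank, 2L)
  expect_identical(fit$df_residual, 2L)
})

test_that("F contrasts equal the full-vs-reduced refit oracle and t^2", {
  set.seed(21)
  n <- 40
  X <- cbind(intercept = 1, a = rnorm(n), b = rnorm(n), c = rnorm(n))
  Xd <- structure(X, class = c("design_matrix", "matrix"),
                  event_cols = c("a", "b"))
  Y <- matrix(rnorm(n * 5), n)
  fit <- fit_glm(Y, Xd)

  fm <- f_contrast(fit, c("a", "b"))
  # oracle: extra sum of squares from explicit full and reduced fits
  for (v in 1:5) {
    rss_full <- sum(stats::lm.fit(X, Y[, v])$residuals^2)
    rss_red <- sum(stats::lm.fit(X[, c("intercept", "c")], Y[, v])$residuals^2)
    F_hand <- ((rss_red - rss_full) / 2) / (rss_full / (n - 4))
    expect_equal(fm$stat[v], F_hand, tolerance = 1e-10)
  }
  expect_equal(unname(fm$df), c(2, n - 4))

  f1 <- f_contrast(fit, "a")
  t1 <- t_contrast(fit, "a")
  expect_equal(f1$stat, t1$stat^2, tolerance = 1e-10)
  expect_equal(f1$p, t1$p, tolerance = 1e-10)

  expect_error(f_contrast(fit, matrix(0, 1, 4)), "all-zero")
  expect_error(f_contrast(fit, "nope"), "unknown regressor")
})

test_that("null-data F contrast p values are uniform", {
  set.seed(22)
  n <- 60
  X <- cbind(intercept = 1, a = rnorm(n))
  Xd <- structure(X, class = c("design_matrix", "matrix"), event_cols = "a")
  Y <- matrix(rnorm(n * 2500), n)
  fm <- f_contrast(fit_glm(Y, Xd), "a")
  ks <- stats::ks.test(fm$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("conjunction null is the intersection of individually passing sets", {
  set.seed(23)
  n <- 30
  X <- cbind(intercept = 1, a = rnorm(n))
  Xd <- structure(X, class = c("design_matrix", "matrix"), event_cols = "a")
  V <- 500
  signal <- rep(c(0, 1), length.out = V)
  Y1 <- X %*% rbind(0, signal) + matrix(rnorm(n * V, 0, 0.8), n)
  Y2 <- X %*% rbind(0, signal * rep(c(1, 1, 0, 1), length.out = V)) +
    matrix(rnorm(n * V, 0, 0.8), n)
  m1 <- f_contrast(fit_glm(Y1, Xd), "a")
  m2 <- f_contrast(fit_glm(Y2, Xd), "a")

  cj <- conjunction_null(list(m1, m2), alpha = 0.05)
  expect_identical(attr(cj, "pass"), m1$p < 0.05 & m2$p < 0.05)
  expect_equal(cj$stat, pmin(m1$stat, m2$stat))
  expect_equal(cj$p, pmax(m1$p, m2$p))

  # idempotence: conjunction of a map with itself = its own thresholding
  cj1 <- conjunction_null(list(m1, m1), alpha = 0.05)
  expect_identical(attr(cj1, "pass"), m1$p < 0.05)

  # one all-null map empties the conjunction
  null_p <- m1; null_p$p <- rep(1, V); null_p$stat <- rep(0, V)
  cj0 <- conjunction_null(list(m1, null_p), alpha = 0.05)
  expect_false(any(attr(cj0, "pass")))

  expect_error(conjunction_null(list(m1, list())), "stat_map")
})

test_that("cluster labeling matches hand-counted components", {
  m <- array(FALSE, c(4, 4, 2))
  m[1:2, 1, 1] <- TRUE            # component A
  m[4, 4, 2] <- TRUE              # component B (far corner)
  m[3, 2, 1] <- TRUE              # touches A diagonally (26-connectivity)
  lab26 <- speechprime:::label_clusters(m, 26)
  expect_identical(sort(attr(lab26, "sizes")), c(1L, 3L))
  lab6 <- speechprime:::label_clusters(m, 6)
  expect_identical(sort(attr(lab6, "sizes")), c(1L, 1L, 2L))
})

test_that("permutation cluster correction finds an embedded effect", {
  set.seed(24)
  dimv <- c(8, 8, 4)
  V <- prod(dimv)
  n <- 14
  data <- matrix(rnorm(n * V), n)
  amp <- array(0, dimv); amp[3:5, 3:5, 2:3] <- 2
  data <- data + rep(1, n) %o% as.vector(amp)
  tab <- cluster_correct(data, dimv, voxel_p = 0.001, n_perm = 300, seed = 25)
  expect_gte(nrow(tab), 1)
  expect_true(any(tab$significant & tab$size >= 10))

  # threshold p = 1 puts every voxel in one cluster spanning the volume
  tab1 <- cluster_correct(matrix(rnorm(10 * 64), 10), c(4, 4, 4),
                          voxel_p = 1, n_perm = 100, seed = 1)
  expect_identical(tab1$size[1], 64L)
  expect_warning(cluster_correct(data, dimv, n_perm = 50, seed = 1), "100")
})

test_that("2x2 interaction equals the difference-of-differences t^2 oracle", {
  set.seed(26)
  subj <- 1:4
  d <- expand.grid(subject = subj, position = c("dw1", "dw2"),
                   condition = c("match", "mismatch"), stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d))
  res <- rm_anova_2x2(d)
  dd <- sapply(subj, function(s) {
    g <- function(p, c) d$value[d$subject == s & d$position == p & d$condition == c]
    (g("dw2", "match") - g("dw1", "match")) -
      (g("dw2", "mismatch") - g("dw1", "mismatch"))
  })
  t_hand <- mean(dd) / (sd(dd) / sqrt(4))
  expect_equal(res$statistic, t_hand^2, tolerance = 1e-10)
  expect_equal(unname(res$df), c(1, 3))
  expect_equal(res$p, 2 * pt(-abs(t_hand), 3), tolerance = 1e-10)

  # additive cells (no interaction), zero noise -> F = 0
  d$value <- with(d, ifelse(position == "dw2", 1, 0) +
                    ifelse(condition == "match", 2, 0))
  res0 <- rm_anova_2x2(d)
  expect_equal(res0$statistic, 0)

  # crossed pattern at large effect
  d$value <- with(d, ifelse(position == "dw2" & condition == "match", 3, 0)) +
    rnorm(nrow(d), 0, 0.1)
  resx <- rm_anova_2x2(d)
  expect_gt(resx$statistic, 0)
  expect_lt(resx$p, 0.05)
})

test_that("factorial rm-ANOVA matches the aov error-strata oracle", {
  set.seed(27)
  d <- expand.grid(subject = factor(1:8), condition = c("match", "mismatch"),
                   roi = c("Te1.0", "Te1.1", "Te1.2"), hemisphere = c("L", "R"),
                   stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d)) + ifelse(d$condition == "match", 0.5, 0)
  mine <- rm_anova(d, factors = c("condition", "roi", "hemisphere"))
  oracle <- summary(stats::aov(
    value ~ condition * roi * hemisphere +
      Error(subject / (condition * roi * hemisphere)), data = d))
  pick <- function(stratum, term) {
    tab <- oracle[[paste0("Error: subject:", stratum)]][[1]]
    tab[trimws(rownames(tab)) == term, c("F value", "Pr(>F)")]
  }
  for (term in c("condition", "roi", "hemisphere", "condition:roi",
                 "condition:hemisphere", "roi:hemisphere",
                 "condition:roi:hemisphere")) {
    o <- pick(term, term)
    expect_equal(mine[[term]]$statistic, o[[1]], tolerance = 1e-8)
    expect_equal(mine[[term]]$p, o[[2]], tolerance = 1e-8)
  }

  # all cells equal -> every F is 0
  d$value <- 1
  flat <- rm_anova(d, factors = c("condition", "roi", "hemisphere"))
  expect_true(all(vapply(flat, function(s) s$statistic, numeric(1)) == 0))

  # Greenhouse-Geisser epsilon stays in [1/(k), 1] and shrinks df
  d$value <- rnorm(nrow(d))
  g <- rm_anova(d, factors = c("condition", "roi", "hemisphere"), gg = TRUE)
  expect_lte(g$roi$effect$gg_epsilon, 1)
  expect_gte(g$roi$effect$gg_epsilon, 0.5)
})

test_that("condition-only effects stay specific in the factorial ANOVA", {
  tab <- toy_roi_table(12, cond_effect = 1, noise_sd = 0.3, seed = 28)
  res <- rm_anova_2x3x2(average_positions(tab))
  expect_lt(res$condition$p, 0.001)
  expect_gt(res$roi$p, 0.01)
  expect_gt(res$hemisphere$p, 0.01)
})

test_that("ROI beta extraction averages the right voxels", {
  sch <- generate_schedule(n_match = 8, n_mismatch = 8, n_catch = 2, seed = 30)
  atlas <- make_roi_atlas(dim = c(8, 8, 4), roi_size = c(2, 2, 1))
  eff <- default_effect_map(atlas)
  b <- simulate_bold(sch, atlas, eff, noise_sd = 0.5, ar_coef = 0, seed = 31)
  fit <- fit_glm(b, build_design(sch, nuisance = b$nuisance))

  # selection_p = 1 keeps every ROI voxel
  tab <- roi_mean_betas(list(fit), atlas, selection_p = 1)
  row <- tab[tab$roi == "Te1.0" & tab$hemisphere == "L" &
             tab$condition == "match" & tab$position == "dw2", ]
  v <- which(b$labels == "Te1.0_L")
  expect_identical(row$n_voxels, length(v))
  expect_equal(row$mean_beta, mean(fit$betas["dw2_match", v]), tolerance = 1e-12)
  expect_equal(row$sd_beta, sd(fit$betas["dw2_match", v]), tolerance = 1e-12)

  # single-voxel ROI: mean equals that voxel's beta
  tiny <- array("", c(2, 2, 1)); tiny[1, 1, 1] <- "Te1.0_L"
  attr(tiny, "roi_names") <- "Te1.0_L"
  fit_small <- list(betas = fit$betas[, 1:4], sigma2 = fit$sigma2[1:4],
                    df_residual = fit$df_residual, rank = fit$rank,
                    cov_unscaled = fit$cov_unscaled, design = fit$design,
                    event_cols = fit$event_cols)
  class(fit_small) <- "glm_fit"
  t2 <- roi_mean_betas(list(fit_small), tiny, selection_p = 1)
  expect_equal(t2$mean_beta[t2$condition == "match" & t2$position == "dw1"],
               unname(fit$betas["dw1_match", 1]), tolerance = 1e-12)

  expect_error(roi_mean_betas(list(fit), array("", c(2, 2, 1))), "no labeled")
})

test_that("BH rejections equal the brute-force step-up oracle", {
  brute_bh <- function(p, q) {
    n <- length(p)
    o <- order(p)
    k <- 0
    for (i in seq_len(n)) if (p[o[i]] <= q * i / n) k <- i
    reject <- rep(FALSE, n)
    if (k > 0) reject[o[seq_len(k)]] <- TRUE
    reject
  }
  toy <- c(0.001, 0.01, 0.02, 0.2, 0.9)
  got <- fdr_correct(toy, 0.05)
  expect_identical(got$reject, brute_bh(toy, 0.05))

  expect_true(all(fdr_correct(rep(0, 6))$reject))
  expect_false(any(fdr_correct(rep(1, 6))$reject))

  set.seed(33)
  for (i in 1:20) {
    p <- runif(15)^2
    expect_identical(fdr_correct(p, 0.05)$reject, brute_bh(p, 0.05))
  }
})

test_that("post-hoc paired t-tests reject only where the effect lives", {
  # null table: identical conditions -> no rejections
  tab0 <- toy_roi_table(10, cond_effect = 0, noise_sd = 0.2, seed = 34)
  res0 <- posthoc_paired_t(tab0)
  expect_identical(nrow(res0), 6L)

  # effect in 5 of 6 ROIs
  tab <- toy_roi_table(16, cond_effect = 0, noise_sd = 0.2, seed = 35)
  on <- !(tab$roi == "Te1.2" & tab$hemisphere == "R")
  tab$mean_beta <- tab$mean_beta + ifelse(tab$condition == "match" & on, 0.8, 0)
  res <- posthoc_paired_t(tab)
  expect_true(all(res$reject[!(res$roi == "Te1.2" & res$hemisphere == "R")]))

  single <- toy_roi_table(1, seed = 36)
  expect_error(posthoc_paired_t(single), "at least 2")
})
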