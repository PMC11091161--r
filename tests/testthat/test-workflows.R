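test_that("ensemble_matrices: zero case, shape, and M*N*(N-1)/2 bookkeeping", {
  base <- toy_structure("AVGLK", seed = 31L)
  st <- comparison_settings("FA")
  copies <- lapply(1:3, function(i) base)
  ens <- ensemble_matrices(copies, st)
  M <- nrow(apply_scheme(base, "FA"))
  expect_length(ens$per_anchor, M)
  expect_true(all(vapply(ens$per_anchor, function(m) all(m == 0), TRUE)))
  expect_equal(dim(ens$mean_matrix), c(3L, 3L))
  expect_equal(unname(ens$anchor_means), rep(0, M))
  # every matrix symmetric, zero diagonal; pair count arithmetic
  noisy <- make_ensemble(base, 3L, noise_sigma = 0.4, seed = 32L)
  ens2 <- ensemble_matrices(noisy, st)
  for (m in ens2$per_anchor[1:5]) {
    expect_true(isSymmetric(unclass(m)))
    expect_equal(diag(m), stats::setNames(rep(0, 3), rownames(m)))
  }
  n_scores <- sum(vapply(ens2$per_anchor, function(m) sum(upper.tri(m)), 0))
  expect_equal(n_scores, M * 3 * 2 / 2)
  expect_true(all(ens2$mean_matrix >= 0 & ens2$mean_matrix <= 1))
  # inventory mismatch is refused with guidance
  expect_error(ensemble_matrices(list(base, toy_structure("AVGL", seed = 1L)), st),
               class = "locohd_domain_error")
})

test_that("kabsch_rmsd: rigid invariance and an independent rotation oracle", {
  set.seed(101)
  X <- matrix(stats::rnorm(12), 4L, 3L)
  expect_equal(kabsch_rmsd(X, X), 0)
  # rigid motion: rotation about z by 0.7 rad + translation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Y <- X %*% t(R) + matrix(c(3, -2, 5), 4L, 3L, byrow = TRUE)
  expect_lt(kabsch_rmsd(X, Y), 1e-9)
  # relabeling both sets identically changes nothing
  perm <- c(3L, 1L, 4L, 2L)
  expect_equal(kabsch_rmsd(X[perm, ], Y[perm, ]), kabsch_rmsd(X, Y))

  # one displaced point: compare against a brute-force orientation search
  # (coarse Euler-angle grid refined by Nelder-Mead; no SVD involved)
  Y2 <- X
  Y2[2L, ] <- Y2[2L, ] + c(1.5, -0.8, 0.6)
  rot <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1)) %*%
      rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy)) %*%
      rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  }
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y2, scale = FALSE)
  obj <- function(a) sqrt(mean(rowSums((Yc %*% t(rot(a)) - Xc)^2)))
  grid <- as.matrix(expand.grid(a1 = seq(0, 2 * pi, length.out = 9L),
                                a2 = seq(0, pi, length.out = 5L),
                                a3 = seq(0, 2 * pi, length.out = 9L)))
  best <- grid[which.min(apply(grid, 1L, obj)), ]
  oracle <- stats::optim(best, obj, control = list(reltol = 1e-12))$value
  expect_equal(kabsch_rmsd(X, Y2), oracle, tolerance = 1e-4)

  expect_error(kabsch_rmsd(X, X[1:3, ]), class = "locohd_domain_error")
})

test_that("rmsd_matrix: zero under rigid motion, noise scale as expected", {
  base <- toy_structure("AVGLKDERFW", seed = 41L)
  copies <- lapply(1:3, function(i) base)
  m0 <- rmsd_matrix(copies, "FA")
  expect_lt(max(m0), 1e-9)
  # rigid-body moved copies are still all-zero
  rot <- as.data.frame(base)
  tmp <- rot$x; rot$x <- -rot$y; rot$y <- tmp; rot$z <- rot$z + 8
  m1 <- rmsd_matrix(list(base, new_structure(rot)), "FA")
  expect_lt(max(m1), 1e-9)
  # iid Gaussian noise sigma on both members: E[RMSD] ~ sqrt(6)*sigma for
  # large atom counts (alignment absorbs only ~6 degrees of freedom)
  sigma <- 0.3
  noisy <- make_ensemble(base, 6L, noise_sigma = sigma, seed = 42L)
  m2 <- rmsd_matrix(noisy, "FA")
  expect_equal(mean(m2[upper.tri(m2)]), sqrt(6) * sigma, tolerance = 0.1)
  # ca_only path uses one atom per residue
  expect_silent(rmsd_matrix(noisy, "FA", ca_only = TRUE))
})

test_that("complete_linkage recovers planted blocks and degenerate cuts", {
  # planted 2-block distance matrix
  d <- matrix(5, 6L, 6L)
  d[1:3, 1:3] <- 0.5; d[4:6, 4:6] <- 0.5
  diag(d) <- 0
  lab <- complete_linkage(d, k = 2L)
  expect_length(unique(lab[1:3]), 1L)
  expect_length(unique(lab[4:6]), 1L)
  expect_false(lab[1L] == lab[4L])
  expect_equal(complete_linkage(d, threshold = 0.1), 1:6)   # all singletons
  expect_equal(unique(complete_linkage(d, threshold = 10)), 1L)
  expect_error(complete_linkage(d, k = 7L), class = "locohd_domain_error")
  expect_error(complete_linkage(d), class = "locohd_config_error")
})

test_that("spearman: monotone cases, hand value, undefined on constants", {
  expect_equal(spearman(1:5, (1:5)^3), 1)
  expect_equal(spearman(1:5, -(1:5)), -1)
  expect_equal(spearman(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_true(is.na(spearman(rep(1, 5), 1:5)))
  expect_error(spearman(1:2, 1:2), class = "locohd_domain_error")
})

test_that("score_model_pair: identity, planted flip, external join", {
  ref <- toy_structure("AVGLKDER", seed = 51L)
  st <- comparison_settings("FA+Cent")
  same <- score_model_pair(ref, ref, st)
  expect_equal(same$table$locohd, rep(0, 8L))
  expect_equal(same$summary$prm_locohd, 0)

  # planted side-chain displacement dominates the ranking
  mod <- as.data.frame(ref)
  target <- residue_keys(ref)[4L]
  sel <- mod$res_key == target & !(mod$atom_name %in% c("N", "CA", "C", "O"))
  mod$y[sel] <- mod$y[sel] + 4
  res <- score_model_pair(ref, new_structure(mod), st)
  expect_equal(which.max(res$table$locohd), 4L)
  expect_gt(res$summary$prm_locohd, 0)

  # external per-residue score join + Spearman summary
  ext <- data.frame(chain = res$table$chain, resnum = res$table$resnum,
                    icode = res$table$icode,
                    score = seq_len(nrow(res$table)))
  res2 <- score_model_pair(ref, new_structure(mod), st, external_scores = ext)
  expect_true("external" %in% names(res2$table))
  expect_false(is.na(res2$summary$spearman))
  expect_equal(res2$summary$prm_external, stats::median(ext$score))
  # unjoinable rows are dropped from the summary, logged not fatal
  ext2 <- ext[-1L, ]
  expect_message(res3 <- score_model_pair(ref, new_structure(mod), st, ext2),
                 "without external score")
  expect_equal(res3$summary$n_unjoined, 1L)
  # centroid-less scheme refused
  expect_error(score_model_pair(ref, ref, comparison_settings("FA")),
               class = "locohd_domain_error")
})

test_that("trajectory_series: flat, strided and two-state behaviour", {
  base <- toy_structure("AVGLKD", seed = 61L)
  st <- comparison_settings("CG+Cent")
  flat <- lapply(1:6, function(i) base)
  ser <- trajectory_series(flat, 1L, st)
  expect_equal(dim(ser), c(6L, 6L))
  expect_true(all(ser == 0))
  expect_equal(ncol(trajectory_series(flat, 1L, st, stride = 2L)), 3L)
  expect_error(trajectory_series(flat, 9L, st), class = "locohd_domain_error")
  expect_error(trajectory_series(flat, 1L, st, stride = 7L),
               class = "locohd_domain_error")

  trj <- make_trajectory(base, 16L, switch_frame = 9L, switch_residue = 2L,
                         displacement = 4, noise_sigma = 0.1, seed = 62L)
  ser2 <- trajectory_series(trj, 1L, st)
  key <- attr(trj, "switch_res_key")
  # switched residue's series is two-level: post-switch scores dominate
  s_key <- ser2[key, ]
  expect_gt(min(s_key[9:16]), max(s_key[2:8]))
})

test_that("bimodality: reference distributions and the ranking", {
  # n = 1e5: Monte-Carlo sd of beta is ~2e-3 for both reference laws,
  # so a 0.01 absolute band is ~5 sigma
  set.seed(71)
  u <- bimodality(stats::runif(1e5))
  expect_lt(abs(u$beta - 5 / 9), 0.01)
  g <- bimodality(stats::rnorm(1e5))
  expect_lt(abs(g$beta - 1 / 3), 0.01)
  two <- bimodality(rep(c(-1, 1), 50L))
  expect_equal(two$beta, 1)
  expect_equal(two$skewness, 0)
  expect_equal(two$kurtosis, 1)
  expect_error(bimodality(rep(1, 10)), class = "locohd_domain_error")
  expect_error(bimodality(1:3), class = "locohd_domain_error")

  # ranking: planted bimodal series first, Gaussians unflagged
  set.seed(72)
  series <- c(list(planted = c(stats::rnorm(40, 0.1, 0.01),
                               stats::rnorm(40, 0.5, 0.01))),
              lapply(stats::setNames(1:5, paste0("g", 1:5)),
                     function(i) stats::rnorm(80, 0.3, 0.05)))
  rk <- rank_bimodal(series)
  expect_equal(rk$anchor[1L], "planted")
  expect_true(rk$flagged[1L])
  expect_false(any(rk$flagged[-1L]))
  expect_equal(nrow(rank_bimodal(list())), 0L)
})
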