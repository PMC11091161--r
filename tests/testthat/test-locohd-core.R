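# Frozen expected values used below:
#  - hellinger((.5,.5,0),(1,0,0)) = sqrt(1 - 1/sqrt(2)) = 0.5411961...
#    (direct scalar evaluation of the formula, checked against
#    sqrt(0.5*((sqrt(.5)-1)^2 + .5)) before freezing)
#  - locohd of {(0,A),(4,B)} vs {(0,A),(6,C)} under uniform(3,10):
#    (2/7)*0.5411961 + (4/7)*sqrt(0.5) = 0.5586885, computed with the
#    independent Riemann oracle before the build and re-checked here.

test_that("worked-example DDEC values are reproduced", {
  cl <- make_cloud("worked_example")
  env <- build_environment(cl, 1L, all_contacts("toy"))
  expect_equal(unname(ddec(env, 2)), c(1, 0, 0))
  expect_equal(unname(ddec(env, 4)), c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(unname(ddec(env, 7)), c(0.5, 0.5, 0))
  expect_equal(unname(ddec(env, 0)), c(1, 0, 0))  # anchor alone at r = 0
  expect_error(ddec(env, -1), class = "locohd_domain_error")
})

test_that("hetero-residue filtering removes same-source atoms, keeps anchor", {
  cl <- make_cloud("worked_example")
  st <- comparison_settings("toy", hetero_only = TRUE, truncation_radius = Inf)
  env <- build_environment(cl, 1L, st)
  expect_equal(env$distances, c(0, 3, 5))     # (A,1,X) removed
  expect_equal(env$type_set[env$types], c("A", "B", "B"))
  # truncation: atom beyond the radius is excluded
  st10 <- comparison_settings("toy", hetero_only = FALSE)
  cl2 <- make_cloud("random", n = 2L, seed = 1L)
  cl2$x <- c(0, 10.5); cl2$y <- c(0, 0); cl2$z <- c(0, 0)
  cl2$res_key <- c("R1", "R2")
  env2 <- build_environment(cl2, 1L, st10)
  expect_length(env2$distances, 1L)
})

test_that("hellinger matches hand values and rejects mismatched sets", {
  expect_equal(hellinger(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(hellinger(c(1, 0, 0), c(0, 1, 0)), 1)
  expect_equal(hellinger(c(0.5, 0.5, 0), c(1, 0, 0)), 0.5411961,
               tolerance = 1e-6)
  expect_error(hellinger(c(1, 0), c(1, 0, 0)), class = "locohd_domain_error")
  expect_error(
    hellinger(stats::setNames(c(1, 0), c("A", "B")),
              stats::setNames(c(1, 0), c("A", "C"))),
    class = "locohd_domain_error")
})

test_that("locohd_pair closed form matches hand computation and trivials", {
  w <- uniform_weight(3, 10)
  eA <- environment_from_pairs(c("A", "B"), c(0, 4), type_set = c("A", "B", "C"))
  eB <- environment_from_pairs(c("A", "C"), c(0, 6), type_set = c("A", "B", "C"))
  expect_equal(locohd_pair(eA, eB, w), 0.5586885, tolerance = 1e-6)
  expect_equal(locohd_pair(eA, eA, w), 0)
  # anchor-only environments with different types: H = 1 on the whole support
  a1 <- environment_from_pairs("A", 0, type_set = c("A", "B"))
  a2 <- environment_from_pairs("B", 0, type_set = c("A", "B"))
  expect_equal(locohd_pair(a1, a2, w), 1)
  expect_error(locohd_pair(eA, a1, w), class = "locohd_domain_error")
})

test_that("closed form equals the Riemann oracle on random environments", {
  set.seed(42)
  w <- uniform_weight(3, 10)
  for (i in 1:50) {
    eA <- random_environment(sample(3:20, 1L))
    eB <- random_environment(sample(3:20, 1L))
    expect_lt(abs(locohd_pair(eA, eB, w) - locohd_riemann(eA, eB, w)), 1e-6)
  }
})

test_that("score range, symmetry, identity and locality hold", {
  set.seed(7)
  w <- uniform_weight(3, 10)
  for (i in 1:200) {
    eA <- random_environment(sample(2:15, 1L))
    eB <- random_environment(sample(2:15, 1L))
    s_ab <- locohd_pair(eA, eB, w)
    expect_gte(s_ab, 0); expect_lte(s_ab, 1)
    expect_identical(s_ab, locohd_pair(eB, eA, w))  # exact symmetry
  }
  # support locality: an atom beyond the upper bound changes nothing ...
  eA <- random_environment(8L)
  eB <- random_environment(8L)
  add_atom <- function(e, d, tp) {
    environment_from_pairs(c(e$type_set[e$types], tp), c(e$distances, d),
                           type_set = e$type_set)
  }
  expect_equal(locohd_pair(add_atom(eA, 10.7, "B"), eB, w),
               locohd_pair(eA, eB, w), tolerance = 1e-15)
  # ... but an atom below the lower bound does change the score
  expect_false(isTRUE(all.equal(locohd_pair(add_atom(eA, 1.2, "B"), eB, w),
                                locohd_pair(eA, eB, w), tolerance = 1e-9)))
})

test_that("triangle inequality holds on random triples (pseudo-metric)", {
  set.seed(99)
  w <- uniform_weight(3, 10)
  for (i in 1:300) {
    e <- replicate(3, random_environment(sample(2:12, 1L)), simplify = FALSE)
    ab <- locohd_pair(e[[1L]], e[[2L]], w)
    bc <- locohd_pair(e[[2L]], e[[3L]], w)
    ac <- locohd_pair(e[[1L]], e[[3L]], w)
    expect_lte(ac, ab + bc + 1e-12)
  }
})

test_that("compare_clouds is local and permutation-invariant", {
  s <- toy_structure("AVGLKDER", seed = 21L)
  cl <- apply_scheme(s, "FA")
  st <- comparison_settings("FA")
  pairs <- default_anchor_pairs(cl, cl, "all_primitive")
  expect_equal(compare_clouds(cl, cl, pairs, st), rep(0, nrow(cl)))

  # displace one atom: only anchors within truncation of old/new site move
  cl2 <- cl
  moved <- nrow(cl)  # last primitive atom
  cl2$x[moved] <- cl2$x[moved] + 2.5
  scores <- compare_clouds(cl, cl2, pairs, st)
  d_old <- sqrt((cl$x - cl$x[moved])^2 + (cl$y - cl$y[moved])^2 +
                  (cl$z - cl$z[moved])^2)
  d_new <- sqrt((cl$x - cl2$x[moved])^2 + (cl$y - cl2$y[moved])^2 +
                  (cl$z - cl2$z[moved])^2)
  far <- d_old > 10 & d_new > 10
  far[moved] <- FALSE
  expect_true(all(scores[far] == 0))
  expect_true(any(scores[!far] > 0))

  # permutation invariance: shuffling cloud order changes no score
  set.seed(5)
  perm <- sample(nrow(cl))
  clp <- permute_cloud(cl2, perm)
  pairs_p <- cbind(pairs[, 1L], match(seq_len(nrow(cl)), perm)[pairs[, 2L]])
  expect_equal(compare_clouds(cl, clp, pairs_p, st), scores, tolerance = 1e-12)
})

test_that("default_anchor_pairs validates inventories and schemes", {
  s <- toy_structure("AVG", seed = 1L)
  fa <- apply_scheme(s, "FA")
  fac <- apply_scheme(s, "FA+Cent")
  expect_error(default_anchor_pairs(fa, fac, "all_primitive"),
               class = "locohd_domain_error")
  expect_error(default_anchor_pairs(fa, fa, "centroid"),
               class = "locohd_domain_error")
  cp <- default_anchor_pairs(fac, fac, "centroid")
  expect_equal(nrow(cp), 3L)
  expect_true(all(fac$ptype[cp[, 1L]] == "Cent"))
  # truncated inventory triggers the prune_to_common guidance
  s2 <- new_structure(as.data.frame(s)[-1L, ])
  expect_error(default_anchor_pairs(fa, apply_scheme(s2, "FA"), "all_primitive"),
               regexp = "prune_to_common", class = "locohd_domain_error")
})
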