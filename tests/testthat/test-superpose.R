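rot_about <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

test_that("self-fit is the identity with zero rmsd", {
  sc <- generate_scene(scene_spec(n_bridges = 1, waters_per_bridge = 1,
                                  n_decoy_waters = 0, seed = 4))
  corr <- scene_correspondence(sc)
  fit <- fit_quartets(sc$structure, sc$structure, corr)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$n_atoms, 11 * 4 * sc$spec$n_quartets)
})

test_that("a known rigid transform is recovered below 1e-6 angstrom", {
  sc <- generate_scene(scene_spec(n_bridges = 2, waters_per_bridge = 2,
                                  n_decoy_waters = 3, seed = 8))
  R0 <- rot_about(c(1, 2, 3), 0.7)
  t0 <- c(-4, 2.5, 7)
  pair <- derive_native_copy(sc, rotation = R0, translation = t0,
                             conserved_fraction = 1, jitter_sd = 0)
  fit <- fit_quartets(sc$structure, pair$native, pair$correspondence)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(fit$rotation, R0, tolerance = 1e-8)
  expect_equal(fit$translation, t0, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  # applying the fit reproduces rmsd over the fitted atoms (self-consistency)
  moved <- apply_superposition(sc$structure, fit)
  expect_equal(max(tidy(fit)$deviation), 0, tolerance = 1e-6)
  expect_equal(glance(fit)$rmsd, fit$rmsd)
  expect_s3_class(moved, "gq_structure")
})

test_that("authored Kabsch agrees with the bio3d reference on random sets", {
  set.seed(31)
  for (i in 1:5) {
    P <- matrix(rnorm(36, sd = 4), ncol = 3)
    Q <- sweep(P %*% rot_about(rnorm(3), runif(1, 0, pi)), 2,
               rnorm(3, sd = 5), `+`) + matrix(rnorm(36, sd = 0.2), ncol = 3)
    fit <- gqwater:::kabsch(P, Q)
    ref <- bio3d::rot.lsq(xx = as.numeric(t(P)), yy = as.numeric(t(Q)))
    ref_moved <- matrix(ref, ncol = 3, byrow = TRUE)
    my_moved <- sweep(P %*% fit$rotation, 2, fit$translation, `+`)
    expect_equal(my_moved, ref_moved, tolerance = 1e-6)
  }
})

test_that("rmsd is invariant under pre-transforming an input", {
  sc <- generate_scene(scene_spec(n_bridges = 1, waters_per_bridge = 2,
                                  n_decoy_waters = 2, seed = 12))
  pair <- derive_native_copy(sc, conserved_fraction = 1, jitter_sd = 0.25,
                             max_displacement = 0.8)
  corr <- pair$correspondence
  fit0 <- fit_quartets(sc$structure, pair$native, corr)
  pre <- list(rotation = rot_about(c(0, 1, 1), 1.1), translation = c(9, -9, 4))
  a2 <- sc$structure
  xyz <- as.matrix(a2[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% pre$rotation, 2, pre$translation, `+`)
  a2$x <- xyz[, 1]; a2$y <- xyz[, 2]; a2$z <- xyz[, 3]
  fit1 <- fit_quartets(a2, pair$native, corr)
  expect_equal(fit1$rmsd, fit0$rmsd, tolerance = 1e-8)
})

test_that("degenerate fits are rejected", {
  line <- data.frame(atom = c("N1", "C2", "N3"), resid = "DG", chain = "A",
                     resno = 1, x = c(0, 1, 2), y = 0, z = 0)
  a <- gq_structure(line)
  corr <- data.frame(chain_a = "A", resno_a = 1, chain_b = "A", resno_b = 1)
  expect_error(fit_quartets(a, a, corr), "collinear|degenerate")
  two <- gq_structure(line[1:2, ])
  expect_error(fit_quartets(two, two, corr), "3 atom pairs|degenerate")
})

test_that("jittered-copy rmsd matches the sigma * sqrt(3) expectation", {
  # one-sided isotropic jitter, sd sigma per coordinate: E rmsd^2 = 3 sigma^2
  # per atom, less the 6 fitted rigid degrees of freedom
  sigma <- 0.25
  ratios <- vapply(1:20, function(seed) {
    sc <- generate_scene(scene_spec(n_quartets = 1, n_bridges = 0,
                                    n_decoy_waters = 0, seed = seed))
    pair <- derive_native_copy(sc, conserved_fraction = 0, jitter_sd = 0,
                               seed = seed + 100)
    nat <- pair$native
    set.seed(seed + 500)
    sel <- nat$resid == "DG"
    nat$x[sel] <- nat$x[sel] + rnorm(sum(sel), 0, sigma)
    nat$y[sel] <- nat$y[sel] + rnorm(sum(sel), 0, sigma)
    nat$z[sel] <- nat$z[sel] + rnorm(sum(sel), 0, sigma)
    fit <- fit_quartets(sc$structure, nat, pair$correspondence)
    fit$rmsd / sigma
  }, numeric(1))
  n_at <- 44  # one quartet, 11 base atoms per guanine
  expected <- sqrt(3 - 6 / n_at)
  expect_equal(mean(ratios), expected, tolerance = 0.2)
})

test_that("conserved-water matching equals the mutual-NN oracle", {
  for (seed in c(2, 6, 19)) {
    sc <- generate_scene(scene_spec(n_bridges = 2, waters_per_bridge = 3,
                                    n_decoy_waters = 8, seed = seed))
    pair <- derive_native_copy(sc, conserved_fraction = 0.6,
                               jitter_sd = 0.2, n_fresh_decoys = 3,
                               seed = seed + 50)
    fit <- fit_quartets(sc$structure, pair$native, pair$correspondence)
    got <- match_conserved_waters(sc$structure, pair$native, fit)
    wa <- sc$structure[sc$structure$category == "water", ]
    wb <- pair$native[pair$native$category == "water", ]
    pa <- as.matrix(wa[, c("x", "y", "z")])
    pa <- sweep(pa %*% fit$rotation, 2, fit$translation, `+`)
    oracle <- oracle_mutual_pairs(pa, as.matrix(wb[, c("x", "y", "z")]),
                                  wa$label, wb$label, 1.0)
    expect_equal(sort(paste(got$water_a, got$water_b, sep = "|")), oracle)
    # and the recovered pairs are exactly the planted truth
    expect_setequal(paste(got$water_a, got$water_b),
                    paste(pair$conserved$water_a, pair$conserved$water_b))
  }
})

test_that("greedy matching agrees with mutual-NN on well-separated waters", {
  sc <- generate_scene(scene_spec(n_bridges = 2, waters_per_bridge = 2,
                                  n_decoy_waters = 6, seed = 41))
  pair <- derive_native_copy(sc, conserved_fraction = 0.8, jitter_sd = 0.2,
                             seed = 42)
  fit <- fit_quartets(sc$structure, pair$native, pair$correspondence)
  mutual <- match_conserved_waters(sc$structure, pair$native, fit)
  greedy <- match_conserved_waters(sc$structure, pair$native, fit,
                                   method = "greedy")
  expect_equal(mutual, greedy)
})

test_that("identical water sets pair at zero distance", {
  sc <- generate_scene(scene_spec(n_bridges = 1, waters_per_bridge = 2,
                                  n_decoy_waters = 3, seed = 9))
  got <- match_conserved_waters(sc$structure, sc$structure, fit = NULL)
  expect_equal(nrow(got), sum(sc$structure$category == "water"))
  expect_equal(max(got$distance), 0)
})

test_that("pair count is monotone non-decreasing in the threshold", {
  sc <- generate_scene(scene_spec(n_bridges = 2, waters_per_bridge = 2,
                                  n_decoy_waters = 6, seed = 14))
  pair <- derive_native_copy(sc, conserved_fraction = 1, jitter_sd = 0.4,
                             max_displacement = 1.6, seed = 77)
  fit <- fit_quartets(sc$structure, pair$native, pair$correspondence)
  counts <- vapply(c(0.2, 0.5, 1.0, 1.5, 2.0), function(thr) {
    nrow(match_conserved_waters(sc$structure, pair$native, fit,
                                threshold = thr))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("matching is symmetric under swapping the structures", {
  sc <- generate_scene(scene_spec(n_bridges = 2, waters_per_bridge = 2,
                                  n_decoy_waters = 5, seed = 16))
  pair <- derive_native_copy(sc, conserved_fraction = 0.7, jitter_sd = 0.15,
                             n_fresh_decoys = 2, seed = 33)
  fit_ab <- fit_quartets(sc$structure, pair$native, pair$correspondence)
  corr_ba <- pair$correspondence[, c("chain_b", "resno_b", "chain_a",
                                     "resno_a")]
  names(corr_ba) <- c("chain_a", "resno_a", "chain_b", "resno_b")
  fit_ba <- fit_quartets(pair$native, sc$structure, corr_ba)
  ab <- match_conserved_waters(sc$structure, pair$native, fit_ab)
  ba <- match_conserved_waters(pair$native, sc$structure, fit_ba)
  expect_setequal(paste(ab$water_a, ab$water_b),
                  paste(ba$water_b, ba$water_a))
})
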