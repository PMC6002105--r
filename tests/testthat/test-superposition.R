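test_that("kabsch_fit recovers exact rigid transforms", {
  set.seed(11)
  a <- matrix(rnorm(30), ncol = 3)
  fit0 <- kabsch_fit(a, a)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  # 90 degrees about z plus a translation
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  b <- a %*% t(Rz)
  b <- sweep(b, 2, c(5, 0, 0), "+")
  fit <- kabsch_fit(a, b)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$rotation, Rz, tolerance = 1e-8)
  expect_equal(sweep(a %*% t(fit$rotation), 2, fit$translation, "+"), b,
               tolerance = 1e-8)
  # proper rotation always
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  # mirror-image pair must still give det +1 (reflection branch corrected)
  m <- a; m[, 1] <- -m[, 1]
  expect_equal(det(kabsch_fit(a, m)$rotation), 1, tolerance = 1e-10)
  expect_error(kabsch_fit(a[1:2, ], a[1:2, ]), "at least 3")
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(kabsch_fit(line, line), "collinear")
})

test_that("kabsch rmsd agrees with quaternion-eigenvalue and rotation-search oracles", {
  set.seed(23)
  for (i in 1:8) {
    n <- sample(4:8, 1)
    a <- matrix(rnorm(3 * n, sd = 3), ncol = 3)
    b <- matrix(rnorm(3 * n, sd = 3), ncol = 3)
    r <- rmsd(a, b)
    expect_equal(r, quaternion_rmsd_oracle(a, b), tolerance = 1e-6)
  }
  # rotation search is expensive; spot-check one fixed 4-atom pair
  a <- matrix(c(0, 0, 0, 2, 0, 0, 0, 3, 0, 1, 1, 2), ncol = 3, byrow = TRUE)
  b <- matrix(c(0.3, 0.1, -0.2, 2.2, -0.4, 0.5,
                -0.2, 2.7, 0.4, 0.8, 1.6, 1.7), ncol = 3, byrow = TRUE)
  expect_equal(rmsd(a, b), rotation_search_rmsd_oracle(a, b, n_scan = 2e5),
               tolerance = 1e-3)
})

test_that("rmsd semantics: symmetry, closed forms, superposed <= raw", {
  set.seed(7)
  a <- matrix(rnorm(24), ncol = 3)
  expect_equal(rmsd(a, a), 0, tolerance = 1e-12)
  # uniform displacement without superposition
  b <- sweep(a, 2, c(1, 0, 0), "+")
  expect_equal(rmsd(a, b, superpose = FALSE), 1.0, tolerance = 1e-12)
  expect_lt(rmsd(a, b), 1e-10)   # pure translation removed by fitting
  for (i in 1:50) {
    x <- matrix(rnorm(18), ncol = 3)
    y <- matrix(rnorm(18), ncol = 3)
    expect_lte(rmsd(x, y), rmsd(x, y, superpose = FALSE) + 1e-12)
    expect_equal(rmsd(x, y), rmsd(y, x), tolerance = 1e-9)
  }
  expect_error(rmsd(a, a[1:3, ]), "mismatch")
})

test_that("rmsd is invariant under rigid transforms and obeys the triangle bound", {
  set.seed(31)
  for (i in 1:30) {
    a <- matrix(rnorm(21), ncol = 3)
    b <- matrix(rnorm(21), ncol = 3)
    cc <- matrix(rnorm(21), ncol = 3)
    R <- random_rotation()
    t <- rnorm(3, 0, 10)
    moved <- sweep(a %*% t(R), 2, t, "+")
    expect_equal(rmsd(moved, b), rmsd(a, b), tolerance = 1e-6)
    expect_lte(rmsd(a, cc), rmsd(a, b) + rmsd(b, cc) + 1e-6)
  }
})

test_that("rmsd_series fits on fit_sel and measures on measure_sel", {
  ref <- render_model(rigid_body_state(c(0, 0, 0)), "xtal")
  sch <- temperature_schedule(10, 303)
  # frames that are rigid transforms of the reference measure as zero
  set.seed(5)
  frames <- lapply(1:4, function(i) {
    R <- random_rotation()
    sweep(ref$xyz %*% t(R), 2, rnorm(3, 0, 4), "+")
  })
  tr <- trajectory("rig", frames, 1, sch, ref)
  ser <- rmsd_series(tr, ref, "name CA", "name CA")
  expect_lt(max(ser$values), 1e-8)
  expect_equal(ser$times, 0:3)
  # one measure-atom displaced by d with fit atoms untouched -> d/sqrt(M)
  d <- 1.7
  f2 <- ref$xyz
  f2[25, ] <- f2[25, ] + c(d, 0, 0)   # a ligand (chain B) atom
  tr2 <- trajectory("disp", list(f2), 1, sch, ref)
  ser2 <- rmsd_series(tr2, ref, fit_sel = "chain A and name CA",
                      measure_sel = "chain B and name CA")
  expect_equal(ser2$values, d / sqrt(10), tolerance = 1e-10)
  expect_error(rmsd_series(tr2, ref, "chain Q", "name CA"), "empty selection")
})

test_that("pairwise endpoint matrix matches direct rmsd recomputation", {
  sch <- temperature_schedule(5, 303)
  set.seed(13)
  sts <- list(rigid_body_state(c(0, 0, 0)),
              rigid_body_state(c(4, 1, 0), quat_from_axis_angle(c(0, 0, 1), 0.7)),
              rigid_body_state(c(-3, 2, 5), quat_from_axis_angle(c(1, 0, 0), 1.9)))
  trajs <- lapply(seq_along(sts), function(i)
    states_trajectory(list(rigid_body_state(c(0, 0, 0)), sts[[i]]), 1, sch,
                      id = paste0("m", i)))
  m <- pairwise_endpoint_rmsd(trajs, "chain A and name CA", "name CA")
  expect_equal(m, t(m), tolerance = 1e-6)
  expect_equal(diag(m), setNames(rep(0, 3), paste0("m", 1:3)))
  ifit <- select_atoms(trajs[[1]]$topology, "chain A and name CA")
  imeas <- select_atoms(trajs[[1]]$topology, "name CA")
  for (i in 1:2) for (j in (i + 1):3) {
    ei <- last_frame(trajs[[i]]); ej <- last_frame(trajs[[j]])
    fit <- kabsch_fit(ei[ifit, ], ej[ifit, ])
    moved <- sweep(ei[imeas, ] %*% t(fit$rotation), 2, fit$translation, "+")
    expect_equal(m[i, j], sqrt(mean(rowSums((moved - ej[imeas, ])^2))),
                 tolerance = 1e-9)
  }
  # identical trajectories -> zero matrix; rigid-transform endpoints -> 0
  m0 <- pairwise_endpoint_rmsd(trajs[c(1, 1)], "name CA", "name CA")
  expect_equal(max(abs(m0)), 0)
})

test_that("minimum cross-selection distance tracks a planted approach", {
  sch <- temperature_schedule(20, 303)
  # ligand approaches the receptor along z: distance ramps 10 -> 2
  dists <- seq(10, 2, length.out = 9)
  states <- lapply(dists, function(d) rigid_body_state(c(0, 0, d)))
  tr <- states_trajectory(states, 1, sch)
  s <- residue_min_distance_series(tr, "chain A", "chain B")
  expect_equal(length(s$values), 9L)
  expect_true(all(diff(s$values) < 0))
  # two atoms at constant 3 A
  top <- toy_model()
  f <- top$xyz; f[5, ] <- f[2, ] + c(3, 0, 0)
  trc <- trajectory("c", list(f, f), 1, sch, top)
  sc <- residue_min_distance_series(trc, "chain A and resid 1 and name CA",
                                    "chain B and resid 3 and name CA")
  expect_equal(sc$values, c(3, 3), tolerance = 1e-12)
  expect_error(residue_min_distance_series(trc, "name CA", "name CA"),
               "overlapping")
})
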