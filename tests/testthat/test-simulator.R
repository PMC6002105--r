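test_that("quaternion utilities handle normalization, composition and double cover", {
  q <- quat_normalize(c(-2, 1, 0.5, -0.3))
  expect_equal(sum(q^2), 1, tolerance = 1e-12)
  expect_gte(q[1], 0)                       # canonical sign
  R <- quat_to_matrix(q)
  expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
  qa <- quat_from_axis_angle(c(0, 0, 1), 0.4)
  qb <- quat_from_axis_angle(c(0, 0, 1), 0.5)
  expect_equal(quat_to_matrix(quat_multiply(qa, qb)),
               quat_to_matrix(quat_from_axis_angle(c(0, 0, 1), 0.9)),
               tolerance = 1e-12)
  expect_equal(quat_angle(q, -q), 0)        # double cover collapses
  expect_equal(quat_angle(c(1, 0, 0, 0), quat_from_axis_angle(c(1, 0, 0), 1.2)),
               1.2, tolerance = 1e-12)
})

test_that("configuration distance combines translation and geodesic rotation", {
  a <- rigid_body_state(c(0, 0, 0))
  expect_equal(configuration_distance(a, a, 10), 0)
  b <- rigid_body_state(c(3, 4, 0))
  expect_equal(configuration_distance(a, b, 10), 5)
  cq <- rigid_body_state(c(0, 0, 0), quat_from_axis_angle(c(0, 1, 0), 0.7))
  expect_equal(configuration_distance(a, cq, 10), 7, tolerance = 1e-12)
  neg <- rigid_body_state(c(0, 0, 0), -a$orientation)
  expect_equal(configuration_distance(a, neg, 10), 0)
  expect_equal(configuration_distance(b, a, 10),
               configuration_distance(a, b, 10))
})

test_that("potential energy matches closed forms and its analytic gradient", {
  kT <- kB * 303
  lone <- landscape(list(well(c(2, -1, 3), quat_from_axis_angle(c(1, 2, 0), 0.8),
                              depth = 5, width = 2, label = "native")),
                    lambda = 10, confinement_radius = 30)
  center <- rigid_body_state(c(2, -1, 3), quat_from_axis_angle(c(1, 2, 0), 0.8))
  expect_equal(potential_energy(center, lone), -5, tolerance = 1e-12)
  far <- rigid_body_state(c(25, 0, 0), quat_from_axis_angle(c(0, 0, 1), 3))
  expect_equal(potential_energy(far, lone), 0, tolerance = 1e-12)
  # quartic wall beyond the confinement radius
  out <- rigid_body_state(c(32, 0, 0))
  expect_equal(potential_energy(out, lone), 1 * (32 - 30)^4, tolerance = 1e-9)

  # analytic gradient vs central differences on a multi-well landscape
  ls <- test_landscape()
  set.seed(17)
  eps <- 1e-5
  for (i in 1:5) {
    st <- rigid_body_state(rnorm(3, 0, 10), random_quaternion())
    g <- potential_gradient(st, ls)
    for (j in 1:3) {
      tp <- st$translation; tm <- st$translation
      tp[j] <- tp[j] + eps; tm[j] <- tm[j] - eps
      num <- (potential_energy(rigid_body_state(tp, st$orientation), ls) -
              potential_energy(rigid_body_state(tm, st$orientation), ls)) /
             (2 * eps)
      expect_equal(g$translation[j], num, tolerance = 1e-5)
      ax <- c(0, 0, 0); ax[j] <- 1
      qp <- quat_multiply(st$orientation, quat_from_axis_angle(ax, eps))
      qm <- quat_multiply(st$orientation, quat_from_axis_angle(ax, -eps))
      numr <- (potential_energy(rigid_body_state(st$translation, qp), ls) -
               potential_energy(rigid_body_state(st$translation, qm), ls)) /
              (2 * eps)
      expect_equal(g$rotation[j], numr, tolerance = 1e-5)
    }
  }
})

test_that("landscape constructor enforces the native well and confinement margin", {
  expect_error(landscape(list(well(c(0, 0, 0), depth = 1, width = 1,
                                   label = "trap")),
                         confinement_radius = 20), "exactly one native")
  w <- well(c(0, 0, 0), depth = 1, width = 2, label = "native")
  expect_error(landscape(list(w, w), confinement_radius = 20),
               "exactly one native")
  expect_error(landscape(list(w), confinement_radius = 5), "confinement_radius")
  expect_error(well(c(0, 0, 0), depth = -1, width = 1, label = "native"),
               "depth")
  f <- withr::local_tempfile(fileext = ".yaml")
  ls <- test_landscape()
  write_landscape(ls, f)
  back <- read_landscape(f)
  expect_equal(length(back$wells), 3L)
  expect_equal(back$lambda, ls$lambda)
  expect_equal(back$wells[[3]]$depth, ls$wells[[3]]$depth, tolerance = 1e-7)
})

test_that("zero-temperature dynamics is pure gradient descent", {
  ls <- test_landscape()
  p <- sim_params()
  center <- rigid_body_state(c(0, 0, 0))
  stepped <- langevin_step(center, ls, p, 0)
  expect_equal(stepped$translation, center$translation, tolerance = 1e-9)
  expect_equal(abs(sum(stepped$orientation * center$orientation)), 1,
               tolerance = 1e-9)
  # from a flank, the configuration distance decreases monotonically
  st <- rigid_body_state(c(4, 0, 0), quat_from_axis_angle(c(0, 1, 0), 0.3))
  d_prev <- configuration_distance(st, center, ls$lambda)
  for (i in 1:300) {
    st <- langevin_step(st, ls, p, 0)
    d <- configuration_distance(st, center, ls$lambda)
    expect_lte(d, d_prev + 1e-12)
    d_prev <- d
  }
  expect_lt(d_prev, 4)
})

test_that("step-size validation rejects too-coarse integration", {
  ls <- test_landscape()
  expect_error(simulate_trajectory(rigid_body_state(c(0, 0, 0)), ls,
                                   sim_params(dt = 0.05),
                                   temperature_schedule(1, 303)),
               "dt too large")
})

test_that("rendering is rigid, deterministic and anchored to the native pose", {
  lig <- default_ligand_template(); rec <- default_receptor_template()
  id_frame <- render_frame(rigid_body_state(c(0, 0, 0)), lig, rec)
  expect_equal(id_frame[21:30, ], unname(lig))
  expect_equal(id_frame[1:20, ], unname(rec))
  # equal configuration -> identical frames (quaternion sign invariance)
  q <- quat_from_axis_angle(c(1, 1, 1), 2.2)
  f1 <- render_frame(rigid_body_state(c(3, 2, 1), q))
  f2 <- render_frame(rigid_body_state(c(3, 2, 1), -q))
  expect_equal(f1, f2, tolerance = 1e-12)
  # ligand template has non-degenerate inertia
  sv <- svd(sweep(lig, 2, colMeans(lig)))$d
  expect_gt(sv[3] / sv[1], 0.05)
  # RMSD between rendered frames grows monotonically along a geodesic path
  a <- rigid_body_state(c(0, 0, 0))
  b <- rigid_body_state(c(6, -3, 2), quat_from_axis_angle(c(0.3, 1, 0.2), 1.8))
  fa <- render_frame(a)
  lastr <- -Inf
  for (s in seq(0, 1, length.out = 20)) {
    qs <- quat_from_axis_angle(c(0.3, 1, 0.2), 1.8 * s)
    ws <- rigid_body_state(s * b$translation, qs)
    r <- rmsd(render_frame(ws), fa, superpose = FALSE)
    expect_gte(r, lastr - 1e-9)
    lastr <- r
  }
})

test_that("simulation is bit-reproducible for a given seed", {
  ls <- test_landscape()
  p <- sim_params(seed = 5)
  sch <- temperature_schedule(1, 303)
  s1 <- simulate_trajectory(rigid_body_state(c(2, 0, 0)), ls, p, sch)
  s2 <- simulate_trajectory(rigid_body_state(c(2, 0, 0)), ls, p, sch)
  expect_identical(s1$states$translations, s2$states$translations)
  expect_identical(s1$states$quaternions, s2$states$quaternions)
  s3 <- simulate_trajectory(rigid_body_state(c(2, 0, 0)), ls, p, sch, seed = 6)
  expect_false(identical(s1$states$translations, s3$states$translations))
  # frames count and spacing respect frames_per_save
  expect_equal(length(s1$trajectory$frames),
               round(1 / p$dt) %/% p$frames_per_save + 1)
  expect_equal(s1$trajectory$frame_spacing, p$dt * p$frames_per_save)
})

test_that("benchmark sets are labelled, placed by class, and reproducible", {
  ls <- test_landscape()
  sch <- ladder_schedule(base_ns = 4, rung_ns = 2, final_rung_ns = 2)
  b <- make_benchmark_set(ls, c(native = 1, funnel_interior = 2, trap = 3,
                                unstable = 4),
                          jitter = 0.5, seed = 7, schedule = sch)
  expect_length(b$models, 10L)
  expect_equal(unname(table(b$truth_labels)[c("native", "funnel_interior",
                                              "trap", "unstable")]),
               c(1L, 2L, 3L, 4L), ignore_attr = TRUE)
  nat0 <- rigid_body_state(c(0, 0, 0))
  # native decoy within jitter of the native center
  nid <- names(b$truth_labels)[b$truth_labels == "native"]
  expect_lte(configuration_distance(b$states[[nid]], nat0, ls$lambda), 0.5)
  expect_lt(rmsd(b$models[[nid]]$xyz, b$reference$xyz), 0.5)
  # trap decoys within jitter of the trap pose
  tw <- ls$wells[[3]]
  trap_pose <- rigid_body_state(tw$center_translation, tw$center_orientation)
  for (id in names(b$truth_labels)[b$truth_labels == "trap"])
    expect_lte(configuration_distance(b$states[[id]], trap_pose, ls$lambda),
               0.5 + 1e-9)
  # funnel decoys at 2-4 basin widths
  bw <- decoysieve:::basin_well(ls)
  for (id in names(b$truth_labels)[b$truth_labels == "funnel_interior"]) {
    d <- configuration_distance(b$states[[id]], nat0, ls$lambda)
    expect_gte(d, 2 * bw$width - 1e-9)
    expect_lte(d, 4 * bw$width + 1e-9)
  }
  # unstable decoys in the flat region, away from every well
  for (id in names(b$truth_labels)[b$truth_labels == "unstable"]) {
    tr <- b$states[[id]]$translation
    for (w in ls$wells)
      expect_gte(sqrt(sum((tr - w$center_translation)^2)), 5 * w$width)
  }
  b2 <- make_benchmark_set(ls, c(native = 1, funnel_interior = 2, trap = 3,
                                 unstable = 4),
                           jitter = 0.5, seed = 7, schedule = sch)
  expect_identical(lapply(b$states, `[[`, "translation"),
                   lapply(b2$states, `[[`, "translation"))
  # native model renders identically to the reference at zero jitter
  b0 <- make_benchmark_set(ls, c(native = 1), jitter = 1e-9, seed = 1,
                           schedule = sch)
  expect_lt(rmsd(b0$models[[1]]$xyz, b0$reference$xyz), 1e-6)
  no_trap <- landscape(list(well(c(0, 0, 0), depth = 1, width = 2,
                                 label = "native")), confinement_radius = 20)
  expect_error(make_benchmark_set(no_trap, c(trap = 1)), "no trap well")
  expect_error(make_benchmark_set(ls, c(bogus = 1)), "n_per_class")
})
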