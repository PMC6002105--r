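test_that("drift classification requires a sustained excursion", {
  cfg <- assessment_config()
  s <- make_series(rep(0.8, 12))
  out <- drift_classify(s, cfg)
  expect_false(out$escaped)
  expect_true(is.na(out$escape_time))
  expect_equal(out$max_drift, 0.8)

  cfg3 <- assessment_config(dwell_frames = 3)
  s2 <- make_series(c(1, 1, 3, 3, 3, 3, 3))
  out2 <- drift_classify(s2, cfg3)
  expect_true(out2$escaped)
  expect_equal(out2$escape_time, 2)   # time of the first 3 A frame

  # single-frame spike filtered at dwell 5
  s3 <- make_series(c(1, 1, 4, 1, 1, 1, 1, 1))
  out3 <- drift_classify(s3, cfg)
  expect_false(out3$escaped)
  expect_equal(out3$max_drift, 4)

  expect_error(drift_classify(make_series(c(1, 2, 3)), cfg), "dwell_frames")
})

test_that("escape is monotone in the drift threshold", {
  set.seed(99)
  for (i in 1:20) {
    v <- abs(cumsum(rnorm(60, 0.05, 0.5)))
    s <- make_series(v)
    prev <- drift_classify(s, assessment_config(drift_threshold = 1.5,
                                                dwell_frames = 3))
    for (thr in c(2.5, 3.5, 5)) {
      cur <- drift_classify(s, assessment_config(drift_threshold = thr,
                                                 dwell_frames = 3))
      if (cur$escaped) {
        expect_true(prev$escaped)          # raising thr never creates escapes
        expect_lte(prev$escape_time, cur$escape_time)
      }
      prev <- cur
    }
  }
})

test_that("binding events need entry plus residence, tolerating brief excursions", {
  cfg <- assessment_config()
  # ramp 8 -> 0.9 crossing the band at t = 50 and staying
  v <- c(seq(8, 1.5, length.out = 50), rep(c(1.0, 0.9), 15))
  s <- make_series(v)
  expect_equal(detect_binding_event(s, cfg), 50)
  # oscillation around 5 A never binds
  expect_true(is.na(detect_binding_event(
    make_series(5 + sin(1:80)), cfg)))
  # short excursion out of band does not cancel the event
  v2 <- c(rep(3, 10), rep(1, 20), c(2, 2), rep(1, 20))
  expect_equal(detect_binding_event(make_series(v2), cfg), 10)
  # sustained exit cancels an earlier entry; later re-entry wins
  v3 <- c(rep(1, 10), rep(4, 10), rep(1, 12))
  expect_equal(detect_binding_event(make_series(v3), cfg), 20)
  # sustained exit with no qualifying re-entry -> none
  v4 <- c(rep(1, 10), rep(4, 10), rep(1, 3))
  expect_true(is.na(detect_binding_event(make_series(v4), cfg)))
})

test_that("assess_decoy assigns the four labels from schedule context", {
  lad <- ladder_schedule(base_ns = 8, rung_ns = 4, final_rung_ns = 4)  # 20 ns
  ref_state <- rigid_body_state(c(0, 0, 0))
  ref <- render_model(ref_state, "xtal")
  cfg <- assessment_config()
  spacing <- 0.5

  # thermal jitter within 1 A of the reference through the whole ladder
  set.seed(42)
  jit <- lapply(1:40, function(i)
    rigid_body_state(rnorm(3, 0, 0.3)))
  v <- assess_decoy(states_trajectory(jit, spacing, lad, id = "r37"),
                    render_model(jit[[1]], "r37"), ref, cfg)
  expect_equal(v$label, "CONVERGED_TO_REFERENCE")
  v_nr <- assess_decoy(states_trajectory(jit, spacing, lad, id = "r37"),
                       render_model(jit[[1]], "r37"), NULL, cfg)
  expect_equal(v_nr$label, "STABLE_CANDIDATE")
  expect_true(is.na(v_nr$final_rmsd_to_reference))

  # flat during base + first two rungs, escaping in the third rung (363 K)
  far <- rigid_body_state(c(25, 0, 0))
  hold <- lapply(1:25, function(i) far)                     # flat through 12 ns
  gone <- lapply(seq_len(15), function(k)
    rigid_body_state(c(25 + 3 * k, 0, 0)))                  # rapid exit at 363 K
  v2 <- assess_decoy(states_trajectory(c(hold, gone), spacing, lad, id = "r23"),
                     render_model(far, "r23"), ref, cfg)
  expect_equal(v2$label, "METASTABLE")
  expect_equal(v2$escape_temperature, 363)
  expect_gt(v2$escape_time, 12)

  # escape during the base segment -> UNSTABLE
  drift <- lapply(seq(0, 19.5, by = 0.5), function(t)
    rigid_body_state(c(25 + t, 0, 0)))
  v3 <- assess_decoy(states_trajectory(drift, spacing, lad, id = "u"),
                     render_model(drift[[1]], "u"), ref, cfg)
  expect_equal(v3$label, "UNSTABLE")
  expect_equal(v3$escape_temperature, 303)

  # wrong start sliding into the native pose -> CONVERGED overrides UNSTABLE
  slide <- lapply(seq(0, 1, length.out = 40), function(f)
    rigid_body_state((1 - f) * c(8, 0, 0)))
  v4 <- assess_decoy(states_trajectory(slide, spacing, lad, id = "r44"),
                     render_model(slide[[1]], "r44"), ref, cfg)
  expect_equal(v4$label, "CONVERGED_TO_REFERENCE")
  expect_false(is.na(v4$binding_time))
  expect_lte(v4$final_rmsd_to_reference, cfg$native_band)
  expect_gt(v4$max_drift, cfg$drift_threshold)
})

test_that("base-only trajectories can never be METASTABLE and verdicts are deterministic", {
  base_only <- temperature_schedule(10, 303)
  ref <- render_model(rigid_body_state(c(0, 0, 0)), "xtal")
  cfg <- assessment_config()
  set.seed(77)
  for (i in 1:5) {
    walk <- Reduce(function(s, .) rigid_body_state(s$translation + rnorm(3, 0, 1.5)),
                   1:19, init = rigid_body_state(c(10, 0, 0)), accumulate = TRUE)
    tr <- states_trajectory(walk, 0.5, base_only, id = paste0("w", i))
    v <- assess_decoy(tr, render_model(walk[[1]], "w"), ref, cfg)
    expect_true(v$label != "METASTABLE")
    v_again <- assess_decoy(tr, render_model(walk[[1]], "w"), ref, cfg)
    expect_identical(verdicts_to_df(v), verdicts_to_df(v_again))
  }
})

test_that("cohort summaries count labels and order candidates", {
  mk <- function(id, label, esc_t = NA_real_, esc_T = NA_real_,
                 bind = NA_real_, maxd = 1, final = NA_real_) {
    structure(list(model_id = id, label = label, escape_time = esc_t,
                   escape_temperature = esc_T, binding_time = bind,
                   max_drift = maxd, final_rmsd_to_reference = final),
              class = "decoy_verdict")
  }
  vs <- c(lapply(1:38, function(i) mk(paste0("r", i), "UNSTABLE", 3, 303,
                                      maxd = 6)),
          lapply(39:45, function(i) mk(paste0("r", i), "METASTABLE", 40, 363,
                                       maxd = 4)),
          list(mk("r46", "STABLE_CANDIDATE", maxd = 1.2, final = 1.1),
               mk("r47", "STABLE_CANDIDATE", maxd = 0.9, final = 0.8),
               mk("r48", "CONVERGED_TO_REFERENCE", bind = 50, maxd = 8,
                  final = 0.7),
               mk("r49", "CONVERGED_TO_REFERENCE", bind = 30, maxd = 9,
                  final = 0.9),
               mk("r50", "UNSTABLE", 2, 303, maxd = 7)))
  s <- summarize_cohort(vs)
  expect_equal(s$n, 50L)
  expect_equal(unname(s$counts["UNSTABLE"]), 39L)
  expect_equal(unname(s$counts["METASTABLE"]), 7L)
  expect_equal(s$candidates$model_id[1], "r48")  # lowest final rmsd first
  expect_equal(s$converged$model_id, c("r49", "r48"))  # binding time order
  expect_error(summarize_cohort(list()), "empty")

  # empty candidate set: no crash, empty section
  s2 <- summarize_cohort(lapply(1:3, function(i) mk(paste0("x", i),
                                                    "UNSTABLE", 1, 303)))
  expect_equal(nrow(s2$candidates), 0L)
  f <- withr::local_tempfile(fileext = ".md")
  write_cohort_report(s2, f)
  expect_true(any(grepl("UNSTABLE: 3", readLines(f))))
})

test_that("assessment config validates thresholds and reads presets from file", {
  expect_error(assessment_config(drift_threshold = 1, native_band = 1.4),
               "drift_threshold")
  expect_error(assessment_config(max_temperature = 200), "max_temperature")
  efb <- assessment_config(preset = "efb")
  expect_equal(efb$drift_threshold, 3.2)
  expect_equal(efb$native_band, 2.5)
  expect_equal(assessment_config(preset = "efb_positive")$native_band, 2.0)
  g3 <- assessment_config(preset = "g3")
  expect_equal(g3$drift_threshold, 2.5)
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("drift_threshold: 3.2", "native_band: 2.5",
               "dwell_frames: 4"), f)
  cfg <- read_assessment_config(f)
  expect_equal(cfg$drift_threshold, 3.2)
  expect_equal(cfg$dwell_frames, 4L)
  writeLines("bogus_key: 1", f)
  expect_error(read_assessment_config(f), "unknown")
})
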