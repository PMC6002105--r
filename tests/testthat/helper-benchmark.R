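# seeded benchmark sweep shared by the label-recovery and nomination
# checks; computed once per test run
.sweep_cache <- new.env(parent = emptyenv())

benchmark_sweep <- function(n_seeds = 20L) {
  key <- paste0("s", n_seeds)
  if (!is.null(.sweep_cache[[key]])) return(.sweep_cache[[key]])
  ls <- default_landscape()
  p <- sim_params()
  sch <- ladder_schedule()
  cfg <- assessment_config()
  runs <- lapply(seq_len(n_seeds), function(seed) {
    b <- make_benchmark_set(ls, c(native = 1, funnel_interior = 2,
                                  trap = 3, unstable = 4),
                            jitter = 0.5, seed = seed, params = p,
                            schedule = sch)
    trajs <- simulate_benchmark(b)
    verdicts <- lapply(names(trajs), function(id)
      assess_decoy(trajs[[id]], b$models[[id]], b$reference, cfg))
    labels <- vapply(verdicts, `[[`, character(1), "label")
    names(labels) <- names(trajs)
    pairs <- pair_table(b$models, trajs)
    pairs <- flag_funnel_signature(pairs, final_cutoff = cfg$native_band,
                                   delta_cutoff = -2)
    nom <- nominate_best_model(pairs)
    list(truth = b$truth_labels, labels = labels, pairs = pairs,
         nomination = nom)
  })
  .sweep_cache[[key]] <- runs
  runs
}

# verdict labels accepted for each planted class
label_ok <- function(truth, label) {
  switch(truth,
    unstable        = label == "UNSTABLE",
    trap            = label == "METASTABLE",
    funnel_interior = label %in% c("CONVERGED_TO_REFERENCE",
                                   "STABLE_CANDIDATE"),
    native          = label %in% c("STABLE_CANDIDATE",
                                   "CONVERGED_TO_REFERENCE"))
}
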