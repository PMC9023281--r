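# shared small fixtures, built once per test run

canonical_motor <- function(v = 63, p_knt = 3.9, init = 15000,
                            start_frame = 3) {
  mot <- data.frame(motor = 1L, init_position_nt = init,
                    velocity_nt_s = v, processivity_knt = p_knt,
                    start_frame = start_frame)
  class(mot) <- c("motor_truth", "data.frame")
  mot
}

# one clean mid-speed clearance stack reused across files
.cfg_small <- sim_config(n_frames = 30, span_px = 80,
                         molecule_length_knt = 16.4)
.stk_clean <- render_kymograph(canonical_motor(), .cfg_small, noise = FALSE)
.stk_noisy <- render_kymograph(canonical_motor(), .cfg_small, seed = 42)

run_small_population <- function(n, seed, mode = "rpa", model = "gaussian",
                                 med_v = 63, iqr_v = c(28, 117),
                                 med_p = 3.9, iqr_p = c(2.7, 5.1),
                                 n_frames = 60, gain_green = 120) {
  cfg <- sim_config(n_frames = n_frames, gain_green = gain_green)
  pop <- motor_population(med_v, iqr_v, med_p, iqr_p, n)
  mot <- sample_motors(pop, cfg, seed = seed)
  ev <- do.call(rbind, lapply(seq_len(n), function(i) {
    stk <- render_kymograph(mot[i, ], cfg, mode = mode,
                            seed = seed * 1000L + i)
    tr <- build_trace(stk, model = model)
    tryCatch(motor_event(tr, paste0("mol", i)), error = function(e) NULL)
  }))
  attr(ev, "motors") <- mot
  ev
}
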