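# Shared fixtures: tiny ROI tables built in code.

# one hand-written ROI row with controllable intensities
roi_row <- function(roi_id = 1, condition = "test", environment = "live",
                    cfp_pre = c(80, 80), cfp_post = c(100, 100),
                    yfp_pre = 100, yfp_post = 10, ground_truth_E = NA_real_) {
  tibble::tibble(
    roi_id = roi_id, condition = condition, environment = environment,
    I_cfp_pre_1 = cfp_pre[1], I_cfp_pre_2 = cfp_pre[2],
    I_cfp_post_1 = cfp_post[1], I_cfp_post_2 = cfp_post[2],
    I_yfp_pre = yfp_pre, I_yfp_post = yfp_post,
    ground_truth_E = ground_truth_E
  )
}

# noise-free population config (for exact round-trip checks)
noiseless <- function(geometry, ...) {
  population_config(geometry, noise_cv = 0, offset_noise_frac = 0,
                    detector_offset = 0, bleed_through_beta = 0, ...)
}

# protocol that destroys essentially every acceptor
full_bleach <- function() bleach_protocol("live", iterations = 40L,
                                          per_iteration_survival = 0.27)
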