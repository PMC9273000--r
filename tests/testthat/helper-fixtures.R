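# Shared fixtures: fast phantom configurations and independent oracles.

# A small, quick phantom: 96 x 96 px over a 40 um field.
small_config <- function(seed = 1L, ...) {
  phantom_config(grid = c(96L, 96L), pixel_size = 40 / 96,
                 aggregate_radius = 1.5, n_aggregates = 4,
                 seed = seed, ...)
}

# A mid-size phantom used where per-ROI counting precision matters.
medium_config <- function(seed = 1L, ...) {
  phantom_config(grid = c(192L, 192L), pixel_size = 40 / 192, seed = seed, ...)
}

# Hand-built two-channel pt_run stack from explicit matrices.
tiny_pt_stack <- function(pt, c2, pixel_size = 0.1, dwell_time = 1,
                          sample_id = "tiny", exposure = 25) {
  acquisition_stack(list(ion_count_map(pt, "194Pt", pixel_size, dwell_time),
                         ion_count_map(c2, "12C2", pixel_size, dwell_time)),
                    sample_id = sample_id, run_type = "pt_run",
                    exposure_concentration = exposure)
}

# Independent textbook oracle for the pooled-variance two-sample t-test.
student_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Assemble per-ROI (q, x) rows from a phantom triple with an aligned mask
# and a known control abundance (bypasses registration; used by module
# tests that probe the isotope layer in isolation).
phantom_qx_rows <- function(triple, a_ctr = 0.003676, a_cddp = 0.99) {
  mask <- triple$truth$mask
  ptc <- extract_roi_counts(triple$pt_run, mask)
  nc <- extract_roi_counts(triple$n_run, mask)
  ab <- abundance_15n(nc)
  qt <- pt_nitrogen_index(ptc, nc)
  conc <- triple$concentration
  if (is.null(conc)) conc <- triple$pt_run$exposure_concentration
  data.frame(compartment = ptc$compartment,
             concentration = conc,
             roi_id = ptc$roi_id, q = qt$q,
             x = (ab$a - a_ctr) / (a_cddp - a_ctr),
             sigma_q = qt$sigma_q,
             sigma_x = ab$sigma / (a_cddp - a_ctr))
}
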