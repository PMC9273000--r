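test_that("15N abundance and its counting error follow the binomial form", {
  expect_equal(abundance_15n(500, 500)$a, 0.5)
  expect_equal(abundance_15n(0, 300)$a, 1)
  expect_equal(abundance_15n(0, 300)$sigma, 0)
  ab <- abundance_15n(1e6, 3690)
  expect_equal(ab$a, 3690 / 1003690)
  expect_equal(ab$a, 3.676e-3, tolerance = 1e-3)
  expect_equal(ab$sigma, sqrt(ab$a * (1 - ab$a) / 1003690))
  expect_equal(ab$sigma, 6.05e-5, tolerance = 1e-2)
  expect_error(abundance_15n(0, 0), "zero total")

  # Monte-Carlo cross-check of the error formula at tracer-level abundance
  set.seed(77)
  tot <- 2e5; a_true <- 0.004
  n15 <- rbinom(20000, tot, a_true)
  emp <- sd(n15 / tot)
  expect_lt(abs(emp - sqrt(a_true * (1 - a_true) / tot)) / emp, 0.05)
})

test_that("label fraction mixing model has exact endpoints and is affine", {
  a_ctr <- 0.00364; a_cddp <- 0.99
  expect_equal(label_fraction(a_ctr, a_ctr, a_cddp)$x, 0)
  expect_equal(label_fraction(a_cddp, a_ctr, a_cddp)$x, 1)
  lf <- label_fraction(0.0040345, a_ctr, a_cddp)
  expect_equal(lf$x, 4.00e-4, tolerance = 1e-3)
  # affine in a_tot to machine precision
  a <- seq(a_ctr, a_cddp, length.out = 11)
  x <- label_fraction(a, a_ctr, a_cddp)$x
  expect_equal(diff(x) / diff(a), rep(1 / (a_cddp - a_ctr), 10))
  expect_equal(max(abs(diff(diff(x)))), 0, tolerance = 1e-15)
  # error scaling
  ab <- abundance_15n(1e6, 4000)
  expect_equal(label_fraction(ab, a_ctr, a_cddp)$sigma_x,
               ab$sigma / (a_cddp - a_ctr))
  expect_error(label_fraction(0.5, 0.9, 0.4), "configuration")
})

test_that("marginally negative fractions are clipped with a flag, not silently", {
  ab <- abundance_15n(1e6, 3600)  # a slightly below a_ctr
  lf <- label_fraction(ab, 0.003676, 0.99)
  expect_true(lf$clipped)
  expect_equal(lf$x, 0)
  expect_lt(lf$x_raw, 0)
  # far below the baseline is an error, not a clip
  expect_error(label_fraction(0.0030, 0.003676, 0.99), "below the control")
  expect_error(label_fraction(0.9999, 0.003676, 0.99), "purity")
})

test_that("Pt/N index reproduces direct arithmetic and its invariances", {
  pt_roi <- data.frame(roi_id = "r", compartment = "nucleolus",
                       "194Pt" = 500, "12C2" = 10000, check.names = FALSE)
  n_roi <- data.frame(roi_id = "r", compartment = "nucleolus",
                      "12C14N" = 249000, "12C15N" = 1000, "12C2" = 10000,
                      check.names = FALSE)
  qt <- pt_nitrogen_index(pt_roi, n_roi)
  expect_equal(qt$q, 0.05 / 25)  # (Pt/C2)_pt / (CN/C2)_avg
  expect_equal(qt$sigma_q,
               0.002 * sqrt(1 / 500 + 1 / 10000 + 1 / 250000 + 1 / 10000))
  # no analyte -> q = 0
  pt0 <- pt_roi; pt0$`194Pt` <- 0
  expect_equal(pt_nitrogen_index(pt0, n_roi)$q, 0)
  # per-run multiplicative gains cancel to machine precision
  g_pt <- 3; g_n <- 7
  pt_g <- pt_roi; pt_g$`194Pt` <- pt_g$`194Pt` * g_pt
  pt_g$`12C2` <- pt_g$`12C2` * g_pt
  n_g <- n_roi
  for (ch in c("12C14N", "12C15N", "12C2")) n_g[[ch]] <- n_g[[ch]] * g_n
  expect_equal(pt_nitrogen_index(pt_g, n_g)$q, qt$q, tolerance = 1e-14)
  # zero reference -> error
  ptz <- pt_roi; ptz$`12C2` <- 0
  expect_error(pt_nitrogen_index(ptz, n_roi), "12C2")
  # roi present only in pt run -> error naming it
  pt2 <- rbind(pt_roi, pt_roi)
  pt2$roi_id[2] <- "r2"
  expect_error(pt_nitrogen_index(pt2, n_roi), "r2")
})

test_that("sigma_q matches Monte-Carlo resampling of all four counts", {
  set.seed(88)
  counts <- c(pt = 500, c2pt = 10000, cn = 250000, c2n = 10000)
  qs <- replicate(10000, {
    (rpois(1, counts["pt"]) / rpois(1, counts["c2pt"])) /
      (rpois(1, counts["cn"]) / rpois(1, counts["c2n"]))
  })
  form <- 0.002 * sqrt(sum(1 / counts))
  expect_lt(abs(sd(qs) - form) / form, 0.05)
})

test_that("curves aggregate ROI replicates into ordered points", {
  pts <- data.frame(compartment = "nucleolus",
                    concentration = rep(c(50, 0, 10), each = 3),
                    roi_id = paste0("r", 1:9),
                    q = rep(c(5, 0, 1), each = 3) * 1e-4 + rep(c(1, 2, 3) * 1e-6, 3),
                    x = c(1, 2, 3, 0, 0, 0, 1, 1, 1) * 1e-4)
  cv <- build_curve(pts, "nucleolus")
  expect_equal(cv$points$concentration, c(0, 10, 50))
  expect_equal(cv$points$x_mean[3], 2e-4)
  expect_equal(cv$points$x_sd[3], 1e-4)
  expect_equal(cv$points$n_roi, rep(3L, 3))
  expect_error(build_curve(pts, "mitochondria"), "empty curve")
})

test_that("slope fitting is exact on collinear points and flags degeneracy", {
  pts <- data.frame(compartment = "cytoplasm", concentration = c(0, 50, 100),
                    roi_id = c("a", "b", "c"),
                    q = c(0, 0.001, 0.002), x = c(0, 2e-4, 4e-4))
  f <- fit_slope(build_curve(pts, "cytoplasm"))
  expect_equal(f$slope, 0.2, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$slope_origin, 0.2, tolerance = 1e-12)
  pts$q <- 0.001
  expect_error(fit_slope(build_curve(pts, "cytoplasm")), "underdetermined")
})

test_that("calibration converts slope to atom ratio exactly on truth points", {
  # closed-form construction: the generator's ground-truth (q, x) pairs are
  # exactly collinear with slope L / (rsf_pt/rsf_n)
  cfg <- small_config(seed = 31L, rsf = c(pt = 6, n = 2),
                      ligand_number = c(cytoplasm = 2, nucleus = 2,
                                        nucleolus = 2, chromatin = 2,
                                        aggregate = 2))
  conc <- c(0, 10, 50, 150)
  truths <- lapply(conc, function(cc) {
    c2 <- cfg; c2$drug_load <- nanostoich:::.default_drug_rates * cc
    .rates <- nanostoich:::.phantom_rates(c2)$truth
    data.frame(compartment = .rates$compartment, concentration = cc,
               roi_id = paste0(.rates$compartment, cc),
               q = .rates$pt_index, x = .rates$label_fraction)
  })
  pts <- do.call(rbind, truths)
  f <- fit_slope(build_curve(pts[pts$compartment == "nucleolus", ], "nucleolus"))
  cal <- calibrate_stoichiometry(f, c(pt = 6, n = 2))
  expect_equal(cal$ratio, 2, tolerance = 1e-10)
  # doubling both sensitivity factors leaves the ratio unchanged
  cal2 <- calibrate_stoichiometry(f, c(pt = 12, n = 4))
  expect_equal(cal2$ratio, cal$ratio)
  expect_equal(calibrate_stoichiometry(0, c(pt = 6, n = 2))$ratio, 0)
  uncal <- calibrate_stoichiometry(f, NULL)
  expect_false(uncal$calibrated)
  expect_true(is.na(uncal$ratio))
})

test_that("phantom label fractions are recovered within combined errors", {
  # per-compartment mean recovered x vs truth over 50 seeds; every ROI here
  # exceeds 1e4 summed CN counts so the propagated errors are in their
  # Gaussian regime
  n_seeds <- 50L
  comps <- c("cytoplasm", "nucleus", "nucleolus", "chromatin", "aggregate")
  err <- matrix(NA_real_, n_seeds, length(comps), dimnames = list(NULL, comps))
  sig <- err
  truth_x <- NULL
  for (k in seq_len(n_seeds)) {
    cfg <- small_config(seed = 500L + k, drug_load = c(
      cytoplasm = 0.8, nucleus = 1, nucleolus = 5, chromatin = 1.2,
      aggregate = 3))
    tri <- generate_phantom(cfg)
    rows <- phantom_qx_rows(tri)
    tr <- tri$truth$compartments
    truth_x <- tr$label_fraction[match(comps, tr$compartment)]
    for (cm in comps) {
      sel <- rows$compartment == cm
      err[k, cm] <- mean(rows$x[sel]) - truth_x[match(cm, comps)]
      sig[k, cm] <- mean(rows$sigma_x[sel]) / sqrt(sum(sel))
    }
  }
  for (cm in comps) {
    se_mean <- sqrt(mean(sig[, cm]^2) / n_seeds)
    expect_lt(abs(mean(err[, cm])), 3 * se_mean)
  }
  # and the true fractions stay below 1e-3 at study-scale settings
  expect_lt(max(truth_x), 1e-3)
})
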