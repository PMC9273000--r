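test_that("identical seed gives bit-identical phantoms", {
  a <- generate_phantom(small_config(seed = 42L))
  b <- generate_phantom(small_config(seed = 42L))
  expect_identical(lapply(a$pt_run$maps, `[[`, "counts"),
                   lapply(b$pt_run$maps, `[[`, "counts"))
  expect_identical(lapply(a$n_run$maps, `[[`, "counts"),
                   lapply(b$n_run$maps, `[[`, "counts"))
  expect_identical(a$truth$mask$labels, b$truth$mask$labels)
  c <- generate_phantom(small_config(seed = 43L))
  expect_false(identical(a$pt_run$maps[["12C2"]]$counts,
                         c$pt_run$maps[["12C2"]]$counts))
})

test_that("zero drug load gives every compartment the control abundance", {
  cfg <- small_config(seed = 7L, drug_load = c(cytoplasm = 0),
                      exposure_concentration = 0)
  tri <- generate_phantom(cfg)
  nc <- extract_roi_counts(tri$n_run, tri$truth$mask)
  ab <- abundance_15n(nc)
  # every ROI abundance within 3 counting errors of natural abundance
  expect_true(all(abs(ab$a - cfg$a_ctr) < 3 * ab$sigma + 1e-12))
  expect_true(all(tri$truth$compartments$label_fraction == 0))
  expect_true(tri$pt_run$is_control)
})

test_that("ROI-summed counts match configured Poisson rates", {
  cfg <- small_config(seed = 9L, drug_load = c(nucleolus = 5))
  tri <- generate_phantom(cfg)
  mask <- tri$truth$mask
  ptc <- extract_roi_counts(tri$pt_run, mask)
  i <- which(ptc$compartment == "nucleolus")
  expected <- 5 * ptc$pixel_count[i]
  expect_lt(abs(ptc[["194Pt"]][i] - expected), 3 * sqrt(expected))
  # dispersion index ~ 1 within a homogeneous compartment (Poisson property)
  px <- tri$pt_run$maps[["12C2"]]$counts[mask$labels == 1L]
  disp <- var(px) / mean(px)
  expect_lt(abs(disp - 1), 4 * sqrt(2 / length(px)))
})

test_that("truth table is the closed-form rate arithmetic", {
  cfg <- small_config(seed = 2L, drug_load = c(nucleolus = 4, cytoplasm = 1),
                      ligand_number = c(nucleolus = 1, cytoplasm = 2),
                      rsf = c(pt = 8, n = 2))
  tr <- generate_phantom(cfg, runs = "pt_run")$truth$compartments
  cn_nucl <- cfg$base_yields["nucleolus", "CN"] + 1 * 4 / 4
  expect_equal(tr$label_fraction[tr$compartment == "nucleolus"], 1 / cn_nucl)
  expect_equal(tr$pt_index[tr$compartment == "nucleolus"], 4 / cn_nucl)
  cn_cyt <- cfg$base_yields["cytoplasm", "CN"] + 2 * 1 / 4
  expect_equal(tr$label_fraction[tr$compartment == "cytoplasm"], 0.5 / cn_cyt)
  # label fraction / pt index = ligand_number / rsf ratio, exactly
  expect_equal(tr$label_fraction / ifelse(tr$pt_index > 0, tr$pt_index, 1),
               ifelse(tr$pt_index > 0, tr$stoichiometry / 4, 0))
})

test_that("geometry that does not fit the grid is rejected", {
  expect_error(phantom_config(grid = c(64L, 64L), pixel_size = 0.1,
                              cell_radius = 9), "does not fit")
  expect_error(small_config(nucleolus_radius = 6), "nucleolus")
  expect_error(small_config(nucleus_radius = 10), "nucleus")
  expect_error(small_config(ligand_number = c(nucleolus = 5)), "ligand_number")
})

test_that("mask geometry is nested and aggregates sit in the cytoplasm", {
  tri <- generate_phantom(small_config(seed = 6L), runs = "pt_run")
  mask <- tri$truth$mask
  leg <- mask$legend
  lab <- mask$labels
  expect_setequal(unique(leg$compartment),
                  c("cytoplasm", "nucleus", "nucleolus", "chromatin", "aggregate"))
  # exactly one label per pixel by construction; non-empty compartments
  counts <- table(factor(lab[lab > 0], levels = leg$label))
  expect_true(all(counts > 0))
  # aggregates are separate ROIs of the same compartment
  expect_equal(sum(leg$compartment == "aggregate"), 4L)
})

test_that("inter-run shift translates the n_run geometry; (0,0) aligns", {
  cfg0 <- small_config(seed = 11L)
  tri0 <- generate_phantom(cfg0)
  # with zero shift the same mask applies to both runs: nucleolus CN signal
  # concentrated where the mask says
  mask <- tri0$truth$mask
  nc <- extract_roi_counts(tri0$n_run, mask)
  cn_nucl <- nc[["12C14N"]][nc$compartment == "nucleolus"] /
    nc$pixel_count[nc$compartment == "nucleolus"]
  expect_gt(cn_nucl, 0.8 * cfg0$base_yields["nucleolus", "CN"])

  cfg <- small_config(seed = 11L, shift = c(5L, -4L))
  tri <- generate_phantom(cfg)
  # pt_run is unaffected by the shift; n_run moves
  expect_identical(tri$pt_run$maps[["12C2"]]$counts,
                   tri0$pt_run$maps[["12C2"]]$counts)
  sh <- estimate_shift(tri$pt_run$maps[["12C2"]], tri$n_run$maps[["12C2"]])
  expect_identical(c(sh$i_row, sh$i_col), c(5L, -4L))
})

test_that("exposure series is ordered, monotone and control-anchored", {
  conc <- c(0, 2.5, 5, 10, 25, 50, 100, 150)
  ser <- nested_exposure_series(small_config(seed = 13L), conc)
  expect_length(ser, 8L)
  expect_equal(vapply(ser, `[[`, 0, "concentration"), conc)
  loads <- t(vapply(ser, function(tr)
    tr$truth$compartments$drug_load, numeric(6)))
  expect_true(all(diff(loads) >= 0))
  expect_true(all(ser[[1]]$truth$compartments$label_fraction == 0))
  expect_true(ser[[1]]$pt_run$is_control)
  # linear accumulation -> true pt index linear in concentration per
  # compartment up to the (known) CN enrichment of the denominator
  q_nucl <- vapply(ser, function(tr)
    tr$truth$compartments$pt_index[tr$truth$compartments$compartment == "nucleolus"],
    numeric(1))
  x_nucl <- vapply(ser, function(tr)
    tr$truth$compartments$label_fraction[tr$truth$compartments$compartment == "nucleolus"],
    numeric(1))
  expect_equal(x_nucl, 0.4 * q_nucl)  # slope L/rsf exactly, all concentrations
  expect_error(nested_exposure_series(small_config(), numeric(0)), "empty")
  expect_error(nested_exposure_series(small_config(), c(5, 10)), "control")
  expect_error(nested_exposure_series(small_config(), conc,
                                      accumulation_model = function(conc)
                                        c(cytoplasm = max(0, 10 - conc))),
               "monotone")
})

test_that("phantom configuration round-trips through YAML", {
  cfg <- small_config(seed = 21L, rsf = c(pt = 7, n = 2), shift = c(1L, 2L))
  f <- tempfile(fileext = ".yaml")
  write_phantom_config(cfg, f)
  r <- read_phantom_config(f)
  expect_equal(r[names(r) != "base_yields"], cfg[names(cfg) != "base_yields"])
  expect_equal(unname(r$base_yields), unname(cfg$base_yields))
})
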