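test_that("counts containers enforce integer non-negative counts", {
  expect_error(ion_count_map(matrix(c(1, -2, 3, 4), 2), "194Pt", 0.1, 1),
               "negative")
  err <- tryCatch(ion_count_map(matrix(c(1, 2.5, 3, 4), 2), "194Pt", 0.1, 1),
                  error = conditionMessage)
  expect_match(err, "row 2, col 1")
  expect_error(ion_count_map(matrix(1, 2, 2), "12C3", 0.1, 1), "unknown species")
  expect_error(ion_count_map(matrix(1, 2, 2), "194Pt", 0, 1), "pixel_size")
})

test_that("stacks enforce run-type channel sets and shared geometry", {
  pt <- ion_count_map(matrix(1L, 4, 4), "194Pt", 0.1, 1)
  c2 <- ion_count_map(matrix(2L, 4, 4), "12C2", 0.1, 1)
  expect_error(acquisition_stack(list(c2), "s", "pt_run"), "194Pt")
  expect_error(acquisition_stack(list(pt, c2), "s", "n_run"), "12C14N")
  c2b <- ion_count_map(matrix(2L, 5, 4), "12C2", 0.1, 1)
  expect_error(acquisition_stack(list(pt, c2b), "s", "pt_run"), "dimensions")
  expect_error(acquisition_stack(list(pt, c2), "s", "pt_run",
                                 exposure_concentration = 5, is_control = TRUE),
               "control")
  s <- acquisition_stack(list(pt, c2), "s", "pt_run", 25)
  expect_identical(stack_dim(s), c(4L, 4L))
  expect_named(s$maps, c("194Pt", "12C2"))
})

test_that("write/read round-trips both layouts bit-identically", {
  tri <- generate_phantom(small_config(seed = 3L), runs = "pt_run")
  s <- tri$pt_run
  for (path in c(file.path(tempfile(), "stackdir"),
                 tempfile(fileext = ".tif"))) {
    write_stack(s, path)
    r <- read_stack(path)
    expect_identical(lapply(r$maps, `[[`, "counts"),
                     lapply(s$maps, `[[`, "counts"))
    expect_identical(names(r$maps), names(s$maps))
    expect_equal(r$maps[["12C2"]]$pixel_size, s$maps[["12C2"]]$pixel_size)
    expect_equal(r$maps[["12C2"]]$dwell_time, s$maps[["12C2"]]$dwell_time)
    expect_identical(r$sample_id, s$sample_id)
    expect_identical(r$run_type, s$run_type)
    expect_equal(r$exposure_concentration, s$exposure_concentration)
    # per-channel totals conserved by I/O
    expect_identical(vapply(r$maps, function(m) sum(as.numeric(m$counts)), 0),
                     vapply(s$maps, function(m) sum(as.numeric(m$counts)), 0))
  }
})

test_that("degenerate 1x1 zero map survives the round trip", {
  s <- tiny_pt_stack(matrix(0L, 1, 1), matrix(0L, 1, 1))
  p <- file.path(tempfile(), "zero")
  write_stack(s, p)
  r <- read_stack(p)
  expect_identical(r$maps[["194Pt"]]$counts, matrix(0L, 1, 1))
})

test_that("reader rejects stacks missing a required channel", {
  s <- tiny_pt_stack(matrix(1L, 3, 3), matrix(5L, 3, 3))
  p <- file.path(tempfile(), "broken")
  write_stack(s, p)
  file.remove(file.path(p, "194Pt.txt"))
  expect_error(read_stack(p), "194Pt")
})

test_that("reader rejects non-integer pixel values with coordinates", {
  s <- tiny_pt_stack(matrix(1L, 3, 3), matrix(5L, 3, 3))
  p <- file.path(tempfile(), "floaty")
  write_stack(s, p)
  m <- matrix(5, 3, 3); m[2, 3] <- 4.25
  write.table(m, file.path(p, "12C2.txt"), row.names = FALSE, col.names = FALSE)
  err <- tryCatch(read_stack(p), error = conditionMessage)
  expect_match(err, "row 2, col 3")
})

test_that("TIFF layout writes one page per channel in declared order", {
  tri <- generate_phantom(small_config(seed = 4L))
  f <- tempfile(fileext = ".tif")
  write_stack(tri$n_run, f)
  pages <- tiff::readTIFF(f, all = TRUE, as.is = TRUE)
  expect_length(pages, 3L)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_identical(vapply(side$channels, `[[`, "", "species_label",
                          USE.NAMES = FALSE),
                   c("12C14N", "12C15N", "12C2"))
  expect_identical(pages[[2]], tri$n_run$maps[["12C15N"]]$counts)
})

test_that("manifest reading validates columns and control consistency", {
  d <- tempfile(); dir.create(d)
  man <- data.frame(sample_id = c("a", "a"), run_type = c("pt_run", "n_run"),
                    path = c("a_pt", "a_n"),
                    exposure_concentration_uM = c(25, 25),
                    is_control = c(FALSE, FALSE))
  f <- file.path(d, "manifest.tsv")
  write.table(man, f, sep = "\t", row.names = FALSE, quote = FALSE)
  m <- read_manifest(f)
  expect_identical(m$path, file.path(d, c("a_pt", "a_n")))
  man$is_control <- TRUE
  write.table(man, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_manifest(f), "control")
  write.table(man[, -2], f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_manifest(f), "run_type")
})

test_that("mask round-trips through directory and TIFF layouts", {
  tri <- generate_phantom(small_config(seed = 5L), runs = "pt_run")
  mask <- tri$truth$mask
  for (p in c(file.path(tempfile(), "maskdir"), tempfile(fileext = ".tif"))) {
    write_mask(mask, p)
    r <- read_mask(p)
    expect_identical(r$labels, mask$labels)
    expect_identical(r$legend$roi_id, mask$legend$roi_id)
    expect_identical(r$legend$compartment, mask$legend$compartment)
  }
})
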