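# Containers and I/O for multi-channel ion-count image stacks.
#
# Counts are raw accumulated ion counts per pixel: non-negative integers.
# Floats are rejected rather than rounded because every downstream error
# estimate is Poisson and only valid on raw counts. Pixel coordinates are
# (row, col), 0-based in documentation, stored as ordinary R matrices
# (row-major raster order, origin top-left).

#' Single-channel ion-count image
#'
#' @param counts Matrix of non-negative integer ion counts (rows x cols).
#'   Non-integral or negative values are an error, not rounded.
#' @param channel A \code{\link{channel_spec}} or a species label string.
#' @param pixel_size Pixel edge length in micrometres (> 0).
#' @param dwell_time Accumulated dwell time per pixel in milliseconds (> 0).
#' @return An object of class \code{"ion_count_map"}.
#' @export
ion_count_map <- function(counts, channel, pixel_size, dwell_time) {
  if (is.character(channel)) channel <- channel_spec(channel)
  stopifnot(inherits(channel, "channel_spec"))
  if (!is.matrix(counts) || nrow(counts) < 1L || ncol(counts) < 1L)
    stop("counts must be a matrix with positive dimensions")
  .check_integer_counts(counts, channel$species_label)
  storage.mode(counts) <- "integer"
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single value > 0 (micrometres)")
  if (!is.numeric(dwell_time) || length(dwell_time) != 1L || dwell_time <= 0)
    stop("dwell_time must be a single value > 0 (milliseconds)")
  structure(list(channel = channel, counts = counts,
                 pixel_size = as.numeric(pixel_size),
                 dwell_time = as.numeric(dwell_time)),
            class = "ion_count_map")
}

# Reject non-integral / negative values, reporting offending coordinates.
.check_integer_counts <- function(counts, label) {
  bad <- !is.finite(counts) | counts < 0 | counts != floor(counts)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf(
      "channel %s: non-integer or negative count %s at (row %d, col %d); raw integer counts are required",
      label, format(counts[bad][1]), idx[1], idx[2]))
  }
  if (max(counts) >= .Machine$integer.max)
    stop("channel ", label, ": counts exceed integer range")
  invisible(TRUE)
}

#' @export
print.ion_count_map <- function(x, ...) {
  cat(sprintf("<ion_count_map %s: %d x %d px, %.4g um/px, %.3g ms dwell, total %.6g counts>\n",
              x$channel$species_label, nrow(x$counts), ncol(x$counts),
              x$pixel_size, x$dwell_time, sum(as.numeric(x$counts))))
  invisible(x)
}

#' Co-registered multi-channel acquisition
#'
#' A set of \code{\link{ion_count_map}}s recorded in one acquisition run of
#' one sample. A \code{"pt_run"} must contain the 194Pt and 12C2 channels; an
#' \code{"n_run"} must contain 12C14N, 12C15N and 12C2 (the shared 12C2
#' channel is what allows the two sequential runs to be registered). All maps
#' must share dimensions, pixel size and dwell time.
#'
#' @param maps List of \code{ion_count_map}s.
#' @param sample_id Sample identifier string.
#' @param run_type \code{"pt_run"} or \code{"n_run"}.
#' @param exposure_concentration Drug exposure concentration in micromolar.
#' @param is_control Logical; controls must have exposure 0.
#' @return An object of class \code{"acquisition_stack"}; \code{maps} is named
#'   by species label.
#' @export
acquisition_stack <- function(maps, sample_id, run_type = c("pt_run", "n_run"),
                              exposure_concentration = 0, is_control = FALSE) {
  run_type <- match.arg(run_type)
  stopifnot(is.list(maps), length(maps) >= 1L,
            all(vapply(maps, inherits, logical(1), "ion_count_map")))
  labels <- vapply(maps, function(m) m$channel$species_label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate channel in stack: ", labels[duplicated(labels)][1])
  names(maps) <- labels
  dims <- vapply(maps, function(m) dim(m$counts), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all maps in a stack must share identical dimensions")
  px <- vapply(maps, `[[`, numeric(1), "pixel_size")
  dw <- vapply(maps, `[[`, numeric(1), "dwell_time")
  if (any(px != px[1]) || any(dw != dw[1]))
    stop("all maps in a stack must share pixel_size and dwell_time")
  missing <- setdiff(.required_channels[[run_type]], labels)
  if (length(missing))
    stop("missing channel ", paste(missing, collapse = ", "),
         " required for run_type ", run_type)
  if (!is.numeric(exposure_concentration) || exposure_concentration < 0)
    stop("exposure_concentration must be >= 0 (uM)")
  is_control <- isTRUE(is_control)
  if (is_control && exposure_concentration != 0)
    stop("a control sample must have exposure_concentration = 0")
  structure(list(sample_id = as.character(sample_id), run_type = run_type,
                 maps = maps,
                 exposure_concentration = as.numeric(exposure_concentration),
                 is_control = is_control),
            class = "acquisition_stack")
}

#' @export
print.acquisition_stack <- function(x, ...) {
  d <- dim(x$maps[[1]]$counts)
  cat(sprintf("<acquisition_stack %s [%s]: %d x %d px, channels %s, %g uM%s>\n",
              x$sample_id, x$run_type, d[1], d[2],
              paste(names(x$maps), collapse = "/"),
              x$exposure_concentration,
              if (x$is_control) ", control" else ""))
  invisible(x)
}

#' Stack dimensions
#' @param stack An \code{acquisition_stack}.
#' @return Integer vector \code{c(rows, cols)}.
#' @export
stack_dim <- function(stack) dim(stack$maps[[1]]$counts)

# ---------------------------------------------------------------------------
# File I/O. Two interchangeable layouts:
#  * a directory of whitespace-delimited integer matrices <species>.txt plus
#    a stack.json sidecar, or
#  * a multi-page uint16 TIFF (one page per channel, in sidecar order) plus a
#    <file>.json sidecar.
# The sidecar carries channel order/metadata and the sample metadata.

.stack_sidecar <- function(stack) {
  list(sample_id = stack$sample_id,
       run_type = stack$run_type,
       exposure_concentration_uM = stack$exposure_concentration,
       is_control = stack$is_control,
       pixel_size_um = stack$maps[[1]]$pixel_size,
       dwell_time_ms = stack$maps[[1]]$dwell_time,
       channels = lapply(stack$maps, function(m)
         list(species_label = m$channel$species_label,
              nominal_mass = m$channel$nominal_mass,
              role = m$channel$role)))
}

#' Write an acquisition stack to disk
#'
#' @param stack An \code{\link{acquisition_stack}}.
#' @param path Output path: a directory (created if absent) for the text
#'   layout, or a file ending in \code{.tif}/\code{.tiff} for the multi-page
#'   TIFF layout (uint16; counts above 65535 are an error in that layout).
#' @return \code{path}, invisibly. Re-reading with \code{\link{read_stack}}
#'   reproduces every count and metadata field exactly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "acquisition_stack"))
  side <- .stack_sidecar(stack)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    mx <- max(vapply(stack$maps, function(m) max(m$counts), numeric(1)))
    if (mx > 65535)
      stop("TIFF layout stores uint16; counts exceed 65535 - use the directory layout")
    pages <- lapply(stack$maps, function(m) m$counts / 65535)
    ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L), silent = TRUE)
    if (inherits(ok, "try-error")) stop("cannot write TIFF at ", path)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    if (!dir.exists(path) && !dir.create(path, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create directory ", path)
    for (m in stack$maps) {
      f <- file.path(path, paste0(m$channel$species_label, ".txt"))
      utils::write.table(m$counts, f, row.names = FALSE, col.names = FALSE)
    }
    jsonlite::write_json(side, file.path(path, "stack.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read an acquisition stack from disk
#'
#' Accepts either layout written by \code{\link{write_stack}}. Channel pages
#' are mapped to channel specifications through the JSON sidecar. Pixel
#' values must be non-negative integers; anything else is rejected with the
#' offending coordinates. A stack missing a channel required for its run type
#' raises an error naming the channel.
#'
#' @param path Directory or multi-page TIFF file written by
#'   \code{\link{write_stack}} (or assembled externally in the same layout).
#' @param manifest_entry Optional one-row data frame (or named list) from the
#'   experiment manifest; its \code{sample_id}, \code{run_type},
#'   \code{exposure_concentration_uM} and \code{is_control} override the
#'   sidecar values.
#' @return An \code{\link{acquisition_stack}}.
#' @export
read_stack <- function(path, manifest_entry = NULL) {
  if (dir.exists(path)) {
    sidef <- file.path(path, "stack.json")
    if (!file.exists(sidef)) stop("no stack.json sidecar in ", path)
    side <- jsonlite::read_json(sidef, simplifyVector = FALSE)
    counts <- lapply(side$channels, function(ch) {
      f <- file.path(path, paste0(ch$species_label, ".txt"))
      if (!file.exists(f)) stop("missing channel file ", f)
      as.matrix(utils::read.table(f, colClasses = "numeric"))
    })
  } else if (file.exists(path)) {
    sidef <- paste0(path, ".json")
    if (!file.exists(sidef)) stop("no JSON sidecar next to ", path)
    side <- jsonlite::read_json(sidef, simplifyVector = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != length(side$channels))
      stop("TIFF has ", length(pages), " pages but sidecar lists ",
           length(side$channels), " channels")
    counts <- pages
  } else stop("path does not exist: ", path)

  if (!is.null(manifest_entry)) {
    me <- as.list(manifest_entry)
    for (k in c("sample_id", "run_type", "is_control"))
      if (!is.null(me[[k]])) side[[k]] <- me[[k]]
    if (!is.null(me$exposure_concentration_uM))
      side$exposure_concentration_uM <- me$exposure_concentration_uM
  }
  maps <- vector("list", length(side$channels))
  for (i in seq_along(side$channels)) {
    ch <- side$channels[[i]]
    m <- counts[[i]]
    dimnames(m) <- NULL
    maps[[i]] <- ion_count_map(
      m,
      channel_spec(ch$species_label, ch$nominal_mass, ch$role),
      pixel_size = side$pixel_size_um, dwell_time = side$dwell_time_ms)
  }
  acquisition_stack(maps, sample_id = side$sample_id, run_type = side$run_type,
                    exposure_concentration = side$exposure_concentration_uM,
                    is_control = isTRUE(side$is_control))
}

#' Read an experiment manifest
#'
#' The manifest is a TSV with columns \code{sample_id}, \code{run_type},
#' \code{path}, \code{exposure_concentration_uM}, \code{is_control}; each row
#' points at one acquisition stack. Relative \code{path}s are resolved
#' against the manifest's directory.
#'
#' @param path Path to the TSV manifest.
#' @return A data frame with the validated columns, paths resolved.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "run_type", "path",
            "exposure_concentration_uM", "is_control")
  missing <- setdiff(need, names(man))
  if (length(missing))
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "))
  if (!all(man$run_type %in% c("pt_run", "n_run")))
    stop("run_type must be pt_run or n_run")
  man$is_control <- as.logical(man$is_control)
  if (any(man$is_control & man$exposure_concentration_uM != 0))
    stop("control rows must have exposure_concentration_uM = 0")
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  man
}
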