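# Compartment label masks. One integer label per pixel (mutually exclusive
# ROIs); a legend maps label ids to ROI ids and compartment names. The
# "nucleus" compartment excludes both the nucleolus and the chromatin rim,
# which carry their own labels.

.compartment_names <- c("background", "cytoplasm", "nucleus", "nucleolus",
                        "chromatin", "aggregate")

#' Compartment / ROI label mask
#'
#' @param labels Integer matrix of label ids (0 = background by convention),
#'   same dimensions as the stacks it will be applied to.
#' @param legend Data frame with columns \code{label} (integer id),
#'   \code{roi_id} (unique string) and \code{compartment} (one of
#'   \code{background, cytoplasm, nucleus, nucleolus, chromatin, aggregate},
#'   or a free-form name). Label 0 need not be listed; it is background.
#' @return An object of class \code{"compartment_mask"}.
#' @export
compartment_mask <- function(labels, legend) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  if (any(labels != floor(labels)) || any(labels < 0))
    stop("labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  stopifnot(is.data.frame(legend),
            all(c("label", "roi_id", "compartment") %in% names(legend)))
  legend$label <- as.integer(legend$label)
  legend$roi_id <- as.character(legend$roi_id)
  legend$compartment <- as.character(legend$compartment)
  if (anyDuplicated(legend$label)) stop("duplicate label id in legend")
  if (anyDuplicated(legend$roi_id)) stop("duplicate roi_id in legend")
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  unknown <- setdiff(present, legend$label)
  if (length(unknown))
    stop("labels present in mask but absent from legend: ",
         paste(unknown, collapse = ", "))
  structure(list(labels = labels, legend = legend), class = "compartment_mask")
}

#' @export
print.compartment_mask <- function(x, ...) {
  cat(sprintf("<compartment_mask %d x %d px, %d ROIs (%s)>\n",
              nrow(x$labels), ncol(x$labels), nrow(x$legend),
              paste(unique(x$legend$compartment), collapse = "/")))
  invisible(x)
}

#' Write a compartment mask
#'
#' Writes \code{labels.txt} (integer matrix) and \code{legend.json} into a
#' directory, or a single-page uint16 label TIFF plus \code{<file>.json} if
#' \code{path} ends in \code{.tif}/\code{.tiff}.
#'
#' @param mask A \code{\link{compartment_mask}}.
#' @param path Output directory or TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "compartment_mask"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (max(mask$labels) > 65535) stop("label ids exceed uint16 range")
    tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
    jsonlite::write_json(mask$legend, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    if (!dir.exists(path) && !dir.create(path, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create directory ", path)
    utils::write.table(mask$labels, file.path(path, "labels.txt"),
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(mask$legend, file.path(path, "legend.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a compartment mask written by \code{\link{write_mask}}
#' @param path Directory or label-TIFF path.
#' @return A \code{\link{compartment_mask}}.
#' @export
read_mask <- function(path) {
  if (dir.exists(path)) {
    labels <- as.matrix(utils::read.table(file.path(path, "labels.txt")))
    legend <- jsonlite::read_json(file.path(path, "legend.json"),
                                  simplifyVector = TRUE)
  } else if (file.exists(path)) {
    labels <- tiff::readTIFF(path, as.is = TRUE)
    legend <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  } else stop("path does not exist: ", path)
  dimnames(labels) <- NULL
  compartment_mask(labels, as.data.frame(legend))
}
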