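# ROI-based ion-count extraction and reference-normalised signals.
#
# Ratios are always formed from ROI-summed counts, never from means of
# per-pixel ratios: per-pixel ratios are undefined at zero counts and biased
# at low counts, while sums remain Poisson so first-order counting-error
# propagation stays valid.

#' Extract per-ROI channel count sums
#'
#' Sums each channel over the pixels of every non-background ROI in the
#' mask. Conservation holds exactly: the ROI sums plus the background sum
#' equal the image total for every channel.
#'
#' @param stack An \code{\link{acquisition_stack}}.
#' @param mask A \code{\link{compartment_mask}} with the same dimensions.
#' @return A data frame with one row per non-empty, non-background ROI:
#'   \code{roi_id}, \code{compartment}, \code{pixel_count}, and one count
#'   column per channel (named by species label). ROIs with zero pixels are
#'   omitted with a warning.
#' @export
extract_roi_counts <- function(stack, mask) {
  stopifnot(inherits(stack, "acquisition_stack"),
            inherits(mask, "compartment_mask"))
  if (!identical(dim(mask$labels), stack_dim(stack)))
    stop(sprintf("mask dimensions (%d x %d) do not match stack dimensions (%d x %d)",
                 nrow(mask$labels), ncol(mask$labels),
                 stack_dim(stack)[1], stack_dim(stack)[2]))
  lab <- as.vector(mask$labels)
  legend <- mask$legend
  npix <- tabulate(lab + 1L, nbins = max(lab, legend$label) + 1L)[legend$label + 1L]
  empty <- npix == 0L
  if (any(empty))
    warning("omitting ROI(s) with zero pixels: ",
            paste(legend$roi_id[empty], collapse = ", "))
  keep <- legend[!empty, , drop = FALSE]
  out <- data.frame(roi_id = keep$roi_id, compartment = keep$compartment,
                    pixel_count = npix[!empty], stringsAsFactors = FALSE)
  for (m in stack$maps) {
    sums <- rowsum(as.numeric(m$counts), lab, reorder = FALSE)
    out[[m$channel$species_label]] <-
      as.vector(sums[match(keep$label, as.integer(rownames(sums))), 1])
  }
  out[order(match(out$roi_id, legend$roi_id)), , drop = FALSE]
}

#' Reference-normalised ROI signal with counting error
#'
#' Forms the ratio \eqn{R = n_{num}/n_{ref}} of summed ROI counts and its
#' Poisson counting error \eqn{\sigma_R = R \sqrt{1/n_{num} + 1/n_{ref}}}
#' (first-order propagation of independent Poisson variates). A zero
#' numerator yields \eqn{R = 0} with the one-sided single-count upper-bound
#' scale \eqn{\sigma_R = 1/n_{ref}}, flagged \code{one_sided}.
#'
#' @param roi One or more rows of the table returned by
#'   \code{\link{extract_roi_counts}} (vectorised over rows).
#' @param numerator,reference Species labels of the numerator and reference
#'   channels (e.g. \code{"194Pt"} and \code{"12C2"}).
#' @return A data frame with \code{roi_id}, \code{compartment},
#'   \code{ratio}, \code{sigma} and \code{one_sided}.
#' @export
normalized_signal <- function(roi, numerator, reference = "12C2") {
  stopifnot(is.data.frame(roi))
  for (ch in c(numerator, reference))
    if (!ch %in% names(roi)) stop("channel ", ch, " not present in ROI table")
  n_num <- roi[[numerator]]
  n_ref <- roi[[reference]]
  if (any(n_ref <= 0))
    stop("undefined ratio: reference channel ", reference,
         " has zero counts in ROI ",
         paste(roi$roi_id[n_ref <= 0], collapse = ", "))
  ratio <- n_num / n_ref
  one_sided <- n_num == 0
  sigma <- ifelse(one_sided, 1 / n_ref,
                  ratio * sqrt(1 / pmax(n_num, 1) + 1 / n_ref))
  data.frame(roi_id = roi$roi_id, compartment = roi$compartment,
             ratio = ratio, sigma = sigma, one_sided = one_sided,
             stringsAsFactors = FALSE, row.names = NULL)
}
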