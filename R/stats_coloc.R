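# Group comparisons and channel-pair colocalisation.

#' Compare two groups of ROI values
#'
#' Two-sample, two-tailed Student's t-test; equal-variance pooling by
#' default (a Welch variant is available). Exact p from the t distribution.
#'
#' @param values_a,values_b Numeric vectors of per-ROI values (e.g.
#'   12C2-normalised 194Pt signals), each of length >= 2.
#' @param var_equal Pool variances (classic Student's t; default TRUE).
#' @return A list of class \code{"group_comparison"}: \code{n_a}, \code{n_b},
#'   \code{mean_a}, \code{mean_b}, \code{t}, \code{df}, \code{p},
#'   \code{variant}.
#' @export
compare_groups <- function(values_a, values_b, var_equal = TRUE) {
  stopifnot(is.numeric(values_a), is.numeric(values_b))
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs >= 2 values")
  if (stats::var(values_a) + stats::var(values_b) == 0)
    stop("degenerate variance: both groups are constant")
  ht <- stats::t.test(values_a, values_b, var.equal = isTRUE(var_equal),
                      alternative = "two.sided")
  structure(list(n_a = length(values_a), n_b = length(values_b),
                 mean_a = mean(values_a), mean_b = mean(values_b),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 variant = if (isTRUE(var_equal)) "student" else "welch"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<%s t-test: t = %.4g (df %.4g), p = %.4g; means %.4g vs %.4g (n %d/%d)>\n",
              x$variant, x$t, x$df, x$p, x$mean_a, x$mean_b, x$n_a, x$n_b))
  invisible(x)
}

# Otsu threshold on non-negative integer counts: maximises between-class
# variance over the count histogram. Returns a value t; "positive" pixels
# are those with count > t. Wide ranges are binned to <= 1024 levels.
.otsu_threshold <- function(x) {
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x)
  if (hi == lo) stop("cannot threshold a constant channel")
  step <- max(1, ceiling((hi - lo + 1) / 1024))
  breaks <- seq(lo - 0.5, hi + step, by = step)
  h <- as.numeric(tabulate(findInterval(x, breaks), nbins = length(breaks) - 1))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- cumsum(h); n <- w[length(w)]
  mu <- cumsum(h * mids)
  muT <- mu[length(mu)]
  w1 <- w; w2 <- n - w
  valid <- w1 > 0 & w2 > 0
  bcv <- rep(-Inf, length(h))
  bcv[valid] <- (muT * w1[valid] - n * mu[valid])^2 / (n * w1[valid] * w2[valid])
  breaks[which.max(bcv) + 1]
}

#' Channel-pair colocalisation within a compartment
#'
#' Pearson correlation of the two channels over the in-scope pixels, plus
#' Manders coefficients: \code{m1} is the fraction of channel-a signal on
#' pixels where channel b exceeds its threshold, \code{m2} vice versa.
#' Thresholds default to per-channel Otsu on the in-scope count histograms
#' and are recorded in the result.
#'
#' @param map_a,map_b \code{\link{ion_count_map}}s of identical dimensions.
#' @param mask A \code{\link{compartment_mask}}; \code{scope} selects the
#'   pixels (a compartment name, an roi_id, or \code{"all"} for every
#'   non-background pixel).
#' @param scope Compartment name / roi_id / \code{"all"}.
#' @param thresholds Optional fixed \code{c(a = , b = )} thresholds
#'   overriding Otsu.
#' @return A list of class \code{"colocalisation_result"}: \code{channels},
#'   \code{scope}, \code{n_pixels}, \code{pearson_r}, \code{m1}, \code{m2},
#'   \code{threshold_a}, \code{threshold_b}, \code{threshold_method}.
#' @export
colocalise <- function(map_a, map_b, mask, scope = "all", thresholds = NULL) {
  stopifnot(inherits(map_a, "ion_count_map"), inherits(map_b, "ion_count_map"),
            inherits(mask, "compartment_mask"))
  if (!identical(dim(map_a$counts), dim(map_b$counts)) ||
      !identical(dim(map_a$counts), dim(mask$labels)))
    stop("maps and mask must share dimensions")
  if (scope == "all") {
    sel <- mask$labels > 0L
  } else {
    ids <- mask$legend$label[mask$legend$compartment == scope |
                               mask$legend$roi_id == scope]
    if (!length(ids)) stop("scope '", scope, "' not present in mask")
    sel <- matrix(mask$labels %in% ids, nrow(mask$labels))
  }
  if (!any(sel)) stop("scope '", scope, "' selects no pixels")
  a <- as.numeric(map_a$counts[sel])
  b <- as.numeric(map_b$counts[sel])
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: constant channel within scope")
  r <- stats::cor(a, b)
  if (is.null(thresholds)) {
    ta <- .otsu_threshold(a); tb <- .otsu_threshold(b)
    method <- "otsu"
  } else {
    ta <- thresholds[["a"]]; tb <- thresholds[["b"]]
    method <- "fixed"
  }
  m1 <- if (sum(a) > 0) sum(a[b > tb]) / sum(a) else NA_real_
  m2 <- if (sum(b) > 0) sum(b[a > ta]) / sum(b) else NA_real_
  structure(list(channels = c(map_a$channel$species_label,
                              map_b$channel$species_label),
                 scope = scope, n_pixels = sum(sel),
                 pearson_r = r, m1 = m1, m2 = m2,
                 threshold_a = ta, threshold_b = tb,
                 threshold_method = method),
            class = "colocalisation_result")
}

#' @export
print.colocalisation_result <- function(x, ...) {
  cat(sprintf("<coloc %s vs %s in %s (%d px): r = %.4f, M1 = %.4f, M2 = %.4f (%s thresholds %.3g/%.3g)>\n",
              x$channels[1], x$channels[2], x$scope, x$n_pixels,
              x$pearson_r, x$m1, x$m2, x$threshold_method,
              x$threshold_a, x$threshold_b))
  invisible(x)
}

#' Volume fraction of a central slab of a sphere
#'
#' The volume sampled by a thin section through the centre of a spherical
#' cell: a slab of thickness \eqn{t} through a sphere of radius \eqn{r} has
#' volume \eqn{\pi t (r^2 - t^2/12)}, so its fraction of the sphere volume
#' is \eqn{3 t (r^2 - t^2/12) / (4 r^3)}. The central slab is the largest
#' such slab, so this is an upper bound for any section position; it is the
#' bound relevant when relating per-cell analyte amounts to what a single
#' semi-thin section can contain.
#'
#' @param diameter Cell diameter (same length unit as \code{thickness}).
#' @param thickness Section thickness.
#' @return The volume fraction (dimensionless, in [0, 1]).
#' @export
#' @examples
#' section_volume_fraction(10, 0.3)  # 300 nm section of a 10 um cell
section_volume_fraction <- function(diameter, thickness) {
  stopifnot(diameter > 0, thickness > 0, thickness <= diameter)
  r <- diameter / 2
  3 * thickness * (r^2 - thickness^2 / 12) / (4 * r^3)
}
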