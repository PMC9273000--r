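# Isotope abundance, label fraction, Pt/N index, stoichiometry curves.
#
# The label fraction is the two-endpoint linear mixing model: a region's
# measured 15N abundance a_tot is a mixture of unlabeled biological nitrogen
# (abundance a_ctr, taken from an untreated control or natural abundance)
# and drug-derived nitrogen (abundance a_cddp, the label purity), so the
# fraction of nitrogen atoms originating from the drug is
#   x = (a_tot - a_ctr) / (a_cddp - a_ctr),
# exactly 0 at the unlabeled endpoint and 1 at the fully labeled one.
#
# The Pt/N index uses 12C2- as internal reference to cancel run-to-run
# sensitivity:  q = [I(194Pt)/I(12C2)]_Pt  /  [I(12CN)/I(12C2)]_avg,
# where the 'avg' bracket is the arithmetic mean of the CN/C2 ratio over the
# acquisitions of the same ROI that record CN. q is proportional to the
# Pt/N_tot concentration ratio; plotting x against q across exposure
# concentrations gives a line whose slope is proportional to the N/Pt
# stoichiometry of the accumulated drug, and equal to it once relative
# sensitivity factors are known.

#' 15N isotopic abundance of an ROI
#'
#' \eqn{a = n_{15} / (n_{14} + n_{15})} with the binomial counting error
#' \eqn{\sigma_a = \sqrt{a (1 - a) / (n_{14} + n_{15})}}.
#'
#' @param n14,n15 Summed 12C14N- and 12C15N- ROI counts. Alternatively pass
#'   a row (or rows) of an \code{\link{extract_roi_counts}} table from an
#'   n_run as \code{n14} and leave \code{n15} missing. Vectorised.
#' @return A data frame with \code{a}, \code{sigma}, \code{n14}, \code{n15}
#'   (class \code{"isotope_abundance"} added).
#' @export
abundance_15n <- function(n14, n15) {
  if (is.data.frame(n14) && missing(n15)) {
    roi <- n14
    if (!all(c("12C14N", "12C15N") %in% names(roi)))
      stop("ROI table lacks the CN isotopologue channels")
    n14 <- roi[["12C14N"]]; n15 <- roi[["12C15N"]]
  }
  stopifnot(is.numeric(n14), is.numeric(n15), length(n14) == length(n15))
  if (any(n14 < 0) || any(n15 < 0)) stop("counts must be non-negative")
  tot <- n14 + n15
  if (any(tot <= 0))
    stop("undefined abundance: zero total CN counts")
  a <- n15 / tot
  sigma <- sqrt(a * (1 - a) / tot)
  structure(data.frame(a = a, sigma = sigma, n14 = n14, n15 = n15),
            class = c("isotope_abundance", "data.frame"))
}

#' Drug-derived nitrogen fraction (two-endpoint mixing model)
#'
#' @param a_tot An \code{\link{abundance_15n}} result (vectorised), or a
#'   numeric abundance (then \code{sigma} is taken as 0).
#' @param a_ctr 15N abundance of the unlabeled control (fraction).
#' @param a_cddp 15N abundance of the administered labeled drug (fraction);
#'   must exceed \code{a_ctr}.
#' @return A data frame with \code{x} (fraction of nitrogen from the drug,
#'   clipped at 0 since it is a physical fraction), \code{x_raw} (the
#'   unclipped estimate; regression on censored values biases slope fits, so
#'   downstream fits use this column), \code{sigma_x}
#'   (\code{= sigma_a / (a_cddp - a_ctr)}), \code{clipped} (TRUE where a
#'   value marginally below \code{a_ctr} was clipped) and the inputs. Values
#'   below \code{a_ctr} by more than 5 counting errors, or above
#'   \code{a_cddp}, are an error.
#' @export
label_fraction <- function(a_tot, a_ctr, a_cddp) {
  if (a_cddp <= a_ctr) stop("configuration error: a_cddp must exceed a_ctr")
  if (is.numeric(a_tot)) a_tot <- data.frame(a = a_tot, sigma = 0)
  a <- a_tot$a; sig <- a_tot$sigma
  low <- a < a_ctr - 5 * sig
  if (any(low))
    stop("abundance more than 5 counting errors below the control baseline; ",
         "check a_ctr (offending value ", format(a[low][1]), ")")
  if (any(a > a_cddp))
    stop("abundance exceeds the label purity a_cddp; check inputs")
  x_raw <- (a - a_ctr) / (a_cddp - a_ctr)
  clipped <- x_raw < 0
  x <- pmax(x_raw, 0)
  data.frame(x = x, x_raw = x_raw, sigma_x = sig / (a_cddp - a_ctr),
             clipped = clipped, a_tot = a, a_ctr = a_ctr, a_cddp = a_cddp)
}

#' Reference-normalised Pt/N concentration index
#'
#' \eqn{q = [I(^{194}Pt)/I(^{12}C_2)]_{Pt} / [I(^{12}CN)/I(^{12}C_2)]_{avg}}
#' from the summed ROI counts of the paired acquisitions. \eqn{I(^{12}CN)}
#' is the sum of the 12C14N- and 12C15N- counts where both are recorded,
#' else 12C14N- alone (flagged; the resulting deficit equals the 15N
#' abundance, well below the counting error at tracer-level enrichment). The
#' 'avg' bracket averages the CN/C2 ratio over every supplied run that
#' records CN. \code{sigma_q} is first-order propagation over the
#' contributing Poisson counts, treated as independent (a shared pt_run C2
#' term, present only if the pt_run records CN, would contribute a small
#' neglected covariance).
#'
#' @param pt_roi ROI table row(s) from the pt_run
#'   (\code{\link{extract_roi_counts}}); must contain \code{194Pt} and
#'   \code{12C2}. Vectorised; rows are matched to \code{n_roi} by
#'   \code{roi_id}.
#' @param n_roi ROI table row(s) from the n_run with the CN channels and
#'   \code{12C2}.
#' @return Data frame with \code{roi_id}, \code{compartment}, \code{q},
#'   \code{sigma_q}, \code{cn_runs} (number of runs contributing CN) and
#'   \code{cn_minor_missing} flag.
#' @export
pt_nitrogen_index <- function(pt_roi, n_roi) {
  stopifnot(is.data.frame(pt_roi), is.data.frame(n_roi),
            all(c("194Pt", "12C2") %in% names(pt_roi)))
  i <- match(pt_roi$roi_id, n_roi$roi_id)
  if (any(is.na(i)))
    stop("ROI(s) missing from the n_run table: ",
         paste(pt_roi$roi_id[is.na(i)], collapse = ", "))
  n_roi <- n_roi[i, , drop = FALSE]

  cn_of <- function(tab) {
    if (all(c("12C14N", "12C15N") %in% names(tab)))
      list(cn = tab[["12C14N"]] + tab[["12C15N"]], partial = FALSE)
    else if ("12C14N" %in% names(tab))
      list(cn = tab[["12C14N"]], partial = TRUE)
    else NULL
  }
  runs <- list(pt = cn_of(pt_roi), n = cn_of(n_roi))
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) stop("no run records a CN channel")
  c2 <- list(pt = pt_roi[["12C2"]], n = n_roi[["12C2"]])
  if (any(pt_roi[["12C2"]] <= 0) || any(n_roi[["12C2"]] <= 0))
    stop("undefined index: zero 12C2 reference counts")

  n_pt <- pt_roi[["194Pt"]]
  A <- n_pt / c2$pt
  ratios <- lapply(names(runs), function(r) runs[[r]]$cn / c2[[r]])
  if (any(unlist(lapply(names(runs), function(r) runs[[r]]$cn <= 0))))
    stop("undefined index: zero CN counts")
  B <- Reduce(`+`, ratios) / length(ratios)
  q <- A / B

  rel_var_A <- ifelse(n_pt > 0, 1 / n_pt, 0) + 1 / c2$pt
  var_B <- Reduce(`+`, lapply(names(runs), function(r) {
    rr <- runs[[r]]$cn / c2[[r]]
    rr^2 * (1 / runs[[r]]$cn + 1 / c2[[r]])
  })) / length(ratios)^2
  sigma_q <- q * sqrt(rel_var_A + var_B / B^2)
  sigma_q[n_pt == 0] <- (1 / c2$pt / B)[n_pt == 0]  # one-sided scale at 0 Pt

  data.frame(roi_id = pt_roi$roi_id, compartment = pt_roi$compartment,
             q = q, sigma_q = sigma_q,
             cn_runs = length(ratios),
             cn_minor_missing = any(vapply(runs, `[[`, logical(1), "partial")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble a per-compartment stoichiometry curve
#'
#' Aggregates per-ROI (q, x) values to one point per exposure concentration:
#' the across-ROI means, and the across-ROI standard deviations as the
#' dispersion (the curve's error bars). Points are ordered by concentration.
#'
#' @param points Data frame with columns \code{compartment},
#'   \code{concentration}, \code{roi_id}, \code{q}, \code{x} (and optionally
#'   \code{sigma_q}, \code{sigma_x}).
#' @param compartment Compartment to extract the curve for.
#' @return An object of class \code{"stoichiometry_curve"}: list with
#'   \code{compartment} and \code{points}, a data frame with
#'   \code{concentration}, \code{q_mean}, \code{q_sd}, \code{x_mean},
#'   \code{x_sd}, \code{n_roi} (and mean propagated errors when supplied).
#' @export
build_curve <- function(points, compartment) {
  stopifnot(is.data.frame(points),
            all(c("compartment", "concentration", "q", "x") %in% names(points)))
  pts <- points[points$compartment == compartment, , drop = FALSE]
  if (nrow(pts) == 0)
    stop("empty curve: compartment '", compartment, "' absent from all samples")
  sp <- split(pts, pts$concentration)
  tab <- do.call(rbind, lapply(sp, function(g) {
    data.frame(concentration = g$concentration[1],
               q_mean = mean(g$q), q_sd = stats::sd(g$q),
               x_mean = mean(g$x), x_sd = stats::sd(g$x),
               sigma_q_mean = if ("sigma_q" %in% names(g)) mean(g$sigma_q) else NA_real_,
               sigma_x_mean = if ("sigma_x" %in% names(g)) mean(g$sigma_x) else NA_real_,
               n_roi = nrow(g))
  }))
  tab <- tab[order(tab$concentration), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(compartment = compartment, points = tab),
            class = "stoichiometry_curve")
}

#' @export
print.stoichiometry_curve <- function(x, ...) {
  cat(sprintf("<stoichiometry_curve %s: %d concentrations>\n",
              x$compartment, nrow(x$points)))
  print(x$points, digits = 4)
  invisible(x)
}

#' Plot a stoichiometry curve
#'
#' Label fraction (per mil, ordinate) against the Pt/N index (abscissa) with
#' one-standard-deviation across-ROI error bars.
#'
#' @param x A \code{"stoichiometry_curve"}.
#' @param ... Passed to \code{plot}.
#' @export
plot.stoichiometry_curve <- function(x, ...) {
  p <- x$points
  plot(p$q_mean, 1000 * p$x_mean, xlab = "Pt/N index q",
       ylab = "label fraction x [per mil]", main = x$compartment, pch = 19, ...)
  ok <- is.finite(p$x_sd) & p$x_sd > 0
  if (any(ok))
    graphics::arrows(p$q_mean[ok], 1000 * (p$x_mean - p$x_sd)[ok],
                     p$q_mean[ok], 1000 * (p$x_mean + p$x_sd)[ok],
                     angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Fit the slope of a stoichiometry curve
#'
#' Least squares of the label fraction on the Pt/N index. The slope is
#' proportional to the N/Pt stoichiometry of the accumulated drug; a free
#' intercept is reported as a QC diagnostic (it should include 0) together
#' with a restricted through-origin slope.
#'
#' @param curve A \code{"stoichiometry_curve"}.
#' @param weighting \code{"none"} (ordinary least squares) or
#'   \code{"inverse-variance"} (weights \code{1/se^2} with \code{se} the
#'   standard error of each point's mean x: across-ROI sd/sqrt(n) where
#'   replicated, else the propagated counting error).
#' @return List of class \code{"stoich_fit"}: \code{slope}, \code{slope_se},
#'   \code{intercept}, \code{intercept_se}, \code{slope_origin},
#'   \code{slope_origin_se}, \code{n}, \code{weighting}, \code{compartment}.
#' @export
fit_slope <- function(curve, weighting = c("none", "inverse-variance")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(curve, "stoichiometry_curve"))
  p <- curve$points
  if (length(unique(p$q_mean)) < 2)
    stop("underdetermined fit: need >= 2 points with distinct q")
  w <- NULL
  if (weighting == "inverse-variance") {
    se <- ifelse(p$n_roi > 1 & is.finite(p$x_sd) & p$x_sd > 0,
                 p$x_sd / sqrt(p$n_roi), p$sigma_x_mean)
    if (any(!is.finite(se) | se <= 0)) {
      warning("non-positive point uncertainties; falling back to unweighted fit")
      weighting <- "none"
    } else w <- 1 / se^2
  }
  fit <- stats::lm(x_mean ~ q_mean, data = p, weights = w)
  fit0 <- stats::lm(x_mean ~ 0 + q_mean, data = p, weights = w)
  # summary() warns on exactly collinear input (zero residual); that case is
  # legitimate here (noise-free truth tables), so the warning is muted
  co <- suppressWarnings(summary(fit)$coefficients)
  co0 <- suppressWarnings(summary(fit0)$coefficients)
  structure(list(slope = unname(co["q_mean", "Estimate"]),
                 slope_se = unname(co["q_mean", "Std. Error"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 intercept_se = unname(co["(Intercept)", "Std. Error"]),
                 slope_origin = unname(co0["q_mean", "Estimate"]),
                 slope_origin_se = unname(co0["q_mean", "Std. Error"]),
                 n = nrow(p), weighting = weighting,
                 compartment = curve$compartment),
            class = "stoich_fit")
}

#' @export
print.stoich_fit <- function(x, ...) {
  cat(sprintf("<fit %s: slope %.5g +/- %.3g, intercept %.3g +/- %.3g, through-origin %.5g +/- %.3g (%s, n=%d)>\n",
              x$compartment, x$slope, x$slope_se, x$intercept, x$intercept_se,
              x$slope_origin, x$slope_origin_se, x$weighting, x$n))
  invisible(x)
}

#' Calibrate a curve slope to an N:Pt atom ratio
#'
#' SIMS is semi-quantitative: count ratios relate to atom ratios through
#' relative sensitivity factors (RSFs), unknown on real samples but known by
#' construction on phantoms. The x-vs-q slope equals (N:Pt) / (RSF ratio)
#' with RSF ratio = \code{rsf["pt"]/rsf["n"]} (the Pt/N count ratio produced
#' by a unit Pt/N atom ratio); the label-purity span (a_cddp - a_ctr) is
#' already absorbed in the label-fraction computation and does not re-enter.
#'
#' @param slope A numeric slope or a \code{"stoich_fit"} (its free slope is
#'   used and its standard error propagated).
#' @param sensitivity_factors Named vector \code{c(pt = , n = )} of positive
#'   RSFs, or NULL/missing for an uncalibrated result.
#' @return List with \code{ratio} (N atoms per Pt atom; NA when
#'   uncalibrated), \code{ratio_se}, \code{slope}, \code{calibrated} flag.
#' @export
calibrate_stoichiometry <- function(slope, sensitivity_factors = NULL) {
  se <- NA_real_
  if (inherits(slope, "stoich_fit")) {
    se <- slope$slope_se
    slope <- slope$slope
  }
  if (is.null(sensitivity_factors))
    return(list(ratio = NA_real_, ratio_se = NA_real_, slope = slope,
                calibrated = FALSE))
  if (!all(c("pt", "n") %in% names(sensitivity_factors)) ||
      any(sensitivity_factors[c("pt", "n")] <= 0))
    stop("sensitivity_factors must be positive and named 'pt' and 'n'")
  k <- unname(sensitivity_factors["pt"] / sensitivity_factors["n"])
  list(ratio = slope * k, ratio_se = se * k, slope = slope, calibrated = TRUE)
}
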