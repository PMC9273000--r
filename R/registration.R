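# Registration of sequentially acquired runs.
#
# The platinum and nitrogen acquisitions of one field are recorded
# sequentially, so the two stacks can be displaced by stage drift. A
# translation-only model is used (successive frames of one field differ
# mainly by drift) and shifts are applied by whole pixels with zero fill:
# resampling/interpolation would turn integer Poisson counts into
# non-integers and invalidate the counting-error model. Registration runs on
# the structural 12C2- channel, which both run types record (drug channels
# can be empty in controls).

#' Estimate the translation between two ion-count maps
#'
#' Phase correlation: the normalised cross-power spectrum of the two
#' (mean-subtracted) images is inverted and the correlation peak within
#' \code{max_shift} gives the integer displacement; an optional separable
#' parabolic fit through the peak's neighbours refines it to sub-pixel
#' precision (reported, never used to resample counts). Deterministic for
#' fixed inputs.
#'
#' @param ref,moving \code{\link{ion_count_map}}s of identical dimensions
#'   (conventionally the 12C2 channel of each run).
#' @param max_shift Maximum |shift| searched, in pixels (default 20).
#' @param subpixel Refine the integer peak parabolically (default TRUE).
#' @return An object of class \code{"shift"}: list with \code{d_row},
#'   \code{d_col} (real), integer parts \code{i_row}, \code{i_col}, and
#'   \code{score}, the Pearson correlation of the overlap after applying the
#'   integer shift. \code{moving} is modelled as \code{ref} translated by
#'   \code{(d_row, d_col)} (positive = down/right).
#' @export
estimate_shift <- function(ref, moving, max_shift = 20, subpixel = TRUE) {
  stopifnot(inherits(ref, "ion_count_map"), inherits(moving, "ion_count_map"))
  a <- ref$counts; b <- moving$counts
  if (!identical(dim(a), dim(b))) stop("maps must share dimensions")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("no structure: an input image has zero variance")
  a <- a - mean(a); b <- b - mean(b)
  fa <- stats::fft(a); fb <- stats::fft(b)
  cp <- fa * Conj(fb)
  mag <- Mod(cp)
  cp <- ifelse(mag > .Machine$double.eps, cp / mag, 0 + 0i)
  surf <- Re(stats::fft(cp, inverse = TRUE)) / length(cp)

  n <- nrow(surf); m <- ncol(surf)
  wrap_r <- ifelse(0:(n - 1) > n / 2, 0:(n - 1) - n, 0:(n - 1))
  wrap_c <- ifelse(0:(m - 1) > m / 2, 0:(m - 1) - m, 0:(m - 1))
  # candidate shift for peak index (i, j) is (-wrap_r[i], -wrap_c[j])
  allowed <- outer(abs(wrap_r) <= max_shift, abs(wrap_c) <= max_shift, "&")
  if (!any(allowed)) stop("max_shift excludes every candidate")
  masked <- ifelse(allowed, surf, -Inf)
  pk <- which(masked == max(masked), arr.ind = TRUE)[1, ]
  i_row <- -wrap_r[pk[1]]; i_col <- -wrap_c[pk[2]]

  d_row <- i_row; d_col <- i_col
  if (isTRUE(subpixel)) {
    para <- function(l, c0, r) {
      den <- l + r - 2 * c0
      if (den < 0) (l - r) / (2 * den) else 0
    }
    rp <- pk[1]; cpk <- pk[2]
    up <- surf[(rp - 2) %% n + 1, cpk]; dn <- surf[rp %% n + 1, cpk]
    lf <- surf[rp, (cpk - 2) %% m + 1]; rt <- surf[rp, cpk %% m + 1]
    # peak index offset maps to shift with opposite sign
    d_row <- i_row - para(up, surf[rp, cpk], dn)
    d_col <- i_col - para(lf, surf[rp, cpk], rt)
  }

  score <- .overlap_correlation(ref$counts, moving$counts, c(i_row, i_col))
  structure(list(d_row = d_row, d_col = d_col,
                 i_row = as.integer(i_row), i_col = as.integer(i_col),
                 score = score, max_shift = max_shift),
            class = "shift")
}

#' @export
print.shift <- function(x, ...) {
  cat(sprintf("<shift (%.3f, %.3f) px, integer (%d, %d), score %.4f>\n",
              x$d_row, x$d_col, x$i_row, x$i_col, x$score))
  invisible(x)
}

# Pearson correlation of ref with moving on the region where moving,
# translated back by -s, overlaps ref.
.overlap_correlation <- function(a, b, s) {
  n <- nrow(a); m <- ncol(a)
  r_ref <- intersect(seq_len(n), seq_len(n) + s[1])
  c_ref <- intersect(seq_len(m), seq_len(m) + s[2])
  if (length(r_ref) < 2 || length(c_ref) < 2) return(NA_real_)
  av <- a[r_ref - s[1], c_ref - s[2]]
  bv <- b[r_ref, c_ref]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(NA_real_)
  stats::cor(as.vector(av), as.vector(bv))
}

#' Apply a shift to an acquisition stack
#'
#' Translates every channel by the integer part of the shift, zero-filling
#' the exposed border; counts are never interpolated. The sub-pixel residual
#' is recorded in the returned stack's \code{subpixel_residual} field only.
#'
#' @param stack An \code{\link{acquisition_stack}}.
#' @param shift A \code{"shift"} object from \code{\link{estimate_shift}},
#'   or a numeric \code{c(d_row, d_col)}.
#' @return The translated stack; attribute-like fields
#'   \code{subpixel_residual} and \code{n_zero_filled} (pixels introduced by
#'   the border fill, per channel count once) are attached.
#' @export
apply_shift <- function(stack, shift) {
  stopifnot(inherits(stack, "acquisition_stack"))
  if (inherits(shift, "shift")) s <- c(shift$d_row, shift$d_col)
  else s <- as.numeric(shift)
  stopifnot(length(s) == 2L, all(is.finite(s)))
  si <- as.integer(round(s))
  resid <- s - si
  d <- stack_dim(stack)
  n_fill <- d[1] * d[2] -
    length(intersect(seq_len(d[1]), seq_len(d[1]) + si[1])) *
    length(intersect(seq_len(d[2]), seq_len(d[2]) + si[2]))
  stack$maps <- lapply(stack$maps, function(m) {
    m$counts <- .translate(m$counts, si, 0L)
    m
  })
  stack$subpixel_residual <- resid
  stack$n_zero_filled <- n_fill
  stack
}
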