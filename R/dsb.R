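# Quantification of DNA double-strand-break (DSB) induction from two-channel
# fluorescence images (nuclei: Hoechst; damage: phospho-H2AX), and the linear
# %DSB-vs-dose response with RBE.

#' Threshold an intensity channel into a binary mask
#'
#' Segments a single fluorescence channel by Otsu's method (default) or a
#' fixed threshold. Otsu is computed by `EBImage::otsu()` on the intensity
#' range of the image; the result is deterministic for a given grid.
#'
#' @param channel Numeric matrix of nonnegative, finite intensities.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Threshold for `method = "fixed"`, on the intensity scale
#'   of `channel`; pixels strictly above it are foreground.
#' @return Logical matrix of the same shape.
#' @export
segment_mask <- function(channel, method = c("otsu", "fixed"),
                         threshold = NULL) {
  method <- match.arg(method)
  if (!is.matrix(channel) || !is.numeric(channel) ||
      any(!is.finite(channel)) || any(channel < 0)) {
    stop("channel must be a numeric matrix of finite nonnegative intensities")
  }
  if (method == "fixed") {
    if (is.null(threshold) || !is.numeric(threshold)) {
      stop("method = 'fixed' requires a numeric threshold")
    }
    return(channel > threshold)
  }
  rng <- range(channel)
  if (rng[1L] == rng[2L]) {
    stop("constant-intensity channel: Otsu threshold is degenerate; use method = 'fixed'")
  }
  x <- (channel - rng[1L]) / (rng[2L] - rng[1L])
  th <- EBImage::otsu(x, range = c(0, 1), levels = 256L)
  x > th
}

#' Percentage of DSB induction from nuclear and damage masks
#'
#' The damage-area fraction: 100 x (damage area) / (nuclear morphology area),
#' where nuclear morphology is the union of the damage and nucleus masks
#' (damage signal lies inside nuclei; the union guards against nuclear-stain
#' dropout over strongly damaged chromatin).
#'
#' @param nuclear_mask,damage_mask Logical matrices of equal shape.
#' @return Percentage in `[0, 100]`.
#' @examples
#' nuc <- matrix(c(rep(TRUE, 75), rep(FALSE, 25)), 10, 10)
#' dmg <- matrix(c(rep(FALSE, 75), rep(TRUE, 25)), 10, 10)
#' percent_dsb(nuc, dmg)  # 25
#' @export
percent_dsb <- function(nuclear_mask, damage_mask) {
  if (!is.logical(nuclear_mask) || !is.logical(damage_mask) ||
      !identical(dim(nuclear_mask), dim(damage_mask))) {
    stop("masks must be logical matrices of equal shape")
  }
  union_area <- sum(nuclear_mask | damage_mask)
  if (union_area == 0) {
    stop("no cells: the union of the nuclear and damage masks is empty")
  }
  100 * sum(damage_mask) / union_area
}

#' Percentage of DSB induction from a two-channel image pair
#'
#' Segments both channels ([segment_mask()]) and applies [percent_dsb()].
#'
#' @param nuclei_channel,damage_channel Numeric intensity matrices of equal
#'   shape.
#' @param method Segmentation method passed to [segment_mask()].
#' @param threshold Fixed threshold, if `method = "fixed"`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_dsb_from_images <- function(nuclei_channel, damage_channel,
                                    method = "otsu", threshold = NULL) {
  if (!identical(dim(nuclei_channel), dim(damage_channel))) {
    stop("channel shapes differ")
  }
  percent_dsb(segment_mask(nuclei_channel, method, threshold),
              segment_mask(damage_channel, method, threshold))
}

#' Linear fit of %DSB induction against absorbed dose
#'
#' Ordinary least squares of `percent_dsb` on `dose_Gy` with a free intercept
#' (control wells show a nonzero damage baseline).
#'
#' @param measurements Data frame with numeric columns `dose_Gy` and
#'   `percent_dsb`; at least 3 distinct doses.
#' @return An object of class `linear_fit`: list with `slope` (%/Gy),
#'   `intercept` (%), `slope_se`, `residual_sd`, `n` and the underlying `lm`
#'   fit under `fit`.
#' @export
fit_linear_response <- function(measurements) {
  if (!is.data.frame(measurements) ||
      !all(c("dose_Gy", "percent_dsb") %in% names(measurements))) {
    stop("measurements must be a data frame with columns dose_Gy, percent_dsb")
  }
  if (length(unique(measurements$dose_Gy)) < 3L) {
    stop("insufficient data: need >= 3 distinct doses for a linear fit")
  }
  fit <- stats::lm(percent_dsb ~ dose_Gy, data = measurements)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 slope_se = sm$coefficients["dose_Gy", "Std. Error"],
                 residual_sd = sm$sigma,
                 n = nrow(measurements),
                 fit = fit),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> slope %.4g +/- %.2g %%/Gy, intercept %.3g %%, n = %d\n",
              x$slope, x$slope_se, x$intercept, x$n))
  invisible(x)
}

#' RBE from the slopes of two linear dose-responses
#'
#' For linear responses, the iso-effect dose ratio (reference dose over test
#' dose producing the same response above baseline) equals the slope ratio
#' test/reference.
#'
#' @param slope_test,slope_ref Positive slopes in %/Gy (test: the radiation
#'   under study; ref: the reference radiation).
#' @return The relative biological effectiveness, `slope_test / slope_ref`.
#' @examples
#' rbe_from_slopes(3.22, 2.0)  # 1.61
#' @export
rbe_from_slopes <- function(slope_test, slope_ref) {
  if (!is.numeric(slope_test) || !is.numeric(slope_ref) ||
      slope_test <= 0 || slope_ref <= 0) {
    stop("both slopes must be positive")
  }
  slope_test / slope_ref
}
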