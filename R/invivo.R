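# Biodistribution-based dosimetry (time-integrated activity concentration and
# absorbed dose per administered MBq) and tumour-growth series summaries.

# 1 %AA/g of a 1 MBq administration = 1e4 Bq per gram of tissue.
PCT_AA_PER_G_TO_BQ_PER_G_PER_MBQ <- 1e4

#' Time-integrated activity concentration from organ kinetics
#'
#' Integrates the activity concentration of an organ over all time from
#' sparse %AA/g samples (percent administered activity per gram, physical
#' decay included), per MBq administered.
#'
#' Two schemes are provided. `"trapezoid_physical_tail"` (default): linear
#' rise from zero at injection to the first sample, trapezoids between
#' samples, and beyond the last sample a mono-exponential tail whose rate is
#' the faster of the fitted terminal rate (last two samples) and the physical
#' decay constant; a non-physical (non-decaying) terminal rate falls back to
#' the physical constant with a warning. `"monoexp_fit"`: a single
#' exponential through all samples (log-linear fit), integrated analytically
#' from 0 to infinity; a non-decaying fitted rate falls back to the physical
#' constant with a warning.
#'
#' @param times_h Sample times in hours (>= 2 distinct, increasing).
#' @param values_pct_aa_g Concentrations in %AA/g at `times_h`.
#' @param nuclide A [get_nuclide()] object (supplies the physical decay
#'   constant).
#' @param scheme `"trapezoid_physical_tail"` or `"monoexp_fit"`.
#' @param organ Optional organ label carried into the result.
#' @return An object of class `time_integrated_activity`: list with
#'   `a_tilde_bq_s_per_g_mbq` (decays per gram per MBq administered),
#'   `scheme`, `organ`, `tail_fraction` (trapezoid scheme) and the fitted
#'   rate used.
#' @examples
#' i131 <- get_nuclide("I-131")
#' time_integrated_concentration(c(3, 24), c(10, 5), i131)
#' @export
time_integrated_concentration <- function(times_h, values_pct_aa_g, nuclide,
                                          scheme = c("trapezoid_physical_tail",
                                                     "monoexp_fit"),
                                          organ = NA_character_) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(nuclide, "nuclide"))
  if (length(times_h) < 2L || length(values_pct_aa_g) != length(times_h)) {
    stop("insufficient data: need >= 2 timepoints with matching values")
  }
  if (any(!is.finite(times_h)) || any(!is.finite(values_pct_aa_g)) ||
      any(times_h <= 0) || any(values_pct_aa_g < 0) || is.unsorted(times_h, strictly = TRUE)) {
    stop("times_h must be positive and strictly increasing; values must be >= 0")
  }
  lam_p <- decay_constant(nuclide$half_life_s)  # 1/s
  t_s <- times_h * 3600
  conc <- values_pct_aa_g * PCT_AA_PER_G_TO_BQ_PER_G_PER_MBQ  # Bq/g per MBq
  n <- length(t_s)

  if (all(conc == 0)) {
    return(structure(list(a_tilde_bq_s_per_g_mbq = 0, scheme = scheme,
                          organ = organ, rate_per_s = lam_p,
                          tail_fraction = 0),
                     class = "time_integrated_activity"))
  }

  if (scheme == "trapezoid_physical_tail") {
    rise <- t_s[1L] * conc[1L] / 2
    mid <- if (n > 2L || n == 2L) {
      sum(diff(t_s) * (conc[-1L] + conc[-n]) / 2)
    } else 0
    # terminal rate from the last two samples
    lam_fit <- if (conc[n] > 0 && conc[n - 1L] > 0) {
      log(conc[n - 1L] / conc[n]) / (t_s[n] - t_s[n - 1L])
    } else {
      NA_real_
    }
    if (is.na(lam_fit) || lam_fit <= 0) {
      if (!is.na(lam_fit)) {
        warning("non-decaying terminal slope; tail uses the physical decay constant")
      }
      lam_tail <- lam_p
    } else {
      lam_tail <- max(lam_fit, lam_p)
    }
    tail <- conc[n] / lam_tail
    a <- rise + mid + tail
    structure(list(a_tilde_bq_s_per_g_mbq = a, scheme = scheme, organ = organ,
                   rate_per_s = lam_tail, tail_fraction = tail / a),
              class = "time_integrated_activity")
  } else {
    pos <- conc > 0
    if (sum(pos) < 2L) stop("monoexp_fit needs >= 2 positive concentrations")
    fit <- stats::lm(log(conc[pos]) ~ t_s[pos])
    lam_eff <- -unname(stats::coef(fit)[2L])
    if (lam_eff <= 0) {
      warning("non-decaying fitted rate; using the physical decay constant")
      lam_eff <- lam_p
      c0 <- exp(mean(log(conc[pos]) + lam_eff * t_s[pos]))
    } else {
      c0 <- exp(unname(stats::coef(fit)[1L]))
    }
    structure(list(a_tilde_bq_s_per_g_mbq = c0 / lam_eff, scheme = scheme,
                   organ = organ, rate_per_s = lam_eff, c0_bq_g_mbq = c0),
              class = "time_integrated_activity")
  }
}

#' @export
print.time_integrated_activity <- function(x, ...) {
  cat(sprintf("<time_integrated_activity>%s %.4g Bq.s/g per MBq (%s)\n",
              if (is.na(x$organ)) "" else paste0(" ", x$organ),
              x$a_tilde_bq_s_per_g_mbq, x$scheme))
  invisible(x)
}

#' Absorbed dose coefficient from a time-integrated activity concentration
#'
#' Converts decays per gram per administered MBq into Gy/MBq:
#' `a_tilde x E_per_decay [keV] x 1.602e-16 [J/keV] x 1000 [g/kg] x
#' absorbed_fraction x rbe_weight`. With `rbe_weight > 1` the result is an
#' equivalent dose coefficient (the recommended weight for alpha-particle
#' dosimetry is 5; default 1 reports absorbed dose).
#'
#' @param a_tilde A [time_integrated_concentration()] result, or a bare
#'   number in Bq.s/g per MBq.
#' @param nuclide A [get_nuclide()] object (supplies energy per decay).
#' @param absorbed_fraction Fraction of emitted energy absorbed locally, in
#'   `(0, 1]`; default 1 (tumour self-dose convention).
#' @param rbe_weight Positive radiation weighting factor, default 1.
#' @return An object of class `dose_coefficient`: list with `gy_per_mbq`,
#'   `organ`, `absorbed_fraction`, `rbe_weight`, `nuclide`.
#' @export
absorbed_dose_per_mbq <- function(a_tilde, nuclide, absorbed_fraction = 1,
                                  rbe_weight = 1) {
  stopifnot(inherits(nuclide, "nuclide"))
  organ <- NA_character_
  if (inherits(a_tilde, "time_integrated_activity")) {
    organ <- a_tilde$organ
    a_tilde <- a_tilde$a_tilde_bq_s_per_g_mbq
  }
  if (!is.numeric(a_tilde) || a_tilde < 0) stop("a_tilde must be >= 0")
  if (!is.numeric(absorbed_fraction) || absorbed_fraction <= 0 ||
      absorbed_fraction > 1) {
    stop("absorbed_fraction must lie in (0, 1]")
  }
  if (!is.numeric(rbe_weight) || rbe_weight <= 0) {
    stop("rbe_weight must be positive")
  }
  gy <- a_tilde * nuclide$energy_per_decay_kev * KEV_TO_JOULE * 1e3 *
    absorbed_fraction * rbe_weight
  structure(list(gy_per_mbq = gy, organ = organ,
                 absorbed_fraction = absorbed_fraction,
                 rbe_weight = rbe_weight, nuclide = nuclide$name),
            class = "dose_coefficient")
}

#' @export
print.dose_coefficient <- function(x, ...) {
  cat(sprintf("<dose_coefficient>%s %s: %.4g Gy/MBq (AF %.2g, w %.2g)\n",
              if (is.na(x$organ)) "" else paste0(" ", x$organ),
              x$nuclide, x$gy_per_mbq, x$absorbed_fraction, x$rbe_weight))
  invisible(x)
}

#' Tumour regrowth day from a relative-size series
#'
#' Operationalises "regrowth": the first measured day after the series
#' minimum at which the relative size is at least `(1 + rebound_fraction)`
#' times the minimum on two consecutive measurements (the second measurement
#' confirms the rebound). Returns `NA` if the series never rebounds.
#'
#' @param day Numeric vector of measurement days, strictly increasing.
#' @param relative_size Positive relative tumour sizes (size / size at day
#'   0), same length, >= 3 points.
#' @param rebound_fraction Rebound threshold above the minimum, default 0.2.
#' @return The day of the first confirmed rebound measurement, or `NA`.
#' @examples
#' regrowth_day(c(0, 3, 6, 9, 12), c(1, 0.5, 0.5, 0.7, 0.8))  # day 9
#' @export
regrowth_day <- function(day, relative_size, rebound_fraction = 0.2) {
  if (length(day) < 3L || length(relative_size) != length(day)) {
    stop("insufficient data: need >= 3 timepoints")
  }
  if (is.unsorted(day, strictly = TRUE)) stop("days must be strictly increasing")
  if (any(relative_size <= 0)) stop("relative_size must be positive")
  m <- which.min(relative_size)
  thr <- (1 + rebound_fraction) * relative_size[m]
  n <- length(day)
  for (i in seq(m + 1L, length.out = max(0L, n - m - 1L))) {
    if (relative_size[i] >= thr && relative_size[i + 1L] >= thr) {
      return(day[i])
    }
  }
  NA_real_
}

#' Pairwise group comparison at one day with Bonferroni correction
#'
#' Classic unpaired two-sample t-tests (pooled variance) between every pair
#' of groups at a given day, with p-values multiplied by the number of
#' comparisons and capped at 1.
#'
#' @param data Data frame with columns `group`, `day` and a value column.
#' @param day The measurement day to compare at.
#' @param value Name of the value column, default `"relative_size"`.
#' @param correction `"bonferroni"` (the only option; kept explicit).
#' @return Data frame with columns `group1`, `group2`, `p_raw`,
#'   `p_corrected`, `n1`, `n2`.
#' @export
compare_groups_at_day <- function(data, day, value = "relative_size",
                                  correction = "bonferroni") {
  correction <- match.arg(correction, "bonferroni")
  if (!is.data.frame(data) || !all(c("group", "day", value) %in% names(data))) {
    stop("data must contain columns group, day and '", value, "'")
  }
  d <- data[data$day == day, , drop = FALSE]
  if (nrow(d) == 0L) stop("no measurements at day ", day)
  groups <- sort(unique(as.character(d$group)))
  counts <- table(as.character(d$group))
  if (any(counts < 2L)) {
    stop("every group needs >= 2 observations at day ", day)
  }
  pairs <- utils::combn(groups, 2L)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(i) {
    g1 <- d[d$group == pairs[1L, i], value]
    g2 <- d[d$group == pairs[2L, i], value]
    p <- stats::t.test(g1, g2, var.equal = TRUE)$p.value
    data.frame(group1 = pairs[1L, i], group2 = pairs[2L, i],
               p_raw = p, p_corrected = min(1, p * m),
               n1 = length(g1), n2 = length(g2))
  })
  do.call(rbind, out)
}
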