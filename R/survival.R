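# Clonogenic survival: surviving fractions from colony counts, linear and
# linear-quadratic fits of SF = exp(-alpha D - beta D^2), iso-effect doses
# and RBE at a survival level.

#' Surviving fraction from a colony count
#'
#' SF = (colonies / cells_seeded) / plating_efficiency, normalising to the
#' colony-forming rate of the untreated control. Values above 1 are permitted
#' (sampling noise) but flagged, as are zero counts (which cannot enter a
#' log-domain fit).
#'
#' @param colonies Nonnegative integer count of colonies.
#' @param cells_seeded Positive integer, cells plated per well (default
#'   1000).
#' @param plating_efficiency Control colony-forming fraction in `(0, 1]`.
#' @return Surviving fraction (numeric), with attribute `flag` set to
#'   `"zero"` for zero counts or `"gt1"` for SF > 1, otherwise `NULL`.
#' @examples
#' surviving_fraction(50, 1000, 0.5)  # 0.1
#' @export
surviving_fraction <- function(colonies, cells_seeded = 1000,
                               plating_efficiency) {
  if (!is.numeric(plating_efficiency) || plating_efficiency <= 0 ||
      plating_efficiency > 1) {
    stop("plating_efficiency must lie in (0, 1]")
  }
  if (!is.numeric(colonies) || colonies < 0 || !is.numeric(cells_seeded) ||
      cells_seeded <= 0) {
    stop("colonies must be >= 0 and cells_seeded > 0")
  }
  sf <- (colonies / cells_seeded) / plating_efficiency
  if (colonies == 0) attr(sf, "flag") <- "zero"
  else if (sf > 1) attr(sf, "flag") <- "gt1"
  sf
}

# Constrained weighted least squares of y = a*D + b*D^2 with a, b >= 0.
# With two parameters the constrained optimum is the best of the interior
# solution and the two boundary fits.
.wls_lq <- function(D, y, w, quadratic) {
  X <- if (quadratic) cbind(D = D, D2 = D^2) else cbind(D = D)
  fit_sub <- function(cols) {
    Xs <- X[, cols, drop = FALSE]
    XtWX <- crossprod(Xs * w, Xs)
    beta <- solve(XtWX, crossprod(Xs * w, y))
    list(cols = cols, beta = drop(beta),
         rss = sum(w * (y - drop(Xs %*% beta))^2),
         XtWX_inv = solve(XtWX))
  }
  cand <- list(fit_sub(seq_len(ncol(X))))
  if (any(cand[[1L]]$beta < 0) && quadratic) {
    cand <- c(cand, list(fit_sub(1L), fit_sub(2L)))
  }
  ok <- vapply(cand, function(f) all(f$beta >= 0), logical(1))
  if (!any(ok)) {
    # all-negative pathologies: clamp to zero response
    return(list(alpha = 0, beta = 0, cov = matrix(0, 2, 2), rss = sum(w * y^2),
                shared_loading = c(0, 0)))
  }
  best <- cand[ok][[which.min(vapply(cand[ok], `[[`, numeric(1), "rss"))]]
  p <- length(best$beta)
  sigma2 <- if (length(y) > p) best$rss / (length(y) - p) else 0
  cov <- matrix(0, 2, 2, dimnames = list(c("alpha", "beta"), c("alpha", "beta")))
  ab <- c(alpha = 0, beta = 0)
  idx <- if (identical(best$cols, 2L)) 2L else seq_along(best$cols)
  ab[idx] <- best$beta
  cov[idx, idx] <- sigma2 * best$XtWX_inv
  # response of the estimate to a unit error shared by every y value
  load <- c(0, 0)
  Xs <- X[, best$cols, drop = FALSE]
  load[idx] <- drop(best$XtWX_inv %*% crossprod(Xs * w, rep(1, length(y))))
  list(alpha = ab[["alpha"]], beta = ab[["beta"]], cov = cov, rss = best$rss,
       shared_loading = load)
}

#' Prepare colony-assay records for survival fitting
#'
#' Normalises colony counts to surviving fractions against the untreated
#' control, and derives the statistical ingredients of a weighted log-domain
#' fit: per-well weights approximating inverse variances of -ln(SF) under
#' Binomial counting noise, and the standard deviation of the shared
#' normalisation error from estimating the plating efficiency (which shifts
#' every -ln(SF) coherently and is therefore not captured by per-well
#' weights; pass it to `fit_survival(shared_sd = )`).
#'
#' @param records Data frame with columns `dose_Gy`, `colonies`,
#'   `cells_seeded`; rows with `dose_Gy == 0` are the control unless
#'   `plating_efficiency` is supplied.
#' @param plating_efficiency Optional known control colony-forming fraction;
#'   default: pooled from the `dose_Gy == 0` rows.
#' @return List with `data` (data frame `dose_Gy`, `sf` for treated wells
#'   with nonzero counts), `weights`, `shared_sd`, `plating_efficiency`,
#'   `n_dropped_zero` (treated wells with zero colonies).
#' @export
prepare_survival_data <- function(records, plating_efficiency = NULL) {
  .require_columns(records, c("dose_Gy", "colonies", "cells_seeded"),
                   "colony records")
  shared_sd <- 0
  if (is.null(plating_efficiency)) {
    ctrl <- records[records$dose_Gy == 0, , drop = FALSE]
    if (nrow(ctrl) == 0L) {
      stop("no dose_Gy == 0 control rows; supply plating_efficiency")
    }
    plating_efficiency <- sum(ctrl$colonies) / sum(ctrl$cells_seeded)
    if (plating_efficiency <= 0) stop("control wells produced no colonies")
    # var(ln PE-hat) under Binomial counting
    shared_sd <- sqrt((1 - plating_efficiency) / sum(ctrl$colonies))
  }
  trt <- records[records$dose_Gy > 0, , drop = FALSE]
  keep <- trt$colonies > 0
  d <- trt[keep, , drop = FALSE]
  p_hat <- pmin(d$colonies / d$cells_seeded, 1 - 1e-9)
  list(data = data.frame(dose_Gy = d$dose_Gy,
                         sf = (d$colonies / d$cells_seeded) / plating_efficiency),
       weights = d$colonies / (1 - p_hat),
       shared_sd = shared_sd,
       plating_efficiency = plating_efficiency,
       n_dropped_zero = sum(!keep))
}

#' Fit a linear or linear-quadratic survival curve
#'
#' Least squares of -ln(SF) on dose (linear) or on dose and dose^2
#' (linear-quadratic), with alpha, beta constrained nonnegative
#' (radiobiological convention). Points above `dose_cutoff` are removed
#' before fitting (used to exclude high-dose alpha points affected by
#' heterogeneous cellular uptake); zero-SF points are excluded with a
#' warning since they have no log transform.
#'
#' @param data Data frame with numeric columns `dose_Gy` and `sf`
#'   (surviving fraction), one row per observation (replicates as separate
#'   rows).
#' @param model `"linear"` or `"linear_quadratic"`.
#' @param dose_cutoff Optional maximum dose (Gy) retained in the fit.
#' @param weights Optional nonnegative observation weights on the -ln(SF)
#'   scale (e.g. inverse variances propagated from counts, as returned by
#'   [prepare_survival_data()]); default unweighted.
#' @param shared_sd Standard deviation of an error shared by every -ln(SF)
#'   value (e.g. from the plating-efficiency estimate); inflates the
#'   parameter covariance, default 0.
#' @return An object of class `survival_fit`: list with `model`, `alpha`
#'   (1/Gy), `beta` (1/Gy^2, 0 for linear), `covariance` (2x2),
#'   `dose_cutoff`, `n_points_used`, `n_points_total` and `data` (the
#'   retained points).
#' @examples
#' d <- data.frame(dose_Gy = 0:4, sf = exp(-0.3 * (0:4)))
#' fit_survival(d, "linear")$alpha  # 0.3
#' @export
fit_survival <- function(data, model = c("linear", "linear_quadratic"),
                         dose_cutoff = NULL, weights = NULL, shared_sd = 0) {
  model <- match.arg(model)
  if (!is.data.frame(data) || !all(c("dose_Gy", "sf") %in% names(data))) {
    stop("data must be a data frame with columns dose_Gy, sf")
  }
  n_total <- nrow(data)
  w <- if (is.null(weights)) rep(1, n_total) else weights
  stopifnot(length(w) == n_total, all(w >= 0))
  keep <- rep(TRUE, n_total)
  if (!is.null(dose_cutoff)) keep <- keep & data$dose_Gy <= dose_cutoff
  zero_sf <- keep & data$sf <= 0
  if (any(zero_sf)) {
    warning(sum(zero_sf), " zero-survival point(s) excluded from the log-domain fit")
    keep <- keep & !zero_sf
  }
  d <- data[keep, , drop = FALSE]
  w <- w[keep]
  need <- if (model == "linear") 2L else 3L
  if (sum(d$dose_Gy > 0) < need - 1L || nrow(d) < need) {
    stop("insufficient data: need >= ", need, " retained points with SF > 0")
  }
  res <- .wls_lq(d$dose_Gy, -log(d$sf), w, model == "linear_quadratic")
  if (shared_sd > 0) {
    res$cov <- res$cov + shared_sd^2 * tcrossprod(res$shared_loading)
  }
  structure(list(model = model, alpha = res$alpha, beta = res$beta,
                 covariance = res$cov, dose_cutoff = dose_cutoff,
                 n_points_used = nrow(d), n_points_total = n_total,
                 data = d),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> %s: alpha = %.4g /Gy, beta = %.4g /Gy^2 (%d/%d points%s)\n",
              x$model, x$alpha, x$beta, x$n_points_used, x$n_points_total,
              if (is.null(x$dose_cutoff)) "" else
                sprintf(", cutoff %.3g Gy", x$dose_cutoff)))
  invisible(x)
}

#' Iso-effect dose at a survival level
#'
#' Inverts the fitted survival curve: for the linear model
#' `D = -ln(level)/alpha`; for the linear-quadratic model the positive root
#' of `beta D^2 + alpha D + ln(level) = 0`.
#'
#' @param fit A [fit_survival()] object.
#' @param level Surviving fraction in `(0, 1]`, default 0.10 (the D10).
#' @return Dose in Gy (0 for `level = 1`).
#' @examples
#' f <- fit_survival(data.frame(dose_Gy = 0:4, sf = exp(-0.2303 * (0:4))),
#'                   "linear")
#' dose_at_survival(f, 0.10)  # ~10 Gy
#' @export
dose_at_survival <- function(fit, level = 0.10) {
  stopifnot(inherits(fit, "survival_fit"))
  if (!is.numeric(level) || level <= 0 || level > 1) {
    stop("level must lie in (0, 1]")
  }
  if (level == 1) return(0)
  if (fit$alpha <= 0 && fit$beta <= 0) {
    stop("no solution: alpha and beta are both zero")
  }
  L <- -log(level)  # > 0
  if (fit$beta <= 0) return(L / fit$alpha)
  (-fit$alpha + sqrt(fit$alpha^2 + 4 * fit$beta * L)) / (2 * fit$beta)
}

#' RBE at a survival level from two fitted curves
#'
#' The iso-effect dose ratio reference/test at a common surviving fraction
#' (default 10%). An optional residual-resampling bootstrap supplies a
#' percentile confidence interval.
#'
#' @param fit_ref Reference-radiation [fit_survival()] (e.g. the beta
#'   emitter).
#' @param fit_test Test-radiation fit (e.g. the alpha emitter).
#' @param level Surviving fraction, default 0.10.
#' @param bootstrap Number of bootstrap replicates (0 = none).
#' @param conf Confidence level for the bootstrap interval, default 0.95.
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `rbe_result`: list with `level`, `dose_ref_gy`,
#'   `dose_test_gy`, `rbe` and optionally `ci` (length-2) and `bootstrap`.
#' @export
rbe_at_level <- function(fit_ref, fit_test, level = 0.10, bootstrap = 0,
                         conf = 0.95, seed = 1) {
  stopifnot(inherits(fit_ref, "survival_fit"), inherits(fit_test, "survival_fit"))
  d_ref <- dose_at_survival(fit_ref, level)
  d_test <- dose_at_survival(fit_test, level)
  out <- list(level = level, dose_ref_gy = d_ref, dose_test_gy = d_test,
              rbe = d_ref / d_test)
  if (bootstrap > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
    boot_dose <- function(fit) {
      y <- -log(fit$data$sf)
      yhat <- fit$alpha * fit$data$dose_Gy + fit$beta * fit$data$dose_Gy^2
      res <- y - yhat
      vapply(seq_len(bootstrap), function(i) {
        yb <- yhat + sample(res, length(res), replace = TRUE)
        db <- fit$data
        db$sf <- exp(-pmax(yb, 0))
        fb <- tryCatch(fit_survival(db, fit$model, fit$dose_cutoff),
                       error = function(e) NULL)
        if (is.null(fb)) NA_real_ else
          tryCatch(dose_at_survival(fb, level), error = function(e) NA_real_)
      }, numeric(1))
    }
    reps <- boot_dose(fit_ref) / boot_dose(fit_test)
    out$bootstrap <- reps
    out$ci <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                              na.rm = TRUE, names = FALSE)
  }
  class(out) <- "rbe_result"
  out
}

#' @export
print.rbe_result <- function(x, ...) {
  cat(sprintf("<rbe_result> RBE = %.3f at SF = %.2g (D_ref %.3g Gy / D_test %.3g Gy)%s\n",
              x$rbe, x$level, x$dose_ref_gy, x$dose_test_gy,
              if (is.null(x$ci)) "" else
                sprintf("; 95%% CI [%.3f, %.3f]", x$ci[1L], x$ci[2L])))
  invisible(x)
}
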