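# Absorbed dose to cells during an in vitro radionuclide treatment:
#   D_T = kappa * (1 - exp(-lambda_p t_T))/lambda_p *
#         (f A0 S_c->c + (1 - f) A0 S_s->c)
# The bracketed term applies the end-of-treatment activity partition
# (fraction f in the cells, 1 - f in the solution); kappa (default 0.5)
# time-averages that partition over a treatment with gradual uptake.

#' Specify an in vitro radionuclide treatment
#'
#' Collects the inputs of the treatment absorbed-dose equation: the nuclide,
#' the administered activity, the fraction of it accumulated in the cells at
#' the end of treatment, the treatment duration, and the two S-values
#' (absorbed dose to the cell layer per decay in the cells and per decay in
#' the solution).
#'
#' @param nuclide A [get_nuclide()] object.
#' @param administered_activity_bq Administered activity A0 in Bq (>= 0).
#' @param uptake_fraction Fraction f of A0 in the cells at end of treatment,
#'   in `[0, 1]`. Measured values: 0.116 for At-211, 0.325 for I-131.
#' @param treatment_time_s Treatment duration t_T in seconds (> 0).
#' @param s_cell_from_cell S-value for decays in the cells, Gy per decay.
#' @param s_cell_from_solution S-value for decays in the solution, Gy per
#'   decay.
#' @param kappa Partition-averaging factor in `(0, 1]`, default 0.5: the
#'   equation applied literally to the end-of-treatment partition yields
#'   twice the dose of a linear-uptake treatment, so the time-averaged
#'   partition is half the final one. Set `kappa = 1` for an instant-uptake
#'   reading.
#' @param volume_cells_mm3,volume_solution_mm3 Optional region volumes (mm^3),
#'   recorded for provenance; they cancel out of the dose equation when
#'   activities are expressed as f * A0.
#' @return An object of class `treatment_spec`.
#' @export
treatment_spec <- function(nuclide, administered_activity_bq, uptake_fraction,
                           treatment_time_s, s_cell_from_cell,
                           s_cell_from_solution, kappa = 0.5,
                           volume_cells_mm3 = NULL,
                           volume_solution_mm3 = NULL) {
  stopifnot(inherits(nuclide, "nuclide"))
  if (!is.numeric(administered_activity_bq) || administered_activity_bq < 0) {
    stop("administered_activity_bq must be >= 0")
  }
  if (!is.numeric(uptake_fraction) || uptake_fraction < 0 ||
      uptake_fraction > 1) {
    stop("uptake_fraction must lie in [0, 1]")
  }
  if (!is.numeric(treatment_time_s) || treatment_time_s <= 0) {
    stop("treatment_time_s must be > 0")
  }
  if (missing(s_cell_from_cell) || missing(s_cell_from_solution) ||
      !is.numeric(s_cell_from_cell) || !is.numeric(s_cell_from_solution) ||
      s_cell_from_cell < 0 || s_cell_from_solution < 0) {
    stop("both S-values (s_cell_from_cell, s_cell_from_solution) are required and must be >= 0")
  }
  if (!is.numeric(kappa) || kappa <= 0 || kappa > 1) {
    stop("kappa must lie in (0, 1]")
  }
  structure(list(nuclide = nuclide,
                 administered_activity_bq = administered_activity_bq,
                 uptake_fraction = uptake_fraction,
                 treatment_time_s = treatment_time_s,
                 s_cell_from_cell = s_cell_from_cell,
                 s_cell_from_solution = s_cell_from_solution,
                 kappa = kappa,
                 volume_cells_mm3 = volume_cells_mm3,
                 volume_solution_mm3 = volume_solution_mm3),
            class = "treatment_spec")
}

#' Absorbed dose to cells for an in vitro treatment
#'
#' Evaluates the treatment dose equation for a [treatment_spec()]: the
#' decay-weighted exposure time ([decay_integral()]) times the
#' partition-weighted dose rate per unit administered activity, scaled by the
#' partition-averaging factor kappa. The cell-source and solution-source
#' contributions are reported separately.
#'
#' @param spec A [treatment_spec()].
#' @return An object of class `dose_result`: list with `dose_gy`,
#'   `cell_term_gy`, `solution_term_gy` and `provenance` (all inputs).
#' @examples
#' at <- get_nuclide("At-211")
#' sp <- treatment_spec(at, 1e6, 0.116, 3600,
#'                      s_cell_from_cell = 33.5e-9,
#'                      s_cell_from_solution = 0.247e-9)
#' compute_treatment_dose(sp)$dose_gy  # ~7.04 Gy
#' @export
compute_treatment_dose <- function(spec) {
  stopifnot(inherits(spec, "treatment_spec"))
  lam <- decay_constant(spec$nuclide$half_life_s)
  ti <- decay_integral(lam, spec$treatment_time_s)
  a0 <- spec$administered_activity_bq
  f <- spec$uptake_fraction
  cell_term <- spec$kappa * ti * f * a0 * spec$s_cell_from_cell
  sol_term <- spec$kappa * ti * (1 - f) * a0 * spec$s_cell_from_solution
  structure(list(dose_gy = cell_term + sol_term,
                 cell_term_gy = cell_term,
                 solution_term_gy = sol_term,
                 provenance = list(
                   nuclide = spec$nuclide$name,
                   half_life_s = spec$nuclide$half_life_s,
                   lambda_per_s = lam,
                   decay_integral_s = ti,
                   administered_activity_bq = a0,
                   uptake_fraction = f,
                   treatment_time_s = spec$treatment_time_s,
                   s_cell_from_cell = spec$s_cell_from_cell,
                   s_cell_from_solution = spec$s_cell_from_solution,
                   kappa = spec$kappa)),
            class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("<dose_result> %.4g Gy (cells %.3g + solution %.3g), %s, A0 = %.3g Bq\n",
              x$dose_gy, x$cell_term_gy, x$solution_term_gy,
              x$provenance$nuclide, x$provenance$administered_activity_bq))
  invisible(x)
}

#' Treatment doses over a series of administered activities
#'
#' Applies [compute_treatment_dose()] to each activity with all other
#' treatment parameters held fixed; the dose is linear in activity.
#'
#' @param spec_template A [treatment_spec()] whose activity is replaced
#'   element-wise.
#' @param activities_bq Numeric vector of administered activities in Bq
#'   (>= 0).
#' @return A data frame with columns `activity_Bq`, `dose_Gy`,
#'   `cell_term_Gy`, `solution_term_Gy`, in input order.
#' @export
dose_for_activity_series <- function(spec_template, activities_bq) {
  stopifnot(inherits(spec_template, "treatment_spec"))
  if (!is.numeric(activities_bq) || any(!is.finite(activities_bq)) ||
      any(activities_bq < 0)) {
    stop("activities_bq must be nonnegative and finite")
  }
  rows <- lapply(activities_bq, function(a) {
    s <- spec_template
    s$administered_activity_bq <- a
    d <- compute_treatment_dose(s)
    data.frame(activity_Bq = a, dose_Gy = d$dose_gy,
               cell_term_Gy = d$cell_term_gy,
               solution_term_Gy = d$solution_term_gy)
  })
  do.call(rbind, rows)
}
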