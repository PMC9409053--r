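# Shared helpers: hand-built nuclides and independent physics oracles.

# A minimal nuclide object with an arbitrary inventory, for transport tests.
make_test_nuclide <- function(kind, energy, yield = 1, half_life_s = 3600,
                              energy_per_decay = sum(yield * energy),
                              group = NA_character_) {
  structure(list(name = "test", half_life_s = half_life_s,
                 energy_per_decay_kev = energy_per_decay,
                 emissions = data.frame(kind = kind, yield = yield,
                                        energy = energy, mean_energy = energy,
                                        group = group,
                                        stringsAsFactors = FALSE),
                 daughters = list()),
            class = "nuclide")
}

# Independent energy-loss oracle: RK4 on dE/dl = -S(E) using the public
# stopping-power interpolator (no range tables). Returns residual energy
# after travelling `dist_um`.
rk4_residual_energy <- function(e0, dist_um, kind = "alpha", dl = 0.02) {
  e <- e0
  s <- 0
  f <- function(en) if (en < 1) Inf else radbiodose::stopping_power(en, kind)
  while (s < dist_um) {
    h <- min(dl, dist_um - s)
    k1 <- f(e);            if (!is.finite(k1) || e - h * k1 / 2 < 1) return(0)
    k2 <- f(e - h * k1 / 2)
    k3 <- f(e - h * k2 / 2); if (e - h * k3 < 1) return(0)
    k4 <- f(e - h * k3)
    e <- e - h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    if (e < 1) return(0)
    s <- s + h
  }
  e
}

# Quadrature oracle for the piecewise time-activity model of the
# trapezoid_physical_tail scheme: linear 0 -> first sample, linear between
# samples, exponential tail at `lam_tail` (1/s). Times in hours, values in
# %AA/g; returns Bq.s/g per MBq.
quadrature_tia_oracle <- function(times_h, values, lam_tail) {
  t_s <- times_h * 3600
  conc <- values * 1e4
  f <- function(u) {
    ifelse(u <= t_s[1], conc[1] * u / t_s[1],
           ifelse(u <= t_s[length(t_s)],
                  approx(t_s, conc, xout = u)$y,
                  conc[length(conc)] * exp(-lam_tail * (u - t_s[length(t_s)]))))
  }
  up <- t_s[length(t_s)] + 60 / lam_tail
  stats::integrate(f, 0, up, subdivisions = 2000L, rel.tol = 1e-10)$value
}
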