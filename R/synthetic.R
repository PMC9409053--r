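# Seeded synthetic-data generators. Each generator emulates the statistical
# structure one analysis stage assumes and returns its ground truth alongside
# the data, so every estimator in the package can be tested for recovery
# without external data.

.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  force(expr)
}

# Non-overlapping disk centres on a square image by rejection.
.place_nuclei <- function(n, size, radius) {
  centres <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(centres) < n) {
    tries <- tries + 1L
    if (tries > 20000L) stop("could not place ", n, " non-overlapping nuclei")
    p <- stats::runif(2, radius + 1, size - radius - 1)
    if (nrow(centres) == 0 ||
        all((centres[, 1] - p[1])^2 + (centres[, 2] - p[2])^2 >
            (2 * radius + 2)^2)) {
      centres <- rbind(centres, p)
    }
  }
  centres
}

#' Generate two-channel DSB image pairs with known damage fractions
#'
#' Renders, for each dose, a nucleus channel (non-overlapping disks) and a
#' damage channel in which each nucleus carries a damaged sub-region whose
#' pixel count is exactly `round((baseline + slope * dose) * nucleus area)`
#' (pixels closest to the nucleus centre, deterministic tie-break), plus
#' Gaussian intensity noise. The ground-truth damage-area percentage is
#' computed from the noiseless masks.
#'
#' @param doses_gy Numeric vector of absorbed doses (Gy).
#' @param n_nuclei Nuclei per image, default 20.
#' @param damage_area_per_gy Damage area fraction added per Gy, default 0.08.
#' @param baseline_fraction Damage area fraction at zero dose, default 0.02.
#' @param noise_sd Gaussian intensity noise SD (intensity scale 0-1),
#'   default 0.05.
#' @param image_size Image side in pixels, default 256.
#' @param nucleus_radius Nucleus radius in pixels, default 10.
#' @param seed RNG seed.
#' @return List with one element per dose: `dose_gy`, `nuclei` and `damage`
#'   intensity matrices, `truth_percent` (ground-truth damage percentage),
#'   `truth_nuclear_mask`, `truth_damage_mask`; plus attribute `seed`.
#' @export
generate_dsb_images <- function(doses_gy, n_nuclei = 20,
                                damage_area_per_gy = 0.08,
                                baseline_fraction = 0.02, noise_sd = 0.05,
                                image_size = 256, nucleus_radius = 10,
                                seed = 1) {
  fr_max <- baseline_fraction + damage_area_per_gy * max(doses_gy)
  if (fr_max > 1) {
    stop("infeasible damage fraction ", signif(fr_max, 3),
         " at the maximum dose; lower baseline_fraction or damage_area_per_gy")
  }
  if (any(doses_gy < 0)) stop("doses must be >= 0")
  .with_seed(seed, {
    xy <- expand.grid(x = seq_len(image_size), y = seq_len(image_size))
    out <- lapply(doses_gy, function(dose) {
      centres <- .place_nuclei(n_nuclei, image_size, nucleus_radius)
      nuc_mask <- matrix(FALSE, image_size, image_size)
      dmg_mask <- matrix(FALSE, image_size, image_size)
      frac <- baseline_fraction + damage_area_per_gy * dose
      for (i in seq_len(n_nuclei)) {
        d2 <- (xy$x - centres[i, 1])^2 + (xy$y - centres[i, 2])^2
        inside <- which(d2 <= nucleus_radius^2)
        nuc_mask[inside] <- TRUE
        n_dmg <- round(frac * length(inside))
        if (n_dmg > 0) {
          ord <- inside[order(d2[inside], inside)]  # centre-out, index tie-break
          dmg_mask[ord[seq_len(n_dmg)]] <- TRUE
        }
      }
      truth <- 100 * sum(dmg_mask) / sum(nuc_mask | dmg_mask)
      nuclei <- 0.15 + 0.7 * nuc_mask + matrix(stats::rnorm(image_size^2, 0, noise_sd),
                                               image_size)
      damage <- 0.15 + 0.7 * dmg_mask + matrix(stats::rnorm(image_size^2, 0, noise_sd),
                                               image_size)
      list(dose_gy = dose,
           nuclei = pmax(nuclei, 0), damage = pmax(damage, 0),
           truth_percent = truth,
           truth_nuclear_mask = nuc_mask, truth_damage_mask = dmg_mask)
    })
    attr(out, "seed") <- seed
    out
  })
}

#' Generate colony-formation assay counts under a survival model
#'
#' Colonies per well are Binomial(`cells_seeded`,
#' `plating_efficiency x exp(-alpha D - beta D^2)`), independently per
#' replicate.
#'
#' @param alpha,beta Survival-model coefficients (1/Gy and 1/Gy^2, >= 0).
#' @param doses_gy Dose levels (Gy).
#' @param cells_seeded Cells plated per well, default 1000.
#' @param plating_efficiency Control colony-forming fraction in `(0, 1]`.
#' @param replicates Wells per dose, default 3.
#' @param seed RNG seed.
#' @return Data frame with columns `dose_Gy`, `replicate`, `colonies`,
#'   `cells_seeded`, and attributes `alpha`, `beta`, `plating_efficiency`,
#'   `seed` (the generating truth).
#' @export
generate_colony_assay <- function(alpha, beta = 0, doses_gy,
                                  cells_seeded = 1000, plating_efficiency,
                                  replicates = 3, seed = 1) {
  stopifnot(alpha >= 0, beta >= 0, all(doses_gy >= 0), cells_seeded >= 1,
            plating_efficiency > 0, plating_efficiency <= 1, replicates >= 1)
  .with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(replicates), dose_Gy = doses_gy)
    p <- plating_efficiency * exp(-alpha * grid$dose_Gy - beta * grid$dose_Gy^2)
    out <- data.frame(dose_Gy = grid$dose_Gy, replicate = grid$replicate,
                      colonies = stats::rbinom(nrow(grid), cells_seeded, p),
                      cells_seeded = cells_seeded)
    out <- out[order(out$dose_Gy, out$replicate), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "alpha") <- alpha
    attr(out, "beta") <- beta
    attr(out, "plating_efficiency") <- plating_efficiency
    attr(out, "seed") <- seed
    out
  })
}

#' Generate an organ biodistribution table with log-normal animal noise
#'
#' Per-organ concentrations follow mono-exponential kinetics anchored at the
#' 3 h uptake: `C(t) = uptake_3h * exp(-lambda_eff (t - 3 h))`, with
#' `lambda_eff` from the organ's effective half-life. Effective half-lives
#' longer than the physical half-life are rejected (clearance can only add
#' to physical decay). Per-animal values are log-normal around the kinetic
#' mean with coefficient of variation `cv`.
#'
#' @param organs Data frame with columns `organ`, `uptake_3h_pct_aa_g`
#'   (%AA/g at 3 h) and `eff_half_life_h`.
#' @param nuclide A [get_nuclide()] object.
#' @param timepoints_h Sampling times in hours, default `c(3, 24)`.
#' @param n_animals Animals per timepoint, default 6.
#' @param cv Coefficient of variation of the log-normal animal noise,
#'   default 0.1.
#' @param seed RNG seed.
#' @return Data frame with columns `organ`, `time_h`, `animal`,
#'   `value_pct_aa_g`, `unit`; attribute `truth` holds the input kinetics and
#'   the seed.
#' @export
generate_biodistribution <- function(organs, nuclide, timepoints_h = c(3, 24),
                                     n_animals = 6, cv = 0.1, seed = 1) {
  stopifnot(inherits(nuclide, "nuclide"), cv >= 0, n_animals >= 1)
  need <- c("organ", "uptake_3h_pct_aa_g", "eff_half_life_h")
  if (!is.data.frame(organs) || !all(need %in% names(organs))) {
    stop("organs must contain columns ", paste(need, collapse = ", "))
  }
  phys_hl_h <- nuclide$half_life_s / 3600
  if (any(organs$eff_half_life_h > phys_hl_h + 1e-9)) {
    stop("effective half-life exceeds the physical half-life (",
         signif(phys_hl_h, 4), " h)")
  }
  .with_seed(seed, {
    sdlog <- sqrt(log(1 + cv^2))
    rows <- lapply(seq_len(nrow(organs)), function(i) {
      lam_eff <- log(2) / organs$eff_half_life_h[i]  # 1/h
      mu <- organs$uptake_3h_pct_aa_g[i] * exp(-lam_eff * (timepoints_h - 3))
      do.call(rbind, lapply(seq_along(timepoints_h), function(j) {
        v <- if (cv == 0) rep(mu[j], n_animals) else
          stats::rlnorm(n_animals, log(mu[j]) - sdlog^2 / 2, sdlog)
        data.frame(organ = organs$organ[i], time_h = timepoints_h[j],
                   animal = seq_len(n_animals), value_pct_aa_g = v,
                   unit = "%AA/g")
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(organs = organs, cv = cv, seed = seed,
                               nuclide = nuclide$name)
    out
  })
}

#' Generate tumour-growth series with a shrink/flat/regrow profile
#'
#' Mean log relative size per group: exponential decline to a nadir of
#' `exp(-kill)` over the first `min(delay, shrink_days)` days, flat until the
#' regrowth `delay_days`, then exponential regrowth at `growth_rate_per_day`.
#' `kill = 0` gives pure exponential growth. Animal noise is log-normal with
#' coefficient of variation `cv`; day-0 values are exactly 1 by construction.
#' Relative body weight is generated as a shallow transient dip.
#'
#' @param groups Data frame with columns `group`, `growth_rate_per_day`,
#'   `kill` (total log-kill, >= 0) and `delay_days`.
#' @param days Measurement days, starting at 0.
#' @param n_animals Animals per group, default 5.
#' @param cv Log-normal noise CV, default 0.1.
#' @param shrink_days Duration of the shrink phase (days), default 7.
#' @param seed RNG seed.
#' @return Data frame with columns `group`, `animal`, `day`,
#'   `relative_size`, `relative_weight`; attribute `truth` holds the group
#'   parameters and seed.
#' @export
generate_tumor_growth <- function(groups, days, n_animals = 5, cv = 0.1,
                                  shrink_days = 7, seed = 1) {
  need <- c("group", "growth_rate_per_day", "kill", "delay_days")
  if (!is.data.frame(groups) || !all(need %in% names(groups))) {
    stop("groups must contain columns ", paste(need, collapse = ", "))
  }
  if (length(days) < 1L || days[1L] != 0) stop("days must start at 0")
  stopifnot(all(groups$kill >= 0), cv >= 0, n_animals >= 1)
  .with_seed(seed, {
    sdlog <- sqrt(log(1 + cv^2))
    mean_log_size <- function(d, g, k, delay) {
      t_dec <- min(delay, shrink_days)
      if (k == 0) return(g * d)
      ifelse(d <= t_dec, -k * d / t_dec,
             ifelse(d <= delay, -k, -k + g * (d - delay)))
    }
    rows <- lapply(seq_len(nrow(groups)), function(i) {
      m <- mean_log_size(days, groups$growth_rate_per_day[i], groups$kill[i],
                         groups$delay_days[i])
      w <- 1 - 0.05 * exp(-((days - 7) / 5)^2) * (groups$kill[i] > 0)
      do.call(rbind, lapply(seq_len(n_animals), function(a) {
        noise <- ifelse(days == 0, 0,
                        stats::rnorm(length(days), -sdlog^2 / 2, sdlog))
        data.frame(group = groups$group[i], animal = a, day = days,
                   relative_size = exp(m + noise),
                   relative_weight = w * exp(ifelse(days == 0, 0,
                     stats::rnorm(length(days), 0, sdlog / 4))))
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(groups = groups, cv = cv, seed = seed,
                               shrink_days = shrink_days)
    out
  })
}
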