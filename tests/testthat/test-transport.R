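test_that("geometry presets match the assay dimensions and validate input", {
  g1 <- geometry_preset("dsb_well")
  expect_equal(g1$diameter_mm, 11.1)
  expect_equal(g1$solution_height_mm, 3.3)
  g2 <- geometry_preset("colony_well")
  expect_equal(g2$diameter_mm, 34.6)
  expect_equal(g2$solution_height_mm, 2.1)
  expect_equal(g1$cell_height_mm, 0.003)
  expect_equal(g1$dish_height_mm, 1)
  # mass of the cell layer: pi r^2 h rho
  expect_equal(g1$mass_kg[["cells"]],
               pi * (1.11 / 2)^2 * 3e-4 * 1 / 1e3, tolerance = 1e-12)
  expect_error(cylinder_assembly(-1, 1, 0.003, 3.3), "positive")
})

test_that("a degenerate single-line inventory yields exactly one alpha per decay", {
  nuc <- make_test_nuclide("alpha", 5000)
  set.seed(1)
  em <- sample_decay(nuc, 500)
  expect_equal(nrow(em), 500L)
  expect_true(all(em$kind == "alpha"))
  expect_true(all(em$energy == 5000))
  expect_equal(sort(unique(em$history)), 1:500)
  # directions are unit vectors
  expect_equal(em$dx^2 + em$dy^2 + em$dz^2, rep(1, 500), tolerance = 1e-12)
})

test_that("At-211 mean sampled alpha energy matches the branch-table expectation", {
  at <- get_nuclide("At-211")
  set.seed(7)
  em <- sample_decay(at, 1e5)
  a <- em[em$kind == "alpha", ]
  ey <- at$emissions[at$emissions$kind == "alpha", ]
  expected <- sum(ey$yield * ey$energy) / sum(ey$yield)
  se <- stats::sd(a$energy) / sqrt(nrow(a))
  expect_lt(abs(mean(a$energy) - expected), 3 * se)
  # one alpha per decay (exclusive branches summing to 1)
  expect_equal(nrow(a), 1e5)
})

test_that("transport conserves energy per particle to 1e-6 relative", {
  geom <- geometry_preset("dsb_well")
  set.seed(11)
  n <- 200
  for (kind in c("alpha", "beta")) {
    for (i in seq_len(n / 2)) {
      z0 <- runif(1, 0, sum(geom$z_um[4]))
      r0 <- sqrt(runif(1)) * geom$radius_um * 0.99
      th <- runif(1, 0, 2 * pi)
      d <- rnorm(3)
      e0 <- runif(1, 5, if (kind == "alpha") 7450 else 806)
      dep <- transport_particle(c(r0 * cos(th), r0 * sin(th), z0), d, kind,
                                e0, geom)
      expect_lt(abs(sum(dep$energy) - e0) / e0, 1e-6)
      expect_true(all(dep$energy >= -1e-12))
    }
  }
})

test_that("an alpha fully contained in a huge region deposits everything there", {
  # all dimensions >= 10x the ~38 um range of a 5 MeV alpha
  geom <- cylinder_assembly(50, 1, 2, 1)
  dep <- transport_particle(c(0, 0, 2000), c(0.3, -0.2, 0.9), "alpha", 5000,
                            geom)
  expect_equal(dep$energy[dep$region == "cells"], 5000, tolerance = 1e-9)
  expect_equal(sum(dep$energy[dep$region != "cells"]), 0)
})

test_that("in-plane alpha from the cell mid-plane stays in the 3 um layer", {
  geom <- geometry_preset("dsb_well")  # diameter 11.1 mm >> 50 um range
  z_mid <- geom$z_um[2] + 1.5  # cell layer mid-plane
  dep <- transport_particle(c(0, 0, z_mid), c(1, 0, 0), "alpha", 6000, geom)
  expect_equal(dep$energy[dep$region == "cells"], 6000, tolerance = 1e-9)
})

test_that("axial alpha from the cell layer ends in the solution, never escapes", {
  geom <- geometry_preset("dsb_well")  # solution 3.3 mm >> range
  z_mid <- geom$z_um[2] + 1.5
  dep <- transport_particle(c(0, 0, z_mid), c(0, 0, 1), "alpha", 7450, geom)
  expect_equal(dep$energy[dep$region == "escaped"], 0)
  expect_equal(dep$energy[dep$region == "dish"], 0)
  expect_gt(dep$energy[dep$region == "solution"], 0)
  expect_equal(sum(dep$energy), 7450, tolerance = 1e-6)
})

test_that("transport rejects origins outside the assembly", {
  geom <- geometry_preset("dsb_well")
  expect_error(transport_particle(c(0, 0, -5), c(0, 0, 1), "alpha", 5000, geom),
               "outside")
  expect_error(transport_particle(c(1e6, 0, 10), c(0, 0, 1), "alpha", 5000,
                                  geom), "outside")
})

test_that("full-absorption S-value equals E/m (with slab leakage) and scales as 1/mass", {
  # uniform isotropic emission in a slab of height h leaks a fraction R/(4h)
  # of the energy through the faces (constant-LET closed form), so the
  # expected S is (E/m)(1 - R/(4h)); allow 3 SE plus a quarter of the
  # leakage term for the LET variation along the track
  nuc <- make_test_nuclide("alpha", 5000)
  R <- csda_range(5000, "alpha")
  geom1 <- cylinder_assembly(50, 1, 1, 1)   # cell layer 1 mm >> 38 um range
  s1 <- estimate_s_values(nuc, geom1, "cells", n_histories = 4000, seed = 5)
  closed <- 5000 * 1.602176634e-16 / geom1$mass_kg[["cells"]]
  leak1 <- closed * R / (4 * 1000)
  expect_lt(abs(s1$s_gy_per_decay - (closed - leak1)),
            3 * s1$se_gy_per_decay + leak1 / 4)
  # doubling the cell height halves S in the full-absorption limit
  geom2 <- cylinder_assembly(50, 1, 2, 1)
  s2 <- estimate_s_values(nuc, geom2, "cells", n_histories = 4000, seed = 6)
  expect_lt(abs(s1$s_gy_per_decay / s2$s_gy_per_decay - 2), 0.03)
})

test_that("thin-slab S-value agrees with a brute-force grid + RK oracle", {
  # mono-energetic alpha uniform in the 3 um cell layer; huge diameter so the
  # radial wall is irrelevant. Oracle: average deposit over a dense (z, mu)
  # grid, integrating dE/dl with RK4 on the public stopping-power curve --
  # fully independent of the transport's range-table machinery.
  e0 <- 5000
  h <- 3
  geom <- geometry_preset("dsb_well")
  nuc <- make_test_nuclide("alpha", e0)
  s_mc <- estimate_s_values(nuc, geom, "cells", n_histories = 3e4, seed = 9)

  zs <- seq(h / 40, h - h / 40, length.out = 20)
  mus <- seq(-0.9875, 0.9875, length.out = 40)
  deposits <- outer(zs, mus, Vectorize(function(z, mu) {
    exit <- if (mu > 0) (h - z) / mu else z / (-mu)
    e0 - rk4_residual_energy(e0, exit, "alpha")
  }))
  s_oracle <- mean(deposits) * 1.602176634e-16 / geom$mass_kg[["cells"]]
  expect_lt(abs(s_mc$s_gy_per_decay - s_oracle),
            3 * s_mc$se_gy_per_decay + 0.02 * s_oracle)
})

test_that("S-value runs are bit-reproducible for a fixed seed", {
  at <- get_nuclide("At-211")
  geom <- geometry_preset("dsb_well")
  s1 <- estimate_s_values(at, geom, "cells", n_histories = 2000, seed = 123)
  s2 <- estimate_s_values(at, geom, "cells", n_histories = 2000, seed = 123)
  expect_identical(s1$s_gy_per_decay, s2$s_gy_per_decay)
  expect_identical(s1$se_gy_per_decay, s2$se_gy_per_decay)
  s3 <- estimate_s_values(at, geom, "cells", n_histories = 2000, seed = 124)
  expect_false(identical(s1$s_gy_per_decay, s3$s_gy_per_decay))
})

test_that("solution-source S never exceeds cell self-dose S for the alpha emitter", {
  at <- get_nuclide("At-211")
  for (preset in c("dsb_well", "colony_well")) {
    g <- geometry_preset(preset)
    sc <- estimate_s_values(at, g, "cells", n_histories = 5000, seed = 21)
    ss <- estimate_s_values(at, g, "solution", n_histories = 5000, seed = 22)
    expect_lt(ss$s_gy_per_decay, sc$s_gy_per_decay)
  }
})

test_that("zero-yield inventory gives S = 0 and bad n_histories errors", {
  nuc <- make_test_nuclide("alpha", 5000, yield = 0)
  geom <- geometry_preset("dsb_well")
  s <- estimate_s_values(nuc, geom, "cells", n_histories = 100, seed = 1)
  expect_identical(s$s_gy_per_decay, 0)
  expect_error(estimate_s_values(nuc, geom, "cells", n_histories = 0, seed = 1),
               "n_histories")
})

test_that("standard error shrinks roughly as 1/sqrt(n_histories)", {
  at <- get_nuclide("At-211")
  geom <- geometry_preset("dsb_well")
  s_small <- estimate_s_values(at, geom, "cells", n_histories = 1000, seed = 3)
  s_big <- estimate_s_values(at, geom, "cells", n_histories = 16000, seed = 3)
  ratio <- s_small$se_gy_per_decay / s_big$se_gy_per_decay
  expect_gt(ratio, 2.4)  # ideal 4, generous band for variance noise
  expect_lt(ratio, 6.7)
})

test_that("gamma energy escapes by default and deposits kerma when asked", {
  geom <- geometry_preset("dsb_well")
  dep_esc <- transport_particle(c(0, 0, 2000), c(0, 0, 1), "gamma", 364.5, geom)
  expect_equal(dep_esc$energy[dep_esc$region == "escaped"], 364.5)
  dep_k <- transport_particle(c(0, 0, 2000), c(0, 0, 1), "gamma", 364.5, geom,
                              gamma_mode = "kerma")
  expect_lt(dep_k$energy[dep_k$region == "escaped"], 364.5)
  expect_gt(dep_k$energy[dep_k$region == "solution"], 0)
  expect_equal(sum(dep_k$energy), 364.5, tolerance = 1e-9)
})
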