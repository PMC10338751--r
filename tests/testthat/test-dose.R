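single_spot <- function(x = 0, y = 0, mu = 1, sigma = 5) {
  tibble::tibble(field_id = "F01", gantry_angle_deg = 0, layer_index = 0,
                 energy_MeV = 100, spot_index = 0, x_mm = x, y_mm = y, mu = mu,
                 sigma_x_mm = sigma, sigma_y_mm = sigma)
}

test_that("a single spot maps to a unimodal Gaussian centred on the spot", {
  g <- fluence_map(single_spot(x = 3, y = -4), spacing_mm = 1)
  ax <- list(x = g$origin_mm[1] + (seq_len(nrow(g$values)) - 1) * g$spacing_mm,
             y = g$origin_mm[2] + (seq_len(ncol(g$values)) - 1) * g$spacing_mm)
  peak <- which(g$values == max(g$values), arr.ind = TRUE)
  expect_equal(ax$x[peak[1]], 3)
  expect_equal(ax$y[peak[2]], -4)
})

test_that("the map of one spot integrates to its MU", {
  for (mu in c(0.01, 0.5, 2)) {
    g <- fluence_map(single_spot(mu = mu), spacing_mm = 1)
    expect_lt(abs(sum(g$values) * g$spacing_mm^2 - mu) / mu, 0.01)
  }
})

test_that("fluence is linear in MU and additive over spots", {
  s <- single_spot(mu = 0.02)
  g1 <- fluence_map(s, spacing_mm = 2)
  s3 <- s; s3$mu <- 3 * s$mu
  g3 <- fluence_map(s3, spacing_mm = 2, grid = g1)
  expect_equal(g3$values, 3 * g1$values, tolerance = 1e-12)
  # two identical coincident spots give exactly twice the single map
  two <- dplyr::bind_rows(s, s)
  g2 <- fluence_map(two, spacing_mm = 2, grid = g1)
  expect_equal(g2$values, 2 * g1$values, tolerance = 1e-12)
})

test_that("sigmas fall back to the commissioning baseline for planned spots", {
  plan <- tiny_plan(n_layers = 1, n_spots = 3)
  b <- flat_baseline(sigma_x = 6, sigma_y = 6)
  g <- fluence_map(plan, baseline = b, spacing_mm = 2)
  manual <- plan
  manual$sigma_x_mm <- 6; manual$sigma_y_mm <- 6
  g2 <- fluence_map(manual, spacing_mm = 2, grid = g)
  expect_equal(g$values, g2$values, tolerance = 1e-12)
  expect_qa_error(fluence_map(plan, spacing_mm = 2), "qa_domain_error", "baseline")
})

test_that("a grid that clips a spot's 3-sigma footprint is rejected", {
  s <- single_spot(sigma = 5)
  small <- dose_grid(matrix(0, 5, 5), c(-4, -4), 2)
  expect_qa_error(fluence_map(s, grid = small), "qa_domain_error", "footprint")
})

test_that("dose difference is signed, element-wise and geometry-checked", {
  g <- fluence_map(single_spot(), spacing_mm = 2)
  expect_equal(dose_difference(g, g)$values, matrix(0, nrow(g$values), ncol(g$values)))
  # scaling: difference of 1.1x map is 0.1x map everywhere
  g11 <- dose_grid(1.1 * g$values, g$origin_mm, g$spacing_mm)
  expect_equal(dose_difference(g, g11)$values, 0.1 * g$values, tolerance = 1e-12)
  # one-pixel shift gives an antisymmetric dipole with near-zero sum
  shifted <- dose_grid(rbind(g$values[-1, ], 0), g$origin_mm, g$spacing_mm)
  dd <- dose_difference(g, shifted)
  expect_true(dd$signed)
  expect_lt(abs(sum(dd$values)) / sum(g$values), 0.01)
  expect_lt(max(dd$values) * -1 / min(dd$values), 1.05)
  other <- dose_grid(g$values, g$origin_mm + 1, g$spacing_mm)
  expect_qa_error(dose_difference(g, other), "qa_domain_error", "geometry")
})

test_that("gamma of identical grids is zero with a 100% pass rate", {
  g <- fluence_map(single_spot(), spacing_mm = 2)
  res <- gamma_analysis(g, g)
  expect_equal(res$pass_rate, 100)
  expect_equal(max(res$gamma, na.rm = TRUE), 0)
  expect_true(res$pass)
  # low-dose pixels are excluded from evaluation
  expect_lt(res$n_evaluated, length(g$values))
})

test_that("an exact 3% global scaling keeps every gamma within unity", {
  g <- fluence_map(single_spot(), spacing_mm = 2)
  g103 <- dose_grid(1.03 * g$values, g$origin_mm, g$spacing_mm)
  res <- gamma_analysis(g, g103)
  expect_lte(max(res$gamma, na.rm = TRUE), 1 + 1e-6)
  expect_equal(res$pass_rate, 100)
})

test_that("optimized gamma equals the exhaustive brute-force search", {
  set.seed(404)
  crit <- gamma_criteria()
  for (i in 1:3) {
    ref <- random_smooth_grid(n = 20, spacing = 2)
    modulation <- (1 + 0.04 * sin(seq_len(20) / 3)) %o% (1 + 0.03 * cos(seq_len(20) / 4))
    ev <- dose_grid(ref$values * modulation, ref$origin_mm, ref$spacing_mm)
    fast <- gamma_analysis(ref, ev, crit)
    slow <- brute_gamma(ref, ev, crit)
    expect_equal(fast$gamma, slow, tolerance = 1e-6)
  }
})

test_that("loosening either criterion never increases any pixel's gamma", {
  set.seed(42)
  ref <- random_smooth_grid(n = 18, spacing = 2)
  ev <- dose_grid(ref$values * 1.05, ref$origin_mm, ref$spacing_mm)
  tight <- gamma_analysis(ref, ev, gamma_criteria(dose_percent = 2, dta_mm = 2))
  loose_dose <- gamma_analysis(ref, ev, gamma_criteria(dose_percent = 4, dta_mm = 2))
  loose_dta <- gamma_analysis(ref, ev, gamma_criteria(dose_percent = 2, dta_mm = 4))
  # dose loosening reuses the identical search lattice: exactly monotone
  expect_true(all(loose_dose$gamma <= tight$gamma + 1e-12, na.rm = TRUE))
  # the dta search lattice rescales with dta (step dta/10), so monotonicity
  # holds up to the lattice resolution rather than exactly
  expect_true(all(loose_dta$gamma <= tight$gamma + 0.15, na.rm = TRUE))
  expect_lt(mean(loose_dta$gamma, na.rm = TRUE), mean(tight$gamma, na.rm = TRUE))
})

test_that("gamma requires matching geometry and evaluable dose", {
  g <- fluence_map(single_spot(), spacing_mm = 2)
  other <- dose_grid(g$values, g$origin_mm + 0.5, g$spacing_mm)
  expect_qa_error(gamma_analysis(g, other), "qa_domain_error", "geometry")
  tiny <- dose_grid(matrix(1, 4, 4), c(0, 0), 2)
  zero <- dose_grid(matrix(0, 4, 4), c(0, 0), 2)
  expect_qa_error(gamma_analysis(zero, tiny), "qa_domain_error")
})

test_that("reconstructed identity delivery passes gamma at 100%", {
  for (seed in c(12, 34)) {
    plan <- generate_plan(n_fields = 1, layers_per_field = 2,
                          spots_per_layer = 9, seed = seed)
    b <- synthetic_size_baseline()
    recon <- reconstruct_plan(plan, plan_as_session(plan, baseline = b))
    ref <- fluence_map(plan, baseline = b, spacing_mm = 3)
    ev <- fluence_map(recon, baseline = b, spacing_mm = 3, grid = ref)
    expect_equal(gamma_analysis(ref, ev)$pass_rate, 100)
  }
})

test_that("dose grids round-trip through the plain-text format", {
  g <- fluence_map(single_spot(mu = 0.37), spacing_mm = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_dose_grid(g, path)
  back <- read_dose_grid(path)
  expect_equal(back$values, g$values, tolerance = 1e-15)
  expect_equal(back$origin_mm, g$origin_mm)
  expect_equal(back$spacing_mm, g$spacing_mm)
  expect_equal(back$signed, g$signed)
})
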