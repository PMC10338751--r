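test_that("spot deviations are component-wise delivered minus planned", {
  paired <- tibble::tibble(x_plan = 10.0, y_plan = -5.0, mu_plan = 0.010,
                           x_del = 10.2, y_del = -5.1, mu_del = 0.010)
  d <- spot_deviations(paired)
  expect_equal(d$d_x_mm, 0.2)
  expect_equal(d$d_y_mm, -0.1)
  expect_equal(d$d_mu, 0)
  # identity pair gives the all-zero deviation
  ident <- spot_deviations(tibble::tibble(x_plan = 1, y_plan = 2, mu_plan = 0.01,
                                          x_del = 1, y_del = 2, mu_del = 0.01))
  expect_equal(unlist(ident[c("d_x_mm", "d_y_mm", "d_mu", "d_mu_percent")]),
               c(d_x_mm = 0, d_y_mm = 0, d_mu = 0, d_mu_percent = 0))
  # percent difference uses the planned MU as denominator
  pm <- spot_deviations(tibble::tibble(x_plan = 0, y_plan = 0, mu_plan = 0.010,
                                       x_del = 0, y_del = 0, mu_del = 0.0102))
  expect_equal(pm$d_mu, 0.0002)
  expect_equal(pm$d_mu_percent, 2.0)
})

test_that("systematic error is the layer mean and random errors the residuals", {
  d <- c(0.1, 0.2, 0.3)
  expect_equal(layer_systematic_error(d), 0.2)
  expect_equal(layer_random_errors(d), c(-0.1, 0, 0.1))
  # a pure block shift: systematic carries it all, residuals vanish
  blk <- rep(0.7, 10)
  expect_equal(layer_systematic_error(blk), 0.7)
  expect_equal(layer_random_errors(blk), rep(0, 10))
  expect_qa_error(layer_systematic_error(numeric(0)), "qa_domain_error")
  expect_qa_error(layer_random_errors(numeric(0)), "qa_domain_error")
})

test_that("the decomposition recovers an injected shift from noisy spots", {
  set.seed(500)
  n <- 1000
  d <- 0.5 + rnorm(n, 0, 0.05)
  est <- layer_systematic_error(d)
  expect_lt(abs(est - 0.5), 3 * 0.05 / sqrt(n))
  res <- layer_random_errors(d)
  expect_equal(mean(res), 0, tolerance = 1e-12)
  expect_lt(abs(sd(res) - 0.05) / 0.05, 0.15)
})

test_that("deviation = systematic + residual exactly; residuals sum to zero", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(2:60, 1)
    d <- rnorm(n, sd = runif(1, 0.01, 2))
    s <- layer_systematic_error(d)
    r <- layer_random_errors(d)
    expect_equal(s + r, d, tolerance = 1e-13)
    expect_lt(abs(sum(r)), 1e-9)
  }
})

test_that("layer size deviation compares the layer mean against baseline", {
  b <- flat_baseline(sigma_x = 5, sigma_y = 5)
  mk_layer <- function(sx) tibble::tibble(energy_MeV = 100, sigma_x_mm = sx,
                                          sigma_y_mm = 5)
  # delivered equal to baseline: zero deviation
  z <- layer_size_deviation(mk_layer(c(5, 5)), b, 0)
  expect_equal(z$size_dev_x_mm, 0)
  expect_equal(z$size_dev_x_percent, 0)
  # +0.4 mm on a 5 mm baseline is +8%, inside a 10% tolerance
  d8 <- layer_size_deviation(mk_layer(c(5.4, 5.4)), b, 0)
  expect_equal(d8$size_dev_x_mm, 0.4)
  expect_equal(d8$size_dev_x_percent, 8)
  # +12% must flag at the 10% tolerance when evaluated
  plan <- tiny_plan(n_layers = 1, n_spots = 4)
  sess <- plan_as_session(plan, baseline = b)
  sess$sigma_x_mm <- 5.6
  rep <- qa_check(plan, sess, b)
  expect_equal(nrow(rep$flags), 1)
  expect_equal(rep$flags$kind, "size")
  expect_equal(rep$flags$axis, "x")
  expect_equal(rep$flags$value, 12, tolerance = 1e-9)
})

test_that("an identity delivery passes with zero flags", {
  plan <- generate_plan(n_fields = 2, layers_per_field = 3,
                        spots_per_layer = 10, seed = 5)
  rep <- qa_check(plan, plan_as_session(plan), synthetic_size_baseline())
  expect_true(rep$pass)
  expect_equal(nrow(rep$flags), 0)
  expect_equal(max(abs(rep$spots$d_x_mm)), 0)
  expect_equal(max(abs(rep$layers$systematic_y_mm)), 0)
})

test_that("one displaced spot yields exactly one random flag at that spot", {
  plan <- generate_plan(n_fields = 1, layers_per_field = 1,
                        spots_per_layer = 100, seed = 31)
  sess <- plan_as_session(plan)
  sess$x_mm[18] <- sess$x_mm[18] + 1.5
  rep <- qa_check(plan, sess, synthetic_size_baseline())
  # systematic mean moves only 1.5/100 = 0.015 mm, far below 1 mm
  expect_equal(rep$layers$systematic_x_mm, 0.015)
  expect_equal(nrow(rep$flags), 1)
  expect_equal(rep$flags$kind, "random")
  expect_equal(rep$flags$axis, "x")
  expect_equal(rep$flags$spot_index, sess$spot_index[18])
  # residual of the displaced spot is 1.5 - 0.015
  expect_equal(rep$flags$value, 1.5 - 0.015)
})

test_that("a whole layer shifted beyond tolerance yields exactly one systematic flag", {
  plan <- generate_plan(n_fields = 1, layers_per_field = 3,
                        spots_per_layer = 40, seed = 32)
  sess <- plan_as_session(plan)
  shift_rows <- sess$layer_index == 1
  sess$y_mm[shift_rows] <- sess$y_mm[shift_rows] + 1.2
  rep <- qa_check(plan, sess, synthetic_size_baseline())
  expect_equal(nrow(rep$flags), 1)
  expect_equal(rep$flags$kind, "systematic")
  expect_equal(rep$flags$axis, "y")
  expect_equal(rep$flags$layer_index, 1)
  expect_equal(rep$flags$value, 1.2, tolerance = 1e-9)
  # the shift is purely systematic: no random residual moved
  expect_lt(max(abs(rep$spots$random_y_mm)), 1e-9)
})

test_that("evaluate_field agrees with a naive double-loop reference", {
  cfg <- tolerance_config(pos_systematic_mm = 0.2, pos_random_mm = 0.1,
                          mu_abs = 3e-4, size_percent = 2)
  b <- synthetic_size_baseline()
  for (seed in c(3, 8, 21, 34)) {
    set.seed(seed)
    plan <- generate_plan(n_fields = 1,
                          layers_per_field = sample(2:5, 1),
                          spots_per_layer = sample(5:20, 1), seed = seed)
    sim <- simulate_delivery(plan, error_model(
      sys_sd_x_mm = 0.3, sys_sd_y_mm = 0.3, rand_sd_x_mm = 0.15,
      rand_sd_y_mm = 0.15, mu_sd = 4e-4, size_sd_x_mm = 0.3,
      size_sd_y_mm = 0.3, seed = seed + 1000), baseline = b)
    got <- sort_flags(qa_check(plan, sim$session, b, cfg)$flags)
    want <- sort_flags(naive_flags(plan, sim$session, b, cfg))
    expect_gt(nrow(want), 0)  # the noisy model must exercise the flag paths
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$kind, want$kind)
    expect_equal(got$value, want$value, tolerance = 1e-12)
    expect_equal(got$spot_index, want$spot_index)
  }
})

test_that("tidy and glance expose report tables", {
  plan <- tiny_plan()
  rep <- qa_check(plan, plan_as_session(plan), synthetic_size_baseline())
  expect_named(glance(rep), c("session_id", "room", "n_fields", "n_layers",
                              "n_spots", "n_flags", "max_abs_systematic_mm",
                              "max_abs_random_mm", "mean_d_mu", "pass"))
  expect_equal(nrow(tidy(rep, "spot")), nrow(plan))
  expect_equal(nrow(tidy(rep, "layer")), 3)
  expect_equal(nrow(tidy(rep, "flag")), 0)
})
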