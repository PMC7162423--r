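test_that("noiseless rise-and-decay samples are recovered exactly", {
  s <- gen_tac(A0 = 1, lambda_r = 1, lambda_d = 0.1,
               times_h = c(2, 4, 8, 24), n_per_time = 1, cv = 0)
  f <- fit_time_activity(s)
  expect_equal(f$A0, 1, tolerance = 1e-6)
  expect_equal(f$lambda_r, 1, tolerance = 1e-6)
  expect_equal(f$lambda_d, 0.1, tolerance = 1e-6)
  expect_false(f$degenerate)
  expect_equal(f$n_points, 4)
})

test_that("noisy fit agrees with the grid-search oracle and the truth", {
  s <- gen_tac(A0 = 100, lambda_r = 0.8, lambda_d = 0.0654,
               times_h = c(1, 2, 4, 6, 8, 12, 18, 24), n_per_time = 1,
               cv = 0.05, seed = 42)
  f <- fit_time_activity(s)
  ref <- oracle_tac_fit(s$time_h, s$activity_bq_per_g)
  expect_equal(f$A0, unname(ref["A0"]), tolerance = 0.02)
  expect_equal(f$lambda_r, unname(ref["lambda_r"]), tolerance = 0.05)
  expect_equal(f$lambda_d, unname(ref["lambda_d"]), tolerance = 0.05)
  # and both are within 10% of the generating parameters
  expect_lt(abs(f$A0 - 100) / 100, 0.10)
  expect_lt(abs(f$lambda_r - 0.8) / 0.8, 0.10)
  expect_lt(abs(f$lambda_d - 0.0654) / 0.0654, 0.10)
})

test_that("degenerate and invalid inputs are handled", {
  zero <- activity_samples("brain", c(2, 4, 8, 24), rep(0, 4))
  f <- fit_time_activity(zero)
  expect_true(f$degenerate)
  expect_equal(f$A0, 0)
  expect_equal(eval_activity(f, c(0, 5, 24)), rep(0, 3))
  expect_equal(cumulated_activity(f)$value, 0)

  expect_error(fit_time_activity(activity_samples("x", c(2, 2, 2), c(1, 2, 3))),
               "distinct positive times")
  two_regions <- rbind(activity_samples("a", c(2, 4, 8), 1:3),
                       activity_samples("b", c(2, 4, 8), 1:3))
  expect_error(fit_time_activity(two_regions), "same region")
})

test_that("fit is invariant to sample ordering", {
  s <- gen_tac(A0 = 50, lambda_r = 1.5, lambda_d = 0.08, cv = 0.05, seed = 7)
  f1 <- fit_time_activity(s)
  f2 <- fit_time_activity(s[sample(nrow(s)), ])
  expect_equal(f1$A0, f2$A0, tolerance = 1e-6)
  expect_equal(f1$lambda_r, f2$lambda_r, tolerance = 1e-6)
  expect_equal(f1$lambda_d, f2$lambda_d, tolerance = 1e-6)
})

test_that("eval_activity matches the model formula and its limits", {
  f <- structure(list(A0 = 10, lambda_r = 0.5, lambda_d = 0.0654,
                      degenerate = FALSE), class = "kinetic_fit")
  expect_equal(eval_activity(f, 0), 0)
  expect_equal(eval_activity(f, 4), 10 * (1 - exp(-2)) * exp(-0.2616))
  nodecay <- structure(list(A0 = 10, lambda_r = 0.5, lambda_d = 0,
                            degenerate = FALSE), class = "kinetic_fit")
  expect_equal(eval_activity(nodecay, 1000), 10, tolerance = 1e-9)
  expect_error(eval_activity(f, -1), "non-negative")
})

test_that("closed-form cumulated activity equals adaptive quadrature", {
  f <- structure(list(A0 = 100, lambda_r = 0.8, lambda_d = 0.0654,
                      degenerate = FALSE), class = "kinetic_fit")
  cf <- cumulated_activity(f, 0, 24)$value
  nq <- 3600 * stats::integrate(function(t) eval_activity(f, t), 0, 24,
                                rel.tol = 1e-12)$value
  expect_equal(cf, nq, tolerance = 1e-8)
  expect_equal(cumulated_activity(f, 0, 24)$window, c(0, 24))
  expect_error(cumulated_activity(f, 10, 10), "t_end > t_start")
})

test_that("cumulated activity limits: no decay and instantaneous uptake", {
  nodecay <- structure(list(A0 = 5, lambda_r = 2, lambda_d = 0,
                            degenerate = FALSE), class = "kinetic_fit")
  nq <- 3600 * stats::integrate(function(t) eval_activity(nodecay, t), 0, 24,
                                rel.tol = 1e-12)$value
  expect_equal(cumulated_activity(nodecay)$value, nq, tolerance = 1e-8)

  fast <- structure(list(A0 = 7, lambda_r = 1e8, lambda_d = 0.1,
                         degenerate = FALSE), class = "kinetic_fit")
  expect_equal(cumulated_activity(fast)$value,
               3600 * 7 * (1 - exp(-0.1 * 24)) / 0.1, tolerance = 1e-6)
})

test_that("chain mean energy: weighted means and the shipped lead-212 config", {
  single <- structure(list(steps = list(list(
    name = "a", occupancy = 1,
    branches = list(fraction = 1, energy_mev = 6, class = "alpha")))),
    class = "chain_energy_model")
  expect_equal(chain_mean_energy(single), 6)

  two <- structure(list(steps = list(list(
    name = "a", occupancy = 1,
    branches = list(fraction = c(0.5, 0.5), energy_mev = c(6, 8),
                    class = c("alpha", "alpha"))))),
    class = "chain_energy_model")
  expect_equal(chain_mean_energy(two), 7)

  # shipped config vs a manual sum over its entries, done on the raw JSON
  path <- system.file("extdata", "pb212_chain.json", package = "tatdose")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  hand <- 0
  for (s in raw$steps) {
    keep <- s$branches$class %in% c("alpha", "beta")
    hand <- hand + s$occupancy *
      sum(s$branches$fraction[keep] * s$branches$energy_mev[keep])
  }
  expect_equal(chain_mean_energy(load_chain_config(path)), hand)

  bad <- raw
  bad$steps[[1]]$branches$fraction <- 0.9
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, tmp, auto_unbox = TRUE, digits = NA)
  expect_error(load_chain_config(tmp), "sum")
})

test_that("absorbed dose: unit conversion, zero case and linearity", {
  expect_equal(absorbed_dose(0, 7.8)$dose_gy, 0)
  expect_equal(absorbed_dose(1e9, 7.8)$dose_gy, 1e9 * 7.8 * 1.602e-13 * 1000)
  d1 <- absorbed_dose(2.5e8, 8.4)$dose_gy
  expect_equal(absorbed_dose(5e8, 8.4)$dose_gy, 2 * d1)       # linear in dis/g
  expect_equal(absorbed_dose(2.5e8, 16.8)$dose_gy, 2 * d1)    # linear in delta
  expect_equal(absorbed_dose(1e9, 7.8, injected_mbq = 2)$gy_per_mbq,
               absorbed_dose(1e9, 7.8)$dose_gy / 2)
  expect_error(absorbed_dose(1e9, 0), "positive")
})

test_that("percent injected dose per gram", {
  expect_equal(percent_id_per_gram(2700, 1e6), 0.27)
  expect_equal(percent_id_per_gram(0, 1e6), 0)
  expect_error(percent_id_per_gram(2700, 0), "positive")
  # decay correction inflates a late measurement by exp(lambda t)
  expect_equal(percent_id_per_gram(2700, 1e6, decay_correct = TRUE,
                                   time_h = 10.64),
               0.27 * 2, tolerance = 1e-9)
})

test_that("TAC csv roundtrip and dose table layout", {
  s <- rbind(gen_tac(A0 = 300, lambda_r = 1.2, lambda_d = 0.07,
                     region = "kidney", cv = 0.05, seed = 11),
             gen_tac(A0 = 20, lambda_r = 0.9, lambda_d = 0.05,
                     region = "brain", cv = 0.05, seed = 12))
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(s, tmp, row.names = FALSE)
  back <- read_tac_csv(tmp)
  expect_equal(back$activity_bq_per_g, s$activity_bq_per_g)

  tab <- dose_table(back, delta = 8.42, injected_mbq = 1)
  expect_named(tab, c("organ", "gy_per_mbq"))
  expect_setequal(tab$organ, c("brain", "kidney"))
  expect_true(all(tab$gy_per_mbq >= 0))
  out <- tempfile(fileext = ".csv")
  write_dose_table(tab, out)
  txt <- readLines(out)
  expect_equal(txt[1], "organ,gy_per_mbq")
  expect_match(txt[2], "^[a-z]+,[0-9]+\\.[0-9]{3}$")
})
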