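test_that("measurement noise is median-preserving lognormal, identity at cv 0", {
  nz0 <- noise_model(0, 0)
  expect_identical(apply_measurement_noise(c(0, 0.3, 0.8), nz0), c(0, 0.3, 0.8))
  nz <- noise_model(0.05, 0, seed = 5)
  set.seed(nz$seed)
  draws <- apply_measurement_noise(rep(0.5, 1e5), nz)
  expect_lt(abs(median(draws) - 0.5), 0.005)
  expect_true(all(draws > 0))
  expect_equal(apply_measurement_noise(0, nz), 0)   # blank stays blank
  # identical seed -> identical draw sequence
  set.seed(11); a <- apply_measurement_noise(rep(0.5, 100), nz)
  set.seed(11); b <- apply_measurement_noise(rep(0.5, 100), nz)
  expect_identical(a, b)
})

test_that("hours = 0 yields one baseline record per well with no dilution", {
  p <- culture_plate("P1", od0 = 0.3, rows = 2, cols = 3)
  sim <- run_turbidostat(p, controller_config(), noise_model(0, 0), 0)
  expect_equal(nrow(sim$records), 6)
  expect_equal(unique(sim$records$t_hours), 0)
  expect_equal(sim$records$vol_exchanged_uL, rep(0, 6))
  expect_equal(sim$records$od_true, rep(0.3, 6))
})

test_that("a pre-converged noiseless loop sits at the setpoint every cycle", {
  cfg <- controller_config(x_set = 0.8, dt_hours = 0.5)
  p <- culture_plate("P1", od0 = cfg$x_set, k = 0.7, rows = 2, cols = 2)
  sim <- run_turbidostat(p, cfg, noise_model(0, 0), 12, k_est_init = 0.7)
  expect_lt(max(abs(sim$records$od_meas - cfg$x_set)), 1e-9)
  y_star <- exp(0.7 * cfg$dt_hours) - 1
  expect_lt(max(abs(sim$records$y_cmd - y_star)), 1e-9)
})

test_that("sterile wells stay sterile and never receive media", {
  p <- culture_plate("P1", od0 = c(0, 0.2, 0, 0.4), rows = 2, cols = 2)
  sim <- run_turbidostat(p, controller_config(), noise_model(0.05, 0.02, 3), 24)
  blank <- dplyr::filter(sim$records, well %in% c("A1", "B1"))
  expect_true(all(blank$od_true == 0))
  expect_true(all(blank$od_meas == 0))
  expect_true(all(blank$y_cmd == 0))
  expect_equal(sum(blank$vol_exchanged_uL), 0)
})

test_that("noise-free simulator equals the analytic dilute-then-grow iteration", {
  cfg <- controller_config(x_set = 0.8, y_max = 1, dt_hours = 0.5,
                           alpha = 0.7, k_init = 0)
  k <- 0.6; od0 <- 0.25
  p <- culture_plate("P1", od0 = od0, k = k, rows = 1, cols = 1)
  sim <- run_turbidostat(p, cfg, noise_model(0, 0), 10)
  # analytic iteration of the same transfer function (plain formulas)
  n <- nrow(sim$records)
  od <- od0; x_prev <- NA; ke <- 0; y_prev <- 0
  for (i in seq_len(n)) {
    if (!is.na(x_prev)) {
      ke <- max(0, cfg$alpha * ke +
                  (1 - cfg$alpha) * log((od / x_prev) * (y_prev + 1)) / 0.5)
    }
    y <- max(0, min(1, od * exp(ke * 0.5) / 0.8 - 1))
    expect_equal(sim$records$od_true[i], od, tolerance = 1e-12)
    expect_equal(sim$records$k_est[i], ke, tolerance = 1e-12)
    expect_equal(sim$records$y_cmd[i], y, tolerance = 1e-12)
    x_prev <- od; y_prev <- y
    od <- od / (1 + y) * exp(k * 0.5)
  }
})

test_that("identical config and seed give byte-identical CSV output", {
  p <- culture_plate("P1", od0 = 0.2, rows = 4, cols = 6)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(run_turbidostat(p, controller_config(),
                                    noise_model(0.05, 0.02, 99), 6), f1)
  write_records_csv(run_turbidostat(p, controller_config(),
                                    noise_model(0.05, 0.02, 99), 6), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and a different seed changes the bytes
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(run_turbidostat(p, controller_config(),
                                    noise_model(0.05, 0.02, 100), 6), f3)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
})

test_that("480 wells across five plates emit 480 records per cycle", {
  plates <- dplyr::bind_rows(lapply(1:5, function(i)
    culture_plate(paste0("P", i), od0 = 0.4)))
  sim <- run_turbidostat(plates, controller_config(), noise_model(0.05, 0.02, 1), 2)
  per_cycle <- dplyr::count(sim$records, t_hours)
  expect_true(all(per_cycle$n == 480))
  expect_equal(nrow(per_cycle), 5)  # t = 0, 0.5, ..., 2
})

test_that("malformed plate tables are rejected before simulation", {
  p <- culture_plate("P1", rows = 2, cols = 2)
  expect_error(run_turbidostat(p[, -3], controller_config(), noise_model(), 1),
               "missing column")
  bad <- p; bad$volume_ul[1] <- 0
  expect_error(run_turbidostat(bad, controller_config(), noise_model(), 1),
               "volume")
  expect_error(run_turbidostat(dplyr::bind_rows(p, p), controller_config(),
                               noise_model(), 1), "duplicate")
})

test_that("with 5% read noise the spread of inocula settles within 12 h", {
  p <- spread_plate()
  sim <- run_turbidostat(p, controller_config(x_set = 0.8, dt_hours = 0.5),
                         noise_model(0.05, 0.02, 42), 24)
  st <- settling_time(sim)
  expect_true(all(is.finite(st$settle_h)))
  expect_lte(max(st$settle_h), 12)
  # time-averaged OD over the final half of the run within 5% of setpoint
  tail_od <- dplyr::filter(sim$records, t_hours >= 12) |>
    dplyr::group_by(well) |>
    dplyr::summarise(m = mean(od_true))
  expect_true(all(abs(tail_od$m - 0.8) / 0.8 < 0.05))
})

test_that("closed-loop runs recover the plant growth constant within 5% under noise", {
  p <- culture_plate("P1", od0 = 0.1, k = 0.7)
  sim <- run_turbidostat(p, controller_config(), noise_model(0.05, 0.02, 42), 24)
  kbar <- dplyr::filter(sim$records, t_hours >= 12) |>
    dplyr::group_by(well) |>
    dplyr::summarise(kbar = mean(k_est))
  expect_true(all(abs(kbar$kbar - 0.7) / 0.7 < 0.05))
})

test_that("settling time flags never-settled and sterile wells", {
  p <- culture_plate("P1", od0 = c(0, 0.001), k = c(0, 0.05),
                     rows = 1, cols = 2)
  sim <- run_turbidostat(p, controller_config(), noise_model(0, 0), 6)
  st <- settling_time(sim)
  expect_true(is.na(st$settle_h[st$well == "A1"]))   # sterile
  expect_equal(st$settle_h[st$well == "A2"], Inf)    # too slow to arrive
})
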