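test_that("double_log_fit inverts the generator on noiseless data", {
  for (i in seq_along(tab_assoc_k)) {
    s <- noiseless_series(assoc_k = tab_assoc_k[i], hill_n = tab_n_sites[i],
                          temperature = design_temps[i])
    fit <- double_log_fit(s)
    expect_equal(fit$assoc_k, tab_assoc_k[i], tolerance = 1e-6)
    expect_equal(fit$n_sites, tab_n_sites[i], tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  }

  # log identity: n = 1, K = 1e5 gives slope 1, intercept (log10 K) = 5
  s <- noiseless_series(assoc_k = 1e5, hill_n = 1)
  fit <- double_log_fit(s)
  expect_equal(fit$n_sites, 1, tolerance = 1e-10)
  expect_equal(log10(fit$assoc_k), 5, tolerance = 1e-10)
})

test_that("points with F >= F0 are dropped and listed, never clamped", {
  s <- noiseless_series(assoc_k = 4073.8, hill_n = 0.89)
  tampered <- titration_series(s$temperature, s$quencher_conc,
                               replace(s$intensity, 1, s$f0), f0 = s$f0)
  fit <- double_log_fit(tampered)
  expect_equal(fit$dropped_points, s$quencher_conc[1])
  expect_equal(fit$n_points_used, length(s$quencher_conc) - 1)
  expect_true(any(grepl("dropped", fit$flags)))
  # remaining points still carry the exact model
  expect_equal(fit$assoc_k, 4073.8, tolerance = 1e-6)

  few <- titration_series(298.15, design_grid[1:4],
                          c(1000.5, 1000.2, 990, 980), f0 = 1000)
  expect_error(double_log_fit(few), class = "quenchfit_insufficient_data")
})

test_that("hill_plot_fit shares the double-log slope and links K = kD^(-n)", {
  for (noise in c(0, 0.02)) {
    s <- generate_titration(synthetic_spec(
      assoc_k = 4073.8, hill_n = 0.89, noise_rel = noise, seed = 3))
    dl <- double_log_fit(s)
    hp <- hill_plot_fit(s)
    # same regression, different log base
    expect_equal(hp$hill_n, dl$n_sites, tolerance = 1e-12)
    # constant linkage through the exponent
    expect_equal(dl$assoc_k, hp$k_d^(-hp$hill_n),
                 tolerance = 1e-9)
  }
  # frozen identity check: kD = K^(-1/n)
  hp <- hill_plot_fit(noiseless_series(assoc_k = 4073.8, hill_n = 0.89))
  expect_equal(hp$k_d, 4073.8^(-1 / 0.89), tolerance = 1e-9)
  expect_equal(hp$k_d, 8.786594e-5, tolerance = 1e-6)
  expect_identical(hp$cooperativity, "non-cooperative")
})

test_that("hill_plot_fit rejects fluorescence rising with quencher", {
  rising <- titration_series(298.15, design_grid,
                             c(500, 550, 620, 700, 760, 830), f0 = 1000)
  expect_error(hill_plot_fit(rising), class = "quenchfit_fit_error")
})

test_that("hill_saturation_fit recovers the saturation model", {
  kd <- 1e-4
  # Q with Qmax = 1 corresponds to F = F0 / (1 + K q^n), K = kd^-n
  s <- noiseless_series(assoc_k = 1 / kd, hill_n = 1)
  fit <- hill_saturation_fit(s)
  expect_equal(fit$k_d, kd, tolerance = 1e-6)
  expect_equal(fit$hill_n, 1, tolerance = 1e-6)
  expect_equal(fit$q_max, 1, tolerance = 1e-6)

  # midpoint property: at [Q] = kD, Q = Qmax/2
  q_mid <- quenching_fraction(s$f0, 1000 / (1 + (1 / kd) * kd))
  expect_equal(q_mid, 0.5)

  # saturation limit: fitted curve approaches Qmax at large [Q]
  big <- 1e4 * fit$k_d
  expect_equal(fit$q_max * big^fit$hill_n / (fit$k_d^fit$hill_n + big^fit$hill_n),
               fit$q_max, tolerance = 1e-3)

  # agreement with the linearized Hill plot when Qmax is held at 1
  s2 <- noiseless_series(assoc_k = 4073.8, hill_n = 0.89)
  fixed <- hill_saturation_fit(s2, fix_qmax = 1)
  hp <- hill_plot_fit(s2)
  expect_equal(fixed$k_d, hp$k_d, tolerance = 1e-6)
  expect_equal(fixed$hill_n, hp$hill_n, tolerance = 1e-6)

  expect_error(hill_saturation_fit(
    titration_series(298, design_grid[1:3], c(900, 800, 700), f0 = 1000)),
    class = "quenchfit_insufficient_data")
})

test_that("classify_cooperativity applies the tolerance band around 1", {
  expect_identical(classify_cooperativity(0.89, 0.15), "non-cooperative")
  expect_identical(classify_cooperativity(1.5, 0.15), "positive")
  expect_identical(classify_cooperativity(0.5, 0.15), "negative")
  expect_identical(classify_cooperativity(1.15, 0.15), "non-cooperative")
  expect_identical(classify_cooperativity(1.1500001, 0.15), "positive")
  expect_error(classify_cooperativity(-1, 0.15),
               class = "quenchfit_domain_error")
})

test_that("noisy recovery: n is accurate; K's error is pure intercept extrapolation", {
  # 50 replicates at 1% noise on the 6-point design (the full 200-replicate
  # study lives in the acceptance suite)
  err_n <- err_logk <- slope_dev <- numeric(50)
  mid <- numeric(50)
  x <- log10(design_grid)
  true_mid <- log10(4073.8) + 0.89 * mean(x)
  for (i in 1:50) {
    s <- generate_titration(synthetic_spec(
      assoc_k = 4073.8, hill_n = 0.89, noise_rel = 0.01, seed = 1000 + i))
    fit <- double_log_fit(s)
    err_n[i] <- abs(fit$n_sites - 0.89) / 0.89
    err_logk[i] <- log10(fit$assoc_k) - log10(4073.8)
    slope_dev[i] <- fit$n_sites - 0.89
    mid[i] <- log10(fit$assoc_k) + fit$n_sites * mean(x)
  }
  expect_lt(median(err_n), 0.05)
  # the fitted line is accurate where the data live: the regression value
  # at the design centroid wanders far less than the extrapolated
  # intercept (= log10 K), whose error tracks the slope's (the centroid
  # sits >4 decades below [Q] = 1 M, so slope noise is amplified into
  # the intercept with opposite-sign leverage)
  expect_lt(median(abs(mid - true_mid)), 0.2 * median(abs(err_logk)))
  expect_gt(cor(slope_dev, err_logk), 0.9)
})
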