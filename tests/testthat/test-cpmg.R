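test_that("constant-time R2eff from intensities", {
  expect_equal(r2eff_from_intensities(100, 100, 0.032), 0)
  expect_equal(r2eff_from_intensities(80, 100, 0.032), -log(0.8) / 0.032)
  expect_equal(r2eff_from_intensities(80, 100, 0.032), 6.973, tolerance = 1e-3)
  expect_equal(r2eff_from_intensities(exp(-1), 1, 1), 1)
  expect_warning(out <- r2eff_from_intensities(c(-1, 50), c(100, 100), 0.032),
                 "non-positive")
  expect_true(is.na(out[1]) && is.finite(out[2]))
})

test_that("Bloch-McConnell propagation obeys its limiting cases", {
  nu <- default_nu_grid()
  # no shift difference: R2eff equals the (equal) intrinsic R2
  expect_equal(simulate_bm(nu, 0.032, 600, 0, 500, 0.1, 8, 8),
               rep(8, 14), tolerance = 1e-9)
  # no minor state: R2eff = free-state R2
  expect_equal(simulate_bm(nu, 0.032, 600, 3, 500, 0, 8, 25),
               rep(8, 14), tolerance = 1e-9)
  # fast limit: Rex = pA pB dw^2 / kex, flat in nu
  dw_ppm <- 1000 / dw_rad_per_s(1, 600)
  r <- simulate_bm(nu, 0.032, 600, dw_ppm, 1e5, 0.1, 5, 5)
  expect_equal(r, rep(5 + 0.9 * 0.1 * 1000^2 / 1e5, 14), tolerance = 0.05)
})

test_that("closed form and numerical propagation agree over the working grid", {
  nu <- default_nu_grid()
  worst <- 0
  for (kex in c(100, 300, 662, 1500, 3000))
    for (pb in c(0.01, 0.05, 0.089, 0.2))
      for (dw in c(0.5, 1, 2, 3, 4))
        for (f in c(600, 850)) {
          bm <- simulate_bm(nu, 0.032, f, dw, kex, pb, 8, 12)
          cr <- simulate_cr(nu, 0.032, f, dw, kex, pb, 8, 12)
          worst <- max(worst, max(abs(bm - cr)))
        }
  expect_lt(worst, 0.1)
})

test_that("closed form reaches the analytic fast-exchange plateau", {
  # for kex >= 10 dw(rad/s): low-nu Rex within 5% of pA pB dw^2 / kex
  # (single long echo so the pulse train does not refocus the exchange)
  for (dw_rad in c(200, 500, 1000)) for (pb in c(0.05, 0.1, 0.2)) {
    kex <- 12 * dw_rad
    dw_ppm <- dw_rad / dw_rad_per_s(1, 600)
    r <- simulate_cr(1 / 0.64, 0.64, 600, dw_ppm, kex, pb, 5)
    rex <- (1 - pb) * pb * dw_rad^2 / kex
    expect_lt(abs((r - 5) - rex) / rex, 0.05)
  }
})

test_that("dispersion decreases with refocusing frequency and refocuses fully", {
  nu <- default_nu_grid()
  # representative intermediate-to-fast parameters (kex >~ dw in rad/s);
  # deep slow exchange can show genuine non-monotonic structure
  for (pars in list(c(662, 1), c(662, 2), c(1500, 3), c(3000, 4))) {
    r <- simulate_cr(nu, 0.032, 600, pars[2], pars[1], 0.089, 8)
    expect_true(all(diff(r) < 1e-6))
  }
  # nu -> infinity limit: population-weighted baseline (fast exchange)
  r_inf <- simulate_cr(64 / 0.032, 0.064, 600, 1, 5000, 0.1, 8, 12)
  expect_equal(r_inf, 0.9 * 8 + 0.1 * 12, tolerance = 0.15)
})

test_that("delta R2 and dispersion detection follow the stated rules", {
  nu <- default_nu_grid()
  prof <- data.frame(nu_cpmg_hz = nu,
                     r2eff = simulate_cr(nu, 0.032, 600, 3, 662, 0.089, 8),
                     error = 0.5)
  dr <- delta_r2(prof)
  expect_equal(dr$error, 1.0) # sum of the two endpoint errors
  expect_gt(dr$delta_r2, 5)
  det <- detect_dispersion(prof)
  expect_true(det$flagged)
  expect_equal(det$pooled_error, 0.5)

  flat <- prof; flat$r2eff <- 8
  expect_false(detect_dispersion(flat)$flagged)
  borderline <- flat
  borderline$r2eff[1] <- 8 + 1.4 # delta = 1.4 < 3 * 0.5
  expect_false(detect_dispersion(borderline)$flagged)
  expect_error(delta_r2(prof[prof$nu_cpmg_hz > 100, ]), "near 31.35")
  expect_true(is.na(detect_dispersion(prof[1:4, ])$flagged))
})

test_that("noiseless multi-residue data are recovered exactly by the global fit", {
  g <- tiny_dispersion(noise_sd = 0, seed = 1)
  fit <- global_fit(g$data, a_total = 100, b_total = 10)
  expect_lt(fit$chisq, 1e-6)
  expect_equal(fit$k_ex, 662, tolerance = 1e-3)
  expect_equal(fit$p_b, 0.089, tolerance = 1e-4)
  expect_equal(sort(fit$dw$dw_ppm), sort(unname(c(2, 3, 1.2))),
               tolerance = 1e-3)
  expect_equal(unique(round(fit$r2_0$r2_0, 4)), 8)
  # the derived kd must equal the closed-form inversion exactly
  expect_equal(fit$derived$kd, kd_from_bound_fraction(fit$p_b, 100, 10))
  expect_equal(fit$derived$k_off, (1 - fit$p_b) * fit$k_ex)
})

test_that("single residue at a single field is fit but flagged degenerate", {
  g <- gen_dispersion(c(`5` = 2.5), k_ex = 662, p_b = 0.089,
                      fields = 600, noise_sd = 0, seed = 2)
  fit <- global_fit(g$data)
  expect_true(any(grepl("identifiability", fit$flags)))
  expect_lt(fit$chisq, 1e-4)
})

test_that("flat data refuse to enter a global exchange fit", {
  g <- gen_dispersion(c(`5` = 0, `6` = 0), k_ex = 662, p_b = 0.089,
                      noise_sd = 0, seed = 3)
  expect_error(global_fit(g$data), "no residue shows significant dispersion")
})
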