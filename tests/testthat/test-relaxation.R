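test_that("exponential decay fits recover rates exactly and under noise", {
  # noiseless decay at the seven standard delays
  dt <- decay_table(rep(1, 7), paper_delays,
                    100 * exp(-5 * paper_delays), rep(0.5, 7))
  fit <- fit_decay(dt, n_mc = 100, seed = 1)
  expect_equal(fit$r1rho, 5, tolerance = 1e-8)
  expect_true(fit$r1rho_error > 0)
  expect_equal(fit$flag, "ok")

  # 2% Gaussian noise: recovery within 3 Monte-Carlo sigma
  set.seed(2)
  y <- 100 * exp(-5 * paper_delays)
  yn <- y + rnorm(7, 0, 2)
  dtn <- decay_table(rep(1, 7), paper_delays, yn, rep(2, 7))
  fn <- fit_decay(dtn, n_mc = 200, seed = 3)
  expect_lt(abs(fn$r1rho - 5), 3 * fn$r1rho_error)

  # flat signal is flagged as baseline
  flat <- decay_table(rep(1, 7), paper_delays, rep(50, 7), rep(0.5, 7))
  expect_equal(fit_decay(flat, n_mc = 50, seed = 4)$flag, "baseline")
})

test_that("weak-binding rate prediction is the stated linear form", {
  expect_equal(predict_r1rho(100, 0, 177, 3, 30), 3)
  expect_equal(predict_r1rho(100, 50, 100, 3, 23), 3 + (50 / 200) * 20)
  expect_equal(predict_r1rho(100, 50, 100, 3, 23), 8)
  expect_equal(predict_r1rho(100, 80, 50, 7, 7), 7) # r_bound == r_free
})

test_that("site KD fits invert noiseless titrations exactly", {
  design <- pct_design()
  sq <- gen_sequence(20, seed = 1)$sequence
  g <- gen_titration_rates(sq, setNames(177, 10), design, r_free = 3,
                           r_bound = 30, noise_sd = 0, seed = 2)
  f <- fit_site_kd(g$rates, design, r_bound = 30, residue = 10,
                   n_mc = 50, seed = 3)
  expect_equal(f$slope, 27 / 277, tolerance = 1e-6)
  expect_equal(f$intercept, 3, tolerance = 1e-6)
  expect_equal(f$kd, 177, tolerance = 1e-3)
  expect_true(f$valid)
})

test_that("flat and descending rate profiles are flagged, not fitted", {
  design <- pct_design()
  flat <- data.frame(residue_number = 1, point_label = design$points$label,
                     r1rho = rep(4, 4), r1rho_error = rep(0.08, 4))
  # exactly flat: slope 0 -> invalid
  f1 <- fit_site_kd(flat, design, r_bound = 30, residue = 1,
                    n_mc = 20, seed = 1)
  expect_false(f1$valid)
  desc <- flat
  desc$r1rho <- c(6, 5, 4, 3)
  f2 <- fit_site_kd(desc, design, r_bound = 30, residue = 1,
                    n_mc = 20, seed = 1)
  expect_equal(f2$flag, "invalid_slope")
  expect_true(is.na(f2$kd))
  short <- flat[1:2, ]
  expect_error(fit_site_kd(short, design, r_bound = 30, residue = 1,
                           n_mc = 20, seed = 1), "fewer than 3")
})

test_that("the linear approximation tracks the exact quadratic when weak", {
  # the neglected term is partner depletion, so the relative error in the
  # bound fraction is ~ (b - complex)/(kd + a); it stays below 5% whenever
  # b <= 0.05 (kd + a) ...
  grid <- expand.grid(a = c(50, 100, 200), kd = c(20, 100, 500, 2000),
                      frac = c(0.25, 0.5, 1))
  for (i in seq_len(nrow(grid))) {
    a <- grid$a[i]; kd <- grid$kd[i]
    b <- grid$frac[i] * 0.05 * (kd + a)
    approx <- b / (kd + a)
    exact <- bound_fraction_exact(a, b, kd)
    expect_lt(abs(approx - exact) / exact, 0.05)
  }
  # ... scales proportionally with b at fixed composition ...
  err_at <- function(a, kd, b)
    abs(b / (kd + a) - bound_fraction_exact(a, b, kd)) /
      bound_fraction_exact(a, b, kd)
  e1 <- err_at(100, 700, 40); e2 <- err_at(100, 700, 80)
  expect_equal(e2 / e1, 2, tolerance = 0.15)
  # ... and the divergence grows as binding tightens (before saturation,
  # where b/(kd+a) -> b/a and the two forms reconverge)
  errs <- vapply(c(2000, 1000, 500, 200), function(kd) err_at(100, kd, 50),
                 numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("eq2-generated rates close the loop; exact-model rates bias it", {
  design <- pct_design()
  sq <- gen_sequence(12, seed = 5)$sequence
  g_exact <- gen_titration_rates(sq, setNames(20, 6), design, r_free = 3,
                                 r_bound = 30, noise_sd = 0, seed = 6,
                                 model = "exact")
  f <- fit_site_kd(g_exact$rates, design, r_bound = 30, residue = 6,
                   n_mc = 20, seed = 7)
  # tight binding (kd << a_total) violates the weak-binding assumption
  expect_gt(abs(f$kd - 20) / 20, 0.2)
})
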