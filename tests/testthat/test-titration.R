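two_state_tables <- function(dh = 0.01, dn = 0.1, res = 5:7) {
  ref <- shift_table(rep(res, each = 2), rep("A", 2 * length(res)),
                     rep(c("H", "N"), length(res)),
                     as.vector(rbind(8 + 0.01 * res, 115 + res)))
  tit <- ref
  move <- tit$residue_number == res[1]
  tit$shift[move & tit$atom == "H"] <- tit$shift[move & tit$atom == "H"] + dh
  tit$shift[move & tit$atom == "N"] <- tit$shift[move & tit$atom == "N"] + dn
  list(ref = ref, tit = tit)
}

test_that("combined CSP follows the scaled-proton quadrature formula", {
  expect_equal(combined_csp(0, 0), 0)
  expect_equal(combined_csp(0.01, 0.1), sqrt(0.065^2 + 0.1^2))
  expect_equal(combined_csp(0.01, 0.1), 0.11927, tolerance = 1e-4)
  # nitrogen-free collapse: CSP = 6.5 * |dH|
  expect_equal(combined_csp(-0.02, 0), 6.5 * 0.02)
  expect_equal(combined_csp(0, -0.3), 0.3)
  # symmetric in which state is the reference
  expect_equal(combined_csp(0.013, -0.21), combined_csp(-0.013, 0.21))
})

test_that("peak matching by number and by nearest neighbour", {
  tb <- two_state_tables(dh = 0.01, dn = 0.1)
  m <- match_peaks(tb$ref, tb$tit)
  expect_equal(m$residue_number, m$matched_number)
  expect_equal(length(attr(m, "unmatched")), 0)

  mn <- match_peaks(tb$ref, tb$tit, tol_h = 0.05, tol_n = 0.5,
                    mode = "nearest")
  expect_true(all(!mn$ambiguous))
  expect_equal(mn$matched_number, mn$residue_number)

  # collision: two reference peaks inside tolerance of one titrated peak
  ref <- shift_table(c(1, 1, 2, 2), rep("A", 4), rep(c("H", "N"), 2),
                     c(8.30, 120.0, 8.31, 120.2))
  tit <- shift_table(c(9, 9), c("A", "A"), c("H", "N"), c(8.305, 120.1))
  mc <- match_peaks(ref, tit, tol_h = 0.05, tol_n = 0.5, mode = "nearest")
  expect_true(all(mc$ambiguous))
  expect_true(all(is.na(mc$matched_number)))
})

test_that("CSP profiles across a titration use matched residues only", {
  tb <- two_state_tables(dh = 0.01, dn = 0.1)
  design <- titration_design(100, data.frame(label = c("ref", "p1"),
                                             b = c(0, 50)))
  ser <- titration_series(design,
                          list(ref = list(shifts = tb$ref),
                               p1 = list(shifts = tb$tit)), "ref")
  csp <- compute_csp(ser)
  expect_equal(nrow(csp), 3)
  expect_equal(csp$csp[csp$residue_number == 5],
               sqrt(0.065^2 + 0.1^2), tolerance = 1e-12)
  expect_equal(csp$csp[csp$residue_number %in% 6:7], c(0, 0))
  # a residue missing its H in the titrated state is skipped
  tit2 <- tb$tit[!(tb$tit$residue_number == 6 & tb$tit$atom == "H"), ]
  class(tit2) <- class(tb$tit)
  ser2 <- titration_series(design, list(ref = list(shifts = tb$ref),
                                        p1 = list(shifts = tit2)), "ref")
  expect_false(6 %in% compute_csp(ser2)$residue_number)
})

test_that("intensity ratios encode disappeared peaks as zero + flag", {
  design <- titration_design(100, data.frame(label = c("ref", "p45"),
                                             b = c("0%", "45%")))
  i0 <- c(`5` = 100, `6` = 80, `7` = 60)
  it <- c(`5` = 40, `6` = 80) # residue 7 broadened away
  ser <- titration_series(design, list(ref = list(intensities = i0),
                                       p45 = list(intensities = it)), "ref")
  rt <- intensity_ratios(ser)
  expect_equal(rt$i_over_i0[rt$residue_number == 5], 0.4)
  expect_equal(rt$i_over_i0[rt$residue_number == 6], 1)
  expect_equal(rt$i_over_i0[rt$residue_number == 7], 0)
  expect_true(rt$disappeared[rt$residue_number == 7])
  # non-positive reference intensities are excluded with a warning
  ser2 <- titration_series(design,
                           list(ref = list(intensities = c(`5` = 0, `6` = 80)),
                                p45 = list(intensities = it)), "ref")
  expect_warning(rt2 <- intensity_ratios(ser2), "excluded")
  expect_false(5 %in% rt2$residue_number)
})

test_that("on fast-exchange synthetic data CSP grows with bound fraction", {
  # planted perturbation proportional to bound fraction at each point
  kd <- 177; a <- 100
  bs <- c(0, 25, 50, 100, 150)
  dmax <- c(h = 0.04, n = 0.4)
  design <- titration_design(a, data.frame(label = paste0("b", bs), b = bs))
  sq <- gen_sequence(10, seed = 3)$sequence
  pts <- lapply(bs, function(b) {
    frac <- bound_fraction_exact(a, b, kd)
    g <- gen_shift_tables(sq, noise_sd = 0, seed = 4,
                          csp_perturb = list(`5` = frac * dmax))
    list(shifts = g$perturbed)
  })
  names(pts) <- paste0("b", bs)
  ser <- titration_series(design, pts, "b0")
  csp <- compute_csp(ser)
  tr <- csp[csp$residue_number == 5, ]
  tr <- tr[order(tr$b_total), ]
  expect_true(all(diff(tr$csp) > 0))
  expect_true(all(csp$csp[csp$residue_number != 5] < 1e-9))
})
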