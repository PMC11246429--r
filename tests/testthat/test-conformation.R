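rc_shift <- function(ty, atom) {
  rc <- random_coil_table()
  rc$shift_ppm[rc$residue_type == ty & rc$atom == atom]
}

make_rc_table <- function(seqrec, atoms = c("CA", "CB", "CO")) {
  # shift table equal to random coil everywhere
  rows <- list()
  for (i in seq_along(seqrec$numbers)) {
    ty <- residue_at(seqrec, seqrec$numbers[i])
    for (a in atoms) {
      v <- rc_shift(ty, a)
      if (length(v))
        rows[[length(rows) + 1]] <- data.frame(
          residue_number = seqrec$numbers[i], residue_type = ty,
          atom = a, shift = v)
    }
  }
  df <- do.call(rbind, rows)
  shift_table(df$residue_number, df$residue_type, df$atom, df$shift)
}

test_that("SCS is observed minus random coil, with defined gaps", {
  sq <- sequence_record("x", "AGLA", 10)
  tab <- make_rc_table(sq)
  scs <- compute_scs(tab, sq)
  expect_true(all(scs$scs == 0))
  # Gly has no CB entry anywhere, and that is not an error
  expect_false(any(scs$residue_type == "G" & scs$atom == "CB"))

  # hand subtraction against the bundled Ala CA reference row (52.6)
  tab2 <- shift_table(10, "A", "CA", 54.2)
  scs2 <- compute_scs(tab2, sq)
  expect_equal(scs2$scs, 54.2 - 52.6)
  expect_equal(scs2$scs, 1.6, tolerance = 1e-12)

  # residue type disagreement between table and sequence is an error
  bad <- shift_table(11, "A", "CA", 54.2) # position 11 is G
  expect_error(compute_scs(bad, sq), "residue 11")
})

test_that("SSP normalization: zero SCS gives 0, full references give +-1", {
  sq <- sequence_record("x", "ALKAVELAKQA", 1)
  ss <- secondary_structure_reference()
  hx <- setNames(ss$helix_delta, paste(ss$residue_type, ss$atom))
  st <- setNames(ss$strand_delta, paste(ss$residue_type, ss$atom))
  base <- make_rc_table(sq, atoms = c("CA", "CB"))

  scs0 <- compute_scs(base, sq)
  ssp0 <- compute_ssp(scs0)
  expect_true(all(ssp0$ssp == 0))

  for (scale in c(1, -1)) { # +1: helix refs; -1 handled below via strand
    tab <- base
    key <- paste(tab$residue_type, tab$atom)
    tab$shift <- tab$shift + if (scale > 0) hx[key] else st[key]
    ssp <- compute_ssp(compute_scs(tab, sq))
    center <- ssp$ssp[ssp$residue_number %in% 3:9]
    expect_equal(center, rep(if (scale > 0) 1 else -1, length(center)),
                 tolerance = 1e-9)
  }
})

test_that("SSP is linear in SCS amplitude between the reference limits", {
  sq <- sequence_record("x", "ALKAVELAKQA", 1)
  ss <- secondary_structure_reference()
  hx <- setNames(ss$helix_delta, paste(ss$residue_type, ss$atom))
  base <- make_rc_table(sq, atoms = c("CA", "CB"))
  key <- paste(base$residue_type, base$atom)
  for (pop in c(0.3, 0.55, 0.8)) {
    tab <- base
    tab$shift <- tab$shift + pop * hx[key]
    ssp <- compute_ssp(compute_scs(tab, sq))
    expect_equal(ssp$ssp[ssp$residue_number == 6], pop, tolerance = 0.02)
  }
})

test_that("SSP sign follows the window-mean CA-CB secondary shift", {
  set.seed(7)
  sq <- sequence_record("x", paste(rep("A", 30), collapse = ""), 1)
  base <- make_rc_table(sq, atoms = c("CA", "CB"))
  tab <- base
  tab$shift <- tab$shift + rnorm(nrow(tab), 0, 0.8)
  scs <- compute_scs(tab, sq)
  ssp <- compute_ssp(scs)
  for (r in 3:28) {
    w <- scs[abs(scs$residue_number - r) <= 2, ]
    m <- mean(w$scs[w$atom == "CA"]) - mean(w$scs[w$atom == "CB"])
    s <- ssp$ssp[ssp$residue_number == r]
    if (abs(m) > 1e-6) expect_equal(sign(s), sign(m))
  }
})

test_that("synthetic helix populations are recovered through SCS/SSP", {
  sq <- gen_sequence(60, seed = 5)$sequence
  g <- gen_shift_tables(sq, helix_spec = list(list(range = c(20, 40),
                                                   population = 0.3)),
                        noise_sd = 0.02, seed = 6)
  ssp <- compute_ssp(compute_scs(g$shifts, sq))
  center <- ssp$ssp[ssp$residue_number %in% 25:35]
  expect_equal(median(center), 0.3, tolerance = 0.05)
  outside <- ssp$ssp[ssp$residue_number %in% 3:12]
  expect_true(all(abs(outside) < 0.15))
  # full population saturates the scale at +1
  g1 <- gen_shift_tables(sq, helix_spec = list(list(range = c(20, 40),
                                                    population = 1)),
                         noise_sd = 0, seed = 7)
  ssp1 <- compute_ssp(compute_scs(g1$shifts, sq))
  expect_equal(ssp1$ssp[ssp1$residue_number == 30], 1, tolerance = 1e-6)
})
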