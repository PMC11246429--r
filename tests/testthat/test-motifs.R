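test_that("motif scanning finds the canonical patterns with numbering", {
  sq <- sequence_record("x", "ADLLGGDPFGGFSDAF", 1)
  hits <- scan_motifs(sq)
  expect_equal(hits$motif_class, c("DLL_DLF", "DPF", "FxDxF"))
  expect_equal(hits$start, c(2, 7, 12))
  expect_equal(hits$end, c(4, 9, 16))
  expect_equal(hits$seq, c("DLL", "DPF", "FSDAF"))

  # dual clathrin/AP2 site: DLF and FxDxF share the central F
  sq2 <- sequence_record("x", "DLFGDAF", 1)
  h2 <- scan_motifs(sq2)
  expect_equal(nrow(h2), 2)
  expect_equal(h2$start, c(1, 3))
  expect_equal(h2$end, c(3, 7))
  expect_equal(h2$seq, c("DLF", "FGDAF"))

  expect_equal(nrow(scan_motifs(sequence_record("x", "GGSGGSGGS", 1))), 0)

  # DIF-type degenerate variant only under the relaxed pattern
  sq3 <- sequence_record("x", "ADIFA", 1)
  expect_equal(nrow(scan_motifs(sq3)), 0)
  expect_equal(scan_motifs(sq3, relaxed = TRUE)$seq, "DIF")
})

test_that("scanner equals the brute-force oracle on random sequences", {
  set.seed(99)
  for (i in 1:300) {
    g <- gen_sequence(sample(20:80, 1), seed = i,
                      first_residue_number = sample(c(1, 281, 435), 1))
    expect_equal(scan_motifs(g$sequence), brute_force_motifs(g$sequence))
  }
})

test_that("interaction windows center on the hottest hydrophobic residue", {
  set.seed(11)
  len <- 100
  sq <- sequence_record("x", paste(
    sample(c("G", "S", "A", "D", "E", "P"), len, TRUE), collapse = ""), 1)
  ch <- strsplit(sq$residues, "")[[1]]
  ch[50] <- "L"; ch[70] <- "D"; ch[69] <- "L"
  sq <- sequence_record("x", paste(ch, collapse = ""), 1)
  base <- rep(3, len)
  inc <- setNames(rep(0, len), 1:len)
  inc[46:54] <- c(2.5, 4, 6, 8, 10, 8, 6, 4, 2.5)
  rates <- setNames(base + inc, 1:len)
  w <- extract_windows(inc, rates, sq, min_prominence = 2)
  expect_equal(nrow(w), 1)
  expect_equal(w$center, 50)
  expect_equal(w$start, 40); expect_equal(w$end, 60)
  expect_equal(nchar(w$seq), 21)

  # peak maximum on D snaps to the adjacent faster L
  inc2 <- setNames(rep(0, len), 1:len)
  inc2[66:72] <- c(2.5, 4, 6, 8, 7, 5, 2.5) # max on 69..70 region
  inc2[70] <- 8.5 # apex on the D at 70
  rates2 <- setNames(base + inc2, 1:len)
  w2 <- extract_windows(inc2, rates2, sq, min_prominence = 2)
  expect_equal(w2$center, 69)
  expect_equal(w2$center_type, "L")

  # region without any hydrophobic residue is skipped with a warning
  inc3 <- setNames(rep(0, len), 1:len)
  inc3[10:14] <- 5
  expect_warning(w3 <- extract_windows(inc3, setNames(base + inc3, 1:len),
                                       sq, min_prominence = 2),
                 "no hydrophobic")
  expect_equal(nrow(w3), 0)
})

test_that("terminal windows are gap-padded to the fixed width", {
  sq <- sequence_record("x", "GGGGLGGGGGGGGGGGGGGG", 1)
  inc <- setNames(c(0, 0, 3, 4, 5, 4, 3, rep(0, 13)), 1:20)
  rates <- setNames(3 + inc, 1:20)
  w <- extract_windows(inc, rates, sq, min_prominence = 2)
  expect_equal(w$center, 5)
  expect_equal(nchar(w$seq), 21)
  expect_equal(substr(w$seq, 1, 6), "------")
})

test_that("window extraction is translation equivariant", {
  g <- gen_sequence(80, seed = 12)$sequence
  inc <- setNames(rep(0, 80), g$numbers)
  inc[30:40] <- 5
  rates <- setNames(3 + inc, g$numbers)
  w1 <- suppressWarnings(extract_windows(inc, rates, g))
  shifted <- sequence_record(g$id, g$residues, 301)
  inc2 <- setNames(unname(inc), shifted$numbers)
  rates2 <- setNames(unname(rates), shifted$numbers)
  w2 <- suppressWarnings(extract_windows(inc2, rates2, shifted))
  if (nrow(w1)) {
    expect_equal(w2$center, w1$center + 300)
    expect_equal(w2$seq, w1$seq)
  } else expect_equal(nrow(w2), 0)
})

test_that("ranking and position frequency matrix respect the conventions", {
  sq <- gen_sequence(200, seed = 21,
                     placements = list(list(pos = 40, seq = "DLL"),
                                       list(pos = 90, seq = "DLF"),
                                       list(pos = 140, seq = "DPF")))$sequence
  inc <- setNames(rep(0, 200), 1:200)
  inc[39:43] <- 6; inc[89:93] <- 8; inc[139:143] <- 4
  rates <- setNames(3 + unname(inc), 1:200)
  w <- extract_windows(inc, rates, sq, min_prominence = 2)
  rl <- rank_and_logo(w)
  expect_equal(rl$ranked$rank, seq_len(nrow(rl$ranked)))
  expect_true(all(diff(rl$ranked$center_rate) <= 0))
  expect_true(all(colSums(rl$pfm) <= nrow(w) * 21))
  expect_true(all(rowSums(rl$pfm) <= nrow(w)))
  # central column only holds hydrophobic letters by construction
  center_counts <- rl$pfm[11, ]
  expect_true(all(names(center_counts)[center_counts > 0] %in%
                    c("L", "F", "I", "V", "M", "W", "Y")))
  # ties order by residue number
  w_tie <- w; w_tie$center_rate <- 5
  rt <- rank_and_logo(w_tie)$ranked
  expect_equal(rt$center, sort(w$center))
  # single window: matrix is the indicator of its letters
  r1 <- rank_and_logo(w[1, ])
  expect_equal(sum(r1$pfm), sum(strsplit(w$seq[1], "")[[1]] != "-"))
})
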