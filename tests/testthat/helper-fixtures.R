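# shared fixture builders; everything is generated in code at test time

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

paper_delays <- seq(0.01, 0.23, length.out = 7)

# the titration design used throughout: 100 uM observed protein,
# partner admixtures 0/50/100/150%
pct_design <- function(a_total = 100,
                       labels = c("0%", "50%", "100%", "150%")) {
  titration_design(a_total, data.frame(label = labels, b = labels))
}

# minimal two-state dispersion dataset from known truth
tiny_dispersion <- function(dw = c(`5` = 2, `6` = 3, `7` = 1.2),
                            k_ex = 662, p_b = 0.089, noise_sd = 0,
                            seed = 1, fields = c(600, 850)) {
  gen_dispersion(dw, k_ex = k_ex, p_b = p_b, fields = fields,
                 noise_sd = noise_sd, seed = seed)
}

# brute-force motif oracle: substring-by-substring pattern check
brute_force_motifs <- function(seqrec) {
  s <- strsplit(seqrec$residues, "")[[1]]
  n <- length(s)
  rows <- list()
  add <- function(cl, i, len) {
    rows[[length(rows) + 1L]] <<- data.frame(
      motif_class = cl, start = seqrec$numbers[i],
      end = seqrec$numbers[i + len - 1L],
      seq = paste(s[i:(i + len - 1L)], collapse = ""))
  }
  for (i in seq_len(n)) {
    if (i + 2 <= n && s[i] == "D" && s[i + 1] == "L" &&
        s[i + 2] %in% c("L", "F")) add("DLL_DLF", i, 3)
    if (i + 2 <= n && s[i] == "D" && s[i + 1] == "P" && s[i + 2] == "F")
      add("DPF", i, 3)
    if (i + 4 <= n && s[i] == "F" && s[i + 2] == "D" && s[i + 4] == "F")
      add("FxDxF", i, 5)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif_class = character(0), start = integer(0),
               end = integer(0), seq = character(0))
  out[order(out$start, out$motif_class), ]
}
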