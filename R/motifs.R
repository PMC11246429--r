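MOTIF_PATTERNS <- c(DLL_DLF = "D[L][LF]", DPF = "DPF", FxDxF = "F.D.F")
MOTIF_PATTERNS_RELAXED <- c(DLL_DLF = "D[LI][LF]", DPF = "DPF",
                            FxDxF = "F.D.F")
HYDROPHOBIC_DEFAULT <- c("L", "F", "I", "V", "M", "W", "Y")

#' Scan a sequence for endocytic short linear motifs
#'
#' Reports every (possibly overlapping) match of the three motif classes:
#' DLL/DLF (`D-L-[LF]`, clathrin box), DPF and FxDxF (AP2 appendage
#' binding). Positions are in full-length numbering. The optional relaxed
#' first pattern `D-[LI]-[LF]` additionally catches degenerate DIF-type
#' variants.
#'
#' @param seqrec A [sequence_record()].
#' @param relaxed Use the relaxed DLL/DLF pattern (default FALSE).
#' @return `data.frame(motif_class, start, end, seq)`, ordered by start.
#' @export
scan_motifs <- function(seqrec, relaxed = FALSE) {
  pats <- if (relaxed) MOTIF_PATTERNS_RELAXED else MOTIF_PATTERNS
  s <- seqrec$residues
  rows <- list()
  for (cl in names(pats)) {
    # lookahead so overlapping occurrences are all reported
    m <- gregexpr(paste0("(?=(", pats[[cl]], "))"), s, perl = TRUE)[[1]]
    if (m[1] == -1) next
    starts <- as.integer(m)
    lens <- attr(m, "capture.length")[, 1]
    rows[[cl]] <- data.frame(
      motif_class = cl,
      start = seqrec$numbers[starts],
      end = seqrec$numbers[starts + lens - 1L],
      seq = substring(s, starts, starts + lens - 1L))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif_class = character(0), start = integer(0),
               end = integer(0), seq = character(0))
  out <- out[order(out$start, out$motif_class), ]
  rownames(out) <- NULL
  out
}

#' Extract hydrophobic-centered interaction windows from a rate profile
#'
#' Regions where the titration-induced rate increase
#' (`r1rho - reference r1rho`, per residue) exceeds `min_prominence`
#' define candidate interaction sites; contiguous runs form one region
#' each. Within a region, the hydrophobic residue (default set
#' L/F/I/V/M/W/Y) with the highest rate becomes the window center; a
#' region without any hydrophobic residue is skipped with a warning. Each
#' window covers `width` residues (odd), gap-padded with `-` beyond the
#' chain termini.
#'
#' @param rate_increase Numeric vector of per-residue rate increases
#'   (s^-1), named by residue number.
#' @param rates Numeric vector of the titration-point rates (s^-1), named
#'   by residue number (used for center selection and ranking).
#' @param seqrec A [sequence_record()] aligned to the same numbering.
#' @param width Window length (odd, default 21).
#' @param hydrophobic_set Candidate center residues.
#' @param min_prominence Region threshold on the rate increase (s^-1,
#'   default 2).
#' @return `data.frame(center, center_type, center_rate, start, end, seq)`
#'   of class `interaction_windows`, one row per region.
#' @export
extract_windows <- function(rate_increase, rates, seqrec, width = 21,
                            hydrophobic_set = HYDROPHOBIC_DEFAULT,
                            min_prominence = 2) {
  stopifnot(width %% 2 == 1, width >= 1)
  resno <- as.integer(names(rate_increase))
  stopifnot(!is.null(resno), !anyNA(resno))
  above <- resno[rate_increase > min_prominence]
  if (!length(above))
    return(structure(data.frame(center = integer(0),
                                center_type = character(0),
                                center_rate = numeric(0),
                                start = integer(0), end = integer(0),
                                seq = character(0)),
                     class = c("interaction_windows", "data.frame")))
  above <- sort(above)
  region_id <- cumsum(c(1L, diff(above) > 1L))
  half <- (width - 1L) %/% 2L
  rows <- lapply(split(above, region_id), function(rr) {
    ty <- residue_at(seqrec, rr)
    hyd <- rr[!is.na(ty) & ty %in% hydrophobic_set]
    if (!length(hyd)) {
      warning("region ", rr[1], "-", rr[length(rr)],
              " has no hydrophobic residue; skipped")
      return(NULL)
    }
    center <- hyd[which.max(rates[as.character(hyd)])]
    win_no <- (center - half):(center + half)
    letters_win <- residue_at(seqrec, win_no)
    letters_win[is.na(letters_win)] <- "-"
    data.frame(center = center,
               center_type = residue_at(seqrec, center),
               center_rate = unname(rates[as.character(center)]),
               start = win_no[1], end = win_no[width],
               seq = paste(letters_win, collapse = ""))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(center = integer(0), center_type = character(0),
               center_rate = numeric(0), start = integer(0),
               end = integer(0), seq = character(0))
  rownames(out) <- NULL
  class(out) <- c("interaction_windows", "data.frame")
  out
}

#' Rank interaction windows and build a position frequency matrix
#'
#' Windows are sorted by the central rate, descending (ties by residue
#' number, ascending), mirroring ranking interaction sites by the height
#' of the central relaxation rate. The count matrix is positions x 20
#' amino acids; gap padding is excluded, so column sums never exceed the
#' number of windows.
#'
#' @param windows An [extract_windows()] result.
#' @return List `ranked` (the sorted table with a `rank` column) and `pfm`
#'   (a `width x 20` integer count matrix, rows `pos1...`, columns the
#'   amino acids).
#' @export
rank_and_logo <- function(windows) {
  stopifnot(nrow(windows) >= 1)
  ord <- order(-windows$center_rate, windows$center)
  ranked <- windows[ord, ]
  ranked$rank <- seq_len(nrow(ranked))
  rownames(ranked) <- NULL
  width <- nchar(ranked$seq[1])
  pfm <- matrix(0L, nrow = width, ncol = length(AA1),
                dimnames = list(paste0("pos", seq_len(width)), AA1))
  for (s in ranked$seq) {
    ch <- strsplit(s, "")[[1]]
    for (i in seq_len(width))
      if (ch[i] %in% AA1) pfm[i, ch[i]] <- pfm[i, ch[i]] + 1L
  }
  list(ranked = ranked, pfm = pfm)
}
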