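#' Bundled random-coil reference shifts
#' @return `data.frame(residue_type, atom, shift_ppm)`.
#' @export
random_coil_table <- function() {
  utils::read.csv(system.file("extdata", "random_coil_shifts.csv",
                              package = "idrbind"),
                  stringsAsFactors = FALSE)
}

#' Bundled fully-formed helix/strand reference deviations
#' @return `data.frame(residue_type, atom, helix_delta, strand_delta)`.
#' @export
secondary_structure_reference <- function() {
  utils::read.csv(system.file("extdata", "secondary_structure_reference.csv",
                              package = "idrbind"),
                  stringsAsFactors = FALSE)
}

#' Secondary chemical shifts against a random-coil reference
#'
#' SCS = observed - random coil, the standard sign convention under which
#' positive CA (and CO) deviations indicate helix and positive CB
#' deviations indicate extended structure. Only CA, CB and CO are used;
#' residues or atoms missing from either table are simply absent from the
#' profile (Gly never has a CB entry).
#'
#' @param shifts A [shift_table()] with carbon shifts.
#' @param seqrec A [sequence_record()] covering the observed residues.
#' @param rc_table Random-coil reference (defaults to the bundled table).
#' @return `data.frame` of class `scs_profile` with columns
#'   `residue_number, residue_type, atom, scs`.
#' @export
compute_scs <- function(shifts, seqrec, rc_table = random_coil_table()) {
  carb <- shifts[shifts$atom %in% c("CA", "CB", "CO"), ]
  seq_ty <- residue_at(seqrec, carb$residue_number)
  known <- !is.na(seq_ty)
  mism <- known & seq_ty != carb$residue_type
  if (any(mism))
    stop("residue type mismatch at residue ",
         carb$residue_number[which(mism)[1]], ": table says ",
         carb$residue_type[which(mism)[1]], ", sequence says ",
         seq_ty[which(mism)[1]])
  ref <- stats::setNames(rc_table$shift_ppm,
                         paste(rc_table$residue_type, rc_table$atom))
  rc <- ref[paste(carb$residue_type, carb$atom)]
  keep <- !is.na(rc)
  out <- data.frame(residue_number = carb$residue_number[keep],
                    residue_type = carb$residue_type[keep],
                    atom = carb$atom[keep],
                    scs = carb$shift[keep] - rc[keep])
  out <- out[order(out$residue_number, out$atom), ]
  rownames(out) <- NULL
  class(out) <- c("scs_profile", "data.frame")
  out
}

#' Secondary structure propensity from carbon secondary shifts
#'
#' Windowed SCS combination normalized by the fully-formed helix/strand
#' reference deviations, so that a stretch whose SCSs exactly match the
#' full-helix reference scores +1 and a full-strand stretch scores -1;
#' partial populations scale linearly in between. Per residue, atoms enter
#' with sign +1 (CA, CO) or -1 (CB); the window sum is divided by the
#' matching-window sum of helix references when positive and of strand
#' references when negative.
#'
#' @param scs A [compute_scs()] profile.
#' @param window Odd window length in residues (default 5).
#' @param atoms Atoms to combine (default CA and CB; CO optional).
#' @param ss_ref Reference deviations (defaults to the bundled table).
#' @return `data.frame` of class `ssp_profile` with columns
#'   `residue_number, ssp`; residues whose window holds no carbon data get
#'   `NA`.
#' @export
compute_ssp <- function(scs, window = 5, atoms = c("CA", "CB"),
                        ss_ref = secondary_structure_reference()) {
  stopifnot(window >= 1, window %% 2 == 1)
  atoms <- toupper(atoms)
  use <- scs[scs$atom %in% atoms, ]
  key <- paste(use$residue_type, use$atom)
  helix <- stats::setNames(ss_ref$helix_delta,
                           paste(ss_ref$residue_type, ss_ref$atom))[key]
  strand <- stats::setNames(ss_ref$strand_delta,
                            paste(ss_ref$residue_type, ss_ref$atom))[key]
  sgn <- ifelse(use$atom == "CB", -1, 1)
  resnos <- sort(unique(scs$residue_number))
  half <- (window - 1) / 2
  ssp <- vapply(resnos, function(r) {
    inw <- abs(use$residue_number - r) <= half & !is.na(helix)
    if (!any(inw)) return(NA_real_)
    num <- sum(sgn[inw] * use$scs[inw])
    if (num >= 0) num / sum(sgn[inw] * helix[inw])
    else num / abs(sum(sgn[inw] * strand[inw]))
  }, numeric(1))
  out <- data.frame(residue_number = resnos, ssp = ssp)
  class(out) <- c("ssp_profile", "data.frame")
  out
}
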