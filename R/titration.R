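#' Titration series: per-point observables tied to a design
#'
#' @param design A [titration_design()].
#' @param points Named list (names = design point labels); each element a
#'   list with optional `shifts` (a [shift_table()]) and `intensities`
#'   (numeric vector named by residue number).
#' @param reference_label Label of the reference point (usually 0% partner).
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(design, points, reference_label) {
  stopifnot(inherits(design, "titration_design"))
  if (!reference_label %in% design$points$label)
    stop("reference label not in design: ", reference_label)
  if (!reference_label %in% names(points))
    stop("no data for reference point: ", reference_label)
  unknown <- setdiff(names(points), design$points$label)
  if (length(unknown))
    stop("data points not in design: ", paste(unknown, collapse = ", "))
  structure(list(design = design, points = points,
                 reference_label = reference_label),
            class = "titration_series")
}

#' Combined 1H/15N chemical shift perturbation
#'
#' `CSP = sqrt((delta_1H * 6.5)^2 + delta_15N^2)`: the proton difference is
#' scaled up by 6.5 and combined in quadrature with the nitrogen
#' difference. Note this weighting multiplies the proton axis rather than
#' down-weighting nitrogen; it is a uniform rescaling of the common
#' `sqrt(dH^2 + (dN/6.5)^2)` convention (by a factor 6.5), so per-residue
#' patterns and relative magnitudes are unchanged.
#'
#' @param delta_h 1H shift difference (ppm).
#' @param delta_n 15N shift difference (ppm).
#' @return CSP in ppm (vectorised).
#' @export
combined_csp <- function(delta_h, delta_n) {
  sqrt((delta_h * 6.5)^2 + delta_n^2)
}

#' Match peaks between two shift tables
#'
#' With transferred assignments (`mode = "number"`) residues match by
#' identical residue number whenever both tables carry H and N shifts for
#' it. `mode = "nearest"` matches each reference peak to the titrated peak
#' inside the `(tol_h, tol_n)` ellipse; a reference peak with two
#' candidates in tolerance, or two reference peaks claiming the same
#' titrated peak, are flagged ambiguous and excluded.
#'
#' @param reference,titrated [shift_table()]s with H and N rows.
#' @param tol_h,tol_n Matching tolerances in ppm (defaults 0.05 and 0.5).
#' @param mode `"number"` or `"nearest"`.
#' @return `data.frame(residue_number, matched_number, ambiguous)` plus an
#'   attribute `unmatched` listing reference residues without a partner.
#' @export
match_peaks <- function(reference, titrated, tol_h = 0.05, tol_n = 0.5,
                        mode = c("number", "nearest")) {
  mode <- match.arg(mode)
  hr <- atom_shifts(reference, "H"); nr <- atom_shifts(reference, "N")
  ht <- atom_shifts(titrated, "H"); nt <- atom_shifts(titrated, "N")
  ref_res <- intersect(names(hr), names(nr))
  tit_res <- intersect(names(ht), names(nt))
  if (!length(ref_res) || !length(tit_res))
    stop("both tables must carry H and N shifts")
  if (mode == "number") {
    common <- intersect(ref_res, tit_res)
    out <- data.frame(residue_number = as.integer(common),
                      matched_number = as.integer(common),
                      ambiguous = FALSE)
    attr(out, "unmatched") <- as.integer(setdiff(ref_res, tit_res))
    return(out[order(out$residue_number), ])
  }
  cand <- lapply(ref_res, function(r) {
    d2 <- ((hr[r] - ht[tit_res]) / tol_h)^2 + ((nr[r] - nt[tit_res]) / tol_n)^2
    tit_res[d2 <= 1]
  })
  matched <- vapply(cand, function(x) if (length(x) == 1) x else NA_character_,
                    character(1))
  ambiguous <- lengths(cand) > 1
  # two reference peaks claiming the same titrated peak are both ambiguous
  dup <- matched[!is.na(matched)][duplicated(matched[!is.na(matched)])]
  clash <- !is.na(matched) & matched %in% dup
  ambiguous <- ambiguous | clash
  matched[ambiguous] <- NA_character_
  out <- data.frame(residue_number = as.integer(ref_res),
                    matched_number = as.integer(matched),
                    ambiguous = ambiguous)
  attr(out, "unmatched") <- as.integer(ref_res[is.na(matched) & !ambiguous])
  out[order(out$residue_number), ]
}

#' Per-residue chemical shift perturbations across a titration
#'
#' For every non-reference point with shift data, residues carrying H and
#' N in both states contribute
#' `CSP = sqrt((6.5 * dH)^2 + dN^2)` ([combined_csp()]); residues missing
#' an atom in either state are skipped.
#'
#' @param series A [titration_series()].
#' @return `data.frame` of class `csp_profile` with columns
#'   `residue_number, point_label, b_total, delta_h, delta_n, csp`.
#' @export
compute_csp <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  ref <- series$points[[series$reference_label]]$shifts
  if (is.null(ref)) stop("reference point carries no shift table")
  h0 <- atom_shifts(ref, "H"); n0 <- atom_shifts(ref, "N")
  rows <- list()
  for (lab in setdiff(names(series$points), series$reference_label)) {
    st <- series$points[[lab]]$shifts
    if (is.null(st)) next
    h1 <- atom_shifts(st, "H"); n1 <- atom_shifts(st, "N")
    common <- Reduce(intersect, list(names(h0), names(n0),
                                     names(h1), names(n1)))
    if (!length(common)) next
    dh <- h1[common] - h0[common]
    dn <- n1[common] - n0[common]
    b <- series$design$points$b_total[series$design$points$label == lab]
    rows[[lab]] <- data.frame(residue_number = as.integer(common),
                              point_label = lab, b_total = b,
                              delta_h = unname(dh), delta_n = unname(dn),
                              csp = unname(combined_csp(dh, dn)))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(residue_number = integer(0), point_label = character(0),
               b_total = numeric(0), delta_h = numeric(0),
               delta_n = numeric(0), csp = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("csp_profile", "data.frame")
  out
}

#' Intensity ratios I/I0 across a titration
#'
#' Ratios of per-residue peak intensities at each point versus the
#' reference. Peaks present in the reference but absent at a point are
#' reported with ratio 0 and `disappeared = TRUE`, so exchange broadening
#' shows up in the profile rather than as a gap. Residues with
#' non-positive reference intensity are excluded.
#'
#' @param series A [titration_series()].
#' @return `data.frame(residue_number, point_label, i_over_i0, disappeared)`.
#' @export
intensity_ratios <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  i0 <- series$points[[series$reference_label]]$intensities
  if (is.null(i0)) stop("reference point carries no intensities")
  excl <- names(i0)[i0 <= 0]
  if (length(excl))
    warning("residue(s) with non-positive reference intensity excluded: ",
            paste(excl, collapse = ", "))
  i0 <- i0[i0 > 0]
  rows <- list()
  for (lab in setdiff(names(series$points), series$reference_label)) {
    it <- series$points[[lab]]$intensities
    if (is.null(it)) next
    ratio <- ifelse(names(i0) %in% names(it),
                    unname(it[names(i0)]) / unname(i0), 0)
    rows[[lab]] <- data.frame(residue_number = as.integer(names(i0)),
                              point_label = lab,
                              i_over_i0 = ratio,
                              disappeared = !(names(i0) %in% names(it)))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(residue_number = integer(0), point_label = character(0),
               i_over_i0 = numeric(0), disappeared = logical(0))
  rownames(out) <- NULL
  out
}
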