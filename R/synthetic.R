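# disorder-promoting background composition for generated IDR sequences
IDR_BACKGROUND_FREQS <- c(
  A = 0.079, R = 0.039, N = 0.039, D = 0.079, C = 0.005, Q = 0.049,
  E = 0.098, G = 0.118, H = 0.020, I = 0.020, L = 0.049, K = 0.059,
  M = 0.015, F = 0.020, P = 0.088, S = 0.118, T = 0.059, W = 0.005,
  V = 0.034, Y = 0.010)

#' Generate an IDR-like sequence with planted motifs
#'
#' Background residues are drawn from a disorder-promoting composition
#' (enriched G/S/A/P/D/E); motif strings are inserted verbatim at the
#' stated full-length positions. The returned truth map records the
#' planted motifs and, separately, every chance background hit found by
#' [scan_motifs()], so generator/scanner agreement can be audited.
#'
#' @param length Sequence length.
#' @param placements List of `list(pos =, seq =)` (full-length position of
#'   the motif's first residue); overlapping placements are an error.
#' @param seed Random seed (required).
#' @param first_residue_number Numbering offset of the construct.
#' @param id Sequence id.
#' @return List `sequence` (a [sequence_record()]) and `truth` (planted
#'   motifs, chance hits, background frequencies, seed).
#' @export
gen_sequence <- function(length, placements = list(), seed,
                         first_residue_number = 1L, id = "synthetic_idr") {
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  chars <- sample(names(IDR_BACKGROUND_FREQS), length, replace = TRUE,
                  prob = IDR_BACKGROUND_FREQS)
  occupied <- integer(0)
  for (pl in placements) {
    idx <- (pl$pos - first_residue_number + 1L) +
      seq_len(nchar(pl$seq)) - 1L
    if (any(idx < 1 | idx > length))
      stop("motif placement out of range at position ", pl$pos)
    if (any(idx %in% occupied))
      stop("overlapping motif placements at position ", pl$pos)
    chars[idx] <- strsplit(toupper(pl$seq), "")[[1]]
    occupied <- c(occupied, idx)
  }
  seqrec <- sequence_record(id, paste(chars, collapse = ""),
                            first_residue_number)
  hits <- scan_motifs(seqrec)
  planted <- if (length(placements))
    data.frame(pos = vapply(placements, `[[`, numeric(1), "pos"),
               seq = vapply(placements, `[[`, character(1), "seq"))
  else data.frame(pos = integer(0), seq = character(0))
  chance <- hits[!hits$start %in% unlist(lapply(placements, function(pl)
    pl$pos + seq_len(nchar(pl$seq)) - 1L)), ]
  list(sequence = seqrec,
       truth = list(planted = planted, all_hits = hits,
                    chance_hits = chance, seed = seed))
}

#' Generate titration R1rho profiles from a per-residue KD map
#'
#' Rates follow the weak-binding linear model ([predict_r1rho()], model
#' `"eq2"`) or the exact 1:1 quadratic bound fraction (model `"exact"`)
#' at every design point, with relative Gaussian noise. Residues outside
#' the KD map relax at their free-state rate. Optionally emits
#' magnetization decay tables consistent with the noise-free rates at
#' seven delays spanning 10-230 ms, for end-to-end tests through
#' [fit_decay()].
#'
#' @param seqrec A [sequence_record()] (defines the residue axis).
#' @param kd_map Named numeric vector, residue number -> KD (uM);
#'   residues absent from the map do not bind.
#' @param design A [titration_design()].
#' @param r_free Free-state rate (s^-1), scalar or named per residue.
#' @param r_bound Bound-state rate R1rho^B of the partner (s^-1).
#' @param noise_sd Relative rate noise (default 0.02).
#' @param seed Random seed (required).
#' @param model `"eq2"` (weak-binding linear) or `"exact"`.
#' @param decays Also generate per-point decay tables.
#' @param delays_s Decay delays (s).
#' @return List `rates` (data.frame `residue_number, point_label, b_total,
#'   r1rho, r1rho_error, flag`), `decays` (named list of [decay_table()]s
#'   or NULL) and `truth`.
#' @export
gen_titration_rates <- function(seqrec, kd_map, design, r_free = 3,
                                r_bound = 30, noise_sd = 0.02, seed,
                                model = c("eq2", "exact"), decays = FALSE,
                                delays_s = seq(0.01, 0.23, length.out = 7)) {
  model <- match.arg(model)
  if (missing(seed)) stop("seed is required")
  stopifnot(inherits(design, "titration_design"), noise_sd >= 0,
            all(kd_map > 0))
  set.seed(as.integer(seed))
  resno <- seqrec$numbers
  rf <- if (length(r_free) == 1) stats::setNames(rep(r_free, length(resno)),
                                                 resno)
        else r_free
  rows <- list(); dec <- list()
  for (i in seq_len(nrow(design$points))) {
    lab <- design$points$label[i]; b <- design$points$b_total[i]
    kd <- kd_map[as.character(resno)]
    kd[is.na(kd)] <- Inf # non-binding residues stay at r_free
    frac <- if (model == "eq2") b / (kd + design$a_total)
            else bound_fraction_exact(design$a_total, b, kd)
    r_true <- unname(rf[as.character(resno)]) +
      unname(frac) * (r_bound - unname(rf[as.character(resno)]))
    r_obs <- r_true + stats::rnorm(length(r_true), 0, noise_sd * r_true)
    err <- pmax(noise_sd * r_true, 1e-6)
    rows[[lab]] <- data.frame(residue_number = resno, point_label = lab,
                              b_total = b, r1rho = r_obs,
                              r1rho_error = err, flag = "ok")
    if (decays) {
      i0 <- 100
      ierr <- noise_sd * i0
      d <- expand.grid(residue_number = resno, delay_s = delays_s)
      mu <- i0 * exp(-rep(r_true, times = length(delays_s)) * d$delay_s)
      dec[[lab]] <- decay_table(d$residue_number, d$delay_s,
                                mu + stats::rnorm(nrow(d), 0, ierr),
                                rep(ierr, nrow(d)))
    }
  }
  list(rates = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       decays = if (decays) dec else NULL,
       truth = list(kd_map = kd_map, r_free = rf, r_bound = r_bound,
                    model = model, noise_sd = noise_sd, seed = seed,
                    a_total = design$a_total))
}

#' Default CPMG frequency grid (integer cycle counts)
#' @param t_relax Constant relaxation time (s).
#' @return 14 frequencies `n / t_relax` for
#'   `n = 1..6, 8, 10, 12, 16, 20, 24, 28, 32` (31.25-1000 Hz at 32 ms).
#' @export
default_nu_grid <- function(t_relax = 0.032) {
  c(1:6, 8, 10, 12, 16, 20, 24, 28, 32) / t_relax
}

#' Generate a two-state-exchange CPMG dispersion dataset
#'
#' R2eff values come from numerical Bloch-McConnell propagation
#' ([simulate_bm()]) plus absolute Gaussian noise; point errors are
#' `max(noise_sd, 0.5)` s^-1, mirroring the 0.5 s^-1 error floor used
#' when fitting.
#'
#' @param dw_map Named numeric vector, residue number -> |dw| (ppm).
#' @param k_ex,p_b Shared exchange parameters.
#' @param fields 1H fields (MHz), default 600 and 850.
#' @param t_relax Constant relaxation time (s), default 0.032.
#' @param nu_grid CPMG frequencies (Hz), default [default_nu_grid()].
#' @param r2_0 Baseline R2 (s^-1): scalar, or function(residue, field).
#' @param noise_sd Absolute R2eff noise (s^-1), default 0.5.
#' @param seed Random seed (required).
#' @return List `data` (a [dispersion_table()]) and `truth`.
#' @export
gen_dispersion <- function(dw_map, k_ex, p_b, fields = c(600, 850),
                           t_relax = 0.032, nu_grid = default_nu_grid(t_relax),
                           r2_0 = 8, noise_sd = 0.5, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(all(round(nu_grid * t_relax) >= 1))
  set.seed(as.integer(seed))
  r2fun <- if (is.function(r2_0)) r2_0 else function(res, f) r2_0
  rows <- list()
  for (res in names(dw_map)) for (f in fields) {
    base <- r2fun(as.integer(res), f)
    mu <- simulate_bm(nu_grid, t_relax, f, dw_map[[res]], k_ex, p_b, base)
    rows[[paste(res, f)]] <- data.frame(
      residue = as.integer(res), field_mhz = f, t_relax_s = t_relax,
      nu_cpmg_hz = nu_grid,
      r2eff = mu + stats::rnorm(length(nu_grid), 0, noise_sd),
      error = max(noise_sd, 0.5))
  }
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(data = dispersion_table(df),
       truth = list(k_ex = k_ex, p_b = p_b, dw_map = dw_map,
                    fields = fields, t_relax = t_relax,
                    noise_sd = noise_sd, seed = seed))
}

#' Generate a 1:1 ITC thermogram
#'
#' Heats from [simulate_injections()] plus Gaussian noise scaled to the
#' largest absolute heat.
#'
#' @param n,kd,dh,offset Ground-truth 1:1 parameters (see
#'   [simulate_injections()]).
#' @param cell_conc,syringe_conc,cell_volume,n_injections,injection_volume
#'   Instrument design (uM, uM, uL, count, uL).
#' @param noise_sd Relative heat noise (fraction of max |heat|, default
#'   0.01).
#' @param seed Random seed (required).
#' @return List `data` (an [itc_table()] with noisy heats) and `truth`.
#' @export
gen_itc <- function(n = 1, kd = 5.1, dh = -10, offset = 0,
                    cell_conc = 30, syringe_conc = 300, cell_volume = 200,
                    n_injections = 19, injection_volume = 2,
                    noise_sd = 0.01, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  design <- itc_table(cell_conc, syringe_conc, cell_volume,
                      data.frame(volume_uL = rep(injection_volume,
                                                 n_injections),
                                 heat_ucal = 0))
  mu <- simulate_injections(design, n, kd, dh, offset)
  heats <- mu + stats::rnorm(n_injections, 0, noise_sd * max(abs(mu)))
  design$injections$heat_ucal <- heats
  list(data = design,
       truth = list(n = n, kd = kd, dh = dh, offset = offset,
                    noise_sd = noise_sd, seed = seed))
}

#' Generate assigned shift tables with planted transient helices
#'
#' Backbone shifts are random coil plus `population x` the full-helix
#' reference deviation inside each helical window, plus Gaussian noise
#' (carbons `noise_sd` ppm; amide H and N at 1/10 and 1x `noise_sd` as a
#' typical precision ratio). Optionally a perturbed copy for CSP tests
#' moves selected residues' H/N shifts by stated amounts.
#'
#' @param seqrec A [sequence_record()].
#' @param helix_spec List of `list(range = c(from, to), population = p)`.
#' @param noise_sd Carbon shift noise (ppm), default 0.02.
#' @param seed Random seed (required).
#' @param csp_perturb Optional named list residue number ->
#'   `c(delta_h, delta_n)` defining the perturbed copy.
#' @return List `shifts` (reference [shift_table()]), `perturbed` (or
#'   NULL) and `truth`.
#' @export
gen_shift_tables <- function(seqrec, helix_spec = list(), noise_sd = 0.02,
                             seed, csp_perturb = NULL) {
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  rc <- random_coil_table()
  ss <- secondary_structure_reference()
  resno <- seqrec$numbers
  ty <- residue_at(seqrec, resno)
  pop <- stats::setNames(rep(0, length(resno)), resno)
  for (h in helix_spec) {
    stopifnot(h$population >= 0, h$population <= 1)
    sel <- resno >= h$range[1] & resno <= h$range[2]
    pop[sel] <- h$population
  }
  rows <- list()
  rc_key <- stats::setNames(rc$shift_ppm, paste(rc$residue_type, rc$atom))
  hx_key <- stats::setNames(ss$helix_delta, paste(ss$residue_type, ss$atom))
  for (atom in c("CA", "CB", "CO", "H", "N")) {
    base <- rc_key[paste(ty, atom)]
    keep <- !is.na(base)
    dev <- if (atom %in% c("CA", "CB", "CO"))
      pop[keep] * hx_key[paste(ty[keep], atom)] else 0
    sd_a <- if (atom == "H") noise_sd / 10 else noise_sd
    rows[[atom]] <- data.frame(
      residue_number = resno[keep], residue_type = ty[keep], atom = atom,
      shift = base[keep] + dev + stats::rnorm(sum(keep), 0, sd_a))
  }
  all_rows <- do.call(rbind, rows)
  ref <- shift_table(all_rows$residue_number, all_rows$residue_type,
                     all_rows$atom, all_rows$shift)
  perturbed <- NULL
  if (!is.null(csp_perturb)) {
    pt <- all_rows
    for (res in names(csp_perturb)) {
      ih <- pt$residue_number == as.integer(res) & pt$atom == "H"
      inn <- pt$residue_number == as.integer(res) & pt$atom == "N"
      pt$shift[ih] <- pt$shift[ih] + csp_perturb[[res]][1]
      pt$shift[inn] <- pt$shift[inn] + csp_perturb[[res]][2]
    }
    perturbed <- shift_table(pt$residue_number, pt$residue_type,
                             pt$atom, pt$shift)
  }
  list(shifts = ref, perturbed = perturbed,
       truth = list(helix_spec = helix_spec, noise_sd = noise_sd,
                    csp_perturb = csp_perturb, seed = seed))
}
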