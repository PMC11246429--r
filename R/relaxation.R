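fit_exp_one <- function(t, y) {
  # two-parameter least squares of y = I0 * exp(-R t), unweighted
  pos <- y > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm(log(y[pos]) ~ t[pos])
    start <- c(I0 = exp(unname(stats::coef(lf)[1])),
               R = -unname(stats::coef(lf)[2]))
  } else start <- c(I0 = max(y), R = 1)
  res <- try(minpack.lm::nls.lm(
    par = start,
    fn = function(p) y - p[["I0"]] * exp(-p[["R"]] * t),
    control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
  if (inherits(res, "try-error") || res$info %in% c(0, 5))
    return(c(I0 = NA_real_, R = NA_real_))
  c(I0 = res$par[["I0"]], R = res$par[["R"]])
}

#' Fit exponential magnetization decays to R1rho rates
#'
#' Per residue, a two-parameter (amplitude, rate) least-squares fit of
#' `I(t) = I0 * exp(-R * t)`. Rate uncertainties are the standard
#' deviation of rates refitted over `n_mc` Monte-Carlo resamples of the
#' intensities from their stated per-point errors.
#'
#' @param decays A [decay_table()].
#' @param n_mc Monte-Carlo resamples (default 500).
#' @param seed Random seed (required, for reproducible errors).
#' @param spin_lock_hz,field_mhz Recorded acquisition metadata.
#' @return `data.frame` of class `rate_profile` with columns
#'   `residue_number, r1rho, r1rho_error, flag` (`"ok"`, `"baseline"` for
#'   essentially flat decays, `"failed"` for non-convergent fits, excluded
#'   downstream).
#' @export
fit_decay <- function(decays, n_mc = 500, seed, spin_lock_hz = 1500,
                      field_mhz = 600) {
  stopifnot(inherits(decays, "decay_table"))
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  res <- lapply(split(decays, decays$residue_number), function(d) {
    fit <- fit_exp_one(d$delay_s, d$intensity)
    if (is.na(fit[["R"]]))
      return(data.frame(residue_number = d$residue_number[1],
                        r1rho = NA_real_, r1rho_error = NA_real_,
                        flag = "failed"))
    span <- diff(range(d$delay_s))
    flag <- if (abs(fit[["R"]]) * span < 0.02) "baseline" else "ok"
    draws <- vapply(seq_len(n_mc), function(i) {
      yi <- d$intensity + stats::rnorm(nrow(d), 0, d$intensity_error)
      fit_exp_one(d$delay_s, yi)[["R"]]
    }, numeric(1))
    data.frame(residue_number = d$residue_number[1],
               r1rho = fit[["R"]],
               r1rho_error = stats::sd(draws, na.rm = TRUE),
               flag = flag)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "spin_lock_hz") <- spin_lock_hz
  attr(out, "field_mhz") <- field_mhz
  class(out) <- c("rate_profile", "data.frame")
  out
}

#' Fast-exchange weak-binding R1rho prediction
#'
#' Under weak 1:1 binding in fast exchange, the observed rate is the
#' population-weighted average
#' `R1rho = b_total / (kd + a_total) * (r_bound - r_free) + r_free`,
#' linear in the added partner concentration.
#'
#' @param a_total Observed-protein concentration (uM).
#' @param b_total Added partner concentration (uM).
#' @param kd Dissociation constant (uM).
#' @param r_free Unbound-state rate R1rho^A (s^-1).
#' @param r_bound Bound-state rate R1rho^B (s^-1).
#' @return Predicted rate (s^-1), vectorised.
#' @export
predict_r1rho <- function(a_total, b_total, kd, r_free, r_bound) {
  stopifnot(all(kd + a_total > 0))
  b_total / (kd + a_total) * (r_bound - r_free) + r_free
}

#' Residue-wise dissociation constant from an R1rho titration
#'
#' Weighted linear regression of a residue's rates against added partner
#' concentration; inverting the weak-binding relation gives
#' `KD = (r_bound - intercept) / slope - a_total`, with the intercept
#' playing the role of the unbound-state rate. The fit is declared invalid
#' (no KD) when the slope is <= 0 or the intercept reaches `r_bound`.
#' Uncertainty is a Monte-Carlo percentile interval (2.5/97.5%) over
#' resampled rates, asymmetric because the transform is nonlinear.
#'
#' @param rates `data.frame` with `residue_number, point_label, r1rho,
#'   r1rho_error` (and optionally `flag`; non-"ok" rows are dropped).
#' @param design A [titration_design()].
#' @param r_bound Bound-state rate measured on the partner (s^-1).
#' @param residue Residue number to fit.
#' @param n_mc Monte-Carlo resamples (default 500).
#' @param seed Random seed (required).
#' @return Object of class `site_kd_fit`: fields `residue_number, kd,
#'   kd_lo, kd_hi, kd_error, slope, intercept, valid, flag, n_points`.
#' @export
fit_site_kd <- function(rates, design, r_bound, residue, n_mc = 500, seed) {
  stopifnot(inherits(design, "titration_design"))
  if (missing(seed)) stop("seed is required")
  d <- rates[rates$residue_number == residue, ]
  if ("flag" %in% names(d)) d <- d[d$flag %in% c("ok", ""), ]
  d$b_total <- NULL # design is authoritative for concentrations
  d <- merge(d, design$points, by.x = "point_label", by.y = "label")
  if (nrow(d) < 3)
    stop("fewer than 3 valid titration points for residue ", residue)
  w <- 1 / d$r1rho_error^2
  fit <- stats::lm(r1rho ~ b_total, data = d, weights = w)
  co <- stats::coef(fit)
  intercept <- unname(co[1]); slope <- unname(co[2])
  kd_of <- function(ic, sl) {
    if (sl <= 0 || ic >= r_bound) return(NA_real_)
    kd <- (r_bound - ic) / sl - design$a_total
    if (kd <= 0) NA_real_ else kd
  }
  kd <- kd_of(intercept, slope)
  flag <- if (slope <= 0) "invalid_slope"
          else if (intercept >= r_bound) "invalid_intercept"
          else if (is.na(kd)) "invalid_kd"
          else if (abs(slope) * max(d$b_total) <
                   2 * stats::median(d$r1rho_error)) "no_binding" else "ok"
  set.seed(as.integer(seed))
  draws <- vapply(seq_len(n_mc), function(i) {
    ri <- d$r1rho + stats::rnorm(nrow(d), 0, d$r1rho_error)
    f <- stats::lm.wfit(cbind(1, d$b_total), ri, w)
    kd_of(f$coefficients[1], f$coefficients[2])
  }, numeric(1))
  ok <- !is.na(draws)
  structure(list(residue_number = residue, kd = kd,
                 kd_lo = if (any(ok)) unname(stats::quantile(draws[ok], 0.025)) else NA_real_,
                 kd_hi = if (any(ok)) unname(stats::quantile(draws[ok], 0.975)) else NA_real_,
                 kd_error = if (any(ok)) stats::sd(draws[ok]) else NA_real_,
                 slope = slope, intercept = intercept,
                 valid = !is.na(kd) && flag == "ok",
                 flag = flag, n_points = nrow(d),
                 mc_valid_fraction = mean(ok)),
            class = "site_kd_fit")
}

#' @export
print.site_kd_fit <- function(x, ...) {
  cat(sprintf("residue %d: KD = %.4g uM [%.4g, %.4g] (%s)\n",
              x$residue_number, x$kd, x$kd_lo, x$kd_hi, x$flag))
  invisible(x)
}

#' Fit residue-wise KDs for every residue in a rate profile
#' @inheritParams fit_site_kd
#' @param residues Residue numbers (default: all in `rates`).
#' @return `data.frame` with one row per residue (kd and diagnostics);
#'   residues with under 3 valid points are skipped with a warning.
#' @export
site_kd_profile <- function(rates, design, r_bound, residues = NULL,
                            n_mc = 500, seed) {
  if (missing(seed)) stop("seed is required")
  if (is.null(residues)) residues <- sort(unique(rates$residue_number))
  rows <- lapply(seq_along(residues), function(i) {
    f <- try(fit_site_kd(rates, design, r_bound, residues[i],
                         n_mc = n_mc, seed = seed + i), silent = TRUE)
    if (inherits(f, "try-error")) {
      warning("residue ", residues[i], " skipped: ",
              attr(f, "condition")$message)
      return(NULL)
    }
    data.frame(residue_number = f$residue_number, kd_uM = f$kd,
               lo = f$kd_lo, hi = f$kd_hi, slope = f$slope,
               intercept = f$intercept, flag = f$flag)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
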