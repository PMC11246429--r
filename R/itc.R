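itc_concentrations <- function(itc) {
  # running cell-composition bookkeeping under the perfect-mixing
  # displaced-volume convention: each injection dilutes the cell contents
  # by (1 - v/V0) and delivers syringe material at v/V0
  v0 <- itc$cell_volume
  vol <- itc$injections$volume_uL
  a <- numeric(length(vol)); b <- numeric(length(vol))
  ca <- itc$cell_conc; cb <- 0
  for (i in seq_along(vol)) {
    f <- 1 - vol[i] / v0
    ca <- ca * f
    cb <- cb * f + itc$syringe_conc * vol[i] / v0
    a[i] <- ca; b[i] <- cb
  }
  data.frame(a_total = a, b_total = b, dilution = 1 - vol / v0)
}

#' Forward model: per-injection heats of a 1:1 ITC titration
#'
#' The complex concentration after each injection follows from the exact
#' 1:1 mass balance ([bound_fraction_exact()]) applied to the running cell
#' composition (perfect-mixing displaced-volume bookkeeping: every
#' injection dilutes the cell by `v/V0`). The heat of injection `i` is
#' `dh * V0 * (complex_i - complex_{i-1} * (1 - v_i/V0)) + offset`
#' converted to ucal (dh in kcal/mol, concentrations uM, volumes uL).
#' Stoichiometry `n` scales the cell-side binding-site concentration.
#'
#' @param itc An [itc_table()] (its heats are ignored; design only).
#' @param n Stoichiometry (sites per cell molecule).
#' @param kd Dissociation constant (uM).
#' @param dh Binding enthalpy (kcal/mol); negative = exothermic.
#' @param offset Per-injection baseline heat (ucal).
#' @return Numeric vector of per-injection heats (ucal).
#' @export
simulate_injections <- function(itc, n, kd, dh, offset = 0) {
  stopifnot(inherits(itc, "itc_table"), n > 0, kd >= 0)
  conc <- itc_concentrations(itc)
  sites <- n * conc$a_total
  complex <- ifelse(sites > 0,
                    bound_fraction_exact(sites, conc$b_total, kd) * sites, 0)
  prev <- c(0, complex[-length(complex)])
  dh * itc$cell_volume * (complex - prev * conc$dilution) * 1e-3 + offset
}

#' Fit a 1:1 binding model to ITC injection heats
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' [simulate_injections()] to the measured per-injection heats, for
#' stoichiometry `n`, `kd`, enthalpy `dh` and a constant per-injection
#' baseline offset. The first injection is excluded by default (common
#' practice for the diffusion-corrupted initial injection). A Wiseman
#' `c = n * cell_conc / kd` outside `[1, 1000]` triggers a warning: the
#' isotherm shape then poorly determines `kd`.
#'
#' @param itc An [itc_table()] with measured heats.
#' @param exclude_first Drop the first injection from the fit.
#' @return Object of class `itc_fit` with fields `n, kd, dh, offset`,
#'   standard errors, `c_value`, residuals and the integrated-heat table
#'   (`molar_ratio`, `heat_per_mol` in kcal/mol of injectant, fitted
#'   curve).
#' @export
fit_itc <- function(itc, exclude_first = itc$exclude_first) {
  stopifnot(inherits(itc, "itc_table"))
  use <- rep(TRUE, nrow(itc$injections))
  if (isTRUE(exclude_first)) use[1] <- FALSE
  if (sum(use) < 8)
    stop("fewer than 8 usable injections; cannot fit a 1:1 isotherm")
  heats <- itc$injections$heat_ucal
  scale <- max(abs(heats[use]), 1e-6)
  resid_fun <- function(p) {
    (heats - simulate_injections(itc, p[["n"]], p[["kd"]], p[["dh"]],
                                 p[["offset"]]))[use] / scale
  }
  # sign of the enthalpy from the early saturating heats
  dh0 <- sum(heats[use][1:3]) / (itc$syringe_conc *
                                   sum(itc$injections$volume_uL[use][1:3]) * 1e-3)
  start <- c(n = 1, kd = itc$cell_conc / 2, dh = dh0, offset = 0)
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fun,
    lower = c(n = 1e-2, kd = 1e-4, dh = -Inf, offset = -Inf),
    upper = c(n = 100, kd = 1e6, dh = Inf, offset = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info == 0 || !is.finite(fit$deviance))
    stop("ITC fit did not converge; residual norm ", signif(fit$deviance, 4))
  note <- if (fit$info == 5)
    "iteration limit reached (flat chi-square surface; kd weakly determined)"
  else NULL
  p <- fit$par
  cv <- try(solve(fit$hessian), silent = TRUE)
  dof <- max(1, sum(use) - 4)
  se <- if (inherits(cv, "try-error")) rep(NA_real_, 4) else
    sqrt(pmax(diag(cv), 0) * fit$deviance / dof)
  names(se) <- names(p)
  c_value <- p[["n"]] * itc$cell_conc / p[["kd"]]
  if (c_value < 1 || c_value > 1000)
    warning(sprintf("Wiseman c = %.3g outside [1, 1000]: kd poorly determined",
                    c_value))
  conc <- itc_concentrations(itc)
  fitted <- simulate_injections(itc, p[["n"]], p[["kd"]], p[["dh"]],
                                p[["offset"]])
  # ucal per nmol of injectant is kcal/mol
  inj_nmol <- itc$syringe_conc * itc$injections$volume_uL * 1e-3
  isotherm <- data.frame(
    injection = seq_along(heats),
    molar_ratio = conc$b_total / conc$a_total,
    heat_ucal = heats, fitted_ucal = fitted,
    heat_per_mol = (heats - p[["offset"]]) / inj_nmol,
    fitted_per_mol = (fitted - p[["offset"]]) / inj_nmol,
    used = use)
  structure(list(n = p[["n"]], kd = p[["kd"]], dh = p[["dh"]],
                 offset = p[["offset"]],
                 n_se = se[["n"]], kd_se = se[["kd"]], dh_se = se[["dh"]],
                 offset_se = se[["offset"]],
                 c_value = c_value, deviance = fit$deviance,
                 note = note, isotherm = isotherm),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("1:1 ITC fit: n = %.3f +- %.3f, KD = %.3g +- %.2g uM, dH = %.3g +- %.2g kcal/mol\n",
              x$n, x$n_se, x$kd, x$kd_se, x$dh, x$dh_se))
  cat(sprintf("  offset = %.3g ucal/injection, Wiseman c = %.3g\n",
              x$offset, x$c_value))
  invisible(x)
}
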