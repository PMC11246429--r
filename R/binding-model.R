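#' Exact 1:1 bound fraction of the observed species
#'
#' Solves the mass-balance quadratic for a bimolecular complex A + B <-> AB
#' and returns the fraction of A that is bound. Concentrations and `kd` are
#' in uM. The numerically stable (multiply-conjugate) form of the quadratic
#' root is used so that the result does not lose precision when
#' `kd` is much smaller than the total concentrations.
#'
#' @param a_total Total concentration of the observed species A (uM).
#' @param b_total Total concentration of the partner B (uM).
#' @param kd Equilibrium dissociation constant (uM).
#' @return Fraction of A in complex, in `[0, 1]`. Vectorised over all
#'   arguments.
#' @examples
#' bound_fraction_exact(1, 1, 1)   # (3 - sqrt(5)) / 2
#' bound_fraction_exact(100, 50, 0) # stoichiometric limit: 0.5
#' @export
bound_fraction_exact <- function(a_total, b_total, kd) {
  n <- max(length(a_total), length(b_total), length(kd))
  a <- rep_len(a_total, n); b <- rep_len(b_total, n); k <- rep_len(kd, n)
  if (any(a < 0 | b < 0 | k < 0)) stop("concentrations and kd must be >= 0")
  if (any(a == 0)) stop("a_total = 0: bound fraction of A is undefined")
  s <- a + b + k
  disc <- s^2 - 4 * a * b
  # complex = (s - sqrt(disc))/2 rewritten as 2ab / (s + sqrt(disc))
  complex <- ifelse(b == 0, 0, 2 * a * b / (s + sqrt(pmax(disc, 0))))
  complex / a
}

#' Dissociation constant from a bound population under 1:1 stoichiometry
#'
#' Inverts the 1:1 mass balance: given the bound fraction `p_b` of the
#' observed species (e.g. the minor-state population from a dispersion fit)
#' and the two total concentrations, the complex concentration is
#' `p_b * a_total` and `kd = a_free * b_free / complex`.
#'
#' @param p_b Bound fraction of A, strictly between 0 and `b_total/a_total`.
#' @param a_total,b_total Total concentrations (uM).
#' @return `kd` in uM.
#' @examples
#' kd_from_bound_fraction(0.089, 100, 10) # ~11.26 uM
#' @export
kd_from_bound_fraction <- function(p_b, a_total, b_total) {
  stopifnot(a_total > 0, b_total >= 0)
  if (any(p_b <= 0) || any(p_b >= 1))
    stop("p_b must lie strictly between 0 and 1")
  complex <- p_b * a_total
  if (any(complex >= b_total))
    stop("p_b * a_total >= b_total: bound A would exceed available partner")
  a_free <- a_total - complex
  b_free <- b_total - complex
  a_free * b_free / complex
}

#' Decompose an exchange rate into on- and off-rates
#'
#' For two-state binding the exchange rate is
#' `k_ex = k_on * b_free + k_off`, and detailed balance fixes
#' `k_off = (1 - p_b) * k_ex` and `k_on = p_b * k_ex / b_free`.
#' The implied `k_off / k_on` is algebraically identical to
#' [kd_from_bound_fraction()].
#'
#' @param k_ex Exchange rate (s^-1), > 0.
#' @param p_b Bound fraction of the observed species.
#' @param a_total,b_total Total concentrations (uM).
#' @return List with `k_on` (uM^-1 s^-1), `k_on_M` (M^-1 s^-1), `k_off`
#'   (s^-1), `kd` (uM, = k_off/k_on) and `b_free` (uM).
#' @examples
#' decompose_kinetics(662, 0.089, 100, 10)
#' @export
decompose_kinetics <- function(k_ex, p_b, a_total, b_total) {
  stopifnot(k_ex > 0)
  if (p_b <= 0 || p_b >= 1) stop("p_b must lie strictly between 0 and 1")
  b_free <- b_total - p_b * a_total
  if (b_free <= 0) stop("free partner concentration <= 0 for these inputs")
  k_off <- (1 - p_b) * k_ex
  k_on <- p_b * k_ex / b_free
  list(k_on = k_on, k_on_M = k_on * 1e6, k_off = k_off,
       kd = k_off / k_on, b_free = b_free)
}

#' Container for 1:1 binding parameters
#'
#' Bundles thermodynamic and (optionally) kinetic descriptors of a 1:1
#' interaction, checking the internal identities that link them.
#'
#' @param kd Dissociation constant (uM).
#' @param a_total,b_total Total concentrations (uM).
#' @param k_ex Optional exchange rate (s^-1); when given, `k_on`/`k_off`
#'   are derived with [decompose_kinetics()].
#' @return Object of class `binding_parameters`.
#' @export
binding_parameters <- function(kd, a_total, b_total, k_ex = NULL) {
  p_b <- bound_fraction_exact(a_total, b_total, kd)
  out <- list(kd = kd, a_total = a_total, b_total = b_total,
              bound_fraction_a = p_b, k_ex = k_ex,
              k_on = NULL, k_off = NULL)
  if (!is.null(k_ex) && p_b > 0) {
    kin <- decompose_kinetics(k_ex, p_b, a_total, b_total)
    stopifnot(abs(kin$kd - kd) <= 1e-6 * kd)
    out$k_on <- kin$k_on
    out$k_off <- kin$k_off
  }
  structure(out, class = "binding_parameters")
}

#' @export
print.binding_parameters <- function(x, ...) {
  cat(sprintf("1:1 binding: KD = %.4g uM  (A = %g uM, B = %g uM, pB = %.4g)\n",
              x$kd, x$a_total, x$b_total, x$bound_fraction_a))
  if (!is.null(x$k_ex))
    cat(sprintf("kinetics: k_ex = %.4g s-1, k_on = %.4g uM-1 s-1, k_off = %.4g s-1\n",
                x$k_ex, x$k_on, x$k_off))
  invisible(x)
}
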