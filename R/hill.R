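#' Least-squares Hill fit of a dose-response curve
#'
#' Fits `response = bottom + (top - bottom) * dose^n / (EC50^n + dose^n)`
#' by Levenberg-Marquardt least squares. Responses are expected on a
#' normalized scale (bound fraction in [0, 1]); a warning is raised if the
#' data are non-monotone beyond tolerance, but the fit is still returned.
#'
#' @param doses Numeric vector of doses (>= 4 points).
#' @param responses Numeric vector of responses.
#' @param fix_range Fix bottom = 0 and top = 1.
#' @return List: `ec50`, `n_hill`, `bottom`, `top`, `fitted`, `r_squared`.
#' @export
fit_hill <- function(doses, responses, fix_range = FALSE) {
  stopifnot(length(doses) >= 4, length(doses) == length(responses))
  ord <- order(doses)
  dd <- doses[ord]; rr <- responses[ord]
  mono_viol <- sum(pmax(0, -diff(rr))) / max(diff(range(rr)), 1e-12)
  if (mono_viol > 0.15)
    warning("dose-response is non-monotone beyond tolerance; fit returned anyway")
  ec50_0 <- stats::approx(rr, dd, xout = (min(rr) + max(rr)) / 2,
                          ties = "ordered")$y
  if (!is.finite(ec50_0)) ec50_0 <- stats::median(dd)
  if (fix_range) {
    fit <- minpack.lm::nlsLM(
      rr ~ dd^n / (ec50^n + dd^n),
      start = list(ec50 = ec50_0, n = 1),
      lower = c(ec50 = 1e-12, n = 0.05), upper = c(ec50 = Inf, n = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    co <- stats::coef(fit)
    bottom <- 0; top <- 1
  } else {
    fit <- minpack.lm::nlsLM(
      rr ~ bottom + (top - bottom) * dd^n / (ec50^n + dd^n),
      start = list(bottom = min(rr), top = max(rr), ec50 = ec50_0, n = 1),
      lower = c(bottom = -Inf, top = -Inf, ec50 = 1e-12, n = 0.05),
      upper = c(bottom = Inf, top = Inf, ec50 = Inf, n = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    co <- stats::coef(fit)
    bottom <- co[["bottom"]]; top <- co[["top"]]
  }
  fitted <- stats::predict(fit)
  ss_res <- sum((rr - fitted)^2)
  ss_tot <- sum((rr - mean(rr))^2)
  list(ec50 = co[["ec50"]], n_hill = co[["n"]], bottom = bottom, top = top,
       fitted = fitted[order(ord)], r_squared = 1 - ss_res / max(ss_tot, 1e-300))
}

#' Equilibrium bound fraction for simple 1:1 receptor-ligand binding
#'
#' @param L Ligand concentrations (same unit as `Kd`).
#' @param Kd Dissociation constant.
#' @return Bound receptor fraction `L / (Kd + L)` (receptor in excess ligand).
#' @export
binding_equilibrium_simple <- function(L, Kd) L / (Kd + L)

#' Equilibrium occupancy for a dimerizing receptor
#'
#' Ligand binds a monomeric receptor (Kd1), and ligand-bound monomers
#' dimerize (Kd2, concentration units of receptor). Because dimerization
#' couples two binding events, the occupancy-vs-ligand curve deviates from a
#' hyperbola (apparent Hill coefficient != 1), most visibly at receptor
#' levels comparable to Kd2. Solved exactly from the coupled equilibria.
#'
#' @param L Ligand concentrations.
#' @param R_total Total receptor (monomer units).
#' @param Kd1 Ligand-monomer dissociation constant.
#' @param Kd2 Dimerization dissociation constant (bound-monomer units).
#' @return Fraction of receptors residing in signaling dimers.
#' @export
binding_equilibrium_dimer <- function(L, R_total, Kd1, Kd2) {
  vapply(L, function(l) {
    occ <- l / (Kd1 + l)            # bound fraction of free monomers
    # solve monomer balance: R_total = M + 2 D, D = (occ*M)^2 / Kd2
    f <- function(M) M + 2 * (occ * M)^2 / Kd2 - R_total
    M <- stats::uniroot(f, c(0, R_total), tol = 1e-12)$root
    2 * (occ * M)^2 / Kd2 / R_total
  }, 0)
}
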