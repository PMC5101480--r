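R_KCAL <- 1.9872e-3  # gas constant, kcal/(mol K); 8.314 J/(mol K)

#' Construct/validate an ITC protocol
#'
#' @param cell_conc Cell analyte concentration (micromolar).
#' @param syringe_conc Titrant concentration (micromolar).
#' @param cell_volume Working cell volume V0 (microlitre); 200 uL matches
#'   a low-volume perfusion calorimeter.
#' @param injection_volumes Vector of injection volumes (microlitre).
#' @param temperature Temperature in K (default 298).
#' @return List of class `itc_protocol`.
#' @export
itc_protocol <- function(cell_conc, syringe_conc, cell_volume = 200,
                         injection_volumes = rep(2, 20), temperature = 298) {
  stopifnot_scalar_pos(cell_conc, "cell_conc")
  stopifnot_scalar_pos(syringe_conc, "syringe_conc")
  stopifnot_scalar_pos(cell_volume, "cell_volume")
  if (any(injection_volumes <= 0)) stop("injection volumes must be positive")
  if (temperature < 273 || temperature > 373)
    stop("temperature outside [273, 373] K")
  structure(list(cell_conc = cell_conc, syringe_conc = syringe_conc,
                 cell_volume = cell_volume,
                 injection_volumes = as.numeric(injection_volumes),
                 temperature = temperature),
            class = "itc_protocol")
}

#' Complete a thermodynamic parameter set from any two of K_d, dH, dS
#'
#' Uses `dG = -R T ln(K_b)` with `R = 1.9872e-3` kcal/(mol K) and
#' `dG = dH - T dS` (dS in cal/(mol K), hence the factor 1000) to fill in
#' the missing member and the derived `dG`, `K_b`.
#'
#' @param K_d Dissociation constant (micromolar), or `NULL`.
#' @param dH Binding enthalpy (kcal/mol), or `NULL`.
#' @param dS Binding entropy (cal/(mol K)), or `NULL`.
#' @param T Temperature (K, default 298).
#' @param n Stoichiometry (default 1).
#' @return List of class `thermo_params` with `K_d` (uM), `K_b` (1/M),
#'   `dG`, `dH` (kcal/mol), `dS` (cal/(mol K)), `n`, `T`.
#' @export
derive_thermo <- function(K_d = NULL, dH = NULL, dS = NULL, T = 298, n = 1) {
  given <- !c(Kd = is.null(K_d), dH = is.null(dH), dS = is.null(dS))
  if (sum(given) != 2L)
    stop("supply exactly two of K_d, dH, dS (got ", sum(given), ")")
  if (is.null(dS)) {
    K_b <- 1 / (K_d * 1e-6)
    dG <- -R_KCAL * T * log(K_b)
    dS <- (dH - dG) / T * 1000
  } else if (is.null(dH)) {
    K_b <- 1 / (K_d * 1e-6)
    dG <- -R_KCAL * T * log(K_b)
    dH <- dG + T * dS / 1000
  } else {
    dG <- dH - T * dS / 1000
    K_b <- exp(-dG / (R_KCAL * T))
    K_d <- 1e6 / K_b
  }
  structure(list(K_d = K_d, K_b = K_b, dG = dG, dH = dH, dS = dS,
                 n = n, T = T),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("K_d = %.4g uM  dG = %.3f kcal/mol  dH = %.3f kcal/mol  dS = %.3f cal/(mol K)  n = %.3g  T = %g K\n",
              x$K_d, x$dG, x$dH, x$dS, x$n, x$T))
  invisible(x)
}

check_thermo <- function(p) {
  rel <- function(a, b) abs(a - b) / max(abs(b), 1e-12)
  if (rel(p$K_b, 1 / (p$K_d * 1e-6)) > 1e-9) stop("K_b != 1/K_d")
  if (abs(p$dG - (p$dH - p$T * p$dS / 1000)) > 1e-9 * max(1, abs(p$dG)))
    stop("dG != dH - T dS")
  if (abs(p$dG + R_KCAL * p$T * log(p$K_b)) > 1e-9 * max(1, abs(p$dG)))
    stop("dG != -RT ln K_b")
  invisible(p)
}

# cell concentrations after each injection under the perfusion
# (displaced-volume) convention: each injection dv dilutes existing cell
# contents by (1 - dv/V0) while delivering syringe_conc * dv / V0
itc_concentrations <- function(protocol) {
  V0 <- protocol$cell_volume
  M <- numeric(length(protocol$injection_volumes))
  X <- numeric(length(protocol$injection_volumes))
  m <- protocol$cell_conc; x <- 0
  for (i in seq_along(protocol$injection_volumes)) {
    dv <- protocol$injection_volumes[i]
    f <- 1 - dv / V0
    m <- m * f
    x <- x * f + protocol$syringe_conc * dv / V0
    M[i] <- m; X[i] <- x
  }
  list(M = M, X = X)
}

# bound complex concentration (uM) for the one-site model with
# stoichiometry n: PL solves the quadratic in terms of sites nM
one_site_bound <- function(M, X, K_d, n) {
  S <- n * M  # binding-site concentration
  s <- S + X + K_d
  (s - sqrt(pmax(s^2 - 4 * S * X, 0))) / 2
}

#' Simulate integrated injection heats for a one-site titration
#'
#' Forward model for a perfusion-cell calorimeter. After injection i the
#' cumulative heat content is `Q_i = dH * V0 * [PL]_i` (in microcalories,
#' with concentrations in uM and V0 in uL). The measured heat of
#' injection i is
#' `q_i = Q_i - Q_{i-1} + (dv_i/V0) * (Q_i + Q_{i-1})/2 + dilution_offset`,
#' the middle term correcting for complex carried out in the displaced
#' volume (mean of the pre-/post-injection bound concentration).
#'
#' @param params A `thermo_params` (see [derive_thermo()]).
#' @param protocol An `itc_protocol`.
#' @param dilution_offset Constant per-injection heat of dilution
#'   (microcal, default 0).
#' @return List of class `thermogram`: `injection_heats` (microcal, one
#'   per injection), `molar_ratio` (cumulative titrant:analyte in the
#'   cell), `protocol`.
#' @export
simulate_injection_heats <- function(params, protocol, dilution_offset = 0) {
  check_thermo(params)
  stopifnot(inherits(protocol, "itc_protocol"))
  conc <- itc_concentrations(protocol)
  V0 <- protocol$cell_volume
  PL <- one_site_bound(conc$M, conc$X, params$K_d, params$n)
  # uM * uL * kcal/mol = 1e-6 mol/L * 1e-6 L * 1e3 cal/mol = 1e-9 cal = 1e-3 ucal
  Q <- params$dH * V0 * PL * 1e-3
  Qprev <- c(0, Q[-length(Q)])
  dv <- protocol$injection_volumes
  q <- Q - Qprev + (dv / V0) * (Q + Qprev) / 2 + dilution_offset
  structure(list(injection_heats = q,
                 molar_ratio = conc$X / conc$M,
                 protocol = protocol),
            class = "thermogram")
}

#' Fit the one-site binding model to an ITC thermogram
#'
#' Levenberg-Marquardt least squares of the perfusion-cell one-site model
#' against integrated injection heats, fitting log10(K_b), dH and a
#' constant dilution offset; stoichiometry n is fixed at 1 by default.
#' Entropy and free energy are derived from the fitted K_b afterwards.
#' Multi-start over log-spaced K_b initial values guards against local
#' minima; the first injection is discarded by default (the usual
#' correction for diffusion across the syringe tip during equilibration).
#'
#' @param thermogram A `thermogram` (heats in microcal).
#' @param fix_n Keep n = 1 (default `TRUE`). When `FALSE`, n is fitted.
#' @param discard_first Drop injection 1 before fitting (default `TRUE`).
#' @param n_starts Number of K_b starting values (default 5).
#' @return List of class `itc_fit`: `params` (a `thermo_params`),
#'   `dilution_offset` (microcal), `residuals` (microcal), `converged`.
#' @export
fit_one_site <- function(thermogram, fix_n = TRUE, discard_first = TRUE,
                         n_starts = 5) {
  stopifnot(inherits(thermogram, "thermogram"))
  q <- thermogram$injection_heats
  prot <- thermogram$protocol
  use <- seq_along(q)
  if (discard_first) use <- use[-1]
  if (length(use) < 5) stop("need at least 5 usable injections")
  if (all(abs(q[use] - mean(q[use])) < 1e-12) && abs(mean(q[use])) < 1e-9)
    return(structure(list(params = NULL, dilution_offset = 0,
                          residuals = rep(NA_real_, length(use)),
                          converged = FALSE,
                          message = "all heats zero: nothing to fit"),
                     class = "itc_fit"))
  conc <- itc_concentrations(prot)
  V0 <- prot$cell_volume
  dv <- prot$injection_volumes
  model_q <- function(lkb, dH, off, n) {
    K_d <- 1e6 / 10^lkb
    PL <- one_site_bound(conc$M, conc$X, K_d, n)
    Q <- dH * V0 * PL * 1e-3
    Qp <- c(0, Q[-length(Q)])
    Q - Qp + (dv / V0) * (Q + Qp) / 2 + off
  }
  dH0 <- sum(q[use]) / (prot$cell_conc * V0 * 1e-3)  # saturation guess
  if (!is.finite(dH0) || dH0 == 0) dH0 <- -1
  starts <- 10^seq(3, 8, length.out = n_starts)  # K_b in 1/M
  best <- NULL
  for (kb0 in starts) {
    par0 <- c(log10(kb0), dH0, 0)
    if (!fix_n) par0 <- c(par0, 1)
    fit <- try(minpack.lm::nls.lm(
      par = par0,
      fn = function(p) {
        nn <- if (fix_n) 1 else p[4]
        q[use] - model_q(p[1], p[2], p[3], nn)[use]
      },
      lower = c(0, -Inf, -Inf, if (!fix_n) 0.2),
      upper = c(12, Inf, Inf, if (!fix_n) 5),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(structure(list(params = NULL, dilution_offset = NA_real_,
                          residuals = rep(NA_real_, length(use)),
                          converged = FALSE,
                          message = "optimiser failed from all starts"),
                     class = "itc_fit"))
  p <- best$par
  lkb <- p[1]; at_bound <- lkb <= 1e-6 || lkb >= 12 - 1e-6
  K_b <- 10^lkb
  K_d <- 1e6 / K_b
  nn <- if (fix_n) 1 else p[4]
  params <- derive_thermo(K_d = K_d, dH = p[2], T = prot$temperature, n = nn)
  structure(list(params = params, dilution_offset = p[3],
                 residuals = q[use] - model_q(lkb, p[2], p[3], nn)[use],
                 converged = best$info %in% 1:4 && !at_bound),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  if (!x$converged && is.null(x$params)) {
    cat("one-site ITC fit: NOT converged (", x$message, ")\n", sep = "")
  } else {
    cat("one-site ITC fit", if (!x$converged) " (flagged: at bounds)", ":\n", sep = "")
    print(x$params)
  }
  invisible(x)
}

#' Read integrated injection heats from CSV
#'
#' @param path CSV with columns `injection` and `heat_ucal`.
#' @param protocol The matching `itc_protocol`.
#' @return A `thermogram`.
#' @export
read_thermogram <- function(path, protocol) {
  df <- utils::read.csv(path)
  if (!all(c("injection", "heat_ucal") %in% names(df)))
    stop("thermogram CSV must have columns injection, heat_ucal")
  df <- df[order(df$injection), ]
  if (nrow(df) != length(protocol$injection_volumes))
    stop("heat count does not match protocol injection count")
  conc <- itc_concentrations(protocol)
  structure(list(injection_heats = df$heat_ucal,
                 molar_ratio = conc$X / conc$M,
                 protocol = protocol),
            class = "thermogram")
}

#' Write a thermogram's integrated heats to CSV
#'
#' @param thermogram A `thermogram`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_thermogram <- function(thermogram, path) {
  utils::write.csv(data.frame(injection = seq_along(thermogram$injection_heats),
                              heat_ucal = thermogram$injection_heats),
                   path, row.names = FALSE)
  invisible(path)
}
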