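#' Fraction of labelled protein bound in a 1:1 equilibrium
#'
#' Closed-form solution of the two mass-balance equations for P + L <-> PL:
#' `[PL] = ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / 2`, returned as
#' `[PL] / P_tot`. Under fast exchange the observed shift of the labelled
#' protein is this fraction times the limiting bound-state shift.
#'
#' @param P_tot Total labelled-protein concentration (micromolar), > 0.
#' @param L_tot Total ligand concentration (micromolar), >= 0. Vectorised.
#' @param K_d Dissociation constant (micromolar), > 0.
#' @return Bound fraction in `[0, min(1, L_tot/P_tot)]`.
#' @export
bound_fraction <- function(P_tot, L_tot, K_d) {
  stopifnot_scalar_pos(P_tot, "P_tot")
  stopifnot_scalar_pos(K_d, "K_d")
  if (any(L_tot < 0)) stop("L_tot must be nonnegative")
  s <- P_tot + L_tot + K_d
  disc <- s^2 - 4 * P_tot * L_tot
  # disc >= (P - L)^2 + Kd^2 > 0 analytically; clamp against roundoff
  pl <- (s - sqrt(pmax(disc, 0))) / 2
  pmin(pmax(pl / P_tot, 0), 1)
}

#' Predicted fast-exchange CSP for one residue
#'
#' @param params List with elements `K_d` (micromolar) and `delta_max`
#'   (named numeric, ppm per residue).
#' @param P_tot,L_tot Total concentrations (micromolar).
#' @param residue Residue number (must exist in `params$delta_max`).
#' @return Predicted combined CSP in ppm.
#' @export
predict_observed_shift <- function(params, P_tot, L_tot, residue) {
  dm <- params$delta_max[as.character(residue)]
  if (anyNA(dm)) stop("residue ", residue, " absent from delta_max map")
  unname(dm) * bound_fraction(P_tot, L_tot, params$K_d)
}

#' Fit a 1:1 fast-exchange binding isotherm to CSP titration data
#'
#' Fits `delta_av(r, i) = delta_max_r * f(P, L_i, K_d)` by nonlinear least
#' squares. In the default `"global"` mode a single K_d is shared across
#' residues; `"per-residue"` mode fits each residue independently (useful
#' as a diagnostic for inconsistent trajectories). The optimisation is in
#' log10(K_d) space over `[1e-3, 1e5]` micromolar: for fixed K_d each
#' `delta_max_r` has the closed-form linear least-squares solution, so the
#' profiled objective is one-dimensional and is minimised by a log-spaced
#' multi-start grid refined with Brent's method.
#'
#' @param trajectories Output of [match_titration_peaks()], or any data
#'   frame with `residue_number`, `molar_ratio`, `labelled_conc`,
#'   `ligand_conc`, `shift_H`, `shift_N`, `observed`.
#' @param residue_subset Optional residue numbers to fit (default: all
#'   residues with any nonzero CSP).
#' @param mode `"global"` (shared K_d) or `"per-residue"`.
#' @param weight_N Nitrogen scaling used to form `delta_av` (default 1/5).
#' @param n_starts Number of log-spaced K_d start points (default 5).
#' @param kd_bounds Bounds on K_d in micromolar (default `c(1e-3, 1e5)`).
#' @return An object of class `binding_fit`: list with `K_d`, `delta_max`
#'   (named, ppm), `residuals` (per observation, ppm), `n_residues_used`,
#'   `converged`, `mode`, and (per-residue mode) `per_residue` table.
#' @export
fit_binding <- function(trajectories, residue_subset = NULL,
                        mode = c("global", "per-residue"),
                        weight_N = 0.2, n_starts = 5,
                        kd_bounds = c(1e-3, 1e5)) {
  mode <- match.arg(mode)
  d <- csp_design(trajectories, weight_N)
  if (!is.null(residue_subset)) d <- d[d$residue_number %in% residue_subset, ]
  npts <- length(unique(d$molar_ratio))
  if (npts < 3L) stop("need at least 3 titration points")
  if (all(abs(d$delta_av) < 1e-12))
    stop("no binding detectable: all CSPs are zero")
  # drop residues that never move (pure negative controls carry no K_d info
  # but would be fit with delta_max = 0 anyway; keep them out of the count)
  moving <- tapply(abs(d$delta_av), d$residue_number, max)
  use <- as.integer(names(moving)[moving > 1e-12])
  d <- d[d$residue_number %in% use, ]

  if (mode == "global") {
    fit <- profile_kd_fit(d, n_starts, kd_bounds)
    res <- structure(list(K_d = fit$K_d, delta_max = fit$delta_max,
                          residuals = fit$residuals,
                          n_residues_used = length(use),
                          converged = fit$converged, mode = mode),
                     class = "binding_fit")
  } else {
    per <- lapply(split(d, d$residue_number), profile_kd_fit,
                  n_starts = n_starts, kd_bounds = kd_bounds)
    tab <- data.frame(residue_number = as.integer(names(per)),
                      K_d = vapply(per, `[[`, 0, "K_d"),
                      delta_max = vapply(per, function(p) unname(p$delta_max), 0),
                      converged = vapply(per, `[[`, TRUE, "converged"))
    rownames(tab) <- NULL
    res <- structure(list(K_d = stats::median(tab$K_d),
                          delta_max = stats::setNames(tab$delta_max,
                                                      tab$residue_number),
                          residuals = unlist(lapply(per, `[[`, "residuals"),
                                             use.names = FALSE),
                          n_residues_used = length(use),
                          converged = all(tab$converged), mode = mode,
                          per_residue = tab),
                     class = "binding_fit")
  }
  res
}

# long-format design table: one row per observed (residue, point) with the
# CSP relative to the free state
csp_design <- function(trajectories, weight_N) {
  tr <- trajectories[trajectories$observed, , drop = FALSE]
  out <- do.call(rbind, lapply(split(tr, tr$residue_number), function(g) {
    g <- g[order(g$molar_ratio), , drop = FALSE]
    if (g$molar_ratio[1] != 0) return(NULL)  # free state required
    data.frame(residue_number = g$residue_number[-1],
               P_tot = g$labelled_conc[-1],
               L_tot = g$ligand_conc[-1],
               molar_ratio = g$molar_ratio[-1],
               delta_av = sqrt((g$shift_H[-1] - g$shift_H[1])^2 +
                               (weight_N * (g$shift_N[-1] - g$shift_N[1]))^2))
  }))
  rownames(out) <- NULL
  out
}

# 1-D profiled least squares over log10(Kd); delta_max solved in closed form
profile_kd_fit <- function(d, n_starts, kd_bounds) {
  lb <- log10(kd_bounds[1]); ub <- log10(kd_bounds[2])
  sse <- function(lkd) {
    f <- bound_fraction_vec(d$P_tot, d$L_tot, 10^lkd)
    s <- 0
    for (g in split(data.frame(f = f, y = d$delta_av), d$residue_number)) {
      dm <- if (sum(g$f^2) > 0) max(sum(g$f * g$y) / sum(g$f^2), 0) else 0
      s <- s + sum((g$y - dm * g$f)^2)
    }
    s
  }
  grid <- seq(lb, ub, length.out = max(n_starts, 2) * 8)
  vals <- vapply(grid, sse, 0)
  starts <- grid[order(vals)][seq_len(n_starts)]
  best <- NULL
  for (s0 in starts) {
    lo <- max(lb, s0 - 1.5); hi <- min(ub, s0 + 1.5)
    o <- stats::optimize(sse, c(lo, hi), tol = 1e-10)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  lkd <- best$minimum
  f <- bound_fraction_vec(d$P_tot, d$L_tot, 10^lkd)
  dm <- vapply(split(data.frame(f = f, y = d$delta_av), d$residue_number),
               function(g) if (sum(g$f^2) > 0) max(sum(g$f * g$y) / sum(g$f^2), 0) else 0,
               0)
  pred <- dm[as.character(d$residue_number)] * f
  at_bound <- lkd <= lb + 1e-3 || lkd >= ub - 1e-3
  list(K_d = 10^lkd, delta_max = dm,
       residuals = unname(d$delta_av - pred), converged = !at_bound)
}

# bound_fraction for paired vectors of P and L
bound_fraction_vec <- function(P, L, K_d) {
  s <- P + L + K_d
  pl <- (s - sqrt(pmax(s^2 - 4 * P * L, 0))) / 2
  pmin(pmax(pl / P, 0), 1)
}

#' Bootstrap uncertainty for a fitted K_d
#'
#' Global mode resamples residues with replacement and refits; per-residue
#' mode resamples fit residuals onto the model curve. The result is
#' deterministic for a fixed seed. A fit whose 90% interval spans more
#' than one order of magnitude is flagged `poorly_determined` — the
#' behaviour expected when the titration is run far above K_d, where the
#' isotherm carries almost no affinity information.
#'
#' @param trajectories The data used for the original fit.
#' @param fit A converged `binding_fit`.
#' @param n_boot Number of bootstrap replicates (>= 10, default 200).
#' @param seed Integer seed.
#' @param level Interval coverage (default 0.90).
#' @param weight_N Nitrogen scaling (default 1/5).
#' @return List with `K_d_stderr`, `interval` (percentile), `level`,
#'   `poorly_determined`, `K_d_boot` (replicate values).
#' @export
bootstrap_uncertainty <- function(trajectories, fit, n_boot = 200, seed = 1,
                                  level = 0.90, weight_N = 0.2) {
  if (!isTRUE(fit$converged)) stop("bootstrap requires a converged fit")
  if (n_boot < 10) stop("n_boot must be at least 10")
  d <- csp_design(trajectories, weight_N)
  d <- d[d$residue_number %in% as.integer(names(fit$delta_max)), ]
  res <- as.integer(names(fit$delta_max))
  kds <- numeric(n_boot)
  set.seed(seed)
  if (fit$mode == "global") {
    for (b in seq_len(n_boot)) {
      pick <- sample(res, length(res), replace = TRUE)
      db <- do.call(rbind, lapply(seq_along(pick), function(k) {
        g <- d[d$residue_number == pick[k], , drop = FALSE]
        g$residue_number <- k  # duplicated draws get distinct delta_max
        g
      }))
      kds[b] <- profile_kd_fit(db, n_starts = 3, kd_bounds = c(1e-3, 1e5))$K_d
    }
  } else {
    f <- bound_fraction_vec(d$P_tot, d$L_tot, fit$K_d)
    pred <- fit$delta_max[as.character(d$residue_number)] * f
    resid <- d$delta_av - pred
    for (b in seq_len(n_boot)) {
      db <- d
      db$delta_av <- pmax(pred + sample(resid, length(resid), replace = TRUE), 0)
      kds[b] <- profile_kd_fit(db, n_starts = 3, kd_bounds = c(1e-3, 1e5))$K_d
    }
  }
  ci <- unname(stats::quantile(kds, c((1 - level) / 2, 1 - (1 - level) / 2)))
  pci <- profile_kd_interval(d, level = level)
  list(K_d_stderr = stats::sd(kds), interval = ci,
       profile_interval = pci, level = level,
       poorly_determined = (ci[2] / ci[1]) > 10 || (pci[2] / pci[1]) > 10,
       K_d_boot = kds)
}

# F-test (profile chi-square) confidence interval for K_d: the set of K_d
# values whose profiled SSE stays below SSE_min * (1 + F/(n-p)). Case
# resampling alone understates uncertainty when the titration is run far
# above K_d (the isotherm is a saturated break with no curvature left),
# so the poorly-determined label consults this interval as well.
profile_kd_interval <- function(d, level = 0.90, kd_bounds = c(1e-3, 1e5)) {
  sse <- function(lkd) {
    f <- bound_fraction_vec(d$P_tot, d$L_tot, 10^lkd)
    s <- 0
    for (g in split(data.frame(f = f, y = d$delta_av), d$residue_number)) {
      dm <- if (sum(g$f^2) > 0) max(sum(g$f * g$y) / sum(g$f^2), 0) else 0
      s <- s + sum((g$y - dm * g$f)^2)
    }
    s
  }
  grid <- seq(log10(kd_bounds[1]), log10(kd_bounds[2]), length.out = 241)
  vals <- vapply(grid, sse, 0)
  n <- nrow(d)
  p <- 1L + length(unique(d$residue_number))
  if (n <= p) return(10^range(grid))
  cut <- min(vals) * (1 + stats::qf(level, 1, n - p) / (n - p))
  inside <- grid[vals <= cut]
  10^range(inside)
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("1:1 fast-exchange fit (%s): K_d = %.4g uM, %d residues, %s\n",
              x$mode, x$K_d, x$n_residues_used,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
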