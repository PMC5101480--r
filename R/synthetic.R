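#' Generate a fast-exchange HSQC titration series
#'
#' Forward model of a two-state fast-exchange titration: each shifting
#' residue moves linearly from its free position toward a bound position,
#' the travelled fraction being the 1:1 mass-balance bound fraction at
#' each point. The per-residue direction of travel (split between the 1H
#' and 15N axes) is drawn once from the seed and held fixed across ratios,
#' giving the straight-line peak trajectories characteristic of fast
#' exchange. Gaussian noise of `noise_csp` ppm (1H; scaled by the inverse
#' nitrogen weight on the 15N axis) is added independently at every point.
#' Non-shifting residues are included as negative controls.
#'
#' @param K_d_true Generating dissociation constant (micromolar).
#' @param delta_max_map Named numeric: limiting combined CSP (ppm) per
#'   shifting residue at saturation.
#' @param P_tot Labelled-protein concentration (micromolar).
#' @param ratios Molar ratios, starting at 0, strictly increasing.
#' @param noise_csp Gaussian shift noise, ppm (default 0).
#' @param n_controls Number of non-shifting residues appended (default 4).
#' @param weight_N Nitrogen weight used to split `delta_max` between axes
#'   (default 1/5).
#' @param seed Integer seed.
#' @return A `titration_series`.
#' @export
gen_titration_dataset <- function(K_d_true, delta_max_map, P_tot, ratios,
                                  noise_csp = 0, n_controls = 4,
                                  weight_N = 0.2, seed = 1) {
  if (!length(delta_max_map)) stop("delta_max_map is empty")
  if (noise_csp < 0) stop("noise must be >= 0")
  set.seed(seed)
  res_shift <- as.integer(names(delta_max_map))
  res_ctrl <- if (n_controls > 0) max(res_shift) + seq_len(n_controls) else integer()
  res <- c(res_shift, res_ctrl)
  nres <- length(res)
  freeH <- stats::runif(nres, 7.0, 9.5)
  freeN <- stats::runif(nres, 105, 130)
  theta <- stats::runif(nres, 0, 2 * pi)  # direction, fixed across ratios
  dmax <- c(unname(delta_max_map), rep(0, length(res_ctrl)))
  pts <- lapply(ratios, function(r) {
    f <- bound_fraction(P_tot, r * P_tot, K_d_true)
    dH <- dmax * cos(theta) * f
    dN <- dmax * sin(theta) / weight_N * f
    pk <- data.frame(residue_number = res,
                     residue_type = "X",
                     shift_H = freeH + dH + stats::rnorm(nres, 0, noise_csp),
                     shift_N = freeN + dN + stats::rnorm(nres, 0,
                                noise_csp / weight_N),
                     intensity = rep(1e6, nres),
                     stringsAsFactors = FALSE)
    class(pk) <- c("peaklist", "data.frame")
    pk
  })
  titration_series(pts, ratios, labelled_conc = P_tot,
                   observed_nucleus = "synthetic-15N")
}

#' Generate saturated/reference intensity tables for a hetNOE experiment
#'
#' Reference intensities are drawn positive; saturated intensities are
#' `noe_true * I_ref * (1 + eps)` with fractional Gaussian noise. Supplies
#' the canonical shapes of a disordered tail: use [hetnoe_profile_free()] /
#' [hetnoe_profile_bound()] for profiles whose last-five-residue windows
#' average -0.71 and 0.48 by construction.
#'
#' @param noe_profile Named numeric: true NOE ratio per residue.
#' @param noise_noe Fractional noise on the saturated intensity
#'   (default 0).
#' @param seed Integer seed.
#' @return List with data frames `sat` and `ref` (columns
#'   `residue_number`, `intensity`).
#' @export
gen_hetnoe_dataset <- function(noe_profile, noise_noe = 0, seed = 1) {
  if (noise_noe < 0) stop("noise must be >= 0")
  set.seed(seed)
  res <- as.integer(names(noe_profile))
  I_ref <- stats::runif(length(res), 5e5, 2e6)
  I_sat <- unname(noe_profile) * I_ref *
    (1 + stats::rnorm(length(res), 0, noise_noe))
  list(sat = data.frame(residue_number = res, intensity = I_sat),
       ref = data.frame(residue_number = res, intensity = I_ref))
}

#' Canonical free-state hetNOE profile with a flexible C-terminal tail
#'
#' Residues up to the tail are rigid (plateau 0.80); the last five
#' residues take values `-0.20, -0.50, -0.80, -0.95, -1.10`, whose mean is
#' exactly -0.71 — the free-state window average of a disordered
#' C-terminal pentapeptide.
#'
#' @param residues Integer residue numbers (>= 8 residues).
#' @return Named numeric NOE profile.
#' @export
hetnoe_profile_free <- function(residues = 380:407) {
  n <- length(residues)
  if (n < 8) stop("need at least 8 residues")
  prof <- c(rep(0.80, n - 5), c(-0.20, -0.50, -0.80, -0.95, -1.10))
  stats::setNames(prof, residues)
}

#' Canonical bound-state hetNOE profile with an ordered C-terminal tail
#'
#' As [hetnoe_profile_free()], but the last five residues take
#' `0.60, 0.55, 0.48, 0.41, 0.36` (mean exactly 0.48): the tail has become
#' partially ordered upon binding.
#'
#' @param residues Integer residue numbers (>= 8 residues).
#' @return Named numeric NOE profile.
#' @export
hetnoe_profile_bound <- function(residues = 380:407) {
  n <- length(residues)
  if (n < 8) stop("need at least 8 residues")
  prof <- c(rep(0.80, n - 5), c(0.60, 0.55, 0.48, 0.41, 0.36))
  stats::setNames(prof, residues)
}

#' PRE intensity ratio expected at distance r from the label
#'
#' Reduced forward model: `Gamma2 = Gamma2_ref * (r_ref / r)^6`;
#' `ratio = R2 / (R2 + Gamma2) * exp(-Gamma2 * t_evol)`. This keeps the
#' correct monotone r^-6 distance structure without the full
#' Solomon-Bloembergen constants, which the analysis side never consumes.
#'
#' @param r Distance(s) from the unpaired electron (Angstrom, > 0).
#' @param R2 Intrinsic transverse relaxation rate (1/s, default 15).
#' @param Gamma2_ref PRE rate at the reference distance (1/s, default 50).
#' @param r_ref Reference distance (Angstrom, default 12).
#' @param t_evol Transverse evolution time (s, default 0.010).
#' @return Expected intensity ratio(s) in (0, 1].
#' @export
pre_ratio_model <- function(r, R2 = 15, Gamma2_ref = 50, r_ref = 12,
                            t_evol = 0.010) {
  if (any(r <= 0)) stop("distance must be positive")
  G2 <- Gamma2_ref * (r_ref / r)^6
  R2 / (R2 + G2) * exp(-G2 * t_evol)
}

#' Generate paramagnetic/diamagnetic intensity tables from a structure
#'
#' Per residue, the distance from its amide nitrogen to the label site's
#' representative atom feeds [pre_ratio_model()]; the paramagnetic
#' intensity is `ratio * I_dia * (1 + eps)` with fractional Gaussian
#' noise.
#'
#' @param structure A `structure_model`.
#' @param label_site Residue number of the spin-label site (must be in
#'   the structure).
#' @param residues Residues to observe (default: all with an amide N,
#'   excluding the label site).
#' @param R2,Gamma2_ref,r_ref,t_evol Forward-model parameters (see
#'   [pre_ratio_model()]).
#' @param noise_pre Fractional noise (default 0).
#' @param seed Integer seed.
#' @return List with data frames `para` and `dia`, plus `distances`
#'   (named by residue) and `ratio_true`.
#' @export
gen_pre_dataset <- function(structure, label_site, residues = NULL,
                            R2 = 15, Gamma2_ref = 50, r_ref = 12,
                            t_evol = 0.010, noise_pre = 0, seed = 1) {
  if (!label_site %in% structure$residue_number)
    stop("label site ", label_site, " not in structure")
  set.seed(seed)
  site <- structure[structure$residue_number == label_site, ]
  rep_atom <- label_representative_atom(site)
  amide <- structure[structure$atom_name == "N" &
                     structure$residue_number != label_site, ]
  if (is.null(residues)) residues <- amide$residue_number
  amide <- amide[amide$residue_number %in% residues, ]
  r <- sqrt((amide$x - rep_atom[1])^2 + (amide$y - rep_atom[2])^2 +
            (amide$z - rep_atom[3])^2)
  if (any(r == 0)) stop("zero distance between label and amide")
  ratio <- pre_ratio_model(r, R2, Gamma2_ref, r_ref, t_evol)
  I_dia <- stats::runif(nrow(amide), 5e5, 2e6)
  I_para <- ratio * I_dia * (1 + stats::rnorm(nrow(amide), 0, noise_pre))
  list(para = data.frame(residue_number = amide$residue_number,
                         intensity = I_para),
       dia = data.frame(residue_number = amide$residue_number,
                        intensity = I_dia),
       distances = stats::setNames(r, amide$residue_number),
       ratio_true = stats::setNames(ratio, amide$residue_number))
}

#' Generate a noisy one-site ITC thermogram
#'
#' [simulate_injection_heats()] plus seeded Gaussian noise on each
#' integrated heat.
#'
#' @param params A `thermo_params`.
#' @param protocol An `itc_protocol`.
#' @param noise_q Heat noise, microcal (default 0).
#' @param dilution_offset Constant dilution heat, microcal (default 0).
#' @param seed Integer seed.
#' @return A `thermogram`.
#' @export
gen_itc_thermogram <- function(params, protocol, noise_q = 0,
                               dilution_offset = 0, seed = 1) {
  if (noise_q < 0) stop("noise must be >= 0")
  tg <- simulate_injection_heats(params, protocol, dilution_offset)
  set.seed(seed)
  tg$injection_heats <- tg$injection_heats +
    stats::rnorm(length(tg$injection_heats), 0, noise_q)
  tg
}

#' Build an ideal toy polypeptide structure
#'
#' Constructs an all-backbone (N, CA, C, O, CB) chain of alanines with
#' standard bond geometry (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom)
#' using internal-coordinate chain extension. `"extended"` uses
#' phi = -120, psi = 120 (CA-CA about 3.8 Angstrom); `"helix"` uses
#' phi = -57, psi = -47 (rise about 1.5 Angstrom per residue). Purely
#' deterministic; intended for synthetic PRE/SASA checks, not as a model
#' of any real protein.
#'
#' @param n_residues Chain length (>= 2).
#' @param geometry `"extended"` or `"helix"`.
#' @param first_residue Number of the first residue (default 1).
#' @return A `structure_model`.
#' @export
gen_toy_structure <- function(n_residues, geometry = c("extended", "helix"),
                              first_residue = 1L) {
  geometry <- match.arg(geometry)
  if (n_residues < 2) stop("need at least 2 residues")
  ang <- if (geometry == "helix") c(phi = -57, psi = -47)
         else c(phi = -120, psi = 120)
  rows <- build_backbone(n_residues, ang["phi"], ang["psi"])
  rows$residue_number <- rows$residue_number + as.integer(first_residue) - 1L
  rows$residue_type <- "ALA"
  rows$chain <- "A"
  rows$element <- substr(rows$atom_name, 1, 1)
  rows$radius <- unname(vdw_radii()[rows$element])
  st <- rows[, c("atom_name", "residue_number", "residue_type", "chain",
                 "element", "x", "y", "z", "radius")]
  class(st) <- c("structure_model", "data.frame")
  st
}

# place atom D given positions A, B, C, bond length |CD|, angle B-C-D (deg)
# and dihedral A-B-C-D (deg): standard NeRF construction
place_atom <- function(A, B, C, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  ab <- B - A; ab <- ab / sqrt(sum(ab^2))
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  C + bond * (-cos(ang) * bc + sin(ang) * (cos(dih) * m + sin(dih) * n))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

build_backbone <- function(nres, phi, psi, omega = 180) {
  # bond lengths / angles: Engh-Huber standard values
  bNCA <- 1.458; bCAC <- 1.525; bCN <- 1.329; bCO <- 1.231; bCACB <- 1.521
  aNCAC <- 111.2; aCACN <- 116.2; aCNCA <- 121.7; aCACO <- 120.8
  atoms <- list()
  add <- function(name, resno, xyz) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      atom_name = name, residue_number = resno,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  }
  # seed first residue in a canonical frame
  N <- c(0, 0, 0)
  CA <- c(bNCA, 0, 0)
  C <- place_atom(c(-1, 1, 0), N, CA, bCAC, aNCAC, phi)
  add("N", 1L, N); add("CA", 1L, CA); add("C", 1L, C)
  prevN <- N; prevCA <- CA; prevC <- C
  for (i in seq_len(nres)) {
    if (i > 1) {
      N <- place_atom(prevN, prevCA, prevC, bCN, aCACN, psi)
      CA <- place_atom(prevCA, prevC, N, bNCA, aCNCA, omega)
      C <- place_atom(prevC, N, CA, bCAC, aNCAC, phi)
      add("N", i, N); add("CA", i, CA); add("C", i, C)
    }
    # carbonyl O antiperiplanar to the next N (psi + 180 off the CA)
    O <- place_atom(N, CA, C, bCO, aCACO, psi + 180)
    add("O", i, O)
    # CB off the improper N-C-CA-CB torsion (~122.5 deg, L-amino acid)
    CB <- place_atom(N, C, CA, bCACB, 110.1, 122.5)
    add("CB", i, CB)
    prevN <- N; prevCA <- CA; prevC <- C
  }
  df <- do.call(rbind, atoms)
  df$residue_number <- as.integer(df$residue_number)
  df
}
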