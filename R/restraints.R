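#' Deterministic unit-sphere point set (golden-section spiral)
#'
#' @param n Number of points (>= 2).
#' @return An n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  # antipodally symmetric set (each point paired with its negative) so
  # that mirror-image atom arrangements receive exactly equal areas
  m <- max(1L, n %/% 2L)
  i <- seq_len(m) - 0.5
  phi <- acos(1 - i / m)          # upper hemisphere
  theta <- pi * (1 + sqrt(5)) * i
  up <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  rbind(up, -up)
}

#' Solvent-accessible surface area (rolling-probe sphere sampling)
#'
#' Shrake-Rupley algorithm: each atom's surface is sampled at `n_points`
#' deterministic sphere points at radius `r_vdw + probe_radius`; a point is
#' accessible when outside every neighbouring atom's probe-expanded sphere.
#' Per-atom SASA is the accessible fraction times the full sphere area;
#' per-residue SASA sums the residue's atoms.
#'
#' @param structure A `structure_model` (heavy atoms with radii).
#' @param probe_radius Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sphere sampling count (>= 92, default 960).
#' @return List of class `sasa_result`: `atom_sasa` (per atom, in
#'   structure order), `residue_sasa` (named by residue number),
#'   `residue_type` (named), `probe_radius`, `n_points`.
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, n_points = 960) {
  if (!nrow(structure)) stop("empty structure")
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (n_points < 92) stop("n_points must be at least 92")
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  r <- structure$radius + probe_radius
  n <- nrow(xyz)
  d2 <- as.matrix(stats::dist(xyz))^2
  if (n > 1 && min(d2[upper.tri(d2)]) == 0)
    stop("overlapping atoms at zero separation")
  pts <- sphere_points(n_points)
  np <- nrow(pts)
  atom_sasa <- numeric(n)
  for (i in seq_len(n)) {
    # neighbours whose expanded spheres can occlude atom i's surface
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    area <- 4 * pi * r[i]^2
    if (!length(nb)) {
      atom_sasa[i] <- area
      next
    }
    surf <- pts * r[i] + rep(xyz[i, ], each = np)
    free <- rep(TRUE, np)
    for (j in nb) {
      dj2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
             (surf[, 3] - xyz[j, 3])^2
      free <- free & dj2 > r[j]^2
      if (!any(free)) break
    }
    atom_sasa[i] <- area * mean(free)
  }
  res_sasa <- tapply(atom_sasa, structure$residue_number, sum)
  res_type <- tapply(structure$residue_type, structure$residue_number,
                     function(t) t[1])
  ord <- order(as.integer(names(res_sasa)))
  out <- list(atom_sasa = atom_sasa,
              residue_sasa = res_sasa[ord],
              residue_type = res_type[ord],
              probe_radius = probe_radius, n_points = n_points)
  class(out) <- "sasa_result"
  out
}

#' Relative solvent accessibility per residue
#'
#' Expresses each residue's SASA as a percentage of a theoretical maximum
#' for its residue type. Termini can legitimately exceed 100%; such values
#' are reported as-is with a message, never clipped.
#'
#' @param result A `sasa_result`.
#' @param reference_table Named vector of maximum ASA values (Angstrom^2)
#'   by three-letter residue code (default [max_asa_reference()]).
#' @return Numeric vector of percentages named by residue number.
#' @export
relative_sasa <- function(result, reference_table = max_asa_reference()) {
  types <- toupper(result$residue_type)
  unknown <- setdiff(unique(types), names(reference_table))
  if (length(unknown))
    stop("residue type(s) missing from reference table: ",
         paste(unknown, collapse = ", "))
  rel <- 100 * as.numeric(result$residue_sasa) / reference_table[types]
  names(rel) <- names(result$residue_sasa)
  over <- rel > 100
  if (any(over))
    message("relative accessibility above 100% (terminal residues?): ",
            paste(names(rel)[over], collapse = ", "))
  rel
}

#' Select active and passive residues for ambiguous docking restraints
#'
#' Active residues show a combined CSP above `csp_threshold` *and*
#' relative solvent accessibility above `sasa_threshold` (both strict).
#' Passive residues are the remaining accessible residues with any heavy
#' atom within `passive_radius` of any active-residue heavy atom — the
#' "solvent-exposed neighbours of active residues" of the standard
#' data-driven docking protocol.
#'
#' @param csp_values Numeric CSP values (ppm) named by residue number
#'   (e.g. `setNames(profile$delta_av, profile$residue_number)`).
#' @param rel_sasa Relative accessibility (%) named by residue number.
#' @param structure A `structure_model` for the neighbourhood search.
#' @param csp_threshold CSP cutoff in ppm (default 0.10).
#' @param sasa_threshold Accessibility cutoff in % (default 45).
#' @param passive_radius Heavy-atom distance defining "juxtaposed"
#'   (default 6.5 Angstrom).
#' @return List with sorted integer vectors `active` and `passive`.
#' @export
select_air_residues <- function(csp_values, rel_sasa, structure,
                                csp_threshold = 0.10, sasa_threshold = 45,
                                passive_radius = 6.5) {
  stopifnot_scalar_pos(csp_threshold, "csp_threshold")
  stopifnot_scalar_pos(sasa_threshold, "sasa_threshold")
  perturbed <- as.integer(names(csp_values)[csp_values > csp_threshold])
  accessible <- as.integer(names(rel_sasa)[rel_sasa > sasa_threshold])
  active <- sort(intersect(perturbed, accessible))
  if (!length(active))
    stop("no active residues: every perturbed residue fails the ",
         "accessibility filter (or no residue passes the CSP cutoff); ",
         "review thresholds")
  candidates <- setdiff(accessible, active)
  if (length(candidates)) {
    axyz <- as.matrix(structure[structure$residue_number %in% active,
                                c("x", "y", "z")])
    near <- vapply(candidates, function(r) {
      cxyz <- as.matrix(structure[structure$residue_number == r,
                                  c("x", "y", "z")])
      if (!nrow(cxyz)) return(FALSE)
      min(proxy_dist2(cxyz, axyz)) <= passive_radius^2
    }, TRUE)
    passive <- sort(candidates[near])
  } else passive <- integer()
  list(active = active, passive = passive)
}

# all-pairs squared distances between two coordinate matrices
proxy_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
}

#' Assemble a two-molecule restraint set
#'
#' @param active_A,passive_A,active_B,passive_B Residue-number vectors for
#'   the two molecules (segids A and B).
#' @param distance_bounds `(target, minus, plus)` in Angstrom; the default
#'   `c(2.0, 2.0, 0.0)` gives the conventional 0-2 Angstrom effective AIR
#'   distance range.
#' @return List of class `restraint_set`.
#' @export
restraint_set <- function(active_A, passive_A = integer(),
                          active_B, passive_B = integer(),
                          distance_bounds = c(2.0, 2.0, 0.0)) {
  active_A <- sort(unique(as.integer(active_A)))
  active_B <- sort(unique(as.integer(active_B)))
  passive_A <- sort(setdiff(unique(as.integer(passive_A)), active_A))
  passive_B <- sort(setdiff(unique(as.integer(passive_B)), active_B))
  if (!length(active_A) || !length(active_B))
    stop("each molecule needs at least one active residue")
  structure(list(active_A = active_A, passive_A = passive_A,
                 active_B = active_B, passive_B = passive_B,
                 distance_bounds = as.numeric(distance_bounds)),
            class = "restraint_set")
}

#' Write ambiguous interaction restraints in CNS syntax
#'
#' Emits one `assign` block per active residue: an ambiguous distance from
#' that residue to the union of the partner's active and passive residues,
#' with bounds `target minus plus` (default `2.0 2.0 0.0`). The file is
#' re-parseable with [read_air_restraints()].
#'
#' @param set A `restraint_set`.
#' @param path Output `.tbl` path.
#' @return `path`, invisibly.
#' @export
write_air_restraints <- function(set, path) {
  stopifnot(inherits(set, "restraint_set"))
  b <- set$distance_bounds
  block <- function(res, seg, partner, pseg) {
    sel <- paste(sprintf("       (resid %d and segid %s)", partner, pseg),
                 collapse = "\n    or\n")
    sprintf("assign (resid %d and segid %s)\n(\n%s\n) %.1f %.1f %.1f\n",
            res, seg, sel, b[1], b[2], b[3])
  }
  tgt_B <- c(set$active_B, set$passive_B)
  tgt_A <- c(set$active_A, set$passive_A)
  blocks <- c(
    vapply(set$active_A, block, "", seg = "A", partner = tgt_B, pseg = "B"),
    vapply(set$active_B, block, "", seg = "B", partner = tgt_A, pseg = "A"))
  writeLines(c("! ambiguous interaction restraints", blocks), path)
  invisible(path)
}

#' Parse a CNS-syntax AIR file back into a restraint set
#'
#' @param path A `.tbl` file written by [write_air_restraints()].
#' @return A `restraint_set`.
#' @export
read_air_restraints <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("!.*?(\n|$)", "\n", txt)
  starts <- gregexpr("assign", txt)[[1]]
  if (starts[1] == -1) stop("no assign blocks in ", path)
  bounds <- NULL
  act <- list(A = integer(), B = integer())
  tgt <- list(A = integer(), B = integer())  # union of partner selections
  ends <- c(starts[-1], nchar(txt) + 1L)
  for (k in seq_along(starts)) {
    blk <- substr(txt, starts[k], ends[k] - 1L)
    sel <- regmatches(blk, gregexpr("resid\\s+(\\d+)\\s+and\\s+segid\\s+([A-Za-z])", blk))[[1]]
    m <- regmatches(sel, regexec("resid\\s+(\\d+)\\s+and\\s+segid\\s+([A-Za-z])", sel))
    resid <- vapply(m, function(x) as.integer(x[2]), 0L)
    segid <- vapply(m, function(x) toupper(x[3]), "")
    act[[segid[1]]] <- c(act[[segid[1]]], resid[1])
    other <- segid[-1][1]
    tgt[[other]] <- union(tgt[[other]], resid[-1])
    nums <- regmatches(blk, regexec("\\)\\s*([-0-9.]+)\\s+([-0-9.]+)\\s+([-0-9.]+)\\s*$", trimws(blk)))[[1]]
    if (length(nums) == 4) bounds <- as.numeric(nums[2:4])
  }
  restraint_set(active_A = act$A,
                passive_A = setdiff(tgt$A, act$A),
                active_B = act$B,
                passive_B = setdiff(tgt$B, act$B),
                distance_bounds = bounds %||% c(2.0, 2.0, 0.0))
}

#' Write a per-residue accessibility report to CSV
#'
#' @param result A `sasa_result`.
#' @param rel Output of [relative_sasa()] for the same structure.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sasa_report <- function(result, rel, path) {
  df <- data.frame(residue_number = as.integer(names(result$residue_sasa)),
                   residue_type = as.character(result$residue_type),
                   sasa = as.numeric(result$residue_sasa),
                   rel_sasa = as.numeric(rel[names(result$residue_sasa)]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
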