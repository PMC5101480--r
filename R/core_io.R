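#' Read an assigned peak list
#'
#' Parses a tabular list of assigned amide peaks into a data frame with one
#' row per assignment. Two dialects are supported:
#'
#' * `"tab"` (default): a 5-column tab-separated layout with columns
#'   `assignment`, `residue_number`, `shift_N`, `shift_H`, `intensity`
#'   (intensity optional), with or without a header line.
#' * `"sparky"`: a Sparky-style list whose first column is an assignment
#'   label such as `A101N-H`, followed by the w1 (15N) and w2 (1H) shifts
#'   and an optional data height.
#'
#' Rows that cannot be parsed are skipped with a warning naming their line
#' numbers; a file that yields zero parseable rows is an error.
#'
#' @param path Path to the peak-list file.
#' @param dialect `"tab"` or `"sparky"`.
#' @return A data frame of class `peaklist` with columns `residue_number`,
#'   `residue_type` (one-letter code, `"X"` if unknown), `shift_H`,
#'   `shift_N`, `intensity` (`NA` when absent).
#' @export
read_peaklist <- function(path, dialect = c("tab", "sparky")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("peak list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  rows <- list()
  bad <- integer()
  for (i in idx) {
    rec <- if (dialect == "tab") parse_tab_peak(lines[i]) else parse_sparky_peak(lines[i])
    if (is.null(rec)) {
      # tolerate a single header line silently; flag anything else
      if (i == idx[1] && grepl("[A-Za-z]", lines[i])) next
      bad <- c(bad, i)
    } else {
      rows[[length(rows) + 1L]] <- rec
    }
  }
  if (length(bad))
    warning("skipped ", length(bad), " unparseable peak-list line(s): ",
            paste(bad, collapse = ", "), call. = FALSE)
  if (!length(rows)) stop("no parseable peaks in ", path)
  pk <- do.call(rbind.data.frame, rows)
  validate_peaks(pk)
  class(pk) <- c("peaklist", "data.frame")
  pk
}

parse_tab_peak <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 4L) return(NULL)
  rn <- suppressWarnings(as.integer(f[2]))
  sN <- suppressWarnings(as.numeric(f[3]))
  sH <- suppressWarnings(as.numeric(f[4]))
  if (any(is.na(c(rn, sN, sH)))) return(NULL)
  it <- if (length(f) >= 5L) suppressWarnings(as.numeric(f[5])) else NA_real_
  rt <- sub("^([A-Za-z]?).*$", "\\1", f[1])
  rt <- if (nzchar(rt) && toupper(rt) %in% names(aa1_to_3)) toupper(rt) else "X"
  data.frame(residue_number = rn, residue_type = rt,
             shift_H = sH, shift_N = sN, intensity = it,
             stringsAsFactors = FALSE)
}

parse_sparky_peak <- function(line) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(f) < 3L) return(NULL)
  m <- regmatches(f[1], regexec("^([A-Za-z])(\\d+)N-?H$", f[1]))[[1]]
  if (length(m) != 3L) return(NULL)
  sN <- suppressWarnings(as.numeric(f[2]))
  sH <- suppressWarnings(as.numeric(f[3]))
  if (any(is.na(c(sN, sH)))) return(NULL)
  it <- if (length(f) >= 4L) suppressWarnings(as.numeric(f[4])) else NA_real_
  rt <- if (toupper(m[2]) %in% names(aa1_to_3)) toupper(m[2]) else "X"
  data.frame(residue_number = as.integer(m[3]), residue_type = rt,
             shift_H = sH, shift_N = sN, intensity = it,
             stringsAsFactors = FALSE)
}

validate_peaks <- function(pk) {
  if (any(pk$residue_number < 1L)) stop("residue numbers must be >= 1")
  if (any(pk$shift_H < -2 | pk$shift_H > 15))
    stop("1H shifts outside [-2, 15] ppm")
  ok_N <- is.na(pk$shift_N) | (pk$shift_N >= 90 & pk$shift_N <= 140)
  if (!all(ok_N)) stop("15N shifts outside [90, 140] ppm")
  invisible(pk)
}

#' Write an assigned peak list in the default tab dialect
#'
#' @param peaks A `peaklist` data frame (see [read_peaklist()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaks, path) {
  assignment <- paste0(peaks$residue_type, peaks$residue_number, "N-H")
  df <- data.frame(assignment = assignment,
                   residue_number = peaks$residue_number,
                   shift_N = sprintf("%.6f", peaks$shift_N),
                   shift_H = sprintf("%.6f", peaks$shift_H),
                   intensity = ifelse(is.na(peaks$intensity), "",
                                      sprintf("%.6g", peaks$intensity)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Assemble a titration series from per-point peak lists
#'
#' A titration series holds one peak list per titration point, ordered by
#' ascending ligand:protein molar ratio, with the labelled-protein
#' concentration held constant (the usual HSQC titration design). The first
#' point must be the ligand-free reference state.
#'
#' @param peak_tables List of `peaklist` data frames, one per point.
#' @param molar_ratios Numeric vector of unlabelled:labelled molar ratios,
#'   same length as `peak_tables`, starting at 0 and strictly increasing.
#' @param labelled_conc Total labelled-protein concentration (micromolar).
#' @param observed_nucleus Identifier for the labelled molecule.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(peak_tables, molar_ratios, labelled_conc,
                             observed_nucleus = "15N-protein") {
  if (length(peak_tables) != length(molar_ratios))
    stop("need one peak table per molar ratio")
  if (any(molar_ratios < 0)) stop("molar ratios must be nonnegative")
  if (molar_ratios[1] != 0) stop("first titration point must be the free state (ratio 0)")
  if (any(diff(molar_ratios) <= 0)) stop("molar ratios must be strictly increasing")
  stopifnot_scalar_pos(labelled_conc, "labelled_conc")
  for (p in peak_tables) {
    if (anyDuplicated(p$residue_number))
      stop("duplicate residue numbers within one titration point")
  }
  structure(list(points = peak_tables,
                 molar_ratios = as.numeric(molar_ratios),
                 labelled_conc = labelled_conc,
                 ligand_conc = as.numeric(molar_ratios) * labelled_conc,
                 observed_nucleus = observed_nucleus),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat("Titration series (", x$observed_nucleus, "), ",
      length(x$points), " points, ratios ",
      paste(format(x$molar_ratios), collapse = ", "),
      "; labelled protein ", x$labelled_conc, " uM\n", sep = "")
  invisible(x)
}

#' Track assigned peaks across titration points
#'
#' Matches peaks across the series by assignment label (residue number).
#' Residues absent at a point — typically broadened beyond detection — are
#' recorded as gaps (`NA` shifts), never interpolated. A warning is raised
#' when the weighted shift step between consecutive observed points exceeds
#' `jump_threshold`, which usually flags a mis-assignment; the trajectory
#' is retained unchanged.
#'
#' @param series A `titration_series`.
#' @param weight_N Nitrogen scaling for the weighted-shift metric
#'   (default 1/5).
#' @param jump_threshold Weighted-ppm step size that triggers a warning
#'   (default 0.15).
#' @return A data frame with one row per (residue, point):
#'   `residue_number`, `molar_ratio`, `labelled_conc`, `ligand_conc`,
#'   `shift_H`, `shift_N`, `observed`.
#' @export
match_titration_peaks <- function(series, weight_N = 0.2, jump_threshold = 0.15) {
  stopifnot(inherits(series, "titration_series"))
  free <- series$points[[1]]
  res <- sort(free$residue_number)
  out <- list()
  for (r in res) {
    sh <- sn <- rep(NA_real_, length(series$points))
    for (i in seq_along(series$points)) {
      p <- series$points[[i]]
      j <- match(r, p$residue_number)
      if (!is.na(j)) {
        sh[i] <- p$shift_H[j]
        sn[i] <- p$shift_N[j]
      }
    }
    obs <- which(!is.na(sh))
    if (length(obs) > 1L) {
      step <- sqrt(diff(sh[obs])^2 + (weight_N * diff(sn[obs]))^2)
      if (any(step > jump_threshold))
        warning(sprintf(
          "residue %d: weighted shift step %.3f ppm exceeds jump threshold %.3f (possible mis-assignment)",
          r, max(step), jump_threshold), call. = FALSE)
    }
    out[[length(out) + 1L]] <- data.frame(
      residue_number = r,
      molar_ratio = series$molar_ratios,
      labelled_conc = series$labelled_conc,
      ligand_conc = series$ligand_conc,
      shift_H = sh, shift_N = sn,
      observed = !is.na(sh))
  }
  traj <- do.call(rbind, out)
  rownames(traj) <- NULL
  traj
}

#' Read a protein chain from a PDB file
#'
#' Loads the heavy atoms of one chain through `bio3d`, resolves alternate
#' locations to the highest-occupancy copy, and attaches element-based van
#' der Waals radii from [vdw_radii()]. Residue numbering in the structure
#' can be reconciled with peak-list numbering via `offset` (structure
#' numbering + offset = assignment numbering), which is always declared
#' explicitly.
#'
#' @param path PDB file path.
#' @param chain Chain identifier (default `"A"`).
#' @param offset Integer added to structure residue numbers (default 0).
#' @return An object of class `structure_model`: a data frame with
#'   `atom_name`, `residue_number`, `residue_type`, `chain`, `element`,
#'   `x`, `y`, `z`, `radius`.
#' @export
read_structure <- function(path, chain = "A", offset = 0L) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  at <- at[at$chain %in% chain & at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (!nrow(at)) stop("chain ", chain, " not present in ", path)
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                substr(trimws(at$elety), 1, 1), at$elesy)))
  at$elem <- elem
  at <- at[elem != "H", , drop = FALSE]
  if (!nrow(at)) stop("no heavy atoms after filtering chain ", chain)
  # altloc: keep highest occupancy copy of each (residue, atom name)
  at$occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -at$occ)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  rad <- vdw_radii()[at$elem]
  if (anyNA(rad)) {
    rad[is.na(rad)] <- 1.70  # unknown elements fall back to carbon
  }
  st <- data.frame(atom_name = trimws(at$elety),
                   residue_number = at$resno + as.integer(offset),
                   residue_type = toupper(at$resid),
                   chain = at$chain,
                   element = at$elem,
                   x = at$x, y = at$y, z = at$z,
                   radius = unname(rad),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(st[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  st <- st[order(st$residue_number), , drop = FALSE]
  rownames(st) <- NULL
  class(st) <- c("structure_model", "data.frame")
  st
}

#' Write a structure model to a PDB file
#'
#' Thin wrapper over `bio3d::write.pdb`; `bfac` values (for example CSP or
#' PRE ratios per residue) can be painted into the B-factor column for
#' structure colouring.
#'
#' @param structure A `structure_model`.
#' @param path Output PDB path.
#' @param bfac Optional numeric vector (length `nrow(structure)`) for the
#'   B-factor column.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, bfac = NULL) {
  n <- nrow(structure)
  xyz <- as.vector(t(as.matrix(structure[, c("x", "y", "z")])))
  if (is.null(bfac)) bfac <- rep(0, n)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = structure$residue_number,
                   resid = structure$residue_type,
                   eleno = seq_len(n),
                   elety = structure$atom_name,
                   chain = structure$chain,
                   o = rep(1, n), b = bfac,
                   elesy = structure$element)
  invisible(path)
}

#' Annotate per-residue values into a PDB B-factor column
#'
#' Maps a named per-residue score (CSP, PRE ratio, ...) onto every atom of
#' the corresponding residue and writes a copy of the structure whose
#' B-factor column carries the score — the standard trick for colouring a
#' structure by an NMR observable.
#'
#' @param structure A `structure_model`.
#' @param values Numeric vector named by residue number.
#' @param path Output PDB path.
#' @param default Value for residues missing from `values` (default 0).
#' @return `path`, invisibly.
#' @export
annotate_bfactor <- function(structure, values, path, default = 0) {
  v <- values[as.character(structure$residue_number)]
  v[is.na(v)] <- default
  write_structure(structure, path, bfac = unname(v))
}
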