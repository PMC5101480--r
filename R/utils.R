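#' Van der Waals radii by element
#'
#' Bondi-style radii (Angstrom) for the heavy elements found in protein
#' coordinate files, plus hydrogen. Used by [read_structure()] and
#' [compute_sasa()].
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
}

#' Theoretical maximum accessible surface areas per residue type
#'
#' Theoretical maximum ASA values (Angstrom^2) for Gly-X-Gly tripeptides
#' from the Tien et al. (2013) table, used as the denominator for relative
#' solvent accessibility. Any other published table can be supplied to
#' [relative_sasa()] instead.
#'
#' @return Named numeric vector keyed by three-letter residue code.
#' @export
max_asa_reference <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
    GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
    LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
    SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
}

aa3_to_1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
aa1_to_3 <- stats::setNames(names(aa3_to_1), unname(aa3_to_1))

#' Read an analysis configuration file
#'
#' Configuration (concentrations, molar ratios, residue-numbering offsets,
#' thresholds) is declared explicitly in a YAML or JSON file, never guessed
#' from the data.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: ", ext))
  if (!is.list(cfg)) stop("config did not parse to a list")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(name, " must be a single positive finite number")
}
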