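# shared fixture builders; everything is generated in code

make_peaks <- function(residues, shift_H, shift_N, intensity = NA_real_,
                       residue_type = "A") {
  pk <- data.frame(residue_number = as.integer(residues),
                   residue_type = residue_type,
                   shift_H = shift_H, shift_N = shift_N,
                   intensity = intensity, stringsAsFactors = FALSE)
  class(pk) <- c("peaklist", "data.frame")
  pk
}

make_structure <- function(x, y, z, radius = 1.7, atom_name = "C",
                           residue_number = seq_along(x),
                           residue_type = "ALA") {
  st <- data.frame(atom_name = atom_name,
                   residue_number = as.integer(residue_number),
                   residue_type = residue_type, chain = "A",
                   element = substr(atom_name, 1, 1),
                   x = x, y = y, z = z, radius = radius,
                   stringsAsFactors = FALSE)
  class(st) <- c("structure_model", "data.frame")
  st
}

# independent oracle for the 1:1 bound fraction: numeric root of the
# mass-balance system P = p + pl, L = l + pl, Kd = p*l/pl in pl
bound_fraction_oracle <- function(P, L, K_d) {
  if (L == 0) return(0)
  g <- function(pl) (P - pl) * (L - pl) - K_d * pl
  pl <- stats::uniroot(g, c(0, min(P, L) * (1 - 1e-15)),
                       tol = 1e-14, extendInt = "downX")$root
  pl / P
}

# the twelve-point titration design used throughout the binding tests
default_ratios <- c(0, 0.1, 0.2, 0.35, 0.5, 0.7, 1, 1.5, 2, 3, 5, 8)
default_dmax <- stats::setNames(seq(0.10, 0.30, length.out = 6), 101:106)
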