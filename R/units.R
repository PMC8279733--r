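# Frozen conversion constants. All internal computation is in atomic units
# (bohr, hartree, electron masses); files store angstrom coordinates and
# hartree energies; reported fit errors and frequencies are in cm^-1.

#' Physical conversion constants
#'
#' Frozen constants used throughout the package. `hartree_to_cm` converts a
#' hartree energy to wavenumbers, `kcalmol_to_cm` a kcal/mol energy to
#' wavenumbers, `bohr_to_angstrom` a bohr length to angstroms and
#' `amu_to_me` an atomic mass (amu) to electron masses.
#'
#' @name constants
#' @keywords internal
NULL

#' @rdname constants
#' @export
hartree_to_cm <- 219474.6313632

#' @rdname constants
#' @export
kcalmol_to_cm <- 349.755

#' @rdname constants
#' @export
bohr_to_angstrom <- 0.529177210903

#' @rdname constants
#' @export
amu_to_me <- 1822.888486209

# unit -> (dimension, factor to the canonical unit of that dimension)
.unit_table <- list(
  "hartree"  = list(dim = "energy", to_canonical = hartree_to_cm),
  "cm-1"     = list(dim = "energy", to_canonical = 1),
  "kcal/mol" = list(dim = "energy", to_canonical = kcalmol_to_cm),
  "bohr"     = list(dim = "length", to_canonical = 1),
  "angstrom" = list(dim = "length", to_canonical = 1 / bohr_to_angstrom)
)

#' Convert values between supported units
#'
#' Exact multiplication by frozen conversion constants. Supported energy
#' units: `"hartree"`, `"cm-1"`, `"kcal/mol"`; length units: `"bohr"`,
#' `"angstrom"`. Conversion across dimensions is an error.
#'
#' @param value numeric vector to convert.
#' @param from,to unit names (see Details).
#' @return converted numeric vector.
#' @examples
#' unit_convert(745, "cm-1", "kcal/mol")  # 2.13
#' @export
unit_convert <- function(value, from, to) {
  uf <- .unit_table[[from]]
  ut <- .unit_table[[to]]
  if (is.null(uf)) stop("unknown unit: ", from)
  if (is.null(ut)) stop("unknown unit: ", to)
  if (uf$dim != ut$dim) {
    stop("cannot convert ", from, " (", uf$dim, ") to ", to, " (", ut$dim, ")")
  }
  value * (uf$to_canonical / ut$to_canonical)
}
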