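#' @title Physical constants and unit conversion
#' @description All internal computation uses Hartree atomic units
#'   (Hartree for energy, Bohr for length, Hartree/Bohr for force).
#'   Conversions to the reporting units common in mechanochemistry
#'   (kcal/mol, Angstrom, nanonewton) are derived once from CODATA
#'   defining constants; no factor is hard-coded at a call site.
#' @name units
NULL

# CODATA 2018 defining/recommended constants (SI)
.lgmf_codata <- list(
  hartree_J   = 4.3597447222071e-18, # Hartree energy in joule
  bohr_m      = 5.29177210903e-11,   # Bohr radius in metre
  avogadro    = 6.02214076e23,       # exact
  calorie_J   = 4.184                # thermochemical calorie, exact
)

# unit registry: dimension + factor converting VALUE IN UNIT -> internal
.lgmf_units <- local({
  cd <- .lgmf_codata
  kcalmol_per_hartree <- cd$hartree_J * cd$avogadro / (cd$calorie_J * 1000)
  nN_per_au_force <- cd$hartree_J / cd$bohr_m * 1e9
  ang_per_bohr <- cd$bohr_m * 1e10
  list(
    "Hartree"       = list(dim = "energy", to_internal = 1),
    "kcal/mol"      = list(dim = "energy", to_internal = 1 / kcalmol_per_hartree),
    "eV"            = list(dim = "energy", to_internal = 1.602176634e-19 / cd$hartree_J),
    "Bohr"          = list(dim = "length", to_internal = 1),
    "Angstrom"      = list(dim = "length", to_internal = 1 / ang_per_bohr),
    "Hartree/Bohr"  = list(dim = "force",  to_internal = 1),
    "nN"            = list(dim = "force",  to_internal = 1 / nN_per_au_force),
    "pN"            = list(dim = "force",  to_internal = 1 / (nN_per_au_force * 1000)),
    "1"             = list(dim = "none",   to_internal = 1)
  )
})

.lgmf_unit_lookup <- function(unit) {
  if (unit %in% names(.lgmf_units)) {
    u <- .lgmf_units[[unit]]
    return(list(dim = u$dim, to_internal = u$to_internal))
  }
  # compound "A/B" where A and B are registered units (e.g. "kcal/mol/nN");
  # split at each "/" and accept the first split whose two sides resolve
  chars <- gregexpr("/", unit, fixed = TRUE)[[1]]
  if (chars[1] > 0) {
    for (pos in chars) {
      num <- substr(unit, 1, pos - 1)
      den <- substr(unit, pos + 1, nchar(unit))
      if (num %in% names(.lgmf_units) && den %in% names(.lgmf_units)) {
        un <- .lgmf_units[[num]]; ud <- .lgmf_units[[den]]
        return(list(dim = paste0(un$dim, "/", ud$dim),
                    to_internal = un$to_internal / ud$to_internal))
      }
    }
  }
  stop("unknown unit: '", unit, "'", call. = FALSE)
}

#' Convert a value between units
#'
#' Supported units: `"Hartree"`, `"kcal/mol"`, `"eV"`, `"Bohr"`,
#' `"Angstrom"`, `"Hartree/Bohr"`, `"nN"`, `"pN"`, the dimensionless `"1"`,
#' and ratios thereof written `"A/B"` (e.g. `"kcal/mol/nN"` for a
#' mechanical response). Conversion between different dimensions is an
#' error; round trips are exact to 1e-12 relative.
#'
#' @param value numeric vector.
#' @param from,to unit names.
#' @return `value` expressed in `to`.
#' @examples
#' unit_convert(1, "Hartree", "kcal/mol")
#' unit_convert(0.05, "nN", "Hartree/Bohr")
#' @export
unit_convert <- function(value, from, to) {
  uf <- .lgmf_unit_lookup(from)
  ut <- .lgmf_unit_lookup(to)
  if (uf$dim != ut$dim)
    stop("incompatible units: '", from, "' (", uf$dim, ") -> '",
         to, "' (", ut$dim, ")", call. = FALSE)
  value * uf$to_internal / ut$to_internal
}

#' Table of the conversion factors in use
#'
#' @return data.frame with one row per registered simple unit.
#' @export
unit_table <- function() {
  data.frame(
    unit = names(.lgmf_units),
    dimension = vapply(.lgmf_units, function(u) u$dim, ""),
    to_internal = vapply(.lgmf_units, function(u) u$to_internal, 0),
    row.names = NULL
  )
}
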