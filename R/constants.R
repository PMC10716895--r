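# Unit system: length Angstrom, energy kcal/mol, mass amu, time ps, charge e.
# Avogadro's number, vacuum permittivity, the elementary charge and Planck's
# constant are absorbed into the four conversion constants below so that every
# formula in the package is written in this single consistent unit system.

.ls_const <- list(
  k_B  = 1.987204e-3,  # Boltzmann constant, kcal mol^-1 K^-1
  k_e  = 332.0636,     # Coulomb conversion e^2 -> kcal A mol^-1
  hbar = 1.5179e-2,    # reduced Planck constant, kcal ps mol^-1
  kcal_to_amuA2ps2 = 418.4,      # 1 kcal/mol expressed in amu A^2 ps^-2
  molar_to_per_A3  = 6.02214076e-4  # mol/L -> number density in A^-3
)

#' Physical constants used throughout the package
#'
#' Returns the fixed conversion constants of the package unit system
#' (Angstrom, kcal/mol, amu, ps, elementary charge).
#'
#' @return Named list with elements `k_B` (kcal mol^-1 K^-1), `k_e`
#'   (kcal A mol^-1 e^-2), `hbar` (kcal ps mol^-1), `kcal_to_amuA2ps2`
#'   (amu A^2 ps^-2 per kcal/mol) and `molar_to_per_A3` (A^-3 per mol/L).
#' @examples
#' ls_constants()$k_B * 300  # thermal energy at 300 K in kcal/mol
#' @export
ls_constants <- function() .ls_const

# seed-scoped RNG: run expr with a fixed seed, restoring global RNG state
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
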