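# Internal unit system: Angstrom, picosecond, amu, kcal/mol, elementary
# charge, Kelvin.  Conversions to reporting units (kJ/mol, ns, mPa*s, Pa)
# happen only at the output layer.

# Coulomb prefactor e^2/(4 pi eps0) in kcal*Angstrom/(mol*e^2)
.COULOMB_K <- 332.0637

# Boltzmann constant
.KB_KCAL <- 0.0019872041      # kcal/(mol*K)
.KB_J    <- 1.380649e-23      # J/K

# kinetic energy: amu*(A/ps)^2 -> kcal/mol
.KE_TO_KCAL <- 1 / 418.4

# pressure conversions to Pa
.KCAL_MOL_A3_TO_PA <- 4184 / 6.02214076e23 / 1e-30
.ATM_TO_PA <- 101325

.KCAL_TO_KJ <- 4.184
.BOHR_PER_ANGSTROM <- 1.8897259886

#' Physical constants used by the package
#'
#' Returns the constants of the internal unit system (Angstrom, ps, amu,
#' kcal/mol, elementary charge, Kelvin) as a named list, chiefly so tests
#' and downstream scripts can audit unit chains.
#'
#' @return Named list: `coulomb_k` (kcal A / (mol e^2)), `kb_kcal`
#'   (kcal/(mol K)), `kb_j` (J/K), `ke_to_kcal` (amu (A/ps)^2 -> kcal/mol),
#'   `kcal_mol_a3_to_pa`, `atm_to_pa`, `kcal_to_kj`, `bohr_per_angstrom`.
#' @export
#' @examples
#' mix_constants()$coulomb_k
mix_constants <- function() {
  list(
    coulomb_k = .COULOMB_K,
    kb_kcal = .KB_KCAL,
    kb_j = .KB_J,
    ke_to_kcal = .KE_TO_KCAL,
    kcal_mol_a3_to_pa = .KCAL_MOL_A3_TO_PA,
    atm_to_pa = .ATM_TO_PA,
    kcal_to_kj = .KCAL_TO_KJ,
    bohr_per_angstrom = .BOHR_PER_ANGSTROM
  )
}
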