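# Chemical potentials and energy parameters. All potentials are expressed in
# kBT units; the electric potential Psi is in thermal-voltage units (RT/F).

#' Interaction-energy parameter set
#'
#' Bundles the mean-field interaction energies of the network/solvent mixture
#' with the chain length and site density. The energies are dimensionless
#' (kBT units). The defaults produce a gel with no drive to swell when fully
#' crosslinked (interaction parameter `I(alpha = 1) = 0`) and a strong drive
#' when uncrosslinked (`I(alpha = 0) = eps1 = -45`); this anchoring is
#' self-checked at construction.
#'
#' @param eps1,eps2,eps3,eps4 Interaction energies (kBT). `eps4` is an
#'   additive constant with no dynamical effect.
#' @param N Monomers per mucin chain (integer, >= 1).
#' @param z_tilde Site density per network volume (M); enters the network
#'   potential through the electrostatic term.
#' @param c_water Molarity of water (55.5 M), the reference for ionic number
#'   ratios.
#' @return A list of class `gel_energies`.
#' @export
interaction_energies <- function(eps1 = -45, eps2 = 25, eps3 = -0.5,
                                 eps4 = 0, N = 6, z_tilde = 0.1,
                                 c_water = 55.5) {
  if (N < 1) abort("N must be >= 1")
  if (c_water <= 0) abort("c_water must be positive")
  en <- structure(
    list(eps1 = eps1, eps2 = eps2, eps3 = eps3, eps4 = eps4, N = N,
         z_tilde = z_tilde, c_water = c_water),
    class = "gel_energies"
  )
  if (eps1 == -45 && eps2 == 25 && N == 6) {
    stopifnot(interaction_parameter(1, en) == 0,
              interaction_parameter(0, en) == -45)
  }
  en
}

#' Total ionic molality
#'
#' Sum of the per-ion number ratios `phi_j = c_j / c_water`; the osmotic
#' strength that enters the solvent and ion potentials.
#'
#' @param c_Na,c_Ca,c_Cl Dissolved concentrations (M per solvent volume).
#' @param c_water Molarity of water (M).
#' @return `sigma_I`, dimensionless.
#' @export
ionic_molality <- function(c_Na = 0, c_Ca = 0, c_Cl = 0, c_water = 55.5) {
  (c_Na + c_Ca + c_Cl) / c_water
}

#' Crosslink-dependent interaction parameter
#'
#' The coefficient of the short-range mixing energy, analogous to a Flory
#' interaction parameter but dependent on the local crosslink fraction:
#' `I = 6 * (eps1 + eps2) - 2 * (1 - 1/N) * eps1 - eps1 * alpha`. `I` is
#' affine in `alpha`; negative values drive swelling.
#'
#' @param alpha Crosslink fraction in `[0, 1]` (vectorized).
#' @param energies A [interaction_energies()] object.
#' @param tol Tolerance on the `alpha` domain check.
#' @return `I` (kBT units).
#' @export
interaction_parameter <- function(alpha, energies, tol = 1e-8) {
  if (any(alpha < -tol | alpha > 1 + tol)) {
    abort("alpha must lie in [0, 1]")
  }
  e <- energies
  6 * (e$eps1 + e$eps2) - 2 * (1 - 1 / e$N) * e$eps1 - e$eps1 * alpha
}

#' Network standard free energy
#'
#' The crosslink-dependent "standard free energy" of the network phase,
#' `mu_n0 = -3 * (eps3 + eps4) * (1 - 1/N) + (alpha / 2) * eps3`. Only its
#' gradient acts in the force balance, so only the `alpha`-dependent term has
#' dynamical consequence.
#'
#' @inheritParams interaction_parameter
#' @return `mu_n0` (kBT units).
#' @export
network_standard_energy <- function(alpha, energies) {
  e <- energies
  -3 * (e$eps3 + e$eps4) * (1 - 1 / e$N) + (alpha / 2) * e$eps3
}

#' Solvent chemical potential
#'
#' `mu_s = ln(theta_s) + (1 - 1/N) * theta_n - sigma_I + (I/2) * theta_n^2
#'  + mu_s0`, in kBT units. The entropic terms capture the osmotic pressure
#' acting on the solvent; the `I` term is the short-range mixing energy.
#'
#' @param theta_n Network volume fraction (vectorized); `theta_s = 1 - theta_n`
#'   must be positive.
#' @param sigma_I Total ionic molality, from [ionic_molality()].
#' @param I Interaction parameter, from [interaction_parameter()].
#' @param energies A [interaction_energies()] object.
#' @param mu_s0 Constant solvent standard free energy (default 0; it has no
#'   effect on dynamics).
#' @return `mu_s` (kBT units).
#' @export
solvent_potential <- function(theta_n, sigma_I, I, energies, mu_s0 = 0) {
  theta_s <- 1 - theta_n
  if (any(theta_s <= 0)) abort("theta_s must be positive (theta_n < 1)")
  log(theta_s) + (1 - 1 / energies$N) * theta_n - sigma_I +
    (I / 2) * theta_n^2 + mu_s0
}

#' Network chemical potential
#'
#' `mu_n = (1/N) * ln(theta_n) + (1/N - 1) * theta_s + (I/2) * theta_s^2
#'  + mu_n0 - z_tilde * Psi`, in kBT units. The last term is the electrostatic
#' potential acting on the negatively charged network.
#'
#' @inheritParams solvent_potential
#' @param mu_n0 Standard free energy from [network_standard_energy()].
#' @param Psi Electric potential (thermal-voltage units).
#' @return `mu_n` (kBT units).
#' @export
network_potential <- function(theta_n, I, mu_n0, Psi, energies) {
  if (any(theta_n <= 0)) abort("theta_n must be positive")
  theta_s <- 1 - theta_n
  (1 / energies$N) * log(theta_n) + (1 / energies$N - 1) * theta_s +
    (I / 2) * theta_s^2 + mu_n0 - energies$z_tilde * Psi
}

#' Dissolved-ion chemical potential
#'
#' `mu_j = ln(phi_j) + 1 - 2 * sigma_I + z_j * Psi` in kBT units, where
#' `phi_j = c_j / c_water`. Valid in the dilute-ion limit.
#'
#' @param phi_j Ion number ratio `c_j / c_water` (must be positive).
#' @param sigma_I Total ionic molality.
#' @param z_j Valence.
#' @param Psi Electric potential (thermal-voltage units).
#' @return `mu_j` (kBT units).
#' @export
ion_potential <- function(phi_j, sigma_I, z_j, Psi) {
  if (any(phi_j <= 0)) abort("phi_j must be positive")
  log(phi_j) + 1 - 2 * sigma_I + z_j * Psi
}
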