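#' Ion species table
#'
#' Builds the table of per-species constants used throughout the model:
#' valence, diffusivity, and the mass-action binding/unbinding rates of each
#' cation with the negatively charged network sites. Chloride is the anion and
#' does not bind. Diffusivities are stored in um^2/s (1e-5 cm^2/s = 1e3 um^2/s);
#' binding rates are in 1/(M s), unbinding rates in 1/s, so the dissociation
#' constant `K = k_off / k_on` is in molar.
#'
#' @param k_Na_on,k_Na_off Sodium binding/unbinding rates (1/(M s), 1/s).
#' @param k_Ca_on,k_Ca_off Calcium binding/unbinding rates (1/(M s), 1/s).
#' @param D_Na,D_Ca,D_Cl Diffusivities in um^2/s. The default corresponds to
#'   2.5e-5 cm^2/s for all three species.
#'
#' @return A tibble with one row per species (`Na`, `Ca`, `Cl`) and columns
#'   `name`, `z`, `D`, `k_on`, `k_off`, `K`.
#' @examples
#' ion_set(5e6, 5e2, 1e6, 1e3)
#' @export
ion_set <- function(k_Na_on, k_Na_off, k_Ca_on, k_Ca_off,
                    D_Na = 2.5e3, D_Ca = 2.5e3, D_Cl = 2.5e3) {
  if (any(c(D_Na, D_Ca, D_Cl) <= 0)) abort("diffusivities must be positive")
  if (any(c(k_Na_on, k_Na_off, k_Ca_on, k_Ca_off) < 0)) {
    abort("rate constants must be non-negative")
  }
  if ((k_Na_on > 0) != (k_Na_off > 0) || (k_Ca_on > 0) != (k_Ca_off > 0)) {
    abort("binding requires both k_on > 0 and k_off > 0 (or both zero)")
  }
  ions <- tibble(
    name  = c("Na", "Ca", "Cl"),
    z     = c(1, 2, -1),
    D     = c(D_Na, D_Ca, D_Cl),
    k_on  = c(k_Na_on, k_Ca_on, 0),
    k_off = c(k_Na_off, k_Ca_off, 0)
  )
  ions$K <- ifelse(ions$k_on > 0, ions$k_off / ions$k_on, Inf)
  ions
}

# Fast scalar view of an ion table for inner loops.
ion_constants <- function(ions) {
  i <- function(nm) which(ions$name == nm)
  list(
    D_Na = ions$D[i("Na")], D_Ca = ions$D[i("Ca")], D_Cl = ions$D[i("Cl")],
    k_Na_on = ions$k_on[i("Na")], k_Na_off = ions$k_off[i("Na")],
    k_Ca_on = ions$k_on[i("Ca")], k_Ca_off = ions$k_off[i("Ca")],
    K_Na = ions$K[i("Na")], K_Ca = ions$K[i("Ca")]
  )
}
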