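#' Energy convention for affinity/free-energy conversion
#'
#' Bundles the gas constant, temperature and standard concentration used to
#' interconvert dissociation constants and binding free energies via
#' \eqn{\Delta G = RT \ln(K_D / c^0)}. Tighter binding is more negative.
#' The default corresponds to experiments at 25 degrees C, giving
#' RT = 0.59248 kcal/mol.
#'
#' @param temperature_K temperature in Kelvin (default 298.15).
#' @param gas_constant gas constant in kcal mol^-1 K^-1 (default 1.9872e-3).
#' @param standard_concentration standard state in molar (default 1).
#' @return An object of class `energy_convention` with fields `R`, `T`, `RT`
#'   and `standard_concentration`.
#' @examples
#' conv <- energy_convention()
#' conv$RT
#' @export
energy_convention <- function(temperature_K = 298.15,
                              gas_constant = 1.9872e-3,
                              standard_concentration = 1) {
  stopifnot(temperature_K > 0, gas_constant > 0, standard_concentration > 0)
  structure(
    list(R = gas_constant, T = temperature_K,
         RT = gas_constant * temperature_K,
         standard_concentration = standard_concentration),
    class = "energy_convention"
  )
}

#' @export
print.energy_convention <- function(x, ...) {
  cat(sprintf("energy_convention: T = %.2f K, RT = %.5f kcal/mol\n", x$T, x$RT))
  invisible(x)
}

#' Convert a dissociation constant to a binding free energy
#'
#' \eqn{\Delta G = RT \ln(K_D / c^0)}; a K_D of 2.32 uM corresponds to
#' about -7.69 kcal/mol at 25 degrees C.
#'
#' @param kd_M dissociation constant in molar; must be positive.
#' @param convention an [energy_convention()].
#' @return Free energy in kcal/mol.
#' @export
kd_to_dg <- function(kd_M, convention = energy_convention()) {
  if (any(!is.finite(kd_M)) || any(kd_M <= 0)) {
    stop("kd_M must be positive and finite")
  }
  convention$RT * log(kd_M / convention$standard_concentration)
}

#' Convert a binding free energy to a dissociation constant
#'
#' Inverse of [kd_to_dg()]: \eqn{K_D = c^0 e^{\Delta G / RT}}.
#'
#' @param dg free energy in kcal/mol.
#' @param convention an [energy_convention()].
#' @return Dissociation constant in molar.
#' @export
dg_to_kd <- function(dg, convention = energy_convention()) {
  convention$standard_concentration * exp(dg / convention$RT)
}

#' Measurability limit of a titration
#'
#' The weakest affinity quantifiable from a titration reaching `p_max` is the
#' K_D at which `min_fraction_bound` of the RNA is bound at that
#' concentration: \eqn{K_D^{lim} = p_{max}(1 - \theta)/\theta}. With the
#' default 409.6 nM ceiling and a 15% minimum bound fraction this gives
#' roughly 2.3 uM, i.e. -7.69 kcal/mol.
#'
#' @param p_max highest protein concentration in nM.
#' @param min_fraction_bound minimum detectable fraction bound, in (0, 1).
#' @param convention an [energy_convention()].
#' @return List with `kd_limit_nM` and `dg_limit` (kcal/mol).
#' @export
detection_limit <- function(p_max = 409.6, min_fraction_bound = 0.15,
                            convention = energy_convention()) {
  stopifnot(p_max > 0)
  if (min_fraction_bound <= 0 || min_fraction_bound >= 1) {
    stop("min_fraction_bound must lie strictly between 0 and 1")
  }
  kd_nM <- p_max * (1 - min_fraction_bound) / min_fraction_bound
  list(kd_limit_nM = kd_nM, dg_limit = kd_to_dg(kd_nM * 1e-9, convention))
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so library functions never perturb user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
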