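#' Physical constants used throughout the package
#'
#' Internal units are Angstrom (length), eV (energy), amu (mass) and Kelvin
#' (temperature). All unit conversions funnel through this single list so that
#' every module shares one source of truth.
#'
#' @format A named list:
#' \describe{
#'   \item{k_B}{Boltzmann constant, eV/K.}
#'   \item{hbar}{Reduced Planck constant, eV s.}
#'   \item{eV_kJmol}{kJ/mol per eV.}
#'   \item{coulomb}{Coulomb prefactor e^2/(4 pi eps0), eV Angstrom.}
#'   \item{amu_kg, eV_J}{SI conversions.}
#'   \item{freq_factor}{rad/s per sqrt(eV / (amu Angstrom^2)); converts
#'     mass-weighted Hessian eigenvalues to angular frequencies.}
#'   \item{u_gram}{Atomic mass unit in grams (for g/cm^3 densities).}
#' }
#' @export
csp_constants <- list(
  k_B        = 8.617333262e-5,
  hbar       = 6.582119569e-16,
  eV_kJmol   = 96.48533,
  coulomb    = 14.399645478425668,   # e^2/(4*pi*eps0) in eV*Angstrom
  amu_kg     = 1.66053906660e-27,
  eV_J       = 1.602176634e-19,
  freq_factor = sqrt(1.602176634e-19 / (1.66053906660e-27 * 1e-20)),
  u_gram     = 1.66053906660e-24
)

# Element data: masses (amu), covalent radii and van der Waals radii (Angstrom).
# Bondi/Cambridge-style values; one packaged table used consistently.
.element_table <- local({
  tab <- rbind(
    #        mass      r_cov  r_vdw
    H  = c(  1.008,    0.31,  1.20),
    He = c(  4.0026,   0.28,  1.40),
    Li = c(  6.94,     1.28,  1.82),
    C  = c( 12.011,    0.76,  1.70),
    N  = c( 14.007,    0.71,  1.55),
    O  = c( 15.999,    0.66,  1.52),
    F  = c( 18.998,    0.57,  1.47),
    Ne = c( 20.180,    0.58,  1.54),
    Na = c( 22.990,    1.66,  2.27),
    Mg = c( 24.305,    1.41,  1.73),
    Si = c( 28.085,    1.11,  2.10),
    P  = c( 30.974,    1.07,  1.80),
    S  = c( 32.06,     1.05,  1.80),
    Cl = c( 35.45,     1.02,  1.75),
    Ar = c( 39.948,    1.06,  1.88),
    K  = c( 39.098,    2.03,  2.75),
    Ca = c( 40.078,    1.76,  2.31),
    Br = c( 79.904,    1.20,  1.85),
    Kr = c( 83.798,    1.16,  2.02),
    I  = c(126.904,    1.39,  1.98),
    Xe = c(131.293,    1.40,  2.16),
    Cs = c(132.905,    2.44,  3.43)
  )
  colnames(tab) <- c("mass", "r_cov", "r_vdw")
  tab
})

#' Look up element properties
#'
#' @param symbols Character vector of element symbols.
#' @return A data.frame with columns `symbol`, `mass` (amu), `r_cov` and
#'   `r_vdw` (Angstrom), one row per input symbol.
#' @examples
#' element_spec(c("C", "H", "O"))
#' @export
element_spec <- function(symbols) {
  bad <- setdiff(unique(symbols), rownames(.element_table))
  if (length(bad) > 0) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  m <- .element_table[symbols, , drop = FALSE]
  data.frame(symbol = symbols, mass = m[, "mass"], r_cov = m[, "r_cov"],
             r_vdw = m[, "r_vdw"], row.names = NULL)
}

#' @rdname element_spec
#' @export
supported_elements <- function() rownames(.element_table)
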