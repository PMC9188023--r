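#' Standard DEB parameter set for one species
#'
#' Constructs and validates a parameter record of the standard Dynamic Energy
#' Budget (DEB) model. All rates and energies are understood at the reference
#' temperature (20 degrees C, see [chemical_constants()]); lengths are
#' structural (volumetric) lengths in cm.
#'
#' @param species_id character identifier, unique within a collection.
#' @param p_Am surface-area-specific maximum assimilation rate (J d^-1 cm^-2).
#' @param v energy conductance (cm d^-1).
#' @param kappa allocation fraction to soma, in (0, 1).
#' @param p_M volume-specific somatic maintenance rate (J d^-1 cm^-3).
#' @param k_J maturity maintenance rate coefficient (d^-1).
#' @param E_G volume-specific cost of structure (J cm^-3).
#' @param E_Hb,E_Hp maturity thresholds at birth and puberty (J), `E_Hb < E_Hp`.
#' @param h_a Weibull aging acceleration (d^-2).
#' @param s_G Gompertz stress coefficient (dimensionless).
#' @param kappa_R reproduction efficiency, in (0, 1].
#' @param T_A Arrhenius temperature (K).
#' @param f scaled functional response in (0, 1]; 1 means abundant food.
#' @param taxon,sub_taxon taxonomic labels used by the comparative module.
#'
#' @return An object of class `"deb_params"` (a named list).
#' @seealso [compound_parameters()], [deb_life_history()]
#' @examples
#' p <- deb_params("example", p_Am = 500, v = 0.05, kappa = 0.8,
#'                 p_M = 20, k_J = 0.002, E_G = 7800,
#'                 E_Hb = 1e3, E_Hp = 1e5, h_a = 1e-9, s_G = 1e-4)
#' compound_parameters(p)
#' @export
deb_params <- function(species_id, p_Am, v, kappa, p_M, k_J, E_G,
                       E_Hb, E_Hp, h_a, s_G,
                       kappa_R = 0.95, T_A = 8000, f = 1,
                       taxon = NA_character_, sub_taxon = NA_character_) {
  p <- structure(list(
    species_id = as.character(species_id),
    taxon = as.character(taxon), sub_taxon = as.character(sub_taxon),
    T_A = T_A, p_Am = p_Am, v = v, kappa = kappa, kappa_R = kappa_R,
    p_M = p_M, k_J = k_J, E_G = E_G, E_Hb = E_Hb, E_Hp = E_Hp,
    h_a = h_a, s_G = s_G, f = f), class = "deb_params")
  validate_deb_params(p)
  p
}

#' Validate a DEB parameter set
#'
#' Checks positivity and ordering constraints of a [deb_params()] record and
#' stops with an informative error naming the offending field.
#'
#' @param p a `"deb_params"` object or a named list with the same fields.
#' @return `p`, invisibly, if valid.
#' @export
validate_deb_params <- function(p) {
  chk_pos <- function(field) {
    x <- p[[field]]
    if (is.null(x) || !is.finite(x) || x <= 0)
      stop("invalid parameter '", field, "': must be a finite positive number",
           call. = FALSE)
  }
  for (field in c("T_A", "p_Am", "v", "kappa", "kappa_R", "p_M", "k_J",
                  "E_G", "E_Hb", "E_Hp", "h_a", "f")) {
    if (field %in% c("k_J", "s_G")) next
    chk_pos(field)
  }
  # k_J = 0 (no maturity maintenance) and s_G = 0 are admissible limits
  for (field in c("k_J", "s_G", "h_a")) {
    x <- p[[field]]
    if (!is.finite(x) || x < 0)
      stop("invalid parameter '", field, "': must be finite and >= 0",
           call. = FALSE)
  }
  if (p$kappa >= 1)
    stop("invalid parameter 'kappa': must lie in (0, 1)", call. = FALSE)
  if (p$kappa_R > 1)
    stop("invalid parameter 'kappa_R': must lie in (0, 1]", call. = FALSE)
  if (p$f > 1)
    stop("invalid parameter 'f': must lie in (0, 1]", call. = FALSE)
  if (p$E_Hb >= p$E_Hp)
    stop("invalid parameter 'E_Hb': must be smaller than E_Hp", call. = FALSE)
  invisible(p)
}

#' @export
print.deb_params <- function(x, ...) {
  cat("Standard DEB parameter set:", x$species_id,
      if (!is.na(x$taxon)) paste0("(", x$taxon, ")"), "\n")
  num <- x[!(names(x) %in% c("species_id", "taxon", "sub_taxon"))]
  print(unlist(num))
  invisible(x)
}

#' Chemical and conversion constants
#'
#' Composition constants used to convert between energies, masses and gas
#' fluxes: specific densities of structure, molar masses and chemical
#' potentials of reserve and structure, the oxycaloric coefficient, and the
#' reference temperature (fixed at 20 degrees C = 293.15 K) at which all
#' traits are reported.
#'
#' @param d_Vw wet specific density of structure (g cm^-3).
#' @param d_Vd dry specific density of structure (g cm^-3).
#' @param w_E,w_V molar masses of reserve and structure (g mol^-1).
#' @param mu_E,mu_V chemical potentials of reserve and structure (J mol^-1).
#' @param mu_O2 oxycaloric coefficient: J dissipated per mol O2 (J mol^-1).
#' @return An object of class `"deb_constants"`.
#' @export
chemical_constants <- function(d_Vw = 1.0, d_Vd = 0.3, w_E = 23.9,
                               w_V = 23.9, mu_E = 5.5e5, mu_V = 5.0e5,
                               mu_O2 = 4.48e5) {
  cc <- list(d_Vw = d_Vw, d_Vd = d_Vd, w_E = w_E, w_V = w_V,
             mu_E = mu_E, mu_V = mu_V, mu_O2 = mu_O2, T_ref = 293.15)
  if (any(!vapply(cc, function(x) is.finite(x) && x > 0, logical(1))))
    stop("all chemical constants must be finite and positive", call. = FALSE)
  structure(cc, class = "deb_constants")
}

#' Compound DEB parameters
#'
#' Derives the compound parameters of the standard DEB model from the primary
#' ones: maximum reserve capacity `E_m = p_Am / v`, energy investment ratio
#' `g = E_G / (kappa * E_m)`, somatic maintenance rate coefficient
#' `k_M = p_M / E_G`, maximum structural length `L_m = kappa * p_Am / p_M`
#' (equivalently `v / (k_M * g)`), the reserve contribution to wet weight
#' `omega = E_m * w_E / (d_Vw * mu_E)`, and the fraction of growth energy
#' fixed in structure `kappa_G = mu_V * d_Vd / (w_V * E_G)`.
#'
#' @param p a [deb_params()] object.
#' @param const a [chemical_constants()] object.
#' @return An object of class `"deb_compound"` with fields `E_m`, `g`, `k_M`,
#'   `L_m`, `omega`, `kappa_G`.
#' @export
compound_parameters <- function(p, const = chemical_constants()) {
  validate_deb_params(p)
  E_m <- p$p_Am / p$v
  g <- p$E_G / (p$kappa * E_m)
  k_M <- p$p_M / p$E_G
  L_m <- p$kappa * p$p_Am / p$p_M
  stopifnot(abs(L_m - p$v / (k_M * g)) <= 1e-12 * L_m)
  omega <- E_m * const$w_E / (const$d_Vw * const$mu_E)
  kappa_G <- const$mu_V * (const$d_Vd / const$w_V) / p$E_G
  if (kappa_G >= 1)
    stop("invalid parameter 'E_G': implies kappa_G >= 1 (cheaper to build ",
         "structure than its own combustion energy)", call. = FALSE)
  structure(list(E_m = E_m, g = g, k_M = k_M, L_m = L_m,
                 omega = omega, kappa_G = kappa_G),
            class = "deb_compound")
}

#' Arrhenius temperature correction factor
#'
#' Physiological rates measured at the reference temperature `T_ref` are
#' multiplied by `exp(T_A / T_ref - T_A / T)` to obtain rates at body
#' temperature `T`; times are divided by the same factor.
#'
#' @param T_K body temperature (K).
#' @param T_A Arrhenius temperature (K).
#' @param T_ref reference temperature (K), default 293.15 K (20 degrees C).
#' @return The dimensionless correction factor (1 at `T_K = T_ref`).
#' @export
arrhenius_factor <- function(T_K, T_A, T_ref = 293.15) {
  if (any(T_K <= 0) || T_ref <= 0)
    stop("temperatures must be positive (K)", call. = FALSE)
  if (any(T_A < 0)) stop("T_A must be >= 0", call. = FALSE)
  exp(T_A / T_ref - T_A / T_K)
}

#' Energy fluxes (powers) of the standard DEB model
#'
#' Evaluates the six powers at an instantaneous state: assimilation
#' `p_A = f * p_Am * L^2` (zero before birth, when the embryo does not feed),
#' mobilization `p_C = E * (v / L) * (g + L / L_m) / (e + g)` with reserve
#' density `e = E / (L^3 * E_m)`, somatic maintenance `p_S = p_M * L^3`,
#' maturity maintenance `p_J = k_J * E_H`, growth `p_G = kappa * p_C - p_S`
#' and maturation/reproduction `p_R = (1 - kappa) * p_C - p_J`. The kappa-rule
#' identities `kappa * p_C = p_S + p_G` and `(1 - kappa) * p_C = p_J + p_R`
#' hold by construction.
#'
#' @param p a [deb_params()] object.
#' @param L structural length (cm).
#' @param E reserve energy (J).
#' @param E_H maturity (J).
#' @param f scaled functional response (ignored before birth).
#' @param const a [chemical_constants()] object.
#' @return Named list with `p_A`, `p_C`, `p_S`, `p_J`, `p_G`, `p_R` (J d^-1).
#' @export
power_fluxes <- function(p, L, E, E_H, f = p$f, const = chemical_constants()) {
  cp <- compound_parameters(p, const)
  e <- E / (L^3 * cp$E_m)
  p_C <- E * (p$v / L) * (cp$g + L / cp$L_m) / (e + cp$g)
  p_A <- if (E_H < p$E_Hb) 0 else f * p$p_Am * L^2
  p_S <- p$p_M * L^3
  p_J <- p$k_J * E_H
  list(p_A = p_A, p_C = p_C, p_S = p_S, p_J = p_J,
       p_G = p$kappa * p_C - p_S, p_R = (1 - p$kappa) * p_C - p_J)
}
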