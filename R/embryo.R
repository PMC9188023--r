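#' Initial reserve and state at birth (embryo shooting problem)
#'
#' Solves for the initial reserve `E_0` (the energy cost of an egg) such that
#' the reserve density at birth equals the mother's scaled functional response
#' `f` (the standard DEB maternal-effect closure). The embryo does not feed;
#' its dynamics are
#' \deqn{dE/da = -p_C, \quad dL/da = (v/3)\,(e - L/L_m)/(e + g), \quad
#'       dE_H/da = (1-\kappa)\,p_C - k_J E_H,}
#' with mobilization \eqn{p_C = E (v/L)(g + L/L_m)/(e + g)} and reserve
#' density \eqn{e = E/(L^3 E_m)}. Birth is the age `a_b` at which maturity
#' first reaches `E_Hb`; `E_0` is found by bracketing and bisection
#' (`uniroot`) on the shooting residual `e(a_b) - f`, to a relative tolerance
#' of 1e-8 on `E_0`.
#'
#' @param p a [deb_params()] object.
#' @param const a [chemical_constants()] object.
#' @param f scaled functional response of the mother (defaults to `p$f`).
#' @return A list of class `"deb_birth"` with `E_0` (J), `a_b` (d), `L_b`
#'   (cm), `e_b` (reserve density at birth, equals `f` within 1e-5 * f).
#' @section Non-viable parameter sets: if maturation stalls before `E_Hb`
#'   (maturity maintenance exceeds the maturation flux) for every initial
#'   reserve in the bracket, an error of class `"deb_nonviable"` is thrown
#'   carrying the maturity level `E_H_stall` reached at the stall.
#' @export
initial_reserve <- function(p, const = chemical_constants(), f = p$f) {
  validate_deb_params(p)
  cp <- compound_parameters(p, const)

  # First-guess egg cost: structure at birth if maintenance were free
  # (L_b^3 ~ kappa * E_Hb / ((1 - kappa) * E_G)), plus reserve at density f,
  # plus the maturity investment itself.
  Lb3_0 <- p$kappa * p$E_Hb / ((1 - p$kappa) * p$E_G)
  E0_guess <- Lb3_0 * (p$E_G / p$kappa + f * cp$E_m) + p$E_Hb / (1 - p$kappa)

  shoot <- function(E_0) embryo_birth_state(p, cp, E_0, f)

  # Geometric bracket growth until the shooting residual changes sign.
  lo <- hi <- E0_guess
  r_hi <- shoot(hi)
  n_try <- 0L
  while (r_hi$residual < 0 && n_try < 80L) {
    hi <- hi * 2; r_hi <- shoot(hi); n_try <- n_try + 1L
  }
  if (r_hi$residual < 0) {
    stop(deb_nonviable_condition(p, r_hi))
  }
  r_lo <- shoot(lo)
  n_try <- 0L
  while (r_lo$residual > 0 && n_try < 80L) {
    lo <- lo / 2; r_lo <- shoot(lo); n_try <- n_try + 1L
  }
  if (r_lo$residual > 0)
    stop("initial-reserve bracketing failed from below for '", p$species_id,
         "'", call. = FALSE)

  root <- stats::uniroot(function(E_0) shoot(E_0)$residual,
                         interval = c(lo, hi),
                         f.lower = r_lo$residual, f.upper = r_hi$residual,
                         tol = 1e-8 * hi, maxiter = 200L)
  sol <- shoot(root$root)
  if (!sol$born) stop(deb_nonviable_condition(p, sol))
  structure(list(E_0 = root$root, a_b = sol$a_b, L_b = sol$L_b,
                 e_b = sol$e_b, f = f),
            class = "deb_birth")
}

# Integrate the embryo ODE for a candidate E_0; birth detected by a root of
# E_H - E_Hb (lsodar dense-output root finding). Returns the birth state and
# the shooting residual e_b - f (negative if birth is never reached, so that
# bisection treats under-provisioned eggs correctly).
embryo_birth_state <- function(p, cp, E_0, f) {
  L0 <- 1e-5 * cp$L_m
  y0 <- c(E = E_0, L = L0, E_H = 0)
  pars <- list(v = p$v, g = cp$g, L_m = cp$L_m, E_m = cp$E_m,
               kappa = p$kappa, k_J = p$k_J, E_Hb = p$E_Hb)
  rhs <- function(a, y, pr) {
    e <- y[1] / (y[2]^3 * pr$E_m)
    p_C <- y[1] * (pr$v / y[2]) * (pr$g + y[2] / pr$L_m) / (e + pr$g)
    list(c(-p_C,
           (pr$v / 3) * (e - y[2] / pr$L_m) / (e + pr$g),
           (1 - pr$kappa) * p_C - pr$k_J * y[3]))
  }
  rootfun <- function(a, y, pr) {
    c(y[3] - pr$E_Hb,      # birth
      y[1] - 1e-12 * E_0)  # reserve exhaustion
  }
  # Incubation time scale: growth-limited plus maintenance-limited components.
  t_scale <- 3 * (1 + cp$g) * cp$L_m / (p$v * cp$g) + 3 / cp$k_M
  out <- deSolve::lsodar(y = y0, times = c(0, 50 * t_scale), func = rhs,
                         parms = pars, rootfunc = rootfun,
                         rtol = 1e-10, atol = c(1e-10 * E_0, 1e-12 * cp$L_m,
                                                1e-10 * p$E_Hb))
  last <- out[nrow(out), ]
  born <- is.finite(last[["E_H"]]) && last[["E_H"]] >= p$E_Hb * (1 - 1e-6)
  if (!born) {
    return(list(born = FALSE, residual = -f, E_H_stall = last[["E_H"]],
                a_b = NA_real_, L_b = NA_real_, e_b = NA_real_))
  }
  e_b <- last[["E"]] / (last[["L"]]^3 * cp$E_m)
  list(born = TRUE, residual = e_b - f, a_b = last[["time"]],
       L_b = last[["L"]], e_b = e_b, E_H_stall = NA_real_)
}

deb_nonviable_condition <- function(p, sol) {
  structure(
    class = c("deb_nonviable", "error", "condition"),
    list(message = paste0(
      "non-viable parameter set '", p$species_id,
      "': maturation stalls before E_Hb (stall maturity ",
      signif(sol$E_H_stall, 6), " J of ", signif(p$E_Hb, 6), " J)"),
      call = NULL, E_H_stall = sol$E_H_stall, species_id = p$species_id))
}
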