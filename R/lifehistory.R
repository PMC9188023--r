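#' Ultimate size at constant food
#'
#' At constant scaled functional response `f`, structural length approaches
#' `L_i = f * L_m` and wet weight (structure plus reserve at equilibrium
#' density, reproduction buffer excluded) approaches
#' `Ww_i = d_Vw * L_i^3 * (1 + f * omega)`.
#'
#' @inheritParams initial_reserve
#' @return List with `L_i` (cm) and `Ww_i` (g).
#' @export
ultimate_state <- function(p, const = chemical_constants(), f = p$f) {
  cp <- compound_parameters(p, const)
  L_i <- f * cp$L_m
  list(L_i = L_i, Ww_i = const$d_Vw * L_i^3 * (1 + f * cp$omega))
}

#' von Bertalanffy growth rate
#'
#' At constant food the post-birth growth curve of the standard DEB model is
#' von Bertalanffy, `L(a) = L_i - (L_i - L_b) exp(-r_B (a - a_b))` with
#' `r_B = k_M / (3 (1 + f / g))`.
#'
#' @inheritParams initial_reserve
#' @return `r_B` (d^-1).
#' @export
von_bertalanffy_rate <- function(p, const = chemical_constants(), f = p$f) {
  cp <- compound_parameters(p, const)
  cp$k_M / (3 * (1 + f / cp$g))
}

#' Wet weight at a given structural length
#'
#' `Ww = d_Vw * L^3 * (1 + f * omega)`: structure plus reserve at equilibrium
#' density `e = f`.
#'
#' @param L structural length (cm).
#' @inheritParams initial_reserve
#' @return Wet weight (g).
#' @export
wet_weight <- function(L, p, const = chemical_constants(), f = p$f) {
  cp <- compound_parameters(p, const)
  const$d_Vw * L^3 * (1 + f * cp$omega)
}

#' Age and length at puberty
#'
#' Integrates the post-birth maturity balance
#' `dE_H/da = (1 - kappa) p_C(a) - k_J E_H` along the closed-form von
#' Bertalanffy length trajectory (reserve density in equilibrium, `e = f`),
#' until maturity reaches `E_Hp`. With `k_J > 0` maturity approaches the
#' equilibrium `(1 - kappa) f E_m v L_i^2 / k_J`; if `E_Hp` is at or above
#' that ceiling, puberty is unreachable and the result is flagged as stalled
#' (`a_p` and `L_p` are `NA`).
#'
#' @param birth a `"deb_birth"` object from [initial_reserve()].
#' @inheritParams initial_reserve
#' @return List with `a_p` (d), `L_p` (cm) and logical `stalled`.
#' @export
grow_to_puberty <- function(p, birth, const = chemical_constants(), f = p$f) {
  cp <- compound_parameters(p, const)
  L_i <- f * cp$L_m
  r_B <- von_bertalanffy_rate(p, const, f)
  if (p$E_Hp <= p$E_Hb)  # degenerate threshold: puberty coincides with birth
    return(list(a_p = birth$a_b, L_p = birth$L_b, stalled = FALSE))

  mat_flux <- function(L) {  # (1 - kappa) * p_C at e = f
    (1 - p$kappa) * f * cp$E_m * p$v * L^2 * (cp$g + L / cp$L_m) / (f + cp$g)
  }
  if (p$k_J > 0 && p$E_Hp >= mat_flux(L_i) / p$k_J)
    return(list(a_p = NA_real_, L_p = NA_real_, stalled = TRUE))

  Lfun <- function(a) L_i - (L_i - birth$L_b) * exp(-r_B * (a - birth$a_b))
  rhs <- function(a, y, pr) list(mat_flux(Lfun(a)) - p$k_J * y[1])
  rootfun <- function(a, y, pr) y[1] - p$E_Hp
  # Time horizon: growth transient plus maturation at the ultimate-size flux.
  t_max <- birth$a_b + 30 / r_B + 5 * p$E_Hp / mat_flux(L_i) +
    if (p$k_J > 0) 10 / p$k_J else 0
  out <- deSolve::lsodar(y = c(E_H = p$E_Hb), times = c(birth$a_b, t_max),
                         func = rhs, parms = NULL, rootfunc = rootfun,
                         rtol = 1e-10, atol = 1e-10 * p$E_Hp)
  last <- out[nrow(out), ]
  if (last[["E_H"]] < p$E_Hp * (1 - 1e-6))
    return(list(a_p = NA_real_, L_p = NA_real_, stalled = TRUE))
  list(a_p = last[["time"]], L_p = Lfun(last[["time"]]), stalled = FALSE)
}

#' Maximum specific growth rate
#'
#' The specific structural-volume growth rate `3 (dL/da) / L` evaluated at the
#' age where absolute growth `dL^3/da` is maximal (at `L = 2/3 L_i`). For the
#' von Bertalanffy trajectory this equals `1.5 * r_B` exactly, independent of
#' `f`; `method = "analytic"` returns that value, `method = "trajectory"`
#' integrates the structure dynamics numerically, locates the argmax of
#' `dL^3/da` on the simulated trajectory and evaluates the rate there.
#'
#' @param birth optional `"deb_birth"` object (required for
#'   `method = "trajectory"`); defaults to [initial_reserve()] output.
#' @param method `"analytic"` or `"trajectory"`.
#' @inheritParams initial_reserve
#' @return `r_max` (d^-1).
#' @export
max_specific_growth <- function(p, const = chemical_constants(), f = p$f,
                                method = c("analytic", "trajectory"),
                                birth = NULL) {
  method <- match.arg(method)
  r_B <- von_bertalanffy_rate(p, const, f)
  if (method == "analytic") return(1.5 * r_B)
  cp <- compound_parameters(p, const)
  L_i <- f * cp$L_m
  if (is.null(birth)) birth <- initial_reserve(p, const, f)
  if (birth$L_b >= (2 / 3) * L_i)
    stop("trajectory method needs L_b < 2/3 L_i (growth already past its ",
         "inflection at birth)", call. = FALSE)
  # Simulate structure dynamics at e = f (no closed form used).
  rhs <- function(a, y, pr)
    list((p$v / 3) * (f - y[1] / cp$L_m) / (f + cp$g))
  times <- seq(birth$a_b, birth$a_b + 12 / r_B, length.out = 4001L)
  out <- deSolve::lsoda(y = c(L = birth$L_b), times = times, func = rhs,
                        parms = NULL, rtol = 1e-11, atol = 1e-12 * L_i)
  Lsp <- stats::splinefun(out[, "time"], out[, "L"], method = "natural")
  dL3 <- function(a) {
    L <- Lsp(a)
    3 * L^2 * (p$v / 3) * (f - L / cp$L_m) / (f + cp$g)
  }
  opt <- stats::optimize(dL3, range(times), maximum = TRUE,
                         tol = 1e-10 * diff(range(times)))
  L_star <- Lsp(opt$maximum)
  3 * ((p$v / 3) * (f - L_star / cp$L_m) / (f + cp$g)) / L_star
}

#' Reproduction rate at ultimate size
#'
#' At ultimate size the mobilization flux is `p_C = f E_m v L_i^2`; the flux
#' to reproduction, converted to eggs of cost `E_0` with efficiency
#' `kappa_R`, gives
#' `R_i = kappa_R * ((1 - kappa) f E_m v L_i^2 - k_J E_Hp) / E_0`
#' (continuous conversion of the reproduction buffer). A negative allocation
#' (maturity maintenance demand exceeding supply) yields `R_i = 0` with
#' `demand_bound = TRUE`.
#'
#' @param E_0 initial reserve per egg (J), from [initial_reserve()].
#' @inheritParams initial_reserve
#' @return List with `R_i` (d^-1) and logical `demand_bound`.
#' @export
reproduction_rate <- function(p, E_0, const = chemical_constants(), f = p$f) {
  cp <- compound_parameters(p, const)
  L_i <- f * cp$L_m
  alloc <- (1 - p$kappa) * f * cp$E_m * p$v * L_i^2 - p$k_J * p$E_Hp
  if (alloc < 0) return(list(R_i = 0, demand_bound = TRUE))
  list(R_i = p$kappa_R * alloc / E_0, demand_bound = FALSE)
}

#' Weight-specific respiration
#'
#' Dioxygen consumption per unit wet weight under the oxycaloric closure: the
#' dissipated power is assimilation minus the energy fixed in eggs and in new
#' structure, `p_resp = p_A - kappa_R * p_R - kappa_G * p_G`. At ultimate
#' size (the default) `p_G = 0` and `p_A = p_C`, so
#' `p_resp = p_S + p_J + (1 - kappa_R) * p_R`. Then
#' `jO2_spec = p_resp / (mu_O2 * Ww)` (mol O2 d^-1 g^-1).
#'
#' @param L structural length at which to evaluate (cm); default ultimate.
#' @param E_H maturity at that length (J); default `E_Hp` (adult).
#' @inheritParams initial_reserve
#' @return `jO2_spec` (mol O2 d^-1 g^-1).
#' @export
specific_respiration <- function(p, const = chemical_constants(), f = p$f,
                                 L = NULL, E_H = p$E_Hp) {
  cp <- compound_parameters(p, const)
  if (is.null(L)) L <- f * cp$L_m
  fl <- power_fluxes(p, L = L, E = f * cp$E_m * L^3, E_H = E_H,
                     f = f, const = const)
  p_resp <- fl$p_A - p$kappa_R * max(fl$p_R, 0) - cp$kappa_G * max(fl$p_G, 0)
  Ww <- const$d_Vw * L^3 * (1 + f * cp$omega)
  (p_resp / const$mu_O2) / Ww
}

#' Mean life span from Weibull-Gompertz aging
#'
#' Integrates the standard DEB aging module along the post-birth growth
#' trajectory (reserve density `e = f`):
#' \deqn{dq/da = (q (L/L_m)^3 s_G + h_a)\, e\, (v/L - r) - r q, \quad
#'       dh/da = q - r h, \quad dS/da = -h S,}
#' with `r = 3 (dL/da) / L`, starting at birth with `q = h = 0`, `S = 1`.
#' The mean life span is `a_m = a_b + integral of S` from birth, truncated
#' when `S < 1e-7` (the remaining tail, bounded by `S/h` at truncation, is
#' added as a correction). In the fully-grown, `s_G = 0` limit this reduces
#' to the Weibull form `S(t) = exp(-h_a f v t^3 / (6 L_i))`.
#'
#' @inheritParams grow_to_puberty
#' @return `a_m` (d), mean age at death.
#' @export
mean_life_span <- function(p, birth, const = chemical_constants(), f = p$f) {
  cp <- compound_parameters(p, const)
  L_i <- f * cp$L_m
  r_B <- von_bertalanffy_rate(p, const, f)
  a_b <- birth$a_b; L_b <- birth$L_b
  if (p$h_a <= 0)
    stop("mean_life_span requires h_a > 0", call. = FALSE)

  rhs <- function(a, y, pr) {
    L <- L_i - (L_i - L_b) * exp(-r_B * (a - a_b))
    dL <- r_B * (L_i - L)
    r <- 3 * dL / L
    q <- y[1]; h <- y[2]; S <- y[3]
    dq <- (q * (L / cp$L_m)^3 * p$s_G + p$h_a) * f * (p$v / L - r) - r * q
    list(c(dq, q - r * h, -h * S, S))
  }
  rootfun <- function(a, y, pr) y[3] - 1e-7
  t_w <- (6 * L_i / (p$h_a * f * p$v))^(1 / 3)  # Weibull time scale
  t_max <- a_b + 20 / r_B + 30 * t_w
  out <- deSolve::lsodar(y = c(q = 0, h = 0, S = 1, A = 0),
                         times = c(a_b, t_max), func = rhs, parms = NULL,
                         rootfunc = rootfun, rtol = 1e-9,
                         atol = c(1e-14, 1e-14, 1e-10, 1e-8 * t_w))
  last <- out[nrow(out), ]
  tail_corr <- if (last[["h"]] > 0) last[["S"]] / last[["h"]] else 0
  a_b + last[["A"]] + tail_corr
}

#' Supply stress
#'
#' Maturity maintenance times squared somatic maintenance divided by cubed
#' assimilation, evaluated at ultimate size:
#' `s_s = (k_J E_Hp) (p_M L_i^3)^2 / (f p_Am L_i^2)^3`. Ranges over
#' `[0, 4/27]` for parameter sets with nonnegative reproduction; the maximum
#' is attained at `kappa = 2/3` when maturity maintenance consumes the whole
#' non-somatic allocation.
#'
#' @inheritParams initial_reserve
#' @return `s_s` (dimensionless).
#' @export
supply_stress <- function(p, const = chemical_constants(), f = p$f) {
  cp <- compound_parameters(p, const)
  L_i <- f * cp$L_m
  (p$k_J * p$E_Hp) * (p$p_M * L_i^3)^2 / (f * p$p_Am * L_i^2)^3
}

#' Precociality coefficient
#'
#' Ratio of maturity at birth to maturity at puberty, `s_Hbp = E_Hb / E_Hp`,
#' in (0, 1]; small values mean relatively undeveloped neonates. It roughly
#' equals the ratio of wet weights at birth and puberty at abundant food.
#'
#' @inheritParams initial_reserve
#' @return `s_Hbp` (dimensionless).
#' @export
precociality <- function(p) {
  if (p$E_Hb > p$E_Hp)
    stop("invalid parameter 'E_Hb': must not exceed E_Hp", call. = FALSE)
  p$E_Hb / p$E_Hp
}

#' Full life history of one species
#'
#' Runs the whole trait derivation for one parameter set at the reference
#' temperature: embryo shooting ([initial_reserve()]), growth to puberty,
#' ultimate size, growth rates, reproduction, respiration, aging life span,
#' supply stress and precociality.
#'
#' @inheritParams initial_reserve
#' @return A list of class `"deb_life_history"` with fields `E_0`, `a_b`,
#'   `L_b`, `Ww_b`, `a_p`, `L_p`, `Ww_p`, `L_i`, `Ww_i`, `r_B`, `r_max`,
#'   `R_i`, `a_m`, `jO2_spec`, `s_s`, `s_Hbp`, and logical flags `stalled`
#'   and `demand_bound`. Traits downstream of a stalled puberty are `NA`.
#' @export
deb_life_history <- function(p, const = chemical_constants(), f = p$f) {
  birth <- initial_reserve(p, const, f)
  ult <- ultimate_state(p, const, f)
  pub <- grow_to_puberty(p, birth, const, f)
  r_B <- von_bertalanffy_rate(p, const, f)
  out <- list(
    E_0 = birth$E_0, a_b = birth$a_b, L_b = birth$L_b,
    Ww_b = wet_weight(birth$L_b, p, const, f),
    a_p = pub$a_p, L_p = pub$L_p,
    Ww_p = if (pub$stalled) NA_real_ else wet_weight(pub$L_p, p, const, f),
    L_i = ult$L_i, Ww_i = ult$Ww_i,
    r_B = r_B, r_max = 1.5 * r_B,
    a_m = mean_life_span(p, birth, const, f),
    s_s = supply_stress(p, const, f),
    s_Hbp = precociality(p),
    stalled = pub$stalled)
  if (pub$stalled) {
    out$R_i <- NA_real_; out$demand_bound <- NA
    out$jO2_spec <- NA_real_
  } else {
    rep <- reproduction_rate(p, birth$E_0, const, f)
    out$R_i <- rep$R_i; out$demand_bound <- rep$demand_bound
    out$jO2_spec <- specific_respiration(p, const, f)
  }
  structure(out, class = "deb_life_history")
}

#' @export
print.deb_life_history <- function(x, ...) {
  cat("DEB life history (reference temperature 20 C):\n")
  num <- x[!(names(x) %in% c("stalled", "demand_bound"))]
  print(unlist(num))
  if (isTRUE(x$stalled)) cat("  [maturation stalled: puberty unreachable]\n")
  if (isTRUE(x$demand_bound)) cat("  [demand-bound: reproduction rate 0]\n")
  invisible(x)
}
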