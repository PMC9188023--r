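test_that("post-birth growth follows the closed-form von Bertalanffy curve", {
  p <- base_params()
  cp <- compound_parameters(p)
  b <- initial_reserve(p)
  r_B <- von_bertalanffy_rate(p)
  L_i <- ultimate_state(p)$L_i
  # simulate structure dynamics at e = f and compare to the closed form
  rhs <- function(a, y, pr)
    list((p$v / 3) * (1 - y[1] / cp$L_m) / (1 + cp$g))
  times <- seq(b$a_b, b$a_b + 8 / r_B, length.out = 400L)
  sim <- deSolve::lsoda(c(L = b$L_b), times, rhs, NULL,
                        rtol = 1e-11, atol = 1e-12)
  closed <- L_i - (L_i - b$L_b) * exp(-r_B * (times - b$a_b))
  expect_lt(max(abs(sim[, "L"] - closed) / closed), 1e-6)
})

test_that("weak homeostasis: reserve density stays at f through growth", {
  p <- base_params(f = 0.8)
  cp <- compound_parameters(p)
  f <- p$f
  b <- initial_reserve(p)
  # full post-birth system with feeding switched on
  rhs <- function(a, y, pr) {
    E <- y[1]; L <- y[2]
    e <- E / (L^3 * cp$E_m)
    p_C <- E * (p$v / L) * (cp$g + L / cp$L_m) / (e + cp$g)
    list(c(f * p$p_Am * L^2 - p_C,
           (p$v / 3) * (e - L / cp$L_m) / (e + cp$g)))
  }
  times <- seq(b$a_b, b$a_b + 6 / von_bertalanffy_rate(p),
               length.out = 200L)
  y0 <- c(E = f * cp$E_m * b$L_b^3, L = b$L_b)
  sim <- deSolve::lsoda(y0, times, rhs, NULL, rtol = 1e-11, atol = 1e-12)
  e_traj <- sim[, "E"] / (sim[, "L"]^3 * cp$E_m)
  expect_lt(max(abs(e_traj - f)), 1e-7)
})

test_that("maximum specific growth is 1.5 x the von Bertalanffy rate,
           independent of food level", {
  p <- fixture_species()[[1]]
  for (f in c(1, 0.5)) {
    b <- initial_reserve(p, f = f)
    r_max <- max_specific_growth(p, f = f, method = "trajectory", birth = b)
    r_B <- von_bertalanffy_rate(p, f = f)
    expect_equal(r_max / r_B, 1.5, tolerance = 1e-5)
  }
})

test_that("absolute growth dL^3/da peaks at two-thirds of ultimate length", {
  p <- base_params()
  b <- initial_reserve(p)
  L_i <- ultimate_state(p)$L_i
  r_B <- von_bertalanffy_rate(p)
  # independent argmax of the analytic rate L^2 (L_i - L) over age
  g_abs <- function(a) {
    L <- L_i - (L_i - b$L_b) * exp(-r_B * (a - b$a_b))
    3 * L^2 * r_B * (L_i - L)
  }
  a_star <- stats::optimize(g_abs, c(b$a_b, b$a_b + 20 / r_B),
                            maximum = TRUE, tol = 1e-8)$maximum
  L_star <- L_i - (L_i - b$L_b) * exp(-r_B * (a_star - b$a_b))
  expect_equal(L_star, (2 / 3) * L_i, tolerance = 1e-5)
})

test_that("puberty age/length: near-degenerate threshold collapses to birth,
           solver matches the fixed-step oracle, stall is detected", {
  p <- fixture_species()[[1]]
  b <- initial_reserve(p)
  pub <- grow_to_puberty(p, b)
  orc <- oracle_a_p(p, b$a_b, b$L_b)
  expect_equal(pub$a_p, orc, tolerance = 1e-3)

  p_deg <- base_params(E_Hb = 2e3, E_Hp = 2e3 * (1 + 1e-9))
  b_deg <- initial_reserve(p_deg)
  pub_deg <- grow_to_puberty(p_deg, b_deg)
  expect_equal(pub_deg$a_p, b_deg$a_b, tolerance = 1e-4)
  expect_equal(pub_deg$L_p, b_deg$L_b, tolerance = 1e-4)

  # maturity maintenance demand at ultimate size exceeds supply -> stall
  p_st <- base_params(k_J = 0.02, E_Hb = 500, E_Hp = 4e5)
  cp <- compound_parameters(p_st)
  expect_gt(p_st$k_J * p_st$E_Hp,
            (1 - p_st$kappa) * cp$E_m * p_st$v * cp$L_m^2)
  b_st <- initial_reserve(p_st)
  expect_true(grow_to_puberty(p_st, b_st)$stalled)
})

test_that("ultimate size scales with f and reserve adds f*omega to weight", {
  p <- base_params()
  cp <- compound_parameters(p)
  expect_equal(ultimate_state(p, f = 1)$L_i, cp$L_m)
  expect_equal(ultimate_state(p, f = 0.5)$L_i, 0.5 * cp$L_m)
  u <- ultimate_state(p)
  expect_equal(u$Ww_i, u$L_i^3 * (1 + cp$omega))
})

test_that("reproduction rate: zero at the supply-demand boundary, linear in
           kappa_R, and equal to its closed form on the fixture", {
  p <- base_params()
  cp <- compound_parameters(p)
  L_i <- cp$L_m
  # boundary: k_J E_Hp exactly absorbs the non-somatic mobilization
  alloc <- (1 - p$kappa) * cp$E_m * p$v * L_i^2
  p_b <- base_params(k_J = alloc / p$E_Hp)
  r_b <- reproduction_rate(p_b, E_0 = 5e4)
  expect_equal(r_b$R_i, 0)
  # linearity in kappa_R
  r1 <- reproduction_rate(base_params(kappa_R = 0.4), E_0 = 5e4)
  r2 <- reproduction_rate(base_params(kappa_R = 0.8), E_0 = 5e4)
  expect_equal(r2$R_i, 2 * r1$R_i)
  # hand evaluation on the fixture species
  pf <- fixture_species()[[1]]
  cpf <- compound_parameters(pf)
  b <- initial_reserve(pf)
  hand <- pf$kappa_R *
    ((1 - pf$kappa) * cpf$E_m * pf$v * cpf$L_m^2 - pf$k_J * pf$E_Hp) / b$E_0
  expect_equal(reproduction_rate(pf, b$E_0)$R_i, hand)
})

test_that("respiration reduces to maintenance when reproduction overhead
           vanishes, and is size-invariant under covariation scaling", {
  p <- base_params(kappa_R = 1)
  cp <- compound_parameters(p)
  L_i <- cp$L_m
  Ww <- L_i^3 * (1 + cp$omega)
  cc <- chemical_constants()
  expect_equal(specific_respiration(p),
               (p$p_M * L_i^3 + p$k_J * p$E_Hp) / cc$mu_O2 / Ww)
  # zoom-doubled species with E_m held fixed (reserve weight negligible):
  # all powers and weight scale together, specific respiration unchanged
  z <- 2
  p_small <- base_params(p_Am = 40, v = 0.06, E_Hb = 100, E_Hp = 1e4)
  p_big <- base_params(p_Am = 40 * z, v = 0.06 * z,
                       E_Hb = 100 * z^1.7454, E_Hp = 1e4 * z^3)
  expect_equal(specific_respiration(p_big), specific_respiration(p_small),
               tolerance = 0.01)
})

test_that("aging: ODE life span matches the fully-grown Weibull closed form
           and its h_a cube-root scaling; the fixed-step oracle agrees on a
           growing individual", {
  p <- base_params(s_G = 0, h_a = 1e-9)
  L_i <- ultimate_state(p)$L_i
  start_grown <- list(a_b = 0, L_b = L_i * (1 - 1e-12))
  closed <- gamma(4 / 3) * (6 * L_i / (p$h_a * p$f * p$v))^(1 / 3)
  expect_equal(mean_life_span(p, start_grown), closed, tolerance = 5e-3)

  p_fast <- base_params(s_G = 0, h_a = 1e-6)
  expect_equal(mean_life_span(p_fast, start_grown) / closed, 0.1,
               tolerance = 5e-3)

  pf <- fixture_species()[[5]]  # short-lived species keeps the oracle cheap
  b <- initial_reserve(pf)
  expect_equal(mean_life_span(pf, b), oracle_a_m(pf, b$a_b, b$L_b),
               tolerance = 1e-3)
})

test_that("supply stress vanishes without maturity maintenance and is capped
           at 4/27 at the demand extreme", {
  expect_equal(supply_stress(base_params(k_J = 0)), 0)
  # demand extreme: p_J = (1 - kappa) p_A at ultimate size -> s_s =
  # kappa^2 (1 - kappa); brute-force grid over kappa
  s_at <- function(kappa) {
    L_i <- kappa * 200 / 18
    E_Hp <- (1 - kappa) * 200 * L_i^2 / 0.002
    p <- base_params(kappa = kappa, E_Hp = E_Hp, E_Hb = E_Hp / 100)
    supply_stress(p)
  }
  kappas <- seq(0.05, 0.95, by = 0.005)
  s_vals <- vapply(kappas, s_at, numeric(1))
  expect_equal(s_vals, kappas^2 * (1 - kappas), tolerance = 1e-10)
  expect_equal(max(s_vals), 4 / 27, tolerance = 1e-3)
  expect_equal(kappas[which.max(s_vals)], 2 / 3, tolerance = 5e-3)
})

test_that("precociality is the maturity ratio and stays in (0, 1]", {
  expect_equal(precociality(base_params(E_Hb = 1e3, E_Hp = 1e6)), 1e-3)
  tab <- fixture_traits()
  expect_true(all(tab$s_Hbp > 0 & tab$s_Hbp <= 1))
  # diagnostic: same order of magnitude as the weight ratio at birth/puberty
  expect_true(all(abs(log10(tab$s_Hbp / (tab$Ww_b / tab$Ww_p))) < 1))
})
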