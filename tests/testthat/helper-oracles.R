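# Independent numerical oracles: fixed-step classical RK4 integration and
# bisection, written without reference to the package's adaptive solvers.

rk4_integrate <- function(rhs, y0, t0, t1, n_steps) {
  h <- (t1 - t0) / n_steps
  out <- matrix(NA_real_, n_steps + 1L, length(y0) + 1L)
  out[1L, ] <- c(t0, y0)
  y <- y0; t <- t0
  for (i in seq_len(n_steps)) {
    k1 <- rhs(t, y)
    k2 <- rhs(t + h / 2, y + h / 2 * k1)
    k3 <- rhs(t + h / 2, y + h / 2 * k2)
    k4 <- rhs(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t0 + i * h
    out[i + 1L, ] <- c(t, y)
  }
  out
}

# Embryo dynamics for the oracle (same model, independent integration).
oracle_embryo_rhs <- function(p, cp) {
  function(t, y) {
    E <- y[1]; L <- y[2]; EH <- y[3]
    e <- E / (L^3 * cp$E_m)
    pC <- E * (p$v / L) * (cp$g + L / cp$L_m) / (e + cp$g)
    c(-pC,
      (p$v / 3) * (e - L / cp$L_m) / (e + cp$g),
      (1 - p$kappa) * pC - p$k_J * EH)
  }
}

# Integrate an embryo at fixed step until maturity crosses E_Hb; linear
# interpolation of the crossing. Returns NULL if birth is not reached.
oracle_embryo_birth <- function(p, E_0, f, n_steps = 8000L,
                                const = chemical_constants()) {
  cp <- compound_parameters(p, const)
  t_scale <- 3 * (1 + cp$g) * cp$L_m / (p$v * cp$g) + 3 / cp$k_M
  tr <- rk4_integrate(oracle_embryo_rhs(p, cp), c(E_0, 1e-5 * cp$L_m, 0),
                      0, 10 * t_scale, n_steps)
  cross <- which(tr[, 4L] >= p$E_Hb)
  if (!length(cross)) return(NULL)
  i <- cross[1L]
  if (i == 1L) return(NULL)
  w <- (p$E_Hb - tr[i - 1L, 4L]) / (tr[i, 4L] - tr[i - 1L, 4L])
  st <- (1 - w) * tr[i - 1L, ] + w * tr[i, ]
  list(a_b = st[1L], E_b = st[2L], L_b = st[3L],
       e_b = st[2L] / (st[3L]^3 * cp$E_m))
}

# Bisection on E_0 for the shooting residual e_b - f.
oracle_E0 <- function(p, f = 1, n_steps = 8000L,
                      const = chemical_constants()) {
  resid <- function(E_0) {
    b <- oracle_embryo_birth(p, E_0, f, n_steps, const)
    if (is.null(b)) -f else b$e_b - f
  }
  cp <- compound_parameters(p, const)
  Lb3 <- p$kappa * p$E_Hb / ((1 - p$kappa) * p$E_G)
  lo <- hi <- Lb3 * (p$E_G / p$kappa + f * cp$E_m) + p$E_Hb / (1 - p$kappa)
  while (resid(hi) < 0) hi <- hi * 2
  while (resid(lo) > 0) lo <- lo / 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (resid(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) / hi < 1e-10) break
  }
  E_0 <- (lo + hi) / 2
  c(list(E_0 = E_0), oracle_embryo_birth(p, E_0, f, n_steps, const))
}

# Fixed-step integration of post-birth maturity to the puberty threshold,
# along the analytic von Bertalanffy length curve.
oracle_a_p <- function(p, a_b, L_b, f = 1, n_steps = 40000L,
                       const = chemical_constants()) {
  cp <- compound_parameters(p, const)
  L_i <- f * cp$L_m
  r_B <- cp$k_M / (3 * (1 + f / cp$g))
  rhs <- function(t, y) {
    L <- L_i - (L_i - L_b) * exp(-r_B * (t - a_b))
    (1 - p$kappa) * f * cp$E_m * p$v * L^2 * (cp$g + L / cp$L_m) /
      (f + cp$g) - p$k_J * y
  }
  t_max <- a_b + 40 / r_B
  tr <- rk4_integrate(function(t, y) rhs(t, y), p$E_Hb, a_b, t_max, n_steps)
  cross <- which(tr[, 2L] >= p$E_Hp)
  if (!length(cross)) return(NULL)
  i <- cross[1L]
  w <- (p$E_Hp - tr[i - 1L, 2L]) / (tr[i, 2L] - tr[i - 1L, 2L])
  (1 - w) * tr[i - 1L, 1L] + w * tr[i, 1L]
}

# Fixed-step integration of the aging states (q, h, S) plus the survival
# integral, along the analytic growth curve from birth.
oracle_a_m <- function(p, a_b, L_b, f = 1, n_steps = 60000L,
                       const = chemical_constants()) {
  cp <- compound_parameters(p, const)
  L_i <- f * cp$L_m
  r_B <- cp$k_M / (3 * (1 + f / cp$g))
  rhs <- function(t, y) {
    L <- L_i - (L_i - L_b) * exp(-r_B * (t - a_b))
    r <- 3 * r_B * (L_i - L) / L
    q <- y[1]; h <- y[2]; S <- y[3]
    c((q * (L / cp$L_m)^3 * p$s_G + p$h_a) * f * (p$v / L - r) - r * q,
      q - r * h, -h * S, S)
  }
  t_w <- (6 * L_i / (p$h_a * f * p$v))^(1 / 3)
  tr <- rk4_integrate(rhs, c(0, 0, 1, 0), a_b, a_b + 20 / r_B + 8 * t_w,
                      n_steps)
  a_b + tr[nrow(tr), 5L]
}

# Brute-force survivor fraction by explicit counting.
oracle_survivor <- function(values, x) {
  vapply(x, function(xi) sum(values > xi) / length(values), numeric(1))
}
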