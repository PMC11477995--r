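# Independent oracles and shared fixture builders. Every oracle here
# re-derives its quantity from the closed form or by brute-force
# summation, without calling the package path it checks.

# CODATA constants, restated independently of the package internals.
ORA <- list(
  h = 6.62607015e-34, kB = 1.380649e-23, c = 2.99792458e10,
  NA_ = 6.02214076e23, amu = 1.66053906660e-27
)
ORA$R <- ORA$h * 0 + ORA$kB * ORA$NA_

# Harmonic-oscillator terms for a single mode, term by term.
oracle_mode <- function(nu, T) {
  theta <- ORA$h * ORA$c * nu / ORA$kB
  x <- theta / T
  list(zpe = 0.5 * ORA$NA_ * ORA$h * ORA$c * nu,
       u = ORA$R * theta / expm1(x),
       s = ORA$R * (x / expm1(x) - log1p(-exp(-x))))
}

# Sackur-Tetrode entropy (mass in amu).
oracle_trans_s <- function(mass_amu, T, P) {
  m <- mass_amu * ORA$amu
  ORA$R * (log((2 * pi * m * ORA$kB * T / ORA$h^2)^1.5 *
                 ORA$kB * T / P) + 2.5)
}

# Rotational terms from principal moments in kg m^2.
oracle_rot <- function(moments, sigma, T, linear) {
  theta <- ORA$h^2 / (8 * pi^2 * moments * ORA$kB)
  if (linear) {
    I <- mean(moments[2:3])
    q <- T / (sigma * (ORA$h^2 / (8 * pi^2 * I * ORA$kB)))
    list(u = ORA$R * T, s = ORA$R * (log(q) + 1))
  } else {
    q <- sqrt(pi) / sigma * sqrt(T^3 / prod(theta))
    list(u = 1.5 * ORA$R * T, s = ORA$R * (log(q) + 1.5))
  }
}

# Free-rotor entropy of one mode (the low-frequency limit of the
# interpolation scheme).
oracle_free_rotor_s <- function(nu, T, b_av) {
  mu <- ORA$h / (8 * pi^2 * ORA$c * nu)
  mu_p <- mu * b_av / (mu + b_av)
  ORA$R * (0.5 + 0.5 * log(8 * pi^3 * mu_p * ORA$kB * T / ORA$h^2))
}

# Closed-form OLS via the normal equations.
oracle_ols <- function(y, x) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  ssr <- sum((y - (intercept + slope * x))^2)
  sst <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = 1 - ssr / sst)
}

# A small rigid fixture: bent three-atom "water-like" geometry.
make_bent_triatomic <- function() {
  atom_table(c("O", "H", "H"),
             x = c(0, 0.7586, -0.7586),
             y = c(0, 0.5043, 0.5043),
             z = c(0, 0, 0))
}

random_rotation_matrix <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
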