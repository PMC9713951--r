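## Independent oracles. Everything here is implemented from first principles,
## separately from the package's code paths, so package results can be checked
## against a second route.

## --- constrained strain energy and finite-difference moduli ----------------

## Wtilde(l1, l2) = W(l1, l2, 1/(l1 l2)) for the exponential (strain-stiffening)
## energy; b = 0 is the neo-Hookean special case.
oracle_wtilde <- function(l1, l2, mu0, b) {
  I1 <- l1^2 + l2^2 + 1 / (l1^2 * l2^2)
  if (b == 0) mu0 / 2 * (I1 - 3) else mu0 / (2 * b) * (exp(b * (I1 - 3)) - 1)
}

## central finite differences: step 1e-6 for first derivatives, 1e-4 for
## second derivatives (roundoff in double precision dominates second
## differences below ~1e-4)
oracle_moduli_fd <- function(l1, l2, mu0, b, h1 = 1e-6, h2 = 1e-4) {
  W <- function(a, c) oracle_wtilde(a, c, mu0, b)
  W1 <- (W(l1 + h1, l2) - W(l1 - h1, l2)) / (2 * h1)
  W2 <- (W(l1, l2 + h1) - W(l1, l2 - h1)) / (2 * h1)
  W11 <- (W(l1 + h2, l2) - 2 * W(l1, l2) + W(l1 - h2, l2)) / h2^2
  W22 <- (W(l1, l2 + h2) - 2 * W(l1, l2) + W(l1, l2 - h2)) / h2^2
  W12 <- (W(l1 + h2, l2 + h2) - W(l1 + h2, l2 - h2) -
            W(l1 - h2, l2 + h2) + W(l1 - h2, l2 - h2)) / (4 * h2^2)
  t_diff <- l1 * W1 - l2 * W2
  d <- l1^2 - l2^2
  list(
    t_diff = t_diff,
    alpha = l1^2 * t_diff / d,
    gamma = l2^2 * t_diff / d,
    beta2 = l1^2 * W11 + l2^2 * W22 - 2 * l1 * l2 * W12 -
      2 * l1 * l2 * (l2 * W1 - l1 * W2) / d)
}

## --- monolithic transcription of the fully substituted dispersion equation --

## Independent transcription in volume-ratio variables with the explicit
## quadratic formula (exponent-corrected: lam1^2 = (V/V0)^(2/3),
## lam2^2 = (V0/V)^(4/3)). The package path goes through lambda-based moduli
## and polyroot instead.
oracle_theta_monolithic <- function(c, f, P, V, V0, h0,
                                    b_stiff = 5, rho = 1000, rhoF = 1000,
                                    cp = 1480,
                                    beta_variant = "derived") {
  q <- V / V0
  l1sq <- q^(2 / 3)
  l2sq <- q^(-4 / 3)
  d <- l1sq - l2sq
  A <- l1sq / d
  B <- switch(beta_variant,
              derived = (2 * b_stiff * d^2 + l1sq + l2sq) / d,
              eq19    = (b_stiff * d^2 + l1sq + l2sq) / d,
              eq17    = 2 * (b_stiff * d^2 + l1sq + l2sq) / d)
  r <- (3 * V / (4 * pi))^(1 / 3)
  h <- h0 * q^(-2 / 3)
  tw <- P * r / (4 * h)                      # thin-wall stress difference
  al <- A * tw
  ga <- (V0^2 / V^2) * A * tw                # lam2^2/lam1^2 = (V0/V)^2
  bb <- B * tw                               # the quantity 2*beta
  k <- 2 * pi * f / c
  rc2 <- rho * c^2
  disc <- as.complex((bb - rc2)^2 - 4 * ga * (al - rc2))
  s1sq <- ((bb - rc2) + sqrt(disc)) / (2 * ga)
  s2sq <- ((bb - rc2) - sqrt(disc)) / (2 * ga)
  ## same ordering convention as the package: larger real part first
  if (Re(s2sq) > Re(s1sq) ||
      (Re(s2sq) == Re(s1sq) && Im(s2sq) > Im(s1sq))) {
    tmp <- s1sq; s1sq <- s2sq; s2sq <- tmp
  }
  s1 <- sqrt(s1sq); s2 <- sqrt(s2sq)
  xi <- sqrt(1 - c^2 / cp^2)
  ga * s1 * (1 + s2sq)^2 * tanh(s1 * k * h) -
    ga * s2 * (1 + s1sq)^2 * tanh(s2 * k * h) +
    rhoF * c^2 * (s1sq - s2sq) / xi
}

## --- classical unstressed fluid-loaded plate, hyperbolic form ---------------

## Antisymmetric characteristic function for an unstressed incompressible
## plate (shear modulus mu0) loaded by fluid on both faces, written directly
## in hyperbolic variables: x = rho c^2 / mu0,
##   (2 - x)^2 tanh(kh) - 4 sqrt(1-x) tanh(kh sqrt(1-x))
##     + (rhoF/rho) x^2 / sqrt(1 - c^2/cp^2) = 0.
oracle_theta_classical <- function(c, f, mu0, h, rho = 1000, rhoF = 1000,
                                   cp = 1480) {
  x <- rho * c^2 / mu0
  k <- 2 * pi * f / c
  s <- sqrt(as.complex(1 - x))
  Re((2 - x)^2 * tanh(k * h) - 4 * s * tanh(s * k * h) +
       (rhoF / rho) * x^2 / sqrt(1 - c^2 / cp^2))
}

## solve the classical A0 branch with uniroot on a fixed bracket scan
oracle_classical_a0 <- function(f, mu0, h, rho = 1000, rhoF = 1000,
                                cp = 1480, c_max = 15) {
  g <- function(c) oracle_theta_classical(c, f, mu0, h, rho, rhoF, cp)
  grid <- seq(0.05, c_max, by = 0.05)
  vals <- vapply(grid, g, numeric(1))
  i <- which(vals[-1] * vals[-length(vals)] < 0)[1]
  if (is.na(i)) return(NA_real_)
  stats::uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-12)$root
}

## --- small builders ----------------------------------------------------------

make_geom <- function(ratio = 1.3, V0_ml = 150, h0 = 2.75e-3) {
  compartment_geometry(V = ratio * V0_ml * 1e-6, V0 = V0_ml * 1e-6, h0 = h0)
}

## replicate acquisition table from a single clean curve
make_acq_table <- function(curve, R = 5, fill = 200) {
  do.call(rbind, lapply(seq_len(R), function(r) {
    data.frame(fill_volume_ml = fill, acquisition = r,
               frequency_hz = curve$frequency_hz,
               phase_velocity_m_s = curve$phase_velocity_m_s)
  }))
}
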