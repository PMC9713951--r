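## Finite-deformation mechanics of an inflating thin-walled sphere under the
## Demiray-Fung model, and the acoustoelastic incremental moduli that enter the
## pre-stressed Lamb-wave characteristic equation.
##
## Kinematics: the wall is in equibiaxial tension. lam1 is the in-plane stretch
## (both in-plane directions, lam3 = lam1), lam2 the through-thickness stretch;
## incompressibility forces lam2 = lam1^-2 when stretches come from volumes.
## The incremental moduli are derivatives of the *constrained* strain energy
## Wtilde(l1, l2) = W(l1, l2, 1/(l1 l2)), i.e. the incompressibility constraint
## is eliminated before differentiating.

#' Constitutive model for the compartment wall
#'
#' Demiray-Fung exponential strain energy
#' \deqn{W = \frac{\mu_0}{2b}\left(e^{b(I_1-3)} - 1\right)}
#' with initial shear modulus \eqn{\mu_0}, strain-stiffening exponent \eqn{b}
#' (dimensionless; \eqn{b \to 0} recovers neo-Hookean behaviour) and solid
#' density \eqn{\rho}.
#'
#' @param mu0 initial shear modulus, Pa (> 0).
#' @param b_stiff strain-stiffening exponent, dimensionless (>= 0).
#' @param rho_solid wall mass density, kg/m^3 (> 0). Default 1000 (1 g/ml).
#' @return an object of class `material_model`.
#' @export
#' @examples
#' material_model(mu0 = 3e3, b_stiff = 5)
material_model <- function(mu0, b_stiff = 5, rho_solid = 1000) {
  if (!is.finite(mu0) || mu0 <= 0) stop_domain("mu0 must be > 0")
  if (!is.finite(b_stiff) || b_stiff < 0) stop_domain("b_stiff must be >= 0")
  if (!is.finite(rho_solid) || rho_solid <= 0) stop_domain("rho_solid must be > 0")
  structure(list(mu0 = mu0, b_stiff = b_stiff, rho_solid = rho_solid),
            class = "material_model")
}

#' Surrounding/filling fluid model
#'
#' @param rho_fluid fluid mass density, kg/m^3 (> 0). Default 1000 (water).
#' @param cp compressional sound speed in the fluid, m/s (> 0). Default 1480.
#' @return an object of class `fluid_model`.
#' @export
fluid_model <- function(rho_fluid = 1000, cp = 1480) {
  if (!is.finite(rho_fluid) || rho_fluid <= 0) stop_domain("rho_fluid must be > 0")
  if (!is.finite(cp) || cp <= 0) stop_domain("cp must be > 0")
  structure(list(rho_fluid = rho_fluid, cp = cp), class = "fluid_model")
}

#' Deformed geometry of the spherical compartment
#'
#' Derives the deformed radius, through-thickness stretch and deformed
#' half-thickness from the deformed and reference volumes and the undeformed
#' half-thickness. `r` is the inner radius; the outer radius is `r + 2h`
#' (used by the thick-wall logarithmic pressure relation).
#'
#' @param V deformed volume, m^3.
#' @param V0 reference (taut but unpressurized) volume, m^3.
#' @param h0 undeformed half-thickness, m. Default 2.75e-3 (5.5 mm wall).
#' @return an object of class `compartment_geometry` with fields `V`, `V0`,
#'   `h0`, `r` (deformed inner radius, m), `r0`, `h` (deformed half-thickness,
#'   m), `a` (= r) and `b_out` (= r + 2h).
#' @export
#' @examples
#' compartment_geometry(V = 260e-6, V0 = 200e-6)
compartment_geometry <- function(V, V0, h0 = 2.75e-3) {
  if (!is.finite(V) || V <= 0) stop_domain("V must be > 0")
  if (!is.finite(V0) || V0 <= 0) stop_domain("V0 must be > 0")
  if (!is.finite(h0) || h0 <= 0) stop_domain("h0 must be > 0")
  defm <- stretches_from_volumes(V, V0)
  r <- radius_from_volume(V)
  h <- defm$lam2 * h0
  structure(list(V = V, V0 = V0, h0 = h0,
                 r = r, r0 = radius_from_volume(V0), h = h,
                 a = r, b_out = r + 2 * h, defm = defm),
            class = "compartment_geometry")
}

#' @export
print.compartment_geometry <- function(x, ...) {
  cat(sprintf(
    "compartment_geometry: V = %.1f ml, V0 = %.1f ml (V/V0 = %.3f)\n  r = %.2f mm, h = %.3f mm (h0 = %.3f mm), lam1 = %.4f\n",
    m3_to_ml(x$V), m3_to_ml(x$V0), x$V / x$V0,
    x$r * 1e3, x$h * 1e3, x$h0 * 1e3, x$defm$lam1))
  invisible(x)
}

#' Sphere radius from volume
#'
#' Inverts \eqn{V = \frac{4}{3}\pi r^3}.
#'
#' @param V volume, m^3 (> 0).
#' @return radius, m.
#' @export
radius_from_volume <- function(V) {
  if (any(!is.finite(V)) || any(V <= 0)) stop_domain("V must be > 0")
  (3 * V / (4 * pi))^(1 / 3)
}

#' Principal stretches of the spherical wall from volumes
#'
#' For an incompressible spherical shell inflated from reference volume `V0`
#' to `V`: in-plane stretch \eqn{\lambda_1 = (V/V_0)^{1/3}}, through-thickness
#' stretch \eqn{\lambda_2 = (V_0/V)^{2/3}} and \eqn{\lambda_3 = \lambda_1}
#' (equibiaxial). Incompressibility gives \eqn{\lambda_1^2 \lambda_2 = 1}.
#'
#' @param V deformed volume, m^3.
#' @param V0 reference volume, m^3.
#' @return an object of class `deformation_state` with `lam1`, `lam2`, `lam3`
#'   and `I1` (first invariant of the left Cauchy-Green tensor,
#'   \eqn{2\lambda_1^2 + \lambda_2^2}).
#' @export
#' @examples
#' stretches_from_volumes(8, 1)  # lam1 = 2, lam2 = 1/4
stretches_from_volumes <- function(V, V0) {
  if (!is.finite(V) || V <= 0) stop_domain("V must be > 0")
  if (!is.finite(V0) || V0 <= 0) stop_domain("V0 must be > 0")
  lam1 <- (V / V0)^(1 / 3)
  lam2 <- (V0 / V)^(2 / 3)
  deformation_state(lam1, lam2)
}

#' General deformation state from principal stretches
#'
#' The third stretch is fixed by incompressibility,
#' \eqn{\lambda_3 = 1/(\lambda_1\lambda_2)}; for the spherical (equibiaxial)
#' case \eqn{\lambda_2 = \lambda_1^{-2}} this reduces to
#' \eqn{\lambda_3 = \lambda_1}.
#'
#' @param lam1 in-plane (propagation-direction) stretch (> 0).
#' @param lam2 through-thickness stretch (> 0); defaults to the spherical
#'   value `lam1^-2`.
#' @return object of class `deformation_state`.
#' @export
deformation_state <- function(lam1, lam2 = lam1^(-2)) {
  if (!is.finite(lam1) || lam1 <= 0) stop_domain("lam1 must be > 0")
  if (!is.finite(lam2) || lam2 <= 0) stop_domain("lam2 must be > 0")
  lam3 <- 1 / (lam1 * lam2)
  structure(list(lam1 = lam1, lam2 = lam2, lam3 = lam3,
                 I1 = lam1^2 + lam2^2 + lam3^2),
            class = "deformation_state")
}

#' Reference volume from a measured wall half-thickness
#'
#' The reference volume of a soft compartment is hard to observe directly
#' (the wall must be taut but unloaded), but `h/h0 = lam2` lets it be
#' inferred from a deformed half-thickness measurement:
#' \eqn{V_0 = (h/h_0)^{3/2} V}.
#'
#' @param h measured deformed half-thickness, m.
#' @param h0 undeformed half-thickness, m.
#' @param V deformed volume, m^3.
#' @return reference volume V0, m^3.
#' @export
reference_volume_from_thickness <- function(h, h0, V) {
  if (!is.finite(h) || h <= 0) stop_domain("h must be > 0")
  if (!is.finite(h0) || h0 <= 0) stop_domain("h0 must be > 0")
  if (!is.finite(V) || V <= 0) stop_domain("V must be > 0")
  (h / h0)^(3 / 2) * V
}

#' Thin-wall (Laplace) pressure from the wall-stress difference
#'
#' \eqn{P = (t_1 - t_2)\,4h/r}: the first-order Taylor expansion of the
#' thick-wall logarithmic relation about b/a = 1, equivalent to the classic
#' spherical pressure-vessel law.
#'
#' @param t_diff principal Cauchy stress difference t1 - t2, Pa.
#' @param h deformed half-thickness, m (> 0).
#' @param r deformed inner radius, m (> 0).
#' @return inflation pressure, Pa.
#' @export
thin_wall_pressure <- function(t_diff, h, r) {
  if (any(!is.finite(h)) || any(h <= 0)) stop_domain("h must be > 0")
  if (any(!is.finite(r)) || any(r <= 0)) stop_domain("r must be > 0")
  t_diff * 4 * h / r
}

#' Thick-wall logarithmic pressure relation (homogeneous stress)
#'
#' \eqn{P = 2(t_1 - t_2)\ln(b/a)} for inner radius a and outer radius b under
#' the homogeneous-stress assumption. Serves as the oracle for the thin-wall
#' approximation, to which it reduces as b/a -> 1.
#'
#' @param t_diff principal Cauchy stress difference, Pa.
#' @param a inner radius, m (> 0).
#' @param b_out outer radius, m (>= a).
#' @return inflation pressure, Pa.
#' @export
log_wall_pressure <- function(t_diff, a, b_out) {
  if (any(!is.finite(a)) || any(a <= 0)) stop_domain("a must be > 0")
  if (any(b_out < a)) stop_domain("b_out must be >= a")
  2 * t_diff * log(b_out / a)
}

#' Demiray-Fung principal Cauchy stress difference
#'
#' The Lagrange multiplier enforcing incompressibility cancels in the
#' difference of principal stresses:
#' \deqn{t_1 - t_2 = (\lambda_1^2 - \lambda_2^2)\,\mu_0\, e^{b(I_1 - 3)}.}
#'
#' @param defm a `deformation_state`.
#' @param mat a `material_model`.
#' @return object of class `stress_state` with field `t_diff` (Pa).
#' @export
demiray_fung_stress_difference <- function(defm, mat) {
  stopifnot(inherits(defm, "deformation_state"), inherits(mat, "material_model"))
  t_diff <- (defm$lam1^2 - defm$lam2^2) * mat$mu0 * exp(mat$b_stiff * (defm$I1 - 3))
  structure(list(t_diff = t_diff), class = "stress_state")
}

## Closed-form derivatives of the constrained energy
## Wtilde(l1, l2) = (mu0 / 2b)(exp(b(I1 - 3)) - 1),  I1 = l1^2 + l2^2 + 1/(l1^2 l2^2).
## Every derivative factors as mu0 * exp(b(I1-3)) * (function of stretches and b),
## which is why all moduli are proportional to the stress difference.
dfung_wtilde_derivs <- function(lam1, lam2, mu0, b) {
  l3sq <- 1 / (lam1^2 * lam2^2)
  I1 <- lam1^2 + lam2^2 + l3sq
  E <- mu0 * exp(b * (I1 - 3))
  g1 <- lam1 - l3sq / lam1           # dI1/dlam1 / 2
  g2 <- lam2 - l3sq / lam2
  list(
    E = E, I1 = I1, l3sq = l3sq,
    W1 = E * g1,
    W2 = E * g2,
    W11 = E * (2 * b * g1^2 + 1 + 3 * l3sq / lam1^2),
    W22 = E * (2 * b * g2^2 + 1 + 3 * l3sq / lam2^2),
    W12 = E * (2 * b * g1 * g2 + 2 * l3sq / (lam1 * lam2))
  )
}

#' Acoustoelastic incremental moduli about a finitely deformed state
#'
#' Coefficients of the linearized (incremental) equations of motion for plane
#' waves in the (1,2)-plane of a pre-stressed incompressible Demiray-Fung
#' solid:
#' \deqn{\alpha = \lambda_1^2 \mu_0 e^{b(I_1-3)}, \quad
#'       \gamma = \lambda_2^2 \mu_0 e^{b(I_1-3)},}
#' and, for the default `derived` variant (obtained by differentiating the
#' constrained energy, with the removable \eqn{\lambda_1 = \lambda_2}
#' singularities cancelled analytically),
#' \deqn{2\beta = \mu_0 e^{b(I_1-3)}
#'   \left[2b(\lambda_1^2-\lambda_2^2)^2 + \lambda_1^2 + \lambda_2^2\right].}
#' All three tend to \eqn{(\mu_0, \mu_0, 2\mu_0)} as \eqn{\lambda_1 \to 1},
#' the classical unstressed incompressible limit.
#'
#' Two published closed forms that disagree with each other by a factor of 2
#' in the strain-stiffening term are available for reproduction studies via
#' `beta_variant`: `"eq17"` gives
#' \eqn{2\beta = 2\mu_0 e^{b(I_1-3)}[b(\lambda_1^2-\lambda_2^2)^2 +
#' \lambda_1^2+\lambda_2^2]} (limit \eqn{4\mu_0}) and `"eq19"` gives half of
#' that (limit \eqn{2\mu_0}). Only `"derived"` matches direct differentiation
#' of the energy.
#'
#' @param defm a `deformation_state`.
#' @param mat a `material_model`.
#' @param beta_variant one of `"derived"` (default), `"eq17"`, `"eq19"`.
#' @return object of class `moduli` with fields `alpha`, `gamma` and `beta2`
#'   (the quantity \eqn{2\beta}), all in Pa.
#' @export
#' @examples
#' m <- material_model(mu0 = 20e3, b_stiff = 5)
#' incremental_moduli(stretches_from_volumes(1.5, 1), m)
incremental_moduli <- function(defm, mat,
                               beta_variant = c("derived", "eq17", "eq19")) {
  stopifnot(inherits(defm, "deformation_state"), inherits(mat, "material_model"))
  beta_variant <- match.arg(beta_variant)
  l1 <- defm$lam1; l2 <- defm$lam2
  E <- mat$mu0 * exp(mat$b_stiff * (defm$I1 - 3))
  alpha <- l1^2 * E
  gamma <- l2^2 * E
  beta2 <- switch(beta_variant,
    derived = E * (2 * mat$b_stiff * (l1^2 - l2^2)^2 + l1^2 + l2^2),
    eq17    = 2 * E * (mat$b_stiff * (l1^2 - l2^2)^2 + l1^2 + l2^2),
    eq19    = E * (mat$b_stiff * (l1^2 - l2^2)^2 + l1^2 + l2^2))
  structure(list(alpha = alpha, gamma = gamma, beta2 = beta2,
                 beta_variant = beta_variant),
            class = "moduli")
}

#' @export
print.moduli <- function(x, ...) {
  cat(sprintf("moduli (%s): alpha = %.4g Pa, gamma = %.4g Pa, 2beta = %.4g Pa\n",
              x$beta_variant, x$alpha, x$gamma, x$beta2))
  invisible(x)
}

#' Dimensionless stretch coefficients A and B
#'
#' The moduli divided by the stress difference depend only on the volume
#' ratio and the stiffening exponent:
#' \eqn{A = \lambda_1^2/(\lambda_1^2 - \lambda_2^2)} so that
#' \eqn{\alpha = A (t_1 - t_2)}, and \eqn{B = 2\beta/(t_1 - t_2)}.
#' With \eqn{\lambda_1^2 = (V/V_0)^{2/3}} and
#' \eqn{\lambda_2^2 = (V_0/V)^{4/3}}. Both diverge as V -> V0, where
#' the stress difference vanishes; the products (the moduli) stay finite.
#'
#' @param V,V0 deformed and reference volumes, m^3 (V != V0).
#' @param b_stiff strain-stiffening exponent.
#' @param beta_variant see [incremental_moduli()].
#' @return list with `A_coef` and `B_coef` (dimensionless).
#' @export
stretch_coefficients <- function(V, V0, b_stiff,
                                 beta_variant = c("derived", "eq17", "eq19")) {
  beta_variant <- match.arg(beta_variant)
  defm <- stretches_from_volumes(V, V0)
  l1sq <- defm$lam1^2; l2sq <- defm$lam2^2
  d <- l1sq - l2sq
  if (d == 0) stop_domain("stretch coefficients are undefined at V = V0")
  B_num <- switch(beta_variant,
    derived = 2 * b_stiff * d^2 + l1sq + l2sq,
    eq17    = 2 * (b_stiff * d^2 + l1sq + l2sq),
    eq19    = b_stiff * d^2 + l1sq + l2sq)
  list(A_coef = l1sq / d, B_coef = B_num / d)
}

#' Incremental moduli directly from pressure and geometry
#'
#' Substitutes the thin-wall law \eqn{t_1 - t_2 = P r / (4h)} into the
#' stretch-coefficient forms, so the moduli are fully determined by pressure,
#' volumes and the stiffening exponent -- the initial shear modulus never
#' enters. Identical to composing [stretches_from_volumes()],
#' [demiray_fung_stress_difference()], [thin_wall_pressure()] and
#' [incremental_moduli()].
#'
#' @param P inflation pressure, Pa (>= 0).
#' @param geom a `compartment_geometry`.
#' @param b_stiff strain-stiffening exponent.
#' @param beta_variant see [incremental_moduli()].
#' @return object of class `moduli`.
#' @export
moduli_from_pressure <- function(P, geom, b_stiff,
                                 beta_variant = c("derived", "eq17", "eq19")) {
  beta_variant <- match.arg(beta_variant)
  stopifnot(inherits(geom, "compartment_geometry"))
  if (!is.finite(P) || P < 0) stop_domain("P must be >= 0")
  t_diff <- P * geom$r / (4 * geom$h)
  co <- stretch_coefficients(geom$V, geom$V0, b_stiff, beta_variant)
  defm <- geom$defm
  structure(list(alpha = co$A_coef * t_diff,
                 gamma = (defm$lam2^2 / defm$lam1^2) * co$A_coef * t_diff,
                 beta2 = co$B_coef * t_diff,
                 beta_variant = beta_variant),
            class = "moduli")
}
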