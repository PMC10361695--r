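# One-term Ogden material (exponent 2) with volumetric/isochoric split.
#
# Strain energy per unit reference volume, in mm-kPa units:
#   Psi = mu/2 * (lb1^2 + lb2^2 + lb3^2 - 3) + kappa/4 * (J^2 - 1 - 2 log J)
# where lbi are the isochoric principal stretches.  Because the Ogden exponent
# is exactly 2, the isochoric term equals mu/2 * (J^{-2/3} tr(C) - 3), i.e. a
# compressible neo-Hookean form, and first Piola-Kirchhoff stress and tangent
# are closed-form in F with no eigen-decomposition.

#' Ogden material parameters
#'
#' Shear and bulk modulus of the one-term (exponent-2) Ogden model used for
#' brain tissue. The unit system of the mechanics is mm-kPa.
#'
#' @param mu Shear modulus in kPa (governs isochoric, distortional response).
#' @param kappa Bulk modulus in kPa (governs dilatational response).
#' @return An object of class `ogden_params`.
#' @export
ogden_params <- function(mu, kappa) {
  stopifnot(is.numeric(mu), is.numeric(kappa), length(mu) == 1, length(kappa) == 1)
  if (mu <= 0 || kappa <= 0) stop("ogden_params: mu and kappa must be positive")
  structure(list(mu = mu, kappa = kappa), class = "ogden_params")
}

#' @export
print.ogden_params <- function(x, ...) {
  cat(sprintf("Ogden (alpha = 2) material: mu = %g kPa, kappa = %g kPa\n", x$mu, x$kappa))
  invisible(x)
}

#' Default tissue parameter table
#'
#' Gray matter uses mu = 0.34 kPa and kappa = 3.3 kPa; white matter is
#' `wm_gm_stiffness_ratio` times stiffer (default 2, giving mu = 0.68 kPa and
#' kappa = 6.6 kPa, a Poisson ratio of about 0.45). WMH tissue inherits the
#' white-matter parameters. The subarachnoid space is an ultrasoft compressible
#' solid specified by Young's modulus 1.0 Pa and Poisson ratio 0.30, converted
#' to (mu, kappa) via the isotropic elasticity relations and expressed in kPa.
#'
#' @param wm_gm_stiffness_ratio White-to-gray matter stiffness ratio (applied
#'   to both mu and kappa). Default 2.
#' @return An object of class `tissue_table`: a named list with entries
#'   `WM`, `GM`, `SAS`, `WMH`, each an [ogden_params()].
#' @export
default_tissue_table <- function(wm_gm_stiffness_ratio = 2) {
  stopifnot(wm_gm_stiffness_ratio > 0)
  gm <- ogden_params(0.34, 3.3)
  wm <- ogden_params(gm$mu * wm_gm_stiffness_ratio, gm$kappa * wm_gm_stiffness_ratio)
  # SAS: E = 1.0 Pa = 1e-3 kPa, nu = 0.30
  E <- 1.0e-3; nu <- 0.30
  sas <- ogden_params(E / (2 * (1 + nu)), E / (3 * (1 - 2 * nu)))
  structure(list(WM = wm, GM = gm, SAS = sas, WMH = wm,
                 wm_gm_stiffness_ratio = wm_gm_stiffness_ratio),
            class = "tissue_table")
}

#' @export
print.tissue_table <- function(x, ...) {
  cat("Tissue parameter table (mm-kPa units):\n")
  for (r in c("WM", "GM", "SAS", "WMH"))
    cat(sprintf("  %-4s mu = %.6g kPa, kappa = %.6g kPa\n", r, x[[r]]$mu, x[[r]]$kappa))
  invisible(x)
}

#' Volumetric/isochoric decomposition of a deformation gradient
#'
#' Splits F into J = det(F) and the isochoric part Fbar = J^{-1/3} F, and
#' derives the right Cauchy-Green tensor C = F'F, its isochoric counterpart
#' Cbar (det(Cbar) = 1), the isochoric invariants I1bar and I2bar, and the
#' isochoric principal stretches (square roots of the eigenvalues of Cbar,
#' sorted descending).
#'
#' @param F A 3x3 deformation gradient with positive determinant.
#' @return An object of class `deformation_state` with fields `F`, `J`, `C`,
#'   `C_bar`, `I1_bar`, `I2_bar`, `lambda_bar`.
#' @export
decompose_deformation <- function(F) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)))
  J <- det(F)
  if (!is.finite(J) || J <= 0) stop("decompose_deformation: det(F) must be positive (inverted state)")
  C <- crossprod(F)                      # F'F
  C_bar <- J^(-2 / 3) * C
  I1_bar <- sum(diag(C_bar))
  I2_bar <- 0.5 * (I1_bar^2 - sum(C_bar * t(C_bar)))
  ev <- eigen(C_bar, symmetric = TRUE, only.values = TRUE)$values
  lambda_bar <- sqrt(pmax(ev, 0))        # already sorted descending by eigen()
  structure(list(F = F, J = J, C = C, C_bar = C_bar,
                 I1_bar = I1_bar, I2_bar = I2_bar, lambda_bar = lambda_bar),
            class = "deformation_state")
}

#' @export
print.deformation_state <- function(x, ...) {
  cat(sprintf("Deformation state: J = %.6g, I1_bar = %.6g, lambda_bar = (%s)\n",
              x$J, x$I1_bar, paste(signif(x$lambda_bar, 6), collapse = ", ")))
  invisible(x)
}

#' Strain-energy density
#'
#' Evaluates the one-term Ogden (exponent 2) energy
#' `mu/2 * (sum lambda_bar_i^2 - 3) + kappa/4 * (J^2 - 1 - 2 log J)` in kPa.
#'
#' @param state A [decompose_deformation()] result.
#' @param p An [ogden_params()] object.
#' @return Scalar energy density in kPa.
#' @export
strain_energy <- function(state, p) {
  stopifnot(inherits(state, "deformation_state"), inherits(p, "ogden_params"))
  p$mu / 2 * (state$I1_bar - 3) + p$kappa / 4 * (state$J^2 - 1 - 2 * log(state$J))
}

#' First Piola-Kirchhoff stress
#'
#' Exact gradient of [strain_energy()] with respect to F:
#' `P = mu J^{-2/3} (F - tr(C)/3 F^{-T}) + kappa/2 (J^2 - 1) F^{-T}`.
#' The volumetric part of the associated Cauchy stress is the pressure
#' `kappa/2 (J - 1/J)` times the identity.
#'
#' @inheritParams strain_energy
#' @return 3x3 first Piola-Kirchhoff stress in kPa.
#' @export
pk1_stress <- function(state, p) {
  stopifnot(inherits(state, "deformation_state"), inherits(p, "ogden_params"))
  F <- state$F; J <- state$J
  B <- t(solve(F))                       # F^{-T}
  I1 <- sum(F * F)                       # tr(C)
  p$mu * J^(-2 / 3) * (F - (I1 / 3) * B) + (p$kappa / 2) * (J^2 - 1) * B
}

#' Cauchy stress
#'
#' `sigma = J^{-1} P F'`, symmetric for the isotropic energy used here.
#'
#' @inheritParams strain_energy
#' @return 3x3 Cauchy stress in kPa.
#' @export
cauchy_stress <- function(state, p) {
  P <- pk1_stress(state, p)
  (P %*% t(state$F)) / state$J
}

#' Material tangent dP/dF
#'
#' Fourth-order tangent of the first Piola-Kirchhoff stress with respect to the
#' deformation gradient, returned as a 3x3x3x3 array `A[i,j,k,l] = dP_ij/dF_kl`.
#' It carries the major symmetry of the elasticity tensor
#' (`A[i,j,k,l] = A[k,l,i,j]`) and is linear in (mu, kappa).
#'
#' @inheritParams strain_energy
#' @return A numeric array of dimension c(3,3,3,3) in kPa.
#' @export
material_tangent <- function(state, p) {
  stopifnot(inherits(state, "deformation_state"), inherits(p, "ogden_params"))
  F <- state$F; J <- state$J
  B <- t(solve(F)); I1 <- sum(F * F); Jm23 <- J^(-2 / 3)
  del <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) del[i, j, i, j] <- 1
  BB <- outer(B, B)
  dB <- -aperm(BB, c(1, 4, 3, 2))        # dB_ijkl = -B_il B_kj
  p$mu * Jm23 * (del - (2 / 3) * outer(F, B)) -
    (p$mu / 3) * Jm23 * (-(2 / 3) * I1 * BB + 2 * outer(B, F) + I1 * dB) +
    (p$kappa / 2) * (2 * J^2 * BB + (J^2 - 1) * dB)
}
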