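#' Material parameters of the fiber-reinforced hyperelastic leaflet model
#'
#' The strain energy is split into a deviatoric part
#' \deqn{\Psi_{dev} = \frac{a}{2b} e^{b(I_1 - 3)}
#'   + \sum_{i=f,t} \frac{a_i}{2 b_i}\{e^{b_i (I_{4i}-1)^2} - 1\}
#'   + \frac{a_{ft}}{2 b_{ft}}\{e^{b_{ft} I_{8ft}^2} - 1\}}
#' and a volumetric part
#' \deqn{\Psi_{vol} = \frac{1}{D}\left(\frac{J^2 - 1}{2} - \ln J\right),}
#' with `a` (kPa) and `b` (-) the isotropic stiffness, `a_f, b_f` the
#' fiber-direction stiffness, `a_t, b_t` the transverse stiffness,
#' `a_ft, b_ft` the fiber-transverse shear rigidity, and `D` (1/kPa) the
#' compressibility parameter, taken as `D = 2/K` with `K` the bulk modulus
#' so that `1/D` carries stress units.
#'
#' @param a,a_f,a_t,a_ft Stress-like moduli (kPa), >= 0.
#' @param b,b_f,b_t,b_ft Dimensionless exponents, > 0.
#' @param D Compressibility parameter (1/kPa), > 0.
#' @param f0,t0 Unit fiber and trans-fiber direction vectors, orthogonal.
#' @return A `material_params` object.
#' @export
material_params <- function(a, b, a_f, b_f, a_t, b_t, a_ft, b_ft, D,
                            f0 = c(1, 0, 0), t0 = c(0, 1, 0)) {
  moduli <- c(a = a, a_f = a_f, a_t = a_t, a_ft = a_ft)
  expo <- c(b = b, b_f = b_f, b_t = b_t, b_ft = b_ft)
  if (any(moduli < 0)) stop("moduli a, a_f, a_t, a_ft must be >= 0", call. = FALSE)
  if (any(expo <= 0)) stop("exponents b, b_f, b_t, b_ft must be > 0", call. = FALSE)
  if (D <= 0) stop("D must be > 0", call. = FALSE)
  f0 <- as.numeric(f0); t0 <- as.numeric(t0)
  if (abs(sqrt(sum(f0^2)) - 1) > 1e-8 || abs(sqrt(sum(t0^2)) - 1) > 1e-8)
    stop("f0 and t0 must be unit vectors", call. = FALSE)
  if (abs(sum(f0 * t0)) > 1e-8)
    stop("f0 and t0 must be orthogonal", call. = FALSE)
  structure(list(a = a, b = b, a_f = a_f, b_f = b_f, a_t = a_t, b_t = b_t,
                 a_ft = a_ft, b_ft = b_ft, D = D, f0 = f0, t0 = t0),
            class = "material_params")
}

#' Synthetic demonstration material
#'
#' A synthetic parameter set in the range of published exponential
#' fiber-reinforced fits for mitral leaflet tissue; it is NOT a published
#' calibration and is intended for demonstrations and verification sweeps
#' only.
#'
#' @inheritParams material_params
#' @return A `material_params` object.
#' @export
demo_material <- function(f0 = c(1, 0, 0), t0 = c(0, 1, 0)) {
  material_params(a = 20, b = 2.5, a_f = 150, b_f = 10,
                  a_t = 40, b_t = 6, a_ft = 10, b_ft = 4,
                  D = 2 / 1e4, f0 = f0, t0 = t0)
}

#' Kinematic invariants of a deformation state
#'
#' From the deformation gradient `F` (with `J = det F > 0`), forms the
#' isochoric right Cauchy-Green tensor \eqn{\bar C = J^{-2/3} F^\top F} and
#' returns \eqn{I_1 = tr(\bar C)}, the fiber and transverse stretch
#' invariants \eqn{I_{4f} = \bar C : (f_0 \otimes f_0)},
#' \eqn{I_{4t} = \bar C : (t_0 \otimes t_0)}, the coupling invariant
#' \eqn{I_{8ft} = \bar C : sym(f_0 \otimes t_0)}, and `J`.
#' `split = "none"` evaluates the invariants on the total `C` instead.
#'
#' @param F 3 x 3 deformation gradient.
#' @param f0,t0 Unit, mutually orthogonal direction vectors.
#' @param split `"isochoric"` (default) or `"none"`.
#' @return Named numeric vector `(I1, I4f, I4t, I8ft, J)`.
#' @examples
#' kinematic_invariants(diag(3), c(1, 0, 0), c(0, 1, 0))  # 3 1 1 0 1
#' @export
kinematic_invariants <- function(F, f0 = c(1, 0, 0), t0 = c(0, 1, 0),
                                 split = c("isochoric", "none")) {
  split <- match.arg(split)
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3L, 3L)))
  J <- det(F)
  if (J <= 0)
    stop(sprintf("det F = %g <= 0: inverted deformation state", J),
         call. = FALSE)
  C <- crossprod(F)
  Cb <- if (split == "isochoric") J^(-2 / 3) * C else C
  c(I1 = sum(diag(Cb)),
    I4f = as.numeric(f0 %*% Cb %*% f0),
    I4t = as.numeric(t0 %*% Cb %*% t0),
    I8ft = as.numeric(f0 %*% Cb %*% t0),   # C symmetric: C:sym(f0 x t0) = f0.C.t0
    J = J)
}

#' Strain energy density
#'
#' Evaluates the deviatoric + volumetric strain energy at a deformation
#' state; returns the total with the two parts as attributes.
#'
#' @param F 3 x 3 deformation gradient.
#' @param params A [material_params()] object.
#' @param split Invariant convention passed to [kinematic_invariants()].
#' @return Energy density in kPa, with attributes `dev` and `vol`.
#' @export
strain_energy <- function(F, params, split = c("isochoric", "none")) {
  split <- match.arg(split)
  stopifnot(inherits(params, "material_params"))
  iv <- kinematic_invariants(F, params$f0, params$t0, split = split)
  p <- params
  args <- c(iso = p$b * (iv[["I1"]] - 3),
            fib = p$b_f * (iv[["I4f"]] - 1)^2,
            trans = p$b_t * (iv[["I4t"]] - 1)^2,
            shear = p$b_ft * iv[["I8ft"]]^2)
  if (any(args > 700)) {
    bad <- names(args)[which.max(args)]
    stop("exponential overflow in the ", bad,
         " energy term (invariant too large)", call. = FALSE)
  }
  dev <- p$a / (2 * p$b) * exp(args[["iso"]]) +
    p$a_f / (2 * p$b_f) * (exp(args[["fib"]]) - 1) +
    p$a_t / (2 * p$b_t) * (exp(args[["trans"]]) - 1) +
    p$a_ft / (2 * p$b_ft) * (exp(args[["shear"]]) - 1)
  J <- iv[["J"]]
  vol <- (1 / p$D) * ((J^2 - 1) / 2 - log(J))
  structure(dev + vol, dev = dev, vol = vol)
}

#' Cauchy stress
#'
#' Analytic Cauchy stress \eqn{\sigma = (2/J) F (\partial\Psi/\partial C)
#' F^\top} for the fiber-reinforced energy, with the isochoric/volumetric
#' split applied consistently with [kinematic_invariants()]: the deviatoric
#' part contributes \eqn{(2/J)\,\mathrm{dev}[\bar F (\partial\Psi_{dev}/
#' \partial\bar C) \bar F^\top]} and the volumetric part the pressure
#' \eqn{(1/D)(J - 1/J)\,I}. At `F = I` the stress vanishes for every
#' admissible parameter set. With `split = "none"` no deviatoric projection
#' is applied (and the reference state generally carries the isotropic
#' term's stress).
#'
#' @inheritParams strain_energy
#' @return Symmetric 3 x 3 Cauchy stress tensor (kPa).
#' @examples
#' max(abs(cauchy_stress(diag(3), demo_material())))  # 0
#' @export
cauchy_stress <- function(F, params, split = c("isochoric", "none")) {
  split <- match.arg(split)
  stopifnot(inherits(params, "material_params"))
  F <- as.matrix(F)
  J <- det(F)
  if (J <= 0)
    stop(sprintf("det F = %g <= 0: inverted deformation state", J),
         call. = FALSE)
  p <- params
  iv <- kinematic_invariants(F, p$f0, p$t0, split = split)
  ## scalar derivatives of Psi_dev wrt its invariants
  psi1 <- p$a / 2 * exp(p$b * (iv[["I1"]] - 3))
  psi4f <- p$a_f * (iv[["I4f"]] - 1) * exp(p$b_f * (iv[["I4f"]] - 1)^2)
  psi4t <- p$a_t * (iv[["I4t"]] - 1) * exp(p$b_t * (iv[["I4t"]] - 1)^2)
  psi8 <- p$a_ft * iv[["I8ft"]] * exp(p$b_ft * iv[["I8ft"]]^2)
  ff <- tcrossprod(p$f0)
  tt <- tcrossprod(p$t0)
  ft <- (tcrossprod(p$f0, p$t0) + tcrossprod(p$t0, p$f0)) / 2
  dPsi_dC <- function(Fe) {           # wrt the (possibly isochoric) C argument
    psi1 * diag(3) + psi4f * ff + psi4t * tt + psi8 * ft
  }
  if (split == "isochoric") {
    Fb <- J^(-1 / 3) * F
    Sig <- Fb %*% dPsi_dC(Fb) %*% t(Fb)
    sig_dev <- (2 / J) * (Sig - sum(diag(Sig)) / 3 * diag(3))
    sig_vol <- (1 / p$D) * (J - 1 / J) * diag(3)
    sig <- sig_dev + sig_vol
  } else {
    Sig <- F %*% dPsi_dC(F) %*% t(F)
    sig <- (2 / J) * Sig + (1 / p$D) * (J - 1 / J) * diag(3)
  }
  (sig + t(sig)) / 2
}

#' Finite-difference Cauchy stress (verification oracle)
#'
#' Independent numerical stress: central finite differences of
#' [strain_energy()] with respect to the components of `C`, pushed forward
#' as \eqn{\sigma = (2/J) F (\partial\Psi/\partial C) F^\top}. The
#' differentiation perturbs `F` via symmetric perturbations of `C`
#' (\eqn{\Psi} depends on `F` only through `C`), so this shares no code path
#' with the analytic derivative.
#'
#' @inheritParams strain_energy
#' @param h Central-difference step (default 1e-6).
#' @return Symmetric 3 x 3 stress tensor (kPa).
#' @export
numeric_cauchy_stress <- function(F, params, split = "isochoric", h = 1e-6) {
  F <- as.matrix(F)
  J <- det(F)
  C <- crossprod(F)
  energy_of_C <- function(Cmat) {
    ## any F with F^T F = C gives the same energy; use the square root
    e <- eigen(Cmat, symmetric = TRUE)
    Fs <- e$vectors %*% diag(sqrt(pmax(e$values, 1e-300))) %*% t(e$vectors)
    as.numeric(strain_energy(Fs, params, split = split))
  }
  dPsi <- matrix(0, 3L, 3L)
  for (i in 1:3) for (j in i:3) {
    E <- matrix(0, 3L, 3L)
    E[i, j] <- E[j, i] <- 1
    ## d/deps Psi(C + eps*E) = dPsi/dC : E = (2 - delta_ij) * dPsi/dC_ij
    g <- (energy_of_C(C + h * E) - energy_of_C(C - h * E)) / (2 * h)
    dPsi[i, j] <- dPsi[j, i] <- g / (2 - (i == j))
  }
  sig <- (2 / J) * F %*% dPsi %*% t(F)
  (sig + t(sig)) / 2
}

#' @export
print.material_params <- function(x, ...) {
  cat("fiber-reinforced hyperelastic material (kPa):\n")
  cat(sprintf("  isotropic a=%g b=%g | fiber a_f=%g b_f=%g | transverse a_t=%g b_t=%g\n",
              x$a, x$b, x$a_f, x$b_f, x$a_t, x$b_t))
  cat(sprintf("  shear a_ft=%g b_ft=%g | D=%g 1/kPa (K=%g kPa)\n",
              x$a_ft, x$b_ft, x$D, 2 / x$D))
  invisible(x)
}

#' Uniaxial stretch sweep table
#'
#' Incompressible uniaxial stretch along the fiber direction
#' (\eqn{F = diag(\lambda, 1/\sqrt\lambda, 1/\sqrt\lambda)} in the fiber
#' frame): energy and fiber-direction Cauchy stress per stretch level.
#' Used by the material check report.
#'
#' @param params A [material_params()] with `f0 = (1,0,0)`, `t0 = (0,1,0)`.
#' @param stretches Stretch ratios (> 0).
#' @return Data frame with columns `stretch`, `energy_kPa`,
#'   `sigma_fiber_kPa`.
#' @export
uniaxial_sweep <- function(params, stretches = seq(1, 1.3, by = 0.05)) {
  rows <- lapply(stretches, function(lam) {
    F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
    data.frame(stretch = lam,
               energy_kPa = as.numeric(strain_energy(F, params)),
               sigma_fiber_kPa = cauchy_stress(F, params)[1L, 1L])
  })
  do.call(rbind, rows)
}
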