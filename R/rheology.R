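#' Carreau viscosity parameters
#'
#' Constants of the Carreau shear-thinning law
#' \deqn{\mu(s) = \mu_\infty + (\mu_0 - \mu_\infty)\,(1 + (\lambda s)^2)^{(n-1)/2}}
#' which interpolates between the low-shear viscosity `mu0` and the high-shear
#' viscosity `mu_inf`. The defaults are the standard Carreau constants for
#' whole blood.
#'
#' @param mu0 Zero-shear viscosity (Pa s).
#' @param mu_inf Infinite-shear viscosity (Pa s).
#' @param lambda Relaxation time (s).
#' @param n Power index (dimensionless, `0 < n < 1` for shear thinning).
#' @return An object of class `carreau_params`.
#' @examples
#' p <- carreau_params()
#' carreau_viscosity(0, p)     # mu0
#' carreau_viscosity(1e6, p)   # ~ mu_inf
#' @export
carreau_params <- function(mu0 = 0.0456, mu_inf = 0.0032, lambda = 10.03,
                           n = 0.344) {
  stopifnot(is.numeric(mu0), is.numeric(mu_inf), is.numeric(lambda),
            is.numeric(n), length(mu0) == 1L, length(mu_inf) == 1L,
            length(lambda) == 1L, length(n) == 1L)
  if (!(mu_inf > 0) || !(mu0 >= mu_inf))
    stop("require mu0 >= mu_inf > 0")
  if (!(lambda > 0)) stop("require lambda > 0")
  if (!(n > 0) || !(n <= 1)) stop("require 0 < n <= 1")
  structure(list(mu0 = mu0, mu_inf = mu_inf, lambda = lambda, n = n),
            class = "carreau_params")
}

#' Fluid parameters
#'
#' Density and choice of constitutive model. `model = "carreau"` uses the
#' shear-thinning law of [carreau_params()]; `model = "newtonian"` uses the
#' constant viscosity `newtonian_mu`. The constant used for Newtonian
#' comparison runs is selectable (`0.0032` Pa s by default; the zero-shear
#' value `0.0456` is the other natural choice).
#'
#' @param rho Density (kg/m^3).
#' @param model `"carreau"` or `"newtonian"`.
#' @param newtonian_mu Constant viscosity for the Newtonian model (Pa s).
#' @param carreau A [carreau_params()] object.
#' @return An object of class `fluid_params`.
#' @export
fluid_params <- function(rho = 1060, model = c("carreau", "newtonian"),
                         newtonian_mu = 0.0032, carreau = carreau_params()) {
  model <- match.arg(model)
  stopifnot(is.numeric(rho), length(rho) == 1L)
  if (!(rho > 0)) stop("require rho > 0")
  if (!(newtonian_mu > 0)) stop("require newtonian_mu > 0")
  stopifnot(inherits(carreau, "carreau_params"))
  structure(list(rho = rho, model = model, newtonian_mu = newtonian_mu,
                 carreau = carreau),
            class = "fluid_params")
}

#' Symmetric strain-rate tensor
#'
#' `D(u) = (grad u + grad u^T) / 2`.
#'
#' @param grad_u 2x2 velocity-gradient matrix, entry `[i, j] = du_i/dx_j`
#'   (1/s).
#' @return Symmetric 2x2 matrix.
#' @export
strain_rate_tensor <- function(grad_u) {
  grad_u <- as.matrix(grad_u)
  stopifnot(identical(dim(grad_u), c(2L, 2L)), all(is.finite(grad_u)))
  (grad_u + t(grad_u)) / 2
}

#' Shear rate of a velocity gradient
#'
#' `s(u) = sqrt(2 D(u) : D(u))`, the scalar shear-rate measure entering the
#' Carreau law. For a simple shear `du_x/dy = g` this reduces to `|g|`.
#'
#' @inheritParams strain_rate_tensor
#' @return Nonnegative scalar (1/s).
#' @export
shear_rate <- function(grad_u) {
  d <- strain_rate_tensor(grad_u)
  sqrt(2 * sum(d * d))
}

#' Carreau viscosity
#'
#' Evaluates the Carreau law at shear rate `s`. Strictly decreasing in `s`
#' for `n < 1`, with `carreau_viscosity(0, p) == p$mu0` exactly and the
#' high-shear limit `p$mu_inf`.
#'
#' @param s Shear rate(s), 1/s; must be `>= 0`.
#' @param p A [carreau_params()] object.
#' @return Viscosity in Pa s, vectorized over `s`.
#' @export
carreau_viscosity <- function(s, p = carreau_params()) {
  stopifnot(inherits(p, "carreau_params"), is.numeric(s))
  if (any(!is.finite(s)) || any(s < 0)) stop("shear rate must be finite and >= 0")
  p$mu_inf + (p$mu0 - p$mu_inf) * (1 + (p$lambda * s)^2)^((p$n - 1) / 2)
}

#' Apparent viscosity under the configured model
#'
#' Dispatches on `fluid$model`: the Carreau law, or the constant
#' `fluid$newtonian_mu`.
#'
#' @param s Shear rate(s), 1/s.
#' @param fluid A [fluid_params()] object.
#' @return Viscosity in Pa s, vectorized over `s`.
#' @export
apparent_viscosity <- function(s, fluid = fluid_params()) {
  stopifnot(inherits(fluid, "fluid_params"))
  if (fluid$model == "newtonian") {
    if (any(!is.finite(s)) || any(s < 0)) stop("shear rate must be finite and >= 0")
    rep_len(fluid$newtonian_mu, length(s))
  } else {
    carreau_viscosity(s, fluid$carreau)
  }
}
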