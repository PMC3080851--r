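#' Constitutive law for the wall springs
#'
#' Springs are tension-only: they develop no force (and store no energy) when
#' their length is at or below the rest length. Under extension the force is
#' either linear in the engineering strain, `f(eps) = k * eps`, or follows the
#' monotone power law `f(eps) = A * eps + B * eps^p` with `p > 1`.
#'
#' The energy of a spring of rest length `L0` is `L0^m * F(eps)` where `F` is
#' the antiderivative of `f` and `m` depends on `form`: `"extension"`
#' (default, `m = 2`) gives the quadratic `(k/2) (L - L0)^2` for linear
#' springs, while `"strain"` (`m = 1`) gives `(k/2) L0 eps^2`. Normalized
#' results (K/K0, moment trajectories) are insensitive to this global
#' prefactor choice.
#'
#' The power-law defaults take `A = k`, `p = 3`, and choose `B` so that the
#' tangent stiffness `f'(eps)` doubles at `eps = 0.3` (i.e. `B = A / (p *
#' 0.3^(p-1))`), a generic stiffening law; force-ranked destruction is
#' insensitive to the particular monotone choice.
#'
#' @param law `"linear"` or `"power"`.
#' @param k linear stiffness (model force units; default 1).
#' @param A,B,p power-law coefficients and exponent (`p > 1`).
#' @param form `"extension"` or `"strain"` energy prefactor (see Details).
#' @return An object of class `"constitutive"`.
#' @examples
#' cp <- constitutive("linear", k = 1)
#' spring_force(c(-0.3, 0, 0.2), cp)   # 0, 0, 0.2
#' @export
constitutive <- function(law = c("linear", "power"), k = 1,
                         A = k, B = NULL, p = 3,
                         form = c("extension", "strain")) {
  law <- match.arg(law)
  form <- match.arg(form)
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("'k' must be a positive scalar")
  if (law == "power") {
    if (!is.numeric(p) || length(p) != 1L || p <= 1)
      stop("'p' must be a scalar > 1")
    if (is.null(B)) B <- A / (p * 0.3^(p - 1))
    if (A < 0 || B <= 0) stop("power law requires A >= 0 and B > 0")
  } else {
    A <- k
    B <- 0
    p <- 2 # unused
  }
  structure(list(law = law, k = k, A = A, B = B, p = p, form = form),
            class = "constitutive")
}

#' @export
print.constitutive <- function(x, ...) {
  if (x$law == "linear") {
    cat(sprintf("Linear tension-only springs: f(eps) = %g * eps (%s form)\n",
                x$k, x$form))
  } else {
    cat(sprintf(
      "Power-law tension-only springs: f(eps) = %g*eps + %g*eps^%g (%s form)\n",
      x$A, x$B, x$p, x$form))
  }
  invisible(x)
}

# L0 exponent implied by the energy form
.law_form_exp <- function(params) if (params$form == "extension") 2L else 1L

#' Spring force as a function of strain
#'
#' The constitutive map from engineering strain to force. Compressive strains
#' give exactly zero force: the walls buckle rather than push back.
#'
#' @param strain numeric vector of engineering strains `(L - L0)/L0`.
#' @param params a [constitutive()] object.
#' @return numeric vector of forces (same length as `strain`).
#' @export
spring_force <- function(strain, params = constitutive()) {
  stopifnot(inherits(params, "constitutive"), is.numeric(strain))
  f <- ifelse(strain > 0,
              params$A * strain +
                if (params$B != 0) params$B * strain^params$p else 0,
              0)
  as.numeric(f)
}

#' Elastic energy stored in one spring
#'
#' Integral of the tension over the extension from rest length `L0` to the
#' current `length`; zero at or below rest length.
#'
#' @param length current spring length (> 0).
#' @param L0 rest length (> 0).
#' @param params a [constitutive()] object.
#' @return numeric vector of stored energies.
#' @export
spring_energy <- function(length, L0, params = constitutive()) {
  stopifnot(inherits(params, "constitutive"))
  if (any(!is.finite(length)) || any(length <= 0) ||
      any(!is.finite(L0)) || any(L0 <= 0))
    stop("'length' and 'L0' must be positive and finite")
  eps <- (length - L0) / L0
  m <- .law_form_exp(params)
  Fa <- ifelse(eps > 0,
               0.5 * params$A * eps^2 +
                 if (params$B != 0)
                   params$B * eps^(params$p + 1) / (params$p + 1) else 0,
               0)
  as.numeric(L0^m * Fa)
}
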