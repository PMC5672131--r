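#' Keratometric corneal power
#'
#' The single-surface power estimate used by keratometers and topographers:
#' Pk = (n_k - 1) / r1c, with the anterior radius in metres. The fictitious
#' keratometric index n_k (conventionally 1.3375) stands in for the optical
#' effect of the posterior surface and corneal thickness.
#'
#' @param r1c Anterior corneal radius, millimetres. Vectorised.
#' @param nk Keratometric refractive index (1 < nk < 1.5).
#' @return Power in dioptres.
#' @examples
#' keratometric_power(7.5, 1.3375)  # 45 D
#' @export
keratometric_power <- function(r1c, nk) {
  .check_radius(r1c, "r1c")
  stopifnot(is.numeric(nk), all(nk > 1), all(nk < 1.5))
  (nk - 1) / mm_to_m(r1c)
}

#' Gaussian thick-lens corneal power
#'
#' Total paraxial power of the cornea as a thick lens in air:
#' P = P1c + P2c - (e_c / n_c) * P1c * P2c, with
#' P1c = (n_c - n_a)/r1c and P2c = (n_ha - n_c)/r2c (radii and thickness in
#' metres). This is the reference standard against which keratometric
#' estimates are judged.
#'
#' @param r1c,r2c Anterior and posterior corneal radii, millimetres.
#'   Vectorised (recycled to common length).
#' @param model An [eye_model()] or its name.
#' @param e_c Central corneal thickness in millimetres; `NULL` (default) uses
#'   the model's nominal thickness.
#' @param decompose If `TRUE` return a data frame with columns `p1c`, `p2c`
#'   and `pc_gauss`; otherwise just the total power vector.
#' @return Dioptres, or a data frame when `decompose = TRUE`.
#' @examples
#' gaussian_power(7.7, 6.8, "gullstrand")
#' @export
gaussian_power <- function(r1c, r2c, model, e_c = NULL, decompose = FALSE) {
  model <- eye_model(model)
  .check_radius(r1c, "r1c")
  .check_radius(r2c, "r2c")
  ec_m <- mm_to_m(.resolve_ec_mm(e_c, model))
  if (any(ec_m < 0)) stop("corneal thickness must be >= 0", call. = FALSE)
  p1c <- (model$n_c - model$n_a) / mm_to_m(r1c)
  p2c <- (model$n_ha - model$n_c) / mm_to_m(r2c)
  pc <- p1c + p2c - (ec_m / model$n_c) * p1c * p2c
  if (decompose) data.frame(p1c = p1c, p2c = p2c, pc_gauss = pc) else pc
}

#' Full power decomposition for one or more geometries
#'
#' Evaluates both the keratometric and Gaussian powers and their difference
#' for a given keratometric index.
#'
#' @inheritParams gaussian_power
#' @param nk Keratometric index used for the keratometric power.
#' @return Data frame with columns `r1c`, `r2c`, `p1c`, `p2c`, `pc_gauss`,
#'   `pk`, `delta_pc` and `nk_used`.
#' @export
power_decomposition <- function(r1c, r2c, nk, model, e_c = NULL) {
  model <- eye_model(model)
  dec <- gaussian_power(r1c, r2c, model, e_c, decompose = TRUE)
  pk <- keratometric_power(r1c, nk)
  data.frame(r1c = r1c, r2c = r2c, dec, pk = pk,
             delta_pc = pk - dec$pc_gauss, nk_used = nk)
}

#' Anterior-to-posterior corneal radius ratio
#'
#' k = r1c / r2c. Near 1.2 in normal corneas; keratoconus and crosslinking
#' push it across roughly 1.04-1.57.
#'
#' @param r1c,r2c Radii in consistent units (conventionally millimetres).
#' @return Dimensionless ratio.
#' @export
k_ratio <- function(r1c, r2c) {
  if (any(!is.finite(r2c)) || any(r2c == 0))
    stop("r2c must be finite and non-zero", call. = FALSE)
  r1c / r2c
}

#' Keratometric error
#'
#' Difference between the keratometric and Gaussian corneal powers,
#' delta_Pc = Pk(nk) - Pc_Gauss. Positive values mean keratometry
#' overestimates the true (Gaussian) power.
#'
#' @inheritParams power_decomposition
#' @return Dioptres.
#' @examples
#' delta_pc(6.8, 4.4, 1.3375, "gullstrand")  # about +3.2 D
#' @export
delta_pc <- function(r1c, r2c, nk, model, e_c = NULL) {
  keratometric_power(r1c, nk) - gaussian_power(r1c, r2c, model, e_c)
}

#' @describeIn delta_pc The algebraically identical k-ratio form, taking the
#'   anterior radius and k = r1c/r2c instead of the posterior radius.
#' @param k Anterior-to-posterior radius ratio.
#' @export
delta_pc_kratio <- function(r1c, k, nk, model, e_c = NULL) {
  delta_pc(r1c, r1c / k, nk, model, e_c)
}

#' Exact keratometric index
#'
#' The unique keratometric index for which the keratometric power equals the
#' Gaussian power of the same cornea: nk_exact = 1 + r1c * Pc_Gauss with r1c
#' in metres. Computed through this identity (numerically stable); the
#' equivalent closed-form radical expression is available as an internal
#' cross-check.
#'
#' @inheritParams gaussian_power
#' @return Dimensionless refractive index, vectorised.
#' @examples
#' nk_exact(8.5, 5.4, "gullstrand")  # 1.3140
#' @export
nk_exact <- function(r1c, r2c, model, e_c = NULL) {
  1 + mm_to_m(r1c) * gaussian_power(r1c, r2c, model, e_c)
}

# Literal closed form of nk_exact over the common denominator n_c * r2c:
#   nk = 1 + (n_c - n_a) + (n_ha - n_c) (n_c r1c - e_c (n_c - n_a)) / (n_c r2c)
# Algebraically identical to 1 + r1c * Pc_Gauss; kept as a distinct expansion
# so tests can cross-check the two routes.
.nk_exact_radical <- function(r1c, r2c, model, e_c = NULL) {
  model <- eye_model(model)
  ec <- mm_to_m(.resolve_ec_mm(e_c, model))
  r1 <- mm_to_m(r1c); r2 <- mm_to_m(r2c)
  nc <- model$n_c; nha <- model$n_ha; na <- model$n_a
  1 + (nc - na) + (nha - nc) * (nc * r1 - ec * (nc - na)) / (nc * r2)
}

.check_radius <- function(r, what) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0))
    stop(what, " must be finite and positive (millimetres)", call. = FALSE)
  invisible(r)
}
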