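#' Schematic eye models
#'
#' The corneal subsystem of a theoretical (schematic) eye supplies the
#' refractive indices of air, cornea and aqueous humor plus a nominal central
#' corneal thickness. Two classical models are built in: Gullstrand
#' (n_c = 1.376, n_ha = 1.336, e_c = 0.5 mm, classical keratometric index
#' 1.3315) and Le Grand (n_c = 1.3771, n_ha = 1.3374, e_c = 0.55 mm,
#' classical index 1.3304). Constants are loaded from a plain-text key/value
#' file shipped with the package so alternate models can be registered
#' without code changes; the two built-ins are immutable.
#'
#' @param name Model name, one of `"gullstrand"` or `"legrand"` (or a name
#'   previously added with [register_eye_model()]). Case-insensitive.
#' @return An object of class `eye_model`: a list with fields `name`, `n_a`,
#'   `n_c`, `n_ha`, `e_c_model` (metres) and `n_k_classic`.
#' @examples
#' eye_model("gullstrand")$n_k_classic  # 1.3315
#' eye_model("legrand")$n_c             # 1.3771
#' @export
eye_model <- function(name) {
  if (inherits(name, "eye_model")) return(name)
  stopifnot(is.character(name), length(name) == 1L)
  key <- tolower(trimws(name))
  reg <- .eye_model_registry()
  if (!key %in% names(reg)) {
    stop("unsupported eye model '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[key]]
}

#' List the registered schematic eye models
#' @return Character vector of model names.
#' @export
list_eye_models <- function() names(.eye_model_registry())

#' Register an additional schematic eye model
#'
#' The built-in Gullstrand and Le Grand models cannot be overwritten.
#'
#' @param name Model name.
#' @param n_c,n_ha Corneal and aqueous-humor refractive indices
#'   (1 < n_ha < n_c < 1.5).
#' @param e_c_model_mm Nominal central corneal thickness in millimetres.
#' @param n_k_classic The model's classical keratometric index.
#' @param n_a Refractive index of the first medium (air), fixed at 1.
#' @return The new `eye_model`, invisibly.
#' @export
register_eye_model <- function(name, n_c, n_ha, e_c_model_mm, n_k_classic,
                               n_a = 1.0) {
  key <- tolower(trimws(name))
  if (key %in% c("gullstrand", "legrand"))
    stop("built-in model '", key, "' is immutable", call. = FALSE)
  m <- .make_eye_model(key, n_a, n_c, n_ha, e_c_model_mm, n_k_classic)
  reg <- .eye_model_registry()
  reg[[key]] <- m
  assign("registry", reg, envir = .kp_state)
  invisible(m)
}

.kp_state <- new.env(parent = emptyenv())

.eye_model_registry <- function() {
  if (!exists("registry", envir = .kp_state)) {
    path <- system.file("extdata", "eye_models.dcf", package = "keratopower")
    raw <- read.dcf(path)
    reg <- list()
    for (i in seq_len(nrow(raw))) {
      r <- as.list(raw[i, ])
      reg[[r$name]] <- .make_eye_model(
        r$name, as.numeric(r$n_a), as.numeric(r$n_c), as.numeric(r$n_ha),
        as.numeric(r$e_c_model_mm), as.numeric(r$n_k_classic))
    }
    assign("registry", reg, envir = .kp_state)
  }
  get("registry", envir = .kp_state)
}

.make_eye_model <- function(name, n_a, n_c, n_ha, e_c_model_mm, n_k_classic) {
  stopifnot(n_a == 1.0, 1 < n_ha, n_ha < n_c, n_c < 1.5,
            e_c_model_mm > 0, e_c_model_mm < 1)
  structure(list(name = name, n_a = n_a, n_c = n_c, n_ha = n_ha,
                 e_c_model = mm_to_m(e_c_model_mm),
                 n_k_classic = n_k_classic),
            class = "eye_model")
}

#' @export
print.eye_model <- function(x, ...) {
  cat(sprintf("Schematic eye model '%s'\n", x$name))
  cat(sprintf("  n_a = %.4f, n_c = %.4f, n_ha = %.4f\n", x$n_a, x$n_c, x$n_ha))
  cat(sprintf("  e_c = %.3f mm, classical n_k = %.4f\n",
              m_to_mm(x$e_c_model), x$n_k_classic))
  invisible(x)
}

#' Unit conversions for ocular lengths
#'
#' Radii and thicknesses are accepted in millimetres (pachymetry in
#' micrometres) at every interface and converted to metres internally, so
#' powers are always dioptres (m^-1).
#'
#' @param x Numeric vector of lengths.
#' @return Converted numeric vector.
#' @export
mm_to_m <- function(x) x / 1000

#' @rdname mm_to_m
#' @export
m_to_mm <- function(x) x * 1000

#' @rdname mm_to_m
#' @export
um_to_m <- function(x) x / 1e6

#' @rdname mm_to_m
#' @export
um_to_mm <- function(x) x / 1000

#' One eye's corneal geometry
#'
#' Bundles the anterior radius, posterior radius and central thickness of a
#' single cornea with validation. The k ratio r1c/r2c is the anterior-to-
#' posterior radius ratio that keratoconus and crosslinking alter.
#'
#' @param r1c Anterior corneal radius, millimetres.
#' @param r2c Posterior corneal radius, millimetres.
#' @param e_c Central corneal thickness, millimetres; `NULL` defers to the
#'   eye model's nominal thickness at power-computation time.
#' @return An object of class `corneal_geometry`.
#' @examples
#' g <- corneal_geometry(7.1, 5.6, 0.488)
#' g$k  # 1.268
#' @export
corneal_geometry <- function(r1c, r2c, e_c = NULL) {
  stopifnot(is.numeric(r1c), is.numeric(r2c), length(r1c) == length(r2c))
  if (any(!is.finite(r1c)) || any(!is.finite(r2c)) ||
      any(r1c <= 0) || any(r2c <= 0))
    stop("corneal radii must be finite and positive", call. = FALSE)
  if (!is.null(e_c)) {
    stopifnot(is.numeric(e_c))
    if (any(e_c < 0)) stop("corneal thickness must be >= 0", call. = FALSE)
  }
  structure(list(r1c = r1c, r2c = r2c, e_c = e_c, k = r1c / r2c),
            class = "corneal_geometry")
}

# Resolve thickness in mm: per-eye value when given, else the model nominal.
.resolve_ec_mm <- function(e_c, model) {
  if (is.null(e_c)) m_to_mm(model$e_c_model) else e_c
}
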