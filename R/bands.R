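#' Calibration bands for the adjusted keratometric index
#'
#' The adjusted index n_k_adj is calibrated over three anterior-radius bands,
#' each paired with fixed posterior-radius extremes that bound the post-CXL
#' k-ratio domain. The banding is identical for both schematic eye models:
#'
#' | band | r1c (mm)     | r2c extremes (mm) | k interval    |
#' |------|--------------|-------------------|---------------|
#' | 1    | 5.6 to 6.8   | 4.4, 5.4          | 1.04 to 1.55  |
#' | 2    | 6.9 to 7.2   | 4.8, 6.0          | 1.15 to 1.50  |
#' | 3    | 7.3 to 8.5   | 5.4, 7.0          | 1.04 to 1.57  |
#'
#' Within each band n_k_adj is exactly linear in r1c, so each row also
#' carries the fitted slope and intercept (exact, unrounded).
#'
#' @param model An [eye_model()] or its name.
#' @param grid_step Grid resolution in millimetres for the linear fit
#'   (default 0.1 mm; the fit is grid-independent because the relation is
#'   exactly linear).
#' @return A data frame of class `calibration_bands` with one row per band:
#'   `model`, `band`, `r1c_min`, `r1c_max`, `r2c_lo`, `r2c_hi`, `k_min`,
#'   `k_max`, `slope`, `intercept`, `r_squared`.
#' @examples
#' default_bands("gullstrand")
#' @export
default_bands <- function(model, grid_step = 0.1) {
  model <- eye_model(model)
  spec <- data.frame(
    band = 1:3,
    r1c_min = c(5.6, 6.9, 7.3), r1c_max = c(6.8, 7.2, 8.5),
    r2c_lo  = c(4.4, 4.8, 5.4), r2c_hi  = c(5.4, 6.0, 7.0))
  fits <- lapply(seq_len(nrow(spec)), function(i) {
    b <- spec[i, ]
    fit_band_algorithm(b$r1c_min, b$r1c_max, b$r2c_lo, b$r2c_hi,
                       model, grid_step)
  })
  out <- cbind(
    model = model$name, spec,
    k_min = round(spec$r1c_min / spec$r2c_hi, 2),
    k_max = round(spec$r1c_max / spec$r2c_lo, 2),
    do.call(rbind, lapply(fits, as.data.frame)))
  class(out) <- c("calibration_bands", "data.frame")
  out
}

#' Adjusted keratometric index from posterior-radius extremes
#'
#' For a given anterior radius, the adjusted index is defined by requiring
#' the keratometric error to have equal magnitude and opposite sign at the
#' two posterior-radius extremes of the band:
#' delta_Pc(r2c_lo) = -delta_Pc(r2c_hi). Equivalently the keratometric power
#' must hit the midpoint of the two Gaussian powers, so
#' nk_adj = 1 + r1c * (Pc_Gauss(r2c_lo) + Pc_Gauss(r2c_hi)) / 2 (r1c in
#' metres).
#'
#' @param r1c Anterior radius, millimetres. Vectorised.
#' @param r2c_lo,r2c_hi Posterior-radius extremes, millimetres
#'   (`r2c_lo <= r2c_hi`).
#' @inheritParams gaussian_power
#' @return Dimensionless adjusted index.
#' @examples
#' nk_adj_from_extremes(5.6, 4.4, 5.4, "gullstrand")  # 1.3309
#' @export
nk_adj_from_extremes <- function(r1c, r2c_lo, r2c_hi, model, e_c = NULL) {
  if (any(r2c_lo > r2c_hi))
    stop("r2c_lo must not exceed r2c_hi", call. = FALSE)
  mid <- (gaussian_power(r1c, r2c_lo, model, e_c) +
          gaussian_power(r1c, r2c_hi, model, e_c)) / 2
  1 + mm_to_m(r1c) * mid
}

#' Fit the linear adjusted-index algorithm of one band
#'
#' Ordinary least squares of `nk_adj_from_extremes()` against r1c (mm) over
#' the band's 0.1 mm grid. Because the midpoint index is exactly linear in
#' r1c, the fit is perfect (R^2 = 1 to machine precision) and the
#' coefficients have a closed form: slope = (P2c(r2c_lo) + P2c(r2c_hi))/2 in
#' index per metre, rescaled to per-mm.
#'
#' @param r1c_min,r1c_max Band limits, millimetres.
#' @param r2c_lo,r2c_hi Posterior-radius extremes, millimetres.
#' @inheritParams default_bands
#' @param e_c Optional thickness override, millimetres.
#' @return List with `slope` (index per mm), `intercept` (index),
#'   `r_squared`, and `max_resid` (largest absolute fit residual).
#' @export
fit_band_algorithm <- function(r1c_min, r1c_max, r2c_lo, r2c_hi, model,
                               grid_step = 0.1, e_c = NULL) {
  r1 <- seq(r1c_min, r1c_max, by = grid_step)
  if (length(r1) < 2) stop("band grid has fewer than 2 points", call. = FALSE)
  y <- nk_adj_from_extremes(r1, r2c_lo, r2c_hi, model, e_c)
  fit <- stats::lm(y ~ r1)
  resid <- stats::resid(fit)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = 1 - sum(resid^2) / ss_tot,
       max_resid = max(abs(resid)))
}

#' Piecewise adjusted keratometric index and power
#'
#' Evaluates the three-band linear algorithm for the adjusted index at a
#' given anterior radius, then the adjusted keratometric power
#' Pk_adj = (nk_adj - 1)/r1c. Exact (unrounded) band coefficients are used
#' by default; `use_printed = TRUE` evaluates the published 5/4-decimal
#' roundings instead, which can differ by one unit in the fourth index
#' decimal.
#'
#' Band assignment between tabulated rows uses the half-open midpoint rule:
#' band 1 for r1c < 6.85 mm, band 2 for 6.85 <= r1c < 7.25 mm, band 3
#' otherwise. Radii outside 5.6-8.5 mm are an error unless
#' `extrapolate = TRUE`, in which case the nearest band's line is extended
#' and the result flagged.
#'
#' @param r1c Anterior radius, millimetres. Vectorised.
#' @inheritParams default_bands
#' @param extrapolate Allow evaluation outside the calibrated 5.6-8.5 mm
#'   domain using the nearest band.
#' @param use_printed Use table-rounded coefficients (5 dp slope, 4 dp
#'   intercept) instead of exact ones.
#' @return Data frame with columns `r1c`, `band`, `nk_adj`, `pk_adj`,
#'   `extrapolated`.
#' @examples
#' nk_adj_piecewise(6.8, "gullstrand")  # nk_adj 1.3210, pk_adj 47.2 D
#' @export
nk_adj_piecewise <- function(r1c, model, extrapolate = FALSE,
                             use_printed = FALSE) {
  .check_radius(r1c, "r1c")
  bands <- default_bands(model)
  outside <- r1c < min(bands$r1c_min) | r1c > max(bands$r1c_max)
  if (any(outside) && !extrapolate)
    stop("r1c outside the calibrated domain [",
         min(bands$r1c_min), ", ", max(bands$r1c_max),
         "] mm: ", paste(format(r1c[outside]), collapse = ", "),
         "; set extrapolate = TRUE to extend the nearest band",
         call. = FALSE)
  band <- assign_band(r1c)
  slope <- bands$slope[band]
  intercept <- bands$intercept[band]
  if (use_printed) {
    slope <- round(slope, 5)
    intercept <- round(intercept, 4)
  }
  nk_adj <- slope * r1c + intercept
  data.frame(r1c = r1c, band = band, nk_adj = nk_adj,
             pk_adj = (nk_adj - 1) / mm_to_m(r1c),
             extrapolated = outside)
}

#' Band assignment for a continuous anterior radius
#'
#' Half-open midpoint rule over the tabulated 0.1 mm rows: band 1 below
#' 6.85 mm, band 2 in [6.85, 7.25) mm, band 3 at or above 7.25 mm.
#'
#' @param r1c Anterior radius, millimetres. Vectorised.
#' @return Integer band id (1, 2 or 3).
#' @export
assign_band <- function(r1c) {
  ifelse(r1c < 6.85, 1L, ifelse(r1c < 7.25, 2L, 3L))
}

#' Export or import calibration bands as CSV
#'
#' The CSV carries `model, band, r1c_min, r1c_max, r2c_lo, r2c_hi, k_min,
#' k_max, slope, intercept` so the published coefficients can be loaded
#' verbatim instead of refit.
#'
#' @param bands A `calibration_bands` data frame.
#' @param path File path.
#' @return `write_bands` returns `path` invisibly; `read_bands` returns a
#'   `calibration_bands` data frame.
#' @export
write_bands <- function(bands, path) {
  cols <- c("model", "band", "r1c_min", "r1c_max", "r2c_lo", "r2c_hi",
            "k_min", "k_max", "slope", "intercept")
  utils::write.csv(as.data.frame(bands)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bands
#' @export
read_bands <- function(path) {
  out <- utils::read.csv(path)
  need <- c("model", "band", "r1c_min", "r1c_max", "r2c_lo", "r2c_hi",
            "slope", "intercept")
  missing <- setdiff(need, names(out))
  if (length(missing))
    stop("bands CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  class(out) <- c("calibration_bands", "data.frame")
  out
}
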