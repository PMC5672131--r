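#' Post-crosslinking curvature domain
#'
#' The simulation sweep covers the corneal curvatures reported after
#' accelerated crosslinking in keratoconus: anterior radius 5.6-8.5 mm,
#' posterior radius 4.4-7.0 mm, constrained to k = r1c/r2c in 1.04-1.57
#' (k rounded to 2 decimals before filtering, matching the tabulated
#' resolution).
#'
#' @param r1c_range,r2c_range Length-2 numeric intervals, millimetres.
#' @param k_range Length-2 admissible k-ratio interval.
#' @param step Grid resolution, millimetres.
#' @return An object of class `sweep_domain`.
#' @export
sweep_domain <- function(r1c_range = c(5.6, 8.5), r2c_range = c(4.4, 7.0),
                         k_range = c(1.04, 1.57), step = 0.1) {
  stopifnot(length(r1c_range) == 2, length(r2c_range) == 2,
            length(k_range) == 2, step > 0,
            r1c_range[1] <= r1c_range[2], r2c_range[1] <= r2c_range[2],
            k_range[1] <= k_range[2])
  structure(list(r1c_range = r1c_range, r2c_range = r2c_range,
                 k_range = k_range, step = step),
            class = "sweep_domain")
}

#' Enumerate the admissible (r1c, r2c) grid
#'
#' Cartesian grid at the domain's step, filtered to pairs whose k ratio,
#' rounded to 2 decimals, lies in the k range. Ordering is deterministic:
#' r1c-major ascending, r2c ascending within r1c.
#'
#' @param domain A [sweep_domain()].
#' @return Data frame with columns `r1c`, `r2c`, `k` (unrounded).
#' @examples
#' nrow(enumerate_domain(sweep_domain()))
#' @export
enumerate_domain <- function(domain = sweep_domain()) {
  stopifnot(inherits(domain, "sweep_domain"))
  # seq() accumulates FP error over ~30 steps; round to the grid resolution
  r1 <- round(seq(domain$r1c_range[1], domain$r1c_range[2], by = domain$step), 10)
  r2 <- round(seq(domain$r2c_range[1], domain$r2c_range[2], by = domain$step), 10)
  g <- expand.grid(r2c = r2, r1c = r1)[, c("r1c", "r2c")]
  k <- g$r1c / g$r2c
  keep <- round(k, 2) >= domain$k_range[1] & round(k, 2) <= domain$k_range[2]
  if (!any(keep)) stop("empty domain after k-ratio filtering", call. = FALSE)
  out <- data.frame(r1c = g$r1c[keep], r2c = g$r2c[keep], k = k[keep])
  rownames(out) <- NULL
  out
}

#' Band-corner evaluation grid
#'
#' Every grid anterior radius of each calibration band crossed with that
#' band's two posterior-radius extremes. This is the scheme on which the
#' published per-band ranges and the reported keratometric-error extremes
#' were evaluated (all printed extreme arg-pairs are corners of it).
#'
#' @inheritParams default_bands
#' @return Data frame with columns `band`, `r1c`, `r2c`.
#' @export
band_corner_grid <- function(model, grid_step = 0.1) {
  b <- default_bands(model, grid_step)
  out <- do.call(rbind, lapply(seq_len(nrow(b)), function(i) {
    r1 <- round(seq(b$r1c_min[i], b$r1c_max[i], by = grid_step), 10)
    cbind(band = b$band[i], expand.grid(r1c = r1, r2c = c(b$r2c_lo[i], b$r2c_hi[i])))
  }))
  rownames(out) <- NULL
  out
}

#' Extremes of the keratometric error over the simulation domain
#'
#' Exhaustively scans for the minimum and maximum of
#' delta_Pc = Pk(nk) - Pc_Gauss. Two schemes are exposed because the study
#' domain can be read either way: `"band_corners"` (default) evaluates the
#' per-band corner grid of [band_corner_grid()], which is what the published
#' extreme values correspond to; `"rectangle"` scans the full k-filtered
#' Cartesian grid of [enumerate_domain()]. Grid points whose error lies
#' within `tie_tol` of an extreme are reported as ties (the published
#' extremes are themselves tied across neighbouring anterior radii).
#'
#' @param nk Keratometric index to evaluate.
#' @inheritParams gaussian_power
#' @param scheme Evaluation domain, see Details.
#' @param domain A [sweep_domain()], used by the `"rectangle"` scheme.
#' @param tie_tol Tolerance for collecting tied arg pairs, dioptres
#'   (default 0.05, half the printed 0.1 D resolution).
#' @return List with `min`, `max` (dioptres), and data frames `argmin`,
#'   `argmax` of the tied `(r1c, r2c)` pairs.
#' @examples
#' delta_pc_extremes(1.3375, "gullstrand")$max  # 3.2 D at (6.8, 4.4)
#' @export
delta_pc_extremes <- function(nk, model,
                              scheme = c("band_corners", "rectangle"),
                              domain = sweep_domain(), tie_tol = 0.05) {
  scheme <- match.arg(scheme)
  grid <- if (scheme == "band_corners") {
    band_corner_grid(model, domain$step)
  } else {
    enumerate_domain(domain)
  }
  d <- delta_pc(grid$r1c, grid$r2c, nk, model)
  list(min = min(d), max = max(d),
       argmin = grid[d <= min(d) + tie_tol, c("r1c", "r2c")],
       argmax = grid[d >= max(d) - tie_tol, c("r1c", "r2c")])
}

#' Simulation summary table for one eye model
#'
#' Rebuilds the published per-band summary: for each calibration band,
#' the k interval, the fitted linear adjusted-index algorithm, and the
#' ranges of nk_adj, nk_exact, Pc_Gauss, Pk_adj and delta_Pc =
#' Pk_adj - Pc_Gauss over the band's corner scheme (every grid r1c crossed
#' with the band's two posterior-radius extremes).
#'
#' @inheritParams default_bands
#' @return A data frame of class `simulation_table`, one row per band, with
#'   the band definition, rounded display coefficients (`slope` 5 dp,
#'   `intercept` 4 dp), and `*_min`/`*_max` columns for each quantity
#'   (indices to 4 dp, powers to 1 dp).
#' @examples
#' build_table("gullstrand")
#' @export
build_table <- function(model, grid_step = 0.1) {
  model <- eye_model(model)
  bands <- default_bands(model, grid_step)
  rows <- lapply(seq_len(nrow(bands)), function(i) {
    b <- bands[i, ]
    r1 <- round(seq(b$r1c_min, b$r1c_max, by = grid_step), 10)
    na <- nk_adj_from_extremes(r1, b$r2c_lo, b$r2c_hi, model)
    pkadj <- (na - 1) / mm_to_m(r1)
    corners <- expand.grid(r1c = r1, r2c = c(b$r2c_lo, b$r2c_hi))
    ne <- nk_exact(corners$r1c, corners$r2c, model)
    pg <- gaussian_power(corners$r1c, corners$r2c, model)
    dpc <- rep(pkadj, 2) - pg
    data.frame(
      model = model$name, band = b$band,
      r1c_min = b$r1c_min, r1c_max = b$r1c_max,
      k_min = b$k_min, k_max = b$k_max,
      slope = round(b$slope, 5), intercept = round(b$intercept, 4),
      nk_adj_min = round(min(na), 4), nk_adj_max = round(max(na), 4),
      nk_exact_min = round(min(ne), 4), nk_exact_max = round(max(ne), 4),
      pc_gauss_min = round(min(pg), 1), pc_gauss_max = round(max(pg), 1),
      pk_adj_min = round(min(pkadj), 1), pk_adj_max = round(max(pkadj), 1),
      delta_pc_min = round(min(dpc), 1), delta_pc_max = round(max(dpc), 1))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("simulation_table", "data.frame")
  out
}

#' Render a simulation table as Markdown
#'
#' @param table A `simulation_table` from [build_table()].
#' @return Character vector of Markdown lines.
#' @export
format_table_markdown <- function(table) {
  fmt_iv <- function(lo, hi, dp) sprintf("[%.*f, %.*f]", dp, lo, dp, hi)
  hdr <- c("| r1c (mm) | k | nk_adj algorithm | nk_adj | nk_exact | PcGauss (D) | Pkadj (D) | dPc (D) |",
           "|---|---|---|---|---|---|---|---|")
  body <- vapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    sprintf("| %s | %s | %.5f r1c + %.4f | %s | %s | %s | %s | %s |",
            fmt_iv(r$r1c_min, r$r1c_max, 1), fmt_iv(r$k_min, r$k_max, 2),
            r$slope, r$intercept,
            fmt_iv(r$nk_adj_min, r$nk_adj_max, 4),
            fmt_iv(r$nk_exact_min, r$nk_exact_max, 4),
            fmt_iv(r$pc_gauss_min, r$pc_gauss_max, 1),
            fmt_iv(r$pk_adj_min, r$pk_adj_max, 1),
            fmt_iv(r$delta_pc_min, r$delta_pc_max, 1))
  }, character(1))
  c(hdr, body)
}
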