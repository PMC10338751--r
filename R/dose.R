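# Planar dose surrogate and gamma analysis.
#
# Spots are 2D Gaussians at the isocenter plane; a layer's (or plan's)
# dose surrogate is the MU-weighted superposition of normalized bivariate
# Gaussians evaluated at pixel centers, in arbitrary units proportional
# to MU-weighted fluence. Planned and reconstructed maps live on the same
# grid and are compared by signed dose difference and by global-gamma
# analysis (dose difference normalized to the reference-map maximum,
# distance-to-agreement in mm).

#' Construct a planar dose grid
#'
#' @param values Numeric matrix of dose surrogate values; rows index x,
#'   columns index y.
#' @param origin_mm Length-2 numeric: (x, y) of the first pixel center.
#' @param spacing_mm Pixel pitch (mm), one scalar for both axes.
#' @param signed Logical; difference grids are signed, dose grids are not.
#' @return A `dose_grid` object.
#' @export
dose_grid <- function(values, origin_mm, spacing_mm, signed = FALSE) {
  if (!is.matrix(values) || !is.numeric(values) || !all(is.finite(values))) {
    qa_abort("dose grid values must be a finite numeric matrix", "qa_domain_error")
  }
  if (!signed && any(values < 0)) {
    qa_abort("dose grid values must be non-negative", "qa_domain_error")
  }
  if (length(spacing_mm) != 1 || spacing_mm <= 0) {
    qa_abort("spacing must be a single positive number", "qa_domain_error")
  }
  structure(list(values = values, origin_mm = as.numeric(origin_mm),
                 spacing_mm = as.numeric(spacing_mm), signed = signed),
            class = "dose_grid")
}

grid_axes <- function(grid) {
  list(x = grid$origin_mm[1] + (seq_len(nrow(grid$values)) - 1) * grid$spacing_mm,
       y = grid$origin_mm[2] + (seq_len(ncol(grid$values)) - 1) * grid$spacing_mm)
}

same_geometry <- function(a, b) {
  all(dim(a$values) == dim(b$values)) &&
    isTRUE(all.equal(a$origin_mm, b$origin_mm, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$spacing_mm, b$spacing_mm, tolerance = 1e-9))
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid%s> %d x %d px, %.3g mm pitch, origin (%.4g, %.4g) mm, max %.4g\n",
              if (x$signed) " (signed)" else "", nrow(x$values), ncol(x$values),
              x$spacing_mm, x$origin_mm[1], x$origin_mm[2], max(x$values)))
  invisible(x)
}

#' @method as_tibble dose_grid
#' @export
as_tibble.dose_grid <- function(x, ...) {
  ax <- grid_axes(x)
  tibble(x_mm = rep(ax$x, times = length(ax$y)),
         y_mm = rep(ax$y, each = length(ax$x)),
         value = as.vector(x$values))
}

#' MU-weighted Gaussian fluence map of a spot list
#'
#' Sums `mu * N2((x, y); (x_i, y_i), diag(sigma_x^2, sigma_y^2))` over
#' spots at pixel centers, so the integral of one spot's map (sum times
#' pixel area) equals its MU. Sigmas come from spot columns when present
#' (`sigma_x_mm`/`sigma_y_mm`), else from the commissioning baseline at
#' each spot's energy and the field's gantry angle.
#'
#' @param spots Plan or session tibble (one or more layers; layer maps
#'   are summed).
#' @param baseline Optional [size_baseline()] supplying sigmas for
#'   planned spots.
#' @param spacing_mm Pixel pitch. Default 2 mm.
#' @param grid Optional `dose_grid` (or list with `origin_mm`,
#'   `spacing_mm` and `dim`) fixing the geometry; it must cover every
#'   spot's 3-sigma footprint. Default: auto grid covering all spots
#'   +/- 4 sigma.
#' @return A `dose_grid`.
#' @export
fluence_map <- function(spots, baseline = NULL, spacing_mm = 2, grid = NULL) {
  check_spot_frame(spots, c("x_mm", "y_mm", "mu", "energy_MeV"), "spots")
  if (nrow(spots) == 0) qa_abort("no spots to map", "qa_domain_error")
  spots <- as_tibble(spots)

  if (!("sigma_x_mm" %in% names(spots)) || all(is.na(spots$sigma_x_mm))) {
    if (is.null(baseline)) {
      qa_abort("spots carry no sizes and no baseline was given", "qa_domain_error")
    }
    ang <- if ("gantry_angle_deg" %in% names(spots)) spots$gantry_angle_deg else 0
    sg <- t(vapply(seq_len(nrow(spots)), function(i) {
      baseline_sigma(baseline, spots$energy_MeV[i], ang[i])
    }, numeric(2)))
    spots$sigma_x_mm <- sg[, 1]
    spots$sigma_y_mm <- sg[, 2]
  }
  if (any(!is.finite(spots$sigma_x_mm)) || any(spots$sigma_x_mm <= 0) ||
      any(!is.finite(spots$sigma_y_mm)) || any(spots$sigma_y_mm <= 0)) {
    qa_abort("all spot sigmas must be positive", "qa_domain_error")
  }

  if (is.null(grid)) {
    pad <- 4
    x0 <- floor(min(spots$x_mm - pad * spots$sigma_x_mm) / spacing_mm) * spacing_mm
    x1 <- ceiling(max(spots$x_mm + pad * spots$sigma_x_mm) / spacing_mm) * spacing_mm
    y0 <- floor(min(spots$y_mm - pad * spots$sigma_y_mm) / spacing_mm) * spacing_mm
    y1 <- ceiling(max(spots$y_mm + pad * spots$sigma_y_mm) / spacing_mm) * spacing_mm
    dims <- c(round((x1 - x0) / spacing_mm) + 1, round((y1 - y0) / spacing_mm) + 1)
    origin <- c(x0, y0)
  } else {
    origin <- grid$origin_mm
    spacing_mm <- grid$spacing_mm
    dims <- if (inherits(grid, "dose_grid")) dim(grid$values) else grid$dim
    xmax <- origin[1] + (dims[1] - 1) * spacing_mm
    ymax <- origin[2] + (dims[2] - 1) * spacing_mm
    covered <- all(spots$x_mm - 3 * spots$sigma_x_mm >= origin[1]) &&
      all(spots$x_mm + 3 * spots$sigma_x_mm <= xmax) &&
      all(spots$y_mm - 3 * spots$sigma_y_mm >= origin[2]) &&
      all(spots$y_mm + 3 * spots$sigma_y_mm <= ymax)
    if (!covered) {
      qa_abort("grid does not cover every spot's 3-sigma footprint", "qa_domain_error")
    }
  }

  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing_mm
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing_mm
  vals <- matrix(0, dims[1], dims[2])
  for (i in seq_len(nrow(spots))) {
    gx <- stats::dnorm(xs, spots$x_mm[i], spots$sigma_x_mm[i])
    gy <- stats::dnorm(ys, spots$y_mm[i], spots$sigma_y_mm[i])
    vals <- vals + spots$mu[i] * outer(gx, gy)
  }
  dose_grid(vals, origin, spacing_mm)
}

#' Signed dose difference between two grids
#'
#' @param reference,evaluated `dose_grid`s on identical geometry.
#' @return A signed `dose_grid` of `evaluated - reference`.
#' @export
dose_difference <- function(reference, evaluated) {
  stopifnot(inherits(reference, "dose_grid"), inherits(evaluated, "dose_grid"))
  if (!same_geometry(reference, evaluated)) {
    qa_abort("dose grids have different geometry", "qa_domain_error")
  }
  dose_grid(evaluated$values - reference$values, reference$origin_mm,
            reference$spacing_mm, signed = TRUE)
}

#' Gamma analysis criteria
#'
#' @param dose_percent Dose-difference criterion, percent of the global
#'   (reference-map maximum) normalization. Default 3.
#' @param dta_mm Distance-to-agreement criterion (mm). Default 3.
#' @param low_dose_threshold_percent Reference pixels below this percent
#'   of the reference maximum are excluded. Default 10.
#' @param pass_threshold_percent Acceptance line on the pass rate.
#'   Default 90.
#' @return A `gamma_criteria` object.
#' @export
gamma_criteria <- function(dose_percent = 3, dta_mm = 3,
                           low_dose_threshold_percent = 10,
                           pass_threshold_percent = 90) {
  cr <- list(dose_percent = dose_percent, dta_mm = dta_mm,
             low_dose_threshold_percent = low_dose_threshold_percent,
             pass_threshold_percent = pass_threshold_percent)
  if (any(vapply(cr, function(v) !is.numeric(v) || length(v) != 1 || v <= 0, logical(1)))) {
    qa_abort("gamma criteria must be single positive numbers", "qa_domain_error")
  }
  structure(cr, class = "gamma_criteria")
}

# offsets of the gamma search lattice: step dta/10 within radius 3*dta
gamma_offsets <- function(dta_mm) {
  step <- dta_mm / 10
  g <- seq(-30, 30) * step
  off <- expand.grid(dx = g, dy = g)
  off <- off[off$dx^2 + off$dy^2 <= (3 * dta_mm)^2 + 1e-12, ]
  off
}

# bilinear interpolation of matrix `m` (pixel coords) at a constant
# fractional shift (fx, fy); NA outside the grid
shift_bilinear <- function(m, fx, fy) {
  nr <- nrow(m); nc <- ncol(m)
  i0 <- floor(fx); j0 <- floor(fy)
  wx <- fx - i0; wy <- fy - j0
  ri <- seq_len(nr) + i0; cj <- seq_len(nc) + j0
  pick <- function(r_off, c_off) {
    r <- ri + r_off; cc <- cj + c_off
    ok_r <- r >= 1 & r <= nr; ok_c <- cc >= 1 & cc <= nc
    out <- matrix(NA_real_, nr, nc)
    if (any(ok_r) && any(ok_c)) {
      out[ok_r, ok_c] <- m[r[ok_r], cc[ok_c], drop = FALSE]
    }
    out
  }
  # accumulate only weighted terms: 0 * NA must not poison exact-integer
  # shifts at the grid boundary
  acc <- matrix(0, nr, nc)
  add <- function(acc, w, term) if (w > 0) acc + w * term else acc
  acc <- add(acc, (1 - wx) * (1 - wy), pick(0, 0))
  acc <- add(acc, wx * (1 - wy), pick(1, 0))
  acc <- add(acc, (1 - wx) * wy, pick(0, 1))
  acc <- add(acc, wx * wy, pick(1, 1))
  acc
}

#' Global gamma analysis of an evaluated dose grid against a reference
#'
#' For each reference pixel at or above the low-dose threshold, gamma is
#' the minimum over a search disc (radius `3 * dta_mm`, lattice step
#' `dta_mm / 10`, evaluated dose sampled by bilinear interpolation) of
#' `sqrt((dD / (dose_percent% of ref max))^2 + (r / dta_mm)^2)`. The pass
#' rate is the percentage of evaluated pixels with gamma <= 1.
#'
#' @param reference,evaluated `dose_grid`s on identical geometry.
#' @param criteria A [gamma_criteria()].
#' @return A `gamma_result`: `gamma` (matrix on the reference geometry,
#'   `NA` at excluded pixels), `pass_rate` (percent of evaluated pixels
#'   with gamma <= 1), `n_evaluated`, and `pass` versus the acceptance
#'   line.
#' @export
gamma_analysis <- function(reference, evaluated, criteria = gamma_criteria()) {
  stopifnot(inherits(reference, "dose_grid"), inherits(evaluated, "dose_grid"))
  if (!same_geometry(reference, evaluated)) {
    qa_abort("dose grids have different geometry", "qa_domain_error")
  }
  ref_max <- max(reference$values)
  if (ref_max <= 0) qa_abort("reference maximum must be positive", "qa_domain_error")
  dd_norm <- criteria$dose_percent / 100 * ref_max
  eval_mask <- reference$values >= criteria$low_dose_threshold_percent / 100 * ref_max
  if (!any(eval_mask)) {
    qa_abort("nothing to evaluate: all pixels below the low-dose threshold",
             "qa_domain_error")
  }

  off <- gamma_offsets(criteria$dta_mm)
  sp <- reference$spacing_mm
  best <- matrix(Inf, nrow(reference$values), ncol(reference$values))
  for (k in seq_len(nrow(off))) {
    shifted <- shift_bilinear(evaluated$values, off$dx[k] / sp, off$dy[k] / sp)
    g2 <- ((shifted - reference$values) / dd_norm)^2 +
      (off$dx[k]^2 + off$dy[k]^2) / criteria$dta_mm^2
    better <- !is.na(g2) & g2 < best
    best[better] <- g2[better]
  }
  gamma <- sqrt(best)
  gamma[!eval_mask] <- NA_real_

  vals <- gamma[eval_mask]
  pass_rate <- 100 * mean(vals <= 1)
  structure(
    list(gamma = gamma, origin_mm = reference$origin_mm,
         spacing_mm = reference$spacing_mm, criteria = criteria,
         n_evaluated = sum(eval_mask), pass_rate = pass_rate,
         pass = pass_rate >= criteria$pass_threshold_percent),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm (global), %d px evaluated\n",
              x$criteria$dose_percent, x$criteria$dta_mm, x$n_evaluated))
  cat(sprintf("  pass rate %.1f%% (acceptance line %g%%) -> %s\n",
              x$pass_rate, x$criteria$pass_threshold_percent,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' @method glance gamma_result
#' @export
glance.gamma_result <- function(x, ...) {
  tibble(dose_percent = x$criteria$dose_percent, dta_mm = x$criteria$dta_mm,
         n_evaluated = x$n_evaluated, pass_rate = x$pass_rate,
         max_gamma = max(x$gamma, na.rm = TRUE), pass = x$pass)
}

#' Write / read a dose grid as plain text
#'
#' Three-line `#` header (origin, spacing, shape) followed by the matrix,
#' one grid row per line.
#'
#' @param grid A `dose_grid`.
#' @param path File path.
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  wl <- function(s) writeLines(s, con, sep = "\n")
  wl(sprintf("# origin_mm %.17g %.17g", grid$origin_mm[1], grid$origin_mm[2]))
  wl(sprintf("# spacing_mm %.17g", grid$spacing_mm))
  wl(sprintf("# shape %d %d signed %d", nrow(grid$values), ncol(grid$values),
             as.integer(grid$signed)))
  wl(apply(grid$values, 1, function(r) paste(formatC(r, format = "g", digits = 17),
                                             collapse = " ")))
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  if (!file.exists(path)) qa_abort(paste0("no such file: ", path), "qa_io_error")
  lines <- readLines(path, warn = FALSE)
  hd <- lines[1:3]
  origin <- as.numeric(strsplit(hd[1], " +")[[1]][3:4])
  spacing <- as.numeric(strsplit(hd[2], " +")[[1]][3])
  shp <- strsplit(hd[3], " +")[[1]]
  dims <- as.numeric(shp[3:4]); signed <- as.integer(shp[6]) == 1
  if (anyNA(c(origin, spacing, dims))) {
    qa_abort(paste0("malformed dose grid header in ", path), "qa_format_error")
  }
  rows <- lapply(lines[-(1:3)], function(l) as.numeric(strsplit(trimws(l), " +")[[1]]))
  vals <- do.call(rbind, rows)
  if (!all(dim(vals) == dims)) {
    qa_abort(paste0("dose grid shape mismatch in ", path), "qa_format_error")
  }
  dose_grid(vals, origin, spacing, signed = signed)
}
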