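# Independent reference implementations used as oracles. They share only
# the definitions with the package code, not the implementation: plain
# double loops and scalar arithmetic.

# naive flag evaluator: double loop over layers and spots
naive_flags <- function(plan, session, baseline, config) {
  flags <- list()
  push <- function(kind, axis, fid, li, si, value, tol) {
    flags[[length(flags) + 1]] <<- tibble::tibble(
      kind = kind, axis = axis, field_id = fid, layer_index = li,
      spot_index = si, value = value, tolerance = tol)
  }
  for (fid in unique(plan$field_id)) {
    pf <- plan[plan$field_id == fid, ]
    sf <- session[session$field_id == fid, ]
    for (li in sort(unique(pf$layer_index))) {
      pl <- pf[pf$layer_index == li, ]
      sl <- sf[sf$layer_index == li, ]
      pl <- pl[order(pl$spot_index), ]
      dx <- sl$x_mm - pl$x_mm
      dy <- sl$y_mm - pl$y_mm
      dmu <- sl$mu - pl$mu
      mx <- sum(dx) / length(dx)
      my <- sum(dy) / length(dy)
      if (abs(mx) > config$pos_systematic_mm)
        push("systematic", "x", fid, li, NA_real_, mx, config$pos_systematic_mm)
      if (abs(my) > config$pos_systematic_mm)
        push("systematic", "y", fid, li, NA_real_, my, config$pos_systematic_mm)
      for (k in seq_along(dx)) {
        if (abs(dx[k] - mx) > config$pos_random_mm)
          push("random", "x", fid, li, pl$spot_index[k], dx[k] - mx, config$pos_random_mm)
        if (abs(dy[k] - my) > config$pos_random_mm)
          push("random", "y", fid, li, pl$spot_index[k], dy[k] - my, config$pos_random_mm)
        if (abs(dmu[k]) > config$mu_abs)
          push("mu", NA_character_, fid, li, pl$spot_index[k], dmu[k], config$mu_abs)
      }
      if (!is.null(baseline)) {
        ref <- baseline_sigma(baseline, pl$energy_MeV[1], pl$gantry_angle_deg[1])
        px <- 100 * (mean(sl$sigma_x_mm) - ref[["sigma_x_mm"]]) / ref[["sigma_x_mm"]]
        py <- 100 * (mean(sl$sigma_y_mm) - ref[["sigma_y_mm"]]) / ref[["sigma_y_mm"]]
        if (abs(px) > config$size_percent)
          push("size", "x", fid, li, NA_real_, px, config$size_percent)
        if (abs(py) > config$size_percent)
          push("size", "y", fid, li, NA_real_, py, config$size_percent)
      }
    }
  }
  if (length(flags) == 0) return(tibble::tibble())
  purrr::list_rbind(flags)
}

# canonical ordering for flag-table comparison
sort_flags <- function(flags) {
  if (nrow(flags) == 0) return(flags)
  flags[order(flags$field_id, flags$layer_index, flags$kind, flags$axis,
              flags$spot_index, method = "radix"), ]
}

# vectorized bilinear gather at arbitrary fractional pixel coordinates;
# mirrors the candidate definition (weight > 0 terms must be in bounds)
bilinear_gather <- function(m, fi, fj) {
  i0 <- floor(fi); j0 <- floor(fj)
  wi <- fi - i0; wj <- fj - j0
  val <- numeric(length(fi))
  ok <- rep(TRUE, length(fi))
  for (term in list(list(i0, j0, (1 - wi) * (1 - wj)),
                    list(i0 + 1, j0, wi * (1 - wj)),
                    list(i0, j0 + 1, (1 - wi) * wj),
                    list(i0 + 1, j0 + 1, wi * wj))) {
    w <- term[[3]]
    use <- w > 0
    if (!any(use)) next
    ii <- term[[1]][use]; jj <- term[[2]][use]
    inb <- ii >= 1 & ii <= nrow(m) & jj >= 1 & jj <= ncol(m)
    ok[use][!inb] <- FALSE
    v <- rep(0, sum(use))
    v[inb] <- m[cbind(ii[inb], jj[inb])]
    val[use] <- val[use] + w[use] * v
  }
  val[!ok] <- NA_real_
  val
}

# exhaustive gamma: per-pixel search over the same offset lattice the
# package defines (step dta/10, radius 3*dta), computed independently
brute_gamma <- function(reference, evaluated, criteria) {
  ref <- reference$values
  ev <- evaluated$values
  sp <- reference$spacing_mm
  ref_max <- max(ref)
  dd <- criteria$dose_percent / 100 * ref_max
  thr <- criteria$low_dose_threshold_percent / 100 * ref_max
  step <- criteria$dta_mm / 10
  g <- seq(-30, 30) * step
  offs <- expand.grid(dx = g, dy = g)
  offs <- offs[offs$dx^2 + offs$dy^2 <= (3 * criteria$dta_mm)^2 + 1e-12, ]
  r2 <- (offs$dx^2 + offs$dy^2) / criteria$dta_mm^2
  out <- matrix(NA_real_, nrow(ref), ncol(ref))
  for (i in seq_len(nrow(ref))) {
    for (j in seq_len(ncol(ref))) {
      if (ref[i, j] < thr) next
      vals <- bilinear_gather(ev, i + offs$dx / sp, j + offs$dy / sp)
      gam2 <- ((vals - ref[i, j]) / dd)^2 + r2
      out[i, j] <- sqrt(min(gam2, na.rm = TRUE))
    }
  }
  out
}

# smooth positive random field: a few random Gaussian bumps on a grid
random_smooth_grid <- function(n = 30, spacing = 2, n_bumps = 4) {
  xs <- (seq_len(n) - 1) * spacing
  vals <- matrix(0, n, n)
  for (b in seq_len(n_bumps)) {
    cx <- runif(1, min(xs) + 10, max(xs) - 10)
    cy <- runif(1, min(xs) + 10, max(xs) - 10)
    s <- runif(1, 6, 14)
    a <- runif(1, 0.5, 1)
    vals <- vals + a * outer(exp(-(xs - cx)^2 / (2 * s^2)),
                             exp(-(xs - cy)^2 / (2 * s^2)))
  }
  dose_grid(vals, c(0, 0), spacing)
}
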