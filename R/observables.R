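#' Reduced volume and reduced area difference of the current field
#'
#' Computes `v = V / ((4 pi / 3) Rs^3)` and `da = dA / (8 pi D Rs)` with
#' `Rs = sqrt(A / 4 pi)` taken from the current field's area. Both equal 1
#' for a sphere; elongation at fixed area lowers `v` below 1
#' (isoperimetric inequality).
#'
#' @param phi A `pf_field`.
#' @param params A `pf_params`.
#' @return A named numeric vector `c(v, da)`.
#' @export
reduced_parameters <- function(phi, params) {
  g <- field_grid(phi)
  st <- model_state(field_values(phi), g, params)
  if (st$A <= sqrt(.Machine$double.eps)) stop("vanishing membrane area")
  Rs <- sqrt(st$A / (4 * pi))
  c(v = st$V / ((4 * pi / 3) * Rs^3),
    da = st$dA / (8 * pi * params$D * Rs))
}

# circular shift of a 3D array by s = (sx, sy, sz); positive s moves content
# toward higher indices. With periodic = FALSE the wrapped slab is filled.
shift3 <- function(a, s, periodic = TRUE, fill = Inf) {
  N <- dim(a)
  idx <- lapply(1:3, function(ax) ((seq_len(N[ax]) - 1L - s[ax]) %% N[ax]) + 1L)
  out <- a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  if (!periodic) {
    for (ax in 1:3) {
      if (s[ax] == 0L) next
      take <- if (s[ax] > 0L) seq_len(s[ax]) else N[ax] + 1L - seq_len(-s[ax])
      if (ax == 1L) out[take, , ] <- fill
      if (ax == 2L) out[, take, ] <- fill
      if (ax == 3L) out[, , take] <- fill
    }
  }
  out
}

conn_offsets <- function(connectivity) {
  if (connectivity == 6) {
    list(c(1L,0L,0L), c(-1L,0L,0L), c(0L,1L,0L), c(0L,-1L,0L),
         c(0L,0L,1L), c(0L,0L,-1L))
  } else if (connectivity == 26) {
    offs <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
    offs <- offs[rowSums(abs(offs)) > 0, ]
    lapply(seq_len(nrow(offs)), function(i) as.integer(offs[i, ]))
  } else stop("connectivity must be 6 or 26")
}

# label connected components of a logical 3D mask by vectorized min-label
# propagation; returns list(labels = numeric array (0 outside), n = count)
label_components <- function(mask, connectivity = 6, periodic = TRUE) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  offs <- conn_offsets(connectivity)
  lab <- array(Inf, dim(mask))
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(list(labels = array(0, dim(mask)), n = 0L))
  repeat {
    lab_new <- lab
    for (s in offs) lab_new <- pmin(lab_new, shift3(lab, s, periodic))
    lab_new[!mask] <- Inf
    if (identical(lab_new, lab)) break
    lab <- lab_new
  }
  ids <- sort(unique(lab[mask]))
  out <- array(0, dim(mask))
  out[mask] <- match(lab[mask], ids)
  list(labels = out, n = length(ids))
}

#' Count connected regions of the interior or exterior
#'
#' Labels the voxel set `{phi > 0}` (interior) or `{phi < 0}` (exterior)
#' by flood fill with the chosen connectivity, honoring the periodic wrap,
#' and returns the number of connected components. The number of membrane
#' sheets is `interior components + exterior components - 1`.
#'
#' @param phi A `pf_field`.
#' @param side `"interior"` or `"exterior"`.
#' @param connectivity 6 (face neighbors, default: never merges diagonal
#'   touches) or 26.
#' @param periodic Honor the periodic wrap (default `TRUE`).
#' @return An integer count.
#' @export
count_regions <- function(phi, side = c("interior", "exterior"),
                          connectivity = 6, periodic = TRUE) {
  side <- match.arg(side)
  v <- field_values(phi)
  mask <- if (side == "interior") v > 0 else v < 0
  label_components(mask, connectivity, periodic)$n
}

#' Count membrane sheets
#'
#' `interior components + exterior components - 1`: one closed membrane
#' separates the one exterior from one interior; each additional sheet adds
#' a region on one side (e.g. a nested sphere-within-shell has interior
#' count 1 + exterior count 2 = 2 sheets).
#'
#' @inheritParams count_regions
#' @export
count_membrane_sheets <- function(phi, connectivity = 6, periodic = TRUE) {
  count_regions(phi, "interior", connectivity, periodic) +
    count_regions(phi, "exterior", connectivity, periodic) - 1L
}

# periodic centroid per axis via circular mean; returns length-3 coordinates
periodic_centroid <- function(mask, grid) {
  N <- grid$N; L <- grid$L
  idx <- which(mask, arr.ind = TRUE)
  vapply(1:3, function(ax) {
    th <- 2 * pi * grid$x[idx[, ax]] / L
    ang <- atan2(mean(sin(th)), mean(cos(th)))
    (ang %% (2 * pi)) * L / (2 * pi)
  }, numeric(1))
}

# minimal-image displacement arrays from point c; list of three N^3 arrays
periodic_disp <- function(grid, cpt) {
  N <- grid$N; L <- grid$L
  one <- rep(1, N)
  d <- lapply(1:3, function(ax) {
    dd <- grid$x - cpt[ax]
    dd <- ((dd + L / 2) %% L) - L / 2
    dd
  })
  list(outer(outer(d[[1]], one), one),
       outer(outer(one, d[[2]]), one),
       outer(outer(one, one), d[[3]]))
}

#' Count arms of a star-like shape
#'
#' An "arm" is a protrusion of the interior `{phi > 0}` beyond a core
#' radius. The core radius interpolates between the waist and the tip of
#' the shape: with `r_lo` the smallest directional extent of the interior
#' (minimum over a coarse set of directions of the farthest interior voxel
#' in that direction), `r_hi` the largest distance from the centroid, the
#' cut radius is `r_c = r_lo + core_fraction * (r_hi - r_lo)` and the arm
#' count is the number of 6-connected components of
#' `{phi > 0, |x - centroid| > r_c}` (periodic distances throughout).
#' Shapes whose tips protrude less than a few grid cells beyond their waist
#' (e.g. a sphere) have no arms.
#'
#' Two robustness filters are applied to the components beyond `r_c`:
#' speckle components smaller than `min_voxels` are ignored (isolated
#' surface voxels that graze the cut radius), and a component only counts
#' as an arm if it is localized in direction — its mean resultant unit
#' vector from the centroid has length at least 0.5. The latter
#' distinguishes true protrusions from structures that surround the core
#' (e.g. the equatorial rim of a discocyte, whose directions cancel).
#'
#' @param phi A `pf_field`.
#' @param core_fraction Fraction of the waist-to-tip span at which the core
#'   is cut (default 0.5).
#' @param min_voxels Minimum component size counted as an arm.
#' @return An integer arm count.
#' @export
count_arms <- function(phi, core_fraction = 0.5, min_voxels = 9L) {
  g <- field_grid(phi)
  v <- field_values(phi)
  mask <- v > 0
  if (!any(mask)) stop("empty interior: no voxels with phi > 0")
  cpt <- periodic_centroid(mask, g)
  disp <- periodic_disp(g, cpt)
  r <- sqrt(disp[[1]]^2 + disp[[2]]^2 + disp[[3]]^2)
  rin <- r[mask]
  r_hi <- max(rin)
  # directional extents over the 26 lattice directions
  dirs <- do.call(rbind, conn_offsets(26))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ok <- rin > g$h  # skip near-centroid voxels with ill-defined direction
  u <- cbind(disp[[1]][mask][ok], disp[[2]][mask][ok], disp[[3]][mask][ok]) /
    rin[ok]
  bin <- max.col(u %*% t(dirs))
  ext <- vapply(split(rin[ok], factor(bin, levels = seq_len(nrow(dirs)))),
                function(z) if (length(z)) max(z) else NA_real_, numeric(1))
  r_lo <- min(ext, na.rm = TRUE)
  # degenerate (round) shapes: tips indistinguishable from the waist
  if (r_hi - r_lo <= max(3 * g$h, 0.05 * r_hi)) return(0L)
  r_c <- r_lo + core_fraction * (r_hi - r_lo)
  sel <- mask & (r > r_c)
  lb <- label_components(sel, connectivity = 6, periodic = TRUE)
  if (lb$n == 0L) return(0L)
  ids <- lb$labels[sel]
  sizes <- tabulate(ids, nbins = lb$n)
  # direction localization: resultant length of the component's unit vectors
  ux <- disp[[1]][sel] / r[sel]; uy <- disp[[2]][sel] / r[sel]
  uz <- disp[[3]][sel] / r[sel]
  res_len <- sqrt(tapply(ux, ids, sum)^2 + tapply(uy, ids, sum)^2 +
                  tapply(uz, ids, sum)^2) / sizes
  sum(sizes >= min_voxels & res_len >= 0.5)
}

#' Reflection asymmetry score
#'
#' Measures up-down mirror-symmetry breaking (e.g. of pear shapes). The
#' interior's principal axis (leading eigenvector of the second-moment
#' tensor about the periodic centroid) is snapped to the nearest grid axis;
#' the field is reflected about the centroid plane normal to that axis
#' (grid-exact index reflection, taking the better of the two candidate
#' planes bracketing the centroid), and the score
#' `||phi - phi_reflected||_1 / ||phi + 1||_1`, clipped to \[0, 1\], is
#' returned. 0 for mirror-symmetric shapes.
#'
#' @param phi A `pf_field`.
#' @return A number in \[0, 1\].
#' @export
reflection_asymmetry <- function(phi) {
  g <- field_grid(phi)
  v <- field_values(phi)
  mask <- v > 0
  if (!any(mask)) stop("empty interior: no voxels with phi > 0")
  cpt <- periodic_centroid(mask, g)
  disp <- periodic_disp(g, cpt)
  d1 <- disp[[1]][mask]; d2 <- disp[[2]][mask]; d3 <- disp[[3]][mask]
  M <- stats::cov(cbind(d1, d2, d3))
  pax <- eigen(M, symmetric = TRUE)$vectors[, 1L]
  ax <- which.max(abs(pax))
  m2 <- 2 * cpt[ax] / g$h   # reflection x -> 2c - x in index units
  norm1 <- sum(abs(v + 1))
  score <- Inf
  for (m in unique(c(floor(m2), ceiling(m2)))) {
    idx <- ((m - (seq_len(g$N) - 1L)) %% g$N) + 1L
    vr <- switch(ax, v[idx, , ], v[, idx, ], v[, , idx])
    score <- min(score, sum(abs(v - vr)) / norm1)
  }
  min(max(score, 0), 1)
}

#' Full shape diagnostics
#'
#' Bundles the morphology metrics used to classify steady states.
#'
#' @inheritParams reduced_parameters
#' @param core_fraction Passed to [count_arms()].
#' @return A `shape_metrics` object: list with `v`, `da`,
#'   `n_interior_components`, `n_exterior_components`,
#'   `n_membrane_components`, `n_arms`, `asymmetry`, `principal_moments`.
#' @export
shape_metrics <- function(phi, params, core_fraction = 0.5) {
  rp <- reduced_parameters(phi, params)
  g <- field_grid(phi)
  v <- field_values(phi)
  mask <- v > 0
  ni <- count_regions(phi, "interior")
  ne <- count_regions(phi, "exterior")
  pm <- if (any(mask)) {
    cpt <- periodic_centroid(mask, g)
    disp <- periodic_disp(g, cpt)
    M <- stats::cov(cbind(disp[[1]][mask], disp[[2]][mask], disp[[3]][mask]))
    eigen(M, symmetric = TRUE)$values
  } else rep(NA_real_, 3)
  structure(list(v = unname(rp["v"]), da = unname(rp["da"]),
                 n_interior_components = ni, n_exterior_components = ne,
                 n_membrane_components = ni + ne - 1L,
                 n_arms = if (any(mask)) count_arms(phi, core_fraction) else 0L,
                 asymmetry = if (any(mask)) reflection_asymmetry(phi) else NA_real_,
                 principal_moments = pm),
            class = "shape_metrics")
}

#' @export
print.shape_metrics <- function(x, ...) {
  cat(sprintf("v = %.4f  da = %.4f\n", x$v, x$da))
  cat(sprintf("components: interior %d, exterior %d, membrane sheets %d\n",
              x$n_interior_components, x$n_exterior_components,
              x$n_membrane_components))
  cat(sprintf("arms: %d   asymmetry: %.4f\n", x$n_arms, x$asymmetry))
  invisible(x)
}
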