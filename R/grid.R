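#' Periodic spectral grid
#'
#' Construct a uniform periodic grid on the cube `[0, L)^3` with `N` nodes
#' per axis (`x_i = i * h`, `h = L / N`) together with the discrete Fourier
#' wavenumbers used by all spectral operators in the package.
#'
#' Wavenumbers follow the standard discrete-transform ordering
#' `k_j = (2 * pi / L) * m_j` with integer frequencies
#' `m = 0, 1, ..., N/2, -(N/2 - 1), ..., -1` for even `N` (the Nyquist mode
#' appears once and carries a real, even symbol, so it is retained in the
#' Laplacian and biharmonic).
#'
#' @param L Edge length of the cubic domain (must be positive).
#' @param N Number of grid points per axis (integer, at least 4).
#' @return An object of class `pf_grid`: a list with elements `L`, `N`,
#'   `h`, node coordinates `x`, per-axis wavenumbers `k`, and the
#'   precomputed array `ksq` of `|k|^2` values (so the Laplacian symbol is
#'   `-ksq`).
#' @examples
#' g <- make_grid(1, 16)
#' g$h          # 1/16
#' range(-g$ksq) # Laplacian symbol is real and <= 0
#' @export
make_grid <- function(L, N) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("invalid grid: L must be a positive number")
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N != round(N) || N < 4)
    stop("invalid grid: N must be an integer >= 4")
  N <- as.integer(N)
  h <- L / N
  x <- (0:(N - 1L)) * h
  m <- fft_freqs(N)
  k <- 2 * pi * m / L
  k2 <- k^2
  # |k|^2 on the full 3D lattice, built from per-axis outer sums
  ksq <- outer(outer(k2, k2, `+`), k2, `+`)
  structure(list(L = L, N = N, h = h, x = x, freqs = m, k = k, ksq = ksq),
            class = "pf_grid")
}

# Integer DFT frequencies in transform ordering: 0..N/2, -(N/2-1)..-1 (even N)
fft_freqs <- function(N) {
  half <- floor(N / 2)
  if (N %% 2L == 0L) c(0:half, -(half - 1L):-1L) else c(0:half, -half:-1L)
}

#' @export
print.pf_grid <- function(x, ...) {
  cat(sprintf("Periodic spectral grid: [0, %g)^3, N = %d per axis, h = %g\n",
              x$L, x$N, x$h))
  invisible(x)
}

#' Scalar field on a periodic grid
#'
#' Wrap a numeric 3D array of nodal values as a `pf_field` attached to its
#' grid. Most package functions accept and return `pf_field` objects; the
#' underlying array can be recovered with `as.array()` / `field_values()`.
#'
#' @param values Numeric array of dimension `c(N, N, N)` (or a single number,
#'   which is recycled).
#' @param grid A `pf_grid`.
#' @return A `pf_field` object.
#' @export
pf_field <- function(values, grid) {
  stopifnot(inherits(grid, "pf_grid"))
  N <- grid$N
  if (length(values) == 1L) values <- array(values, c(N, N, N))
  if (!is.array(values) || !identical(dim(values), c(N, N, N)))
    stop("values must be an N x N x N array matching the grid")
  if (!all(is.finite(values))) stop("field values must all be finite")
  structure(values, grid = grid, class = "pf_field")
}

#' @rdname pf_field
#' @param x A `pf_field`.
#' @export
field_grid <- function(x) {
  g <- attr(x, "grid")
  if (is.null(g)) stop("not a pf_field: no grid attribute")
  g
}

#' @rdname pf_field
#' @export
field_values <- function(x) {
  v <- unclass(x)
  attr(v, "grid") <- NULL
  v
}

#' @export
as.array.pf_field <- function(x, ...) field_values(x)

#' @export
print.pf_field <- function(x, ...) {
  g <- field_grid(x)
  v <- field_values(x)
  cat(sprintf("pf_field on %d^3 grid (L = %g): range [%.4g, %.4g]\n",
              g$N, g$L, min(v), max(v)))
  invisible(x)
}

#' Mid-plane slice image of a field
#'
#' Draws the `z = L/2` cross-section of a phase field, with the zero level
#' set (the membrane) overlaid.
#'
#' @param x A `pf_field`.
#' @param k Slice index along the third axis (defaults to the mid-plane).
#' @param ... Passed on to [graphics::image()].
#' @export
plot.pf_field <- function(x, k = NULL, ...) {
  g <- field_grid(x)
  v <- field_values(x)
  if (is.null(k)) k <- g$N %/% 2 + 1L
  sl <- v[, , k]
  graphics::image(g$x, g$x, sl, asp = 1, xlab = "x", ylab = "y",
                  col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
  graphics::contour(g$x, g$x, sl, levels = 0, add = TRUE, drawlabels = FALSE)
  invisible(x)
}

# --- internal raw-array spectral kernels -----------------------------------
# These operate on plain arrays for speed; the exported wrappers attach grids.

fftn <- function(u) stats::fft(u)
ifftn_re <- function(U) Re(stats::fft(U, inverse = TRUE)) / length(U)

lap_raw <- function(u, grid) ifftn_re(-grid$ksq * fftn(u))

# integral of |grad u|^2 over the domain via Parseval
gradsq_integral_raw <- function(uk, grid) {
  grid$h^3 * sum(grid$ksq * (Re(uk)^2 + Im(uk)^2)) / length(uk)
}

integrate_raw <- function(u, grid) grid$h^3 * sum(u)

#' Spectral Laplacian
#'
#' Applies the periodic Laplacian by multiplication with `-|k|^2` in
#' transform space. Exact (to roundoff) for band-limited fields.
#'
#' @param u A `pf_field`.
#' @return A `pf_field` holding `Delta u`.
#' @export
laplacian <- function(u) {
  g <- field_grid(u)
  pf_field(lap_raw(field_values(u), g), g)
}

#' Domain integral of a field
#'
#' Rectangle-rule quadrature `h^3 * sum(u)`, which on a periodic grid is the
#' trapezoid rule and is spectrally accurate for smooth integrands.
#'
#' @param u A `pf_field`.
#' @return A number.
#' @export
integrate_field <- function(u) {
  integrate_raw(field_values(u), field_grid(u))
}

#' Solve a constant-coefficient implicit operator
#'
#' Solves `(s0 + s2 * Delta + s4 * Delta^2) u = rhs` diagonally in transform
#' space. This is the linear solve at the core of the semi-implicit and
#' fully implicit time steppers, whose implicit part is
#' `1/dt + kappa * (eps * Delta^2 + (2/eps) * Delta)`.
#'
#' @param rhs A `pf_field`.
#' @param s0,s2,s4 Coefficients of the identity, Laplacian and biharmonic.
#' @return A `pf_field` solving the system to spectral accuracy.
#' @details The Fourier symbol `s0 - s2 |k|^2 + s4 |k|^4` must be strictly
#'   positive at every mode; a non-positive symbol (typically a too-large
#'   time step) raises an error naming the offending mode.
#' @export
solve_implicit_operator <- function(rhs, s0, s2, s4) {
  g <- field_grid(rhs)
  sym <- s0 - s2 * g$ksq + s4 * g$ksq^2
  if (any(sym <= 0)) {
    bad <- which(sym <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "implicit operator not positive: symbol %.3g at mode (%d,%d,%d); reduce dt or check parameters",
      sym[bad[1L], bad[2L], bad[3L]],
      g$freqs[bad[1L]], g$freqs[bad[2L]], g$freqs[bad[3L]]))
  }
  pf_field(ifftn_re(fftn(field_values(rhs)) / sym), g)
}

# apply (s0 + s2*Lap + s4*Lap^2) -- inverse of the solve, used in tests
apply_implicit_operator <- function(u, s0, s2, s4) {
  g <- field_grid(u)
  sym <- s0 - s2 * g$ksq + s4 * g$ksq^2
  pf_field(ifftn_re(fftn(field_values(u)) * sym), g)
}

# smooth band-limited random field (spectrally filtered white noise);
# used by verification suites and tests
random_smooth_field <- function(grid, amplitude = 0.5, kcut = 4) {
  w <- array(stats::rnorm(grid$N^3), rep(grid$N, 3))
  filt <- exp(-(grid$ksq / (2 * pi * kcut / grid$L)^2))
  u <- ifftn_re(fftn(w) * filt)
  u <- u / max(abs(u)) * amplitude
  pf_field(u, grid)
}
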