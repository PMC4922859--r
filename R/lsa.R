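#' Assemble a reaction-diffusion system
#'
#' Couples a Jacobian of first-order kinetic rates with per-node diffusion
#' coefficients. `J[i, j]` is the rate with which node `j` regulates node
#' `i` (positive = activation, negative = inhibition); `D` holds one
#' diffusion coefficient per node, exactly zero for non-diffusible nodes.
#'
#' @param J square numeric matrix of kinetic rates.
#' @param D numeric vector of diffusion coefficients, `length(D) == nrow(J)`.
#' @param topology optional [topology()] whose signed support `J` must match.
#' @param labels optional node labels.
#' @return An object of class `rd_system`.
#' @examples
#' rd_system(J = rbind(c(1, -1), c(3, -2)), D = c(1, 10))
#' @export
rd_system <- function(J, D, topology = NULL, labels = NULL) {
  J <- as.matrix(J)
  n <- nrow(J)
  stopifnot(ncol(J) == n, length(D) == n, all(D >= 0))
  if (!is.null(topology)) {
    sup <- matrix(0L, n, n)
    ts <- cell_from_index(topology$network$cells, n)
    sup[cbind(ts[, "target"], ts[, "source"])] <- topology$signs
    if (!all(sign(J) == sup))
      stop("sign pattern of J does not match the topology's signed support")
  }
  if (is.null(labels)) {
    labels <- if (!is.null(topology)) topology$network$nodes$label
              else paste0("n", seq_len(n))
  }
  structure(list(J = J, D = as.numeric(D), topology = topology,
                 labels = labels, diffusible = D > 0),
            class = "rd_system")
}

#' @export
print.rd_system <- function(x, ...) {
  cat(sprintf("<rd_system> %d nodes, %d diffusible\n", nrow(x$J),
              sum(x$diffusible)))
  cat("J:\n"); print(x$J)
  cat("D:", x$D, "\n")
  invisible(x)
}

#' Characteristic polynomial of the linearized mode equations
#'
#' For wave number q, spatial mode q of the linearized reaction-diffusion
#' system is governed by the matrix `J - q^2 diag(D)`. This returns the
#' coefficients `a_1 .. a_N` of its characteristic polynomial
#' `lambda^N + a_1 lambda^(N-1) + ... + a_N`, where `a_m` equals `(-1)^m`
#' times the sum of the order-m principal minors.
#'
#' @param J square numeric matrix.
#' @param D numeric vector of diffusion coefficients (0 allowed); a scalar
#'   is recycled.
#' @param q2 the squared wave number, a non-negative scalar.
#' @return An object of class `char_poly`: list with `coefficients`
#'   (`a_1..a_N`), `n`, and `q2`.
#' @examples
#' char_poly_coeffs(diag(c(-1, -2, -3)), 0, 0) # a = (6, 11, 6)
#' @export
char_poly_coeffs <- function(J, D = 0, q2 = 0) {
  J <- as.matrix(J)
  n <- nrow(J)
  if (ncol(J) != n) stop("J must be square")
  stopifnot(length(q2) == 1L, q2 >= 0)
  if (length(D) == 1L) D <- rep(D, n)
  stopifnot(length(D) == n)
  m <- J - q2 * diag(D, n)
  a <- vapply(seq_len(n), function(ord) {
    subs <- utils::combn(n, ord)
    (-1)^ord * sum(apply(subs, 2L, function(s) det(m[s, s, drop = FALSE])))
  }, numeric(1L))
  structure(list(coefficients = a, n = n, q2 = q2), class = "char_poly")
}

#' @export
print.char_poly <- function(x, ...) {
  cat("<char_poly> degree", x$n, "at q2 =", x$q2, "\n")
  cat("a:", signif(x$coefficients, 6), "\n")
  invisible(x)
}

coef_vector <- function(coeffs) {
  if (inherits(coeffs, "char_poly")) coeffs$coefficients
  else as.numeric(coeffs)
}

#' Routh-Hurwitz stability test
#'
#' Decides whether every root of `lambda^N + a_1 lambda^(N-1) + ... + a_N`
#' has negative real part, using the explicit Routh-Hurwitz inequalities
#' for N = 2, 3, 4 and the full Routh array for N = 5. Marginal
#' polynomials (zero pivots) are classified not stable.
#'
#' @param coeffs a [char_poly_coeffs()] result or numeric vector `a_1..a_N`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' routh_hurwitz_stable(c(6, 11, 6)) # roots -1, -2, -3
#' @export
routh_hurwitz_stable <- function(coeffs) {
  a <- coef_vector(coeffs)
  n <- length(a)
  if (n < 2 || n > 5)
    stop("unsupported polynomial degree ", n, " (supported: 2 to 5)")
  switch(as.character(n),
    "2" = a[1] > 0 && a[2] > 0,
    "3" = a[1] > 0 && a[3] > 0 && a[1] * a[2] > a[3],
    "4" = a[1] > 0 && a[3] > 0 && a[4] > 0 &&
          a[1] * a[2] * a[3] > a[3]^2 + a[1]^2 * a[4],
    "5" = routh_array_stable(a))
}

# full Routh array for degree-5 polynomials; first-column positivity
routh_array_stable <- function(a) {
  a <- c(1, a)
  b1 <- (a[2] * a[3] - a[4]) / a[2]
  b2 <- (a[2] * a[5] - a[6]) / a[2]
  c1 <- (b1 * a[4] - a[2] * b2) / b1
  c2 <- a[6]
  d1 <- (c1 * b2 - b1 * c2) / c1
  ok <- c(a[2], b1, c1, d1, a[6])
  all(is.finite(ok)) && all(ok > 0)
}

# spectral abscissa (max real part of eigenvalues)
spectral_abscissa <- function(m) {
  if (length(m) == 0L) return(-Inf)
  max(Re(eigen(m, only.values = TRUE)$values))
}

default_q2_grid <- function(n_grid = 64L, q2_range = c(1e-3, 1e3)) {
  exp(seq(log(q2_range[1]), log(q2_range[2]), length.out = n_grid))
}

#' Dispersion relation of a reaction-diffusion system
#'
#' Evaluates the growth rate of spatial mode q — the maximum real part of
#' the eigenvalues of `J - q^2 diag(D)` — over a logarithmic grid of q^2,
#' refines around the best grid point by golden-section search, and records
#' the analytic q -> infinity limit: the spectral abscissa of the
#' sub-Jacobian of the non-diffusible nodes (the "capacitor" block), or
#' -Inf when every node diffuses.
#'
#' @param J square numeric matrix.
#' @param D diffusion coefficient vector (0 for non-diffusible nodes).
#' @param n_grid number of grid points.
#' @param q2_range range of the q^2 grid.
#' @param im_tol tolerance below which the dominant eigenvalue is flagged
#'   real.
#' @return An object of class `dispersion_relation` with fields `q2_grid`,
#'   `max_re_lambda`, `is_real`, `q2_star`, `q_star`, `max_growth`,
#'   `eigvec_star`, `limit_at_infinity`.
#' @examples
#' d <- dispersion(rbind(c(1, -1), c(3, -2)), c(1, 10))
#' d$max_growth > 0
#' @export
dispersion <- function(J, D, n_grid = 64L, q2_range = c(1e-3, 1e3),
                       im_tol = 1e-9) {
  J <- as.matrix(J)
  n <- nrow(J)
  if (length(D) == 1L) D <- rep(D, n)
  scale <- max(abs(J), 1e-300)
  grid <- default_q2_grid(n_grid, q2_range)
  dominant <- function(q2) {
    ev <- eigen(J - q2 * diag(D, n), only.values = TRUE)$values
    ev[which.max(Re(ev))]
  }
  lam <- vapply(grid, dominant, complex(1L))
  best <- which.max(Re(lam))
  # golden-section refinement on log q2 around the best grid point
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(n_grid, best + 1L)]
  gold <- (sqrt(5) - 1) / 2
  f <- function(lq2) Re(dominant(exp(lq2)))
  a <- log(lo); b <- log(hi)
  x1 <- b - gold * (b - a); x2 <- a + gold * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  for (iter in seq_len(48L)) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gold * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gold * (b - a); f1 <- f(x1)
    }
    if ((b - a) < 1e-10) break
  }
  q2_star <- exp((a + b) / 2)
  lam_star <- dominant(q2_star)
  if (Re(lam_star) < max(Re(lam))) { # refinement never worsens the grid max
    q2_star <- grid[best]
    lam_star <- lam[best]
  }
  nd <- which(D == 0)
  limit_inf <- spectral_abscissa(J[nd, nd, drop = FALSE])
  at_infinity <- limit_inf > Re(lam_star)
  max_growth <- max(Re(lam_star), limit_inf)
  eig_q2 <- if (at_infinity) q2_range[2] * 1e3 else q2_star
  es <- eigen(J - eig_q2 * diag(D, n))
  dom <- which.max(Re(es$values))
  structure(list(
    q2_grid = grid,
    max_re_lambda = Re(lam),
    is_real = abs(Im(lam)) <= im_tol * scale,
    q2_star = if (at_infinity) Inf else q2_star,
    q_star = if (at_infinity) Inf else sqrt(q2_star),
    lambda_star = if (at_infinity) complex(real = limit_inf) else lam_star,
    max_growth = max_growth,
    eigvec_star = es$vectors[, dom],
    eigvec_q2 = eig_q2,
    limit_at_infinity = limit_inf), class = "dispersion_relation")
}

#' @export
print.dispersion_relation <- function(x, ...) {
  cat("<dispersion_relation>\n")
  cat(sprintf("  max growth rate: %.6g at q2* = %s\n", x$max_growth,
              format(x$q2_star)))
  cat(sprintf("  q -> Inf limit (non-diffusible block): %.6g\n",
              x$limit_at_infinity))
  invisible(x)
}

#' Serialize a dispersion relation to a flat table
#'
#' @param x a [dispersion()] result.
#' @return data frame with columns `q2`, `max_re_lambda`, `is_real`.
#' @export
as.data.frame.dispersion_relation <- function(x, ...) {
  data.frame(q2 = x$q2_grid, max_re_lambda = x$max_re_lambda,
             is_real = x$is_real)
}

#' Diffusion-driven instability test
#'
#' A system is Turing unstable when its homogeneous steady state is stable
#' to uniform perturbations (all eigenvalues of `J` in the left half-plane,
#' tested with the Routh-Hurwitz criterion at q = 0) yet some spatial mode
#' q > 0 grows.
#'
#' Two notions of "grows" are exposed. `mode = "any"` accepts every growing
#' mode: oscillatory (complex) growth rates and growth in the q -> infinity
#' limit carried by an unstable non-diffusible sub-block (the capacitor
#' channel). `mode = "band"` asks for a finite-wavelength stationary Turing
#' band — the non-diffusible sub-block must be stable, so the dispersion
#' relation closes again at large q, and the determinant channel
#' `a_N(q^2) < 0` must open at some finite q, which guarantees a growing
#' real (non-oscillatory) mode with a selected wavelength. The screening
#' pipeline classifies with the band notion; mode `"any"` is the permissive
#' analysis notion.
#'
#' @param sys an [rd_system()], or a matrix `J` (then `D` must be given).
#' @param D diffusion coefficients when `sys` is a bare matrix.
#' @param tol positivity tolerance for the growth rate, absolute after
#'   scaling `J` to unit maximum absolute entry.
#' @param mode `"any"` (default) or `"band"`, see Details.
#' @param require_stationary if `TRUE` (with `mode = "any"`), an
#'   oscillatory dominant mode is not counted as pattern-forming.
#' @param ... passed to [dispersion()].
#' @return An object of class `stability_report` with fields
#'   `stable_at_q0`, `turing_unstable`, `oscillatory`, `band`
#'   (finite-wavelength stationary instability), `q_star`, `max_growth`,
#'   `limit_at_infinity`, `dispersion`.
#' @examples
#' is_turing_unstable(rbind(c(1, -1), c(3, -2)), D = c(1, 10))$turing_unstable
#' @export
is_turing_unstable <- function(sys, D = NULL, tol = 1e-9,
                               mode = c("any", "band"),
                               require_stationary = FALSE, ...) {
  mode <- match.arg(mode)
  if (inherits(sys, "rd_system")) {
    J <- sys$J; D <- sys$D
  } else {
    J <- as.matrix(sys)
    if (is.null(D)) stop("D is required when sys is a bare matrix")
  }
  n <- nrow(J)
  if (any(D < 0)) stop("diffusion coefficients must be non-negative")
  scale <- max(abs(J), 1e-300)
  eps <- tol * scale
  stable0 <- routh_hurwitz_stable(char_poly_coeffs(J, D, 0))
  disp <- dispersion(J, D, ...)
  oscillatory <- abs(Im(disp$lambda_star)) > eps
  # determinant channel: a_N(q^2) < 0 at some finite q; the grid minimum is
  # refined because the unstable window is narrow near onset
  a_n <- function(s) (-1)^n * det(J - s * diag(D, n))
  an_grid <- vapply(disp$q2_grid, a_n, numeric(1L))
  det_open <- any(an_grid < 0)
  if (!det_open) {
    b <- which.min(an_grid)
    lo <- disp$q2_grid[max(1L, b - 1L)]
    hi <- disp$q2_grid[min(length(an_grid), b + 1L)]
    det_open <- stats::optimize(function(l) a_n(exp(l)), c(log(lo), log(hi)),
                                tol = 1e-12)$objective < 0
  }
  band <- stable0 && disp$limit_at_infinity < eps && det_open
  turing <- if (mode == "band") band
  else stable0 && disp$max_growth > eps &&
    !(require_stationary && oscillatory)
  structure(list(stable_at_q0 = stable0, turing_unstable = turing,
                 oscillatory = oscillatory, band = band,
                 q_star = disp$q_star,
                 q2_star = disp$q2_star, max_growth = disp$max_growth,
                 limit_at_infinity = disp$limit_at_infinity,
                 dispersion = disp, tol = eps), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>\n")
  cat("  stable at q = 0:  ", x$stable_at_q0, "\n")
  cat("  Turing unstable:  ", x$turing_unstable, "\n")
  cat("  oscillatory mode: ", x$oscillatory, "\n")
  cat(sprintf("  max growth %.6g at q* = %s\n", x$max_growth,
              format(x$q_star)))
  invisible(x)
}
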