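#' Build a saturating kinetic model from a Jacobian
#'
#' Fields are interpreted as deviations from the homogeneous steady state.
#' The reaction term of node i is the linear form `sum_j J[i,j] x_j`
#' clamped symmetrically to `[-s, s]`, and the fields themselves saturate
#' at `[-s, s]` (production and depletion of real reactants are bounded),
#' so trajectories stay in a box by construction while the linearization
#' at the origin recovers `J` exactly — the property the screen certifies.
#'
#' @param x a [topology()] with all rates fixed, an [rd_system()], or a
#'   Jacobian matrix.
#' @param saturation clamp bound `s > 0`.
#' @param labels optional node labels.
#' @return An object of class `kinetic_model`.
#' @export
kinetic_model <- function(x, saturation = 1, labels = NULL) {
  stopifnot(saturation > 0)
  if (inherits(x, "rd_system")) {
    J <- x$J
    if (is.null(labels)) labels <- x$labels
  } else if (inherits(x, "rd_topology")) {
    if (is.null(x$values) || anyNA(x$values))
      stop("topology must carry fixed rate values")
    n <- nrow(x$network$nodes)
    J <- matrix(0, n, n)
    ts <- cell_from_index(x$network$cells, n)
    J[cbind(ts[, "target"], ts[, "source"])] <- x$values
    if (is.null(labels)) labels <- x$network$nodes$label
  } else {
    J <- as.matrix(x)
  }
  if (is.null(labels)) labels <- paste0("n", seq_len(nrow(J)))
  structure(list(J = J, saturation = saturation, labels = labels),
            class = "kinetic_model")
}

clamp <- function(x, s) pmin(pmax(x, -s), s)

#' Simulate reaction-diffusion dynamics
#'
#' Explicit finite-difference (forward Euler) integration of the clamped
#' kinetic model with zero-flux (reflecting) boundaries, from an initial
#' condition of uniform noise around the homogeneous state. 1D uses the
#' 3-point Laplacian, 2D the 5-point Laplacian on a square grid.
#'
#' @param model a [kinetic_model()] (or Jacobian matrix).
#' @param D diffusion coefficient per node.
#' @param L domain length (the grid spacing is `h = L / nx`).
#' @param nx grid points per dimension.
#' @param dt time step; must satisfy the CFL bound
#'   `dt <= h^2 / (2 * max(D) * dims)`; defaults to 40% of the bound.
#' @param t_end total simulated time; defaults to `5000 / max_growth` of
#'   the dispersion relation (capped for stable systems).
#' @param noise amplitude of the uniform initial perturbation.
#' @param seed RNG seed (initial condition); identical seeds give
#'   identical trajectories.
#' @param dims 1 or 2 spatial dimensions.
#' @param n_snapshots number of intermediate field snapshots to retain.
#' @return An object of class `rd_simulation`: list with `fields` (final
#'   state, `nx` x N in 1D, `nx` x `nx` x N in 2D), `snapshots`, `times`,
#'   and the run parameters.
#' @examples
#' m <- kinetic_model(rbind(c(1, -1), c(3, -2)))
#' sim <- simulate_rd(m, D = c(1, 20), nx = 64, t_end = 50, seed = 1)
#' @export
simulate_rd <- function(model, D, L = 200, nx = 200, dt = NULL,
                        t_end = NULL, noise = 1e-3, seed = 1L, dims = 1L,
                        n_snapshots = 0L) {
  if (!inherits(model, "kinetic_model")) model <- kinetic_model(model)
  J <- model$J
  n <- nrow(J)
  stopifnot(length(D) == n, all(D >= 0), noise >= 0, dims %in% c(1L, 2L))
  h <- L / nx
  cfl <- if (max(D) > 0) h^2 / (2 * max(D) * dims) else Inf
  if (is.null(dt)) dt <- if (is.finite(cfl)) 0.4 * cfl else 0.1
  if (dt > cfl)
    stop(sprintf("dt = %g violates the diffusion CFL bound; use dt <= %g",
                 dt, cfl))
  if (is.null(t_end)) {
    g <- dispersion(J, D)$max_growth
    t_end <- if (g > 1e-6) min(5000 / g, 1e5) else 100
  }
  steps <- max(1L, ceiling(t_end / dt))
  snap_at <- if (n_snapshots > 0L)
    unique(round(seq(1L, steps, length.out = n_snapshots))) else integer(0)
  set.seed(seed)
  s <- model$saturation
  if (dims == 1L) {
    X <- matrix(stats::runif(nx * n, -noise, noise), nx, n)
    lap <- function(M) {
      up <- M[c(1L, seq_len(nx - 1L)), , drop = FALSE]
      dn <- M[c(seq_len(nx - 1L) + 1L, nx), , drop = FALSE]
      (up + dn - 2 * M) / h^2
    }
  } else {
    X <- array(stats::runif(nx * nx * n, -noise, noise), c(nx, nx, n))
    lap2 <- function(M) {
      (M[c(1L, seq_len(nx - 1L)), , drop = FALSE] +
       M[c(seq_len(nx - 1L) + 1L, nx), , drop = FALSE] +
       M[, c(1L, seq_len(nx - 1L)), drop = FALSE] +
       M[, c(seq_len(nx - 1L) + 1L, nx), drop = FALSE] - 4 * M) / h^2
    }
  }
  snapshots <- list(); times <- numeric(0)
  tJ <- t(J)
  for (step in seq_len(steps)) {
    if (dims == 1L) {
      reaction <- clamp(X %*% tJ, s)
      X <- clamp(X + dt * (reaction + sweep(lap(X), 2L, D, `*`)), s)
    } else {
      flat <- matrix(X, nx * nx, n)
      reaction <- array(clamp(flat %*% tJ, s), c(nx, nx, n))
      for (i in seq_len(n)) {
        X[, , i] <- clamp(X[, , i] +
          dt * (reaction[, , i] + D[i] * lap2(X[, , i])), s)
      }
    }
    if (step %in% snap_at) {
      snapshots[[length(snapshots) + 1L]] <- X
      times <- c(times, step * dt)
    }
    if (any(!is.finite(X)))
      stop("simulation diverged at t = ", step * dt)
  }
  structure(list(fields = X, snapshots = snapshots, times = times,
                 h = h, dt = dt, t_end = steps * dt, L = L, nx = nx,
                 dims = dims, noise = noise, seed = seed, D = D,
                 J = J, saturation = s, labels = model$labels),
            class = "rd_simulation")
}

#' @export
print.rd_simulation <- function(x, ...) {
  cat(sprintf("<rd_simulation> %dD, %d nodes, nx = %d, t = %g (dt = %g, seed %d)\n",
              x$dims, ncol(as.matrix(x$J)), x$nx, x$t_end, x$dt, x$seed))
  invisible(x)
}

node_field <- function(result, node) {
  if (result$dims == 1L) result$fields[, node] else result$fields[, , node]
}

#' Dominant spatial wave number of a simulated pattern
#'
#' Location of the spatial-spectrum peak (discrete Fourier transform, mean
#' removed) of one node's final 1D field, in the same units as the `q` of
#' [dispersion()] (`q = 2 pi m / L`). Returns `NA` for a spatially
#' constant field. The spectral resolution `2 pi / L` is attached as
#' attribute `bin_width`.
#'
#' @param result a 1D [simulate_rd()] result.
#' @param node node index (default: first node with positive diffusion).
#' @return wave number, or `NA_real_` if the field is constant.
#' @export
dominant_wavenumber <- function(result, node = NULL) {
  stopifnot(inherits(result, "rd_simulation"), result$dims == 1L)
  if (is.null(node)) node <- which(result$D > 0)[1L]
  f <- node_field(result, node)
  f <- f - mean(f)
  if (max(abs(f)) < 1e-10)
    return(structure(NA_real_, bin_width = 2 * pi / result$L))
  spec <- Mod(stats::fft(f))[seq_len(floor(result$nx / 2))]
  m <- which.max(spec[-1L]) # skip the (removed) mean bin
  structure(2 * pi * m / result$L, bin_width = 2 * pi / result$L)
}

#' Check simulated phase relations against a prediction
#'
#' Computes the pairwise spatial correlation of the final fields; two
#' nodes are observed in-phase when their correlation is positive. When a
#' predicted sign vector (from [phase_pattern()]) is supplied, the
#' observed sign pattern is compared against it.
#'
#' @param result a [simulate_rd()] result with non-constant fields.
#' @param prediction optional +1/-1 vector over nodes.
#' @return list with `correlation` (matrix), `signs` (observed sign
#'   vector, first diffusing node normalized to +1), and `consistent`
#'   (logical, only when `prediction` given).
#' @export
phase_check <- function(result, prediction = NULL) {
  stopifnot(inherits(result, "rd_simulation"))
  n <- ncol(as.matrix(result$J))
  flat <- if (result$dims == 1L) result$fields
          else matrix(result$fields, result$nx^2, n)
  flat <- sweep(flat, 2L, colMeans(flat))
  if (any(apply(flat, 2L, stats::sd) < 1e-12))
    stop("phase_check requires non-constant fields")
  cors <- stats::cor(flat)
  ref <- which(result$D > 0)[1L]
  signs <- ifelse(cors[ref, ] >= 0, 1L, -1L)
  names(signs) <- result$labels
  out <- list(correlation = cors, signs = signs)
  if (!is.null(prediction)) {
    pred <- as.integer(sign(prediction))
    pred <- pred * pred[ref] # normalize to the same reference node
    out$consistent <- all(signs == pred)
  }
  out
}

#' Export simulated fields as delimited text
#'
#' Writes one tab-separated matrix per node (rows = grid points), plus a
#' JSON sidecar with the run metadata (seed, dt, h, t_end, D), so a run
#' can be reproduced exactly.
#'
#' @param result a [simulate_rd()] result.
#' @param dir output directory (created if missing).
#' @param stem file-name stem.
#' @return invisibly, the written file paths.
#' @export
write_simulation <- function(result, dir, stem = "simulation") {
  stopifnot(inherits(result, "rd_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- ncol(as.matrix(result$J))
  paths <- character(0)
  for (i in seq_len(n)) {
    p <- file.path(dir, sprintf("%s_%s.tsv", stem, result$labels[i]))
    utils::write.table(as.matrix(node_field(result, i)), p, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- file.path(dir, paste0(stem, "_meta.json"))
  jsonlite::write_json(list(seed = result$seed, dt = result$dt,
                            h = result$h, t_end = result$t_end,
                            L = result$L, nx = result$nx,
                            dims = result$dims, noise = result$noise,
                            D = result$D, saturation = result$saturation,
                            J = result$J, labels = result$labels),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta))
}
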