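# Vectorized Monte-Carlo machinery behind the screening steps.
#
# Samples are held as an ndraws x N^2 matrix whose column (i-1)*N + j is the
# Jacobian cell J[i, j] (row-major cell order, matching the enumeration and
# canonical-key conventions). All stability decisions on batches are made
# with closed-form Routh-Hurwitz inequalities on characteristic-polynomial
# coefficients assembled from principal minors, so a whole batch is decided
# with a few hundred vectorized operations regardless of its size.

# accessor factory: get(i, j) returns the column of samples for cell (i, j),
# with the diagonal optionally shifted by `shift[[i]]` (the -q^2 d_i term)
.get_factory <- function(jmat, n, shift = NULL) {
  force(jmat); force(n); force(shift)
  function(i, j) {
    col <- jmat[, (i - 1L) * n + j]
    if (i == j && !is.null(shift)) col - shift[[i]] else col
  }
}

# vectorized determinant of the submatrix rows x cols, expanded along the
# first row; closed forms up to 3x3, cofactor recursion above
.detv <- function(rows, cols, get) {
  m <- length(rows)
  if (m == 1L) return(get(rows[1L], cols[1L]))
  if (m == 2L)
    return(get(rows[1L], cols[1L]) * get(rows[2L], cols[2L]) -
           get(rows[1L], cols[2L]) * get(rows[2L], cols[1L]))
  if (m == 3L) {
    a <- get(rows[1L], cols[1L]); b <- get(rows[1L], cols[2L])
    cc <- get(rows[1L], cols[3L])
    d <- get(rows[2L], cols[1L]); e <- get(rows[2L], cols[2L])
    f <- get(rows[2L], cols[3L])
    g <- get(rows[3L], cols[1L]); h <- get(rows[3L], cols[2L])
    i <- get(rows[3L], cols[3L])
    return(a * (e * i - f * h) - b * (d * i - f * g) + cc * (d * h - e * g))
  }
  acc <- 0
  for (jj in seq_len(m)) {
    term <- get(rows[1L], cols[jj]) * .detv(rows[-1L], cols[-jj], get)
    acc <- acc + if (jj %% 2L == 1L) term else -term
  }
  acc
}

# characteristic-polynomial coefficients a_1..a_n for every sample;
# a_m = (-1)^m * sum of order-m principal minors
.charpoly_batch <- function(get, n, ndraws) {
  a <- matrix(0, ndraws, n)
  for (m in seq_len(n)) {
    subs <- utils::combn(n, m)
    acc <- 0
    for (s_i in seq_len(ncol(subs))) {
      s <- subs[, s_i]
      acc <- acc + .detv(s, s, get)
    }
    a[, m] <- (-1)^m * acc
  }
  a
}

# vectorized Routh-Hurwitz: TRUE where all roots have negative real parts
.rh_batch <- function(a) {
  n <- ncol(a)
  if (n == 1L) return(a[, 1L] > 0) # scalar block: -J_ii > 0
  if (n == 2L) return(a[, 1L] > 0 & a[, 2L] > 0)
  if (n == 3L) return(a[, 1L] > 0 & a[, 3L] > 0 & a[, 1L] * a[, 2L] > a[, 3L])
  if (n == 4L)
    return(a[, 1L] > 0 & a[, 3L] > 0 & a[, 4L] > 0 &
           a[, 1L] * a[, 2L] * a[, 3L] > a[, 3L]^2 + a[, 1L]^2 * a[, 4L])
  if (n == 5L) {
    b1 <- (a[, 1L] * a[, 2L] - a[, 3L]) / a[, 1L]
    b2 <- (a[, 1L] * a[, 4L] - a[, 5L]) / a[, 1L]
    c1 <- (b1 * a[, 3L] - a[, 1L] * b2) / b1
    d1 <- (c1 * b2 - b1 * a[, 5L]) / c1
    ok <- a[, 1L] > 0 & b1 > 0 & c1 > 0 & d1 > 0 & a[, 5L] > 0
    ok[!is.finite(ok)] <- FALSE
    return(ok)
  }
  stop("unsupported size ", n)
}

# draw a batch of Jacobian samples for a signed topology. The stability and
# instability conditions are scale-free, so the existence searches mix
# uniform draws in (0, box_hi] with log-uniform draws over three decades to
# cover regions that need widely separated rate magnitudes; pure uniform
# draws (`mix = FALSE`) are used by the robustness volume estimator.
.draw_jbatch <- function(ndraws, n, cells, signs, values, box_hi = 0.5,
                         mix = TRUE) {
  jmat <- matrix(0, ndraws, n * n)
  logdraw <- if (mix) stats::runif(ndraws) < 0.5 else rep(FALSE, ndraws)
  for (e_i in seq_along(cells)) {
    cl <- cells[e_i]
    if (!is.na(values[e_i])) {
      jmat[, cl] <- values[e_i]
    } else {
      mag <- ifelse(logdraw, box_hi * 10^stats::runif(ndraws, -3, 0),
                    stats::runif(ndraws, 0, box_hi))
      jmat[, cl] <- signs[e_i] * mag
    }
  }
  jmat
}

# diffusion draws per regime: ndraws x n matrix (0 for non-diffusible)
.draw_dbatch <- function(ndraws, diffusible, regime, d_box = c(0, 1),
                         fixed_d = NULL, mix = TRUE) {
  n <- length(diffusible)
  d <- matrix(0, ndraws, n)
  idx <- which(diffusible)
  if (regime == "free") {
    logdraw <- if (mix) stats::runif(ndraws) < 0.5 else rep(FALSE, ndraws)
    for (i in idx) {
      d[, i] <- ifelse(logdraw,
                       d_box[2] * 10^stats::runif(ndraws, -2, 0),
                       stats::runif(ndraws, d_box[1], d_box[2]))
    }
  } else if (regime == "equal") {
    common <- stats::runif(ndraws, d_box[1], d_box[2])
    for (i in idx) d[, i] <- common
  } else if (regime == "fixed") {
    stopifnot(!is.null(fixed_d), length(fixed_d) == n)
    for (i in idx) d[, i] <- fixed_d[i]
  } else stop("unknown regime ", regime)
  # avoid exactly-zero diffusion on diffusible nodes (degenerate draws)
  d[, idx][d[, idx] == 0] <- .Machine$double.eps
  d
}

# TRUE where the non-diffusible sub-block has positive spectral abscissa
.block_unstable_batch <- function(get, nd_nodes, ndraws) {
  m <- length(nd_nodes)
  if (m == 0L) return(rep(FALSE, ndraws))
  if (m == 1L) return(get(nd_nodes, nd_nodes) > 0)
  if (m == 2L) {
    tr <- get(nd_nodes[1L], nd_nodes[1L]) + get(nd_nodes[2L], nd_nodes[2L])
    dt <- .detv(nd_nodes, nd_nodes, get)
    return(tr > 0 | dt < 0)
  }
  !.block_stable_batch(get, nd_nodes, ndraws)
}

# TRUE where the non-diffusible sub-block is strictly Routh-Hurwitz stable
# (empty block counts as stable: diffusion damps every mode as q -> Inf)
.block_stable_batch <- function(get, nd_nodes, ndraws) {
  m <- length(nd_nodes)
  if (m == 0L) return(rep(TRUE, ndraws))
  sub_get <- function(i, j) get(nd_nodes[i], nd_nodes[j])
  a <- if (m == 1L) matrix(-get(nd_nodes, nd_nodes), ndraws, 1L)
       else .charpoly_batch(sub_get, m, ndraws)
  .rh_batch(a)
}

# Instability of spatial modes for samples already stable at q = 0.
# criterion "band": finite-wavelength stationary Turing instability — the
#   non-diffusible sub-block is stable (the dispersion relation closes
#   again as q -> Inf) and the determinant channel opens at some finite
#   grid q^2 (a_N(q^2) < 0 guarantees a growing real mode there).
# criterion "any": any growing mode — Routh-Hurwitz failure at some grid
#   q^2 or an unstable non-diffusible sub-block (growth in the q -> Inf
#   limit, the capacitor channel), oscillatory modes included.
.instability_batch <- function(jmat, dmat, n, grid, ndraws,
                               criterion = c("band", "any")) {
  criterion <- match.arg(criterion)
  get0 <- .get_factory(jmat, n)
  nd <- which(colSums(dmat) == 0)
  if (criterion == "band") {
    # marginal blocks (e.g. no self-edge on the non-diffusible node,
    # spectral abscissa exactly 0) still select a finite wavelength: the
    # growth rate tends to 0 from below/above as q -> Inf, so only a
    # strictly unstable block is excluded
    alive <- !.block_unstable_batch(get0, nd, ndraws)
    hit <- rep(FALSE, ndraws)
    for (s in grid) {
      todo <- which(alive & !hit)
      if (!length(todo)) break
      shift <- lapply(seq_len(n), function(i) s * dmat[todo, i])
      get_s <- .get_factory(jmat[todo, , drop = FALSE], n, shift)
      an <- (-1)^n * .detv(seq_len(n), seq_len(n), get_s)
      hit[todo] <- an < 0
    }
    return(hit & alive)
  }
  unstable <- .block_unstable_batch(get0, nd, ndraws)
  for (s in grid) {
    todo <- which(!unstable)
    if (!length(todo)) break
    shift <- lapply(seq_len(n), function(i) s * dmat[todo, i])
    get_s <- .get_factory(jmat[todo, , drop = FALSE], n, shift)
    a <- .charpoly_batch(get_s, n, length(todo))
    unstable[todo] <- !.rh_batch(a)
  }
  unstable
}

# derive a reproducible sub-seed (< 2^31) from a master seed and indices
.sub_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (v in idx) s <- (s * 48271 + as.double(v) * 16807 + 1) %% 2147483647
  as.integer(s)
}

# probe diffusion vectors for the universal regime: a single rate set must
# support patterning at every probe (ratios spanning four orders of
# magnitude for two diffusible nodes; log-uniform probes otherwise)
.universal_probes <- function(diffusible, probe_ratios = c(0.01, 0.1, 1,
                                                           10, 100)) {
  idx <- which(diffusible)
  n <- length(diffusible)
  if (length(idx) == 2L) {
    lapply(probe_ratios, function(r) {
      d <- rep(0, n); d[idx] <- c(1, r); d
    })
  } else {
    # several diffusible nodes: equal diffusivities plus fixed spreads of
    # per-node ratios covering both orderings
    spreads <- list(rep(1, length(idx)),
                    10^seq(-1, 1, length.out = length(idx)),
                    10^seq(1, -1, length.out = length(idx)),
                    10^seq(-2, 2, length.out = length(idx)),
                    10^seq(2, -2, length.out = length(idx)))
    lapply(spreads, function(sp) {
      d <- rep(0, n); d[idx] <- sp; d
    })
  }
}

# Exact diffusion-independence (Type III) test for two diffusible nodes.
# Substituting x = q^2 d_v, y = q^2 d_w, the determinant instability
# channel is f(x, y) = (-1)^(n+1) det(J - x E_v - y E_w), bilinear:
# f = c00 + c10 x + c01 y + c11 xy, with c00 < 0 whenever J is stable.
# Patterning for EVERY positive diffusion pair means: along every ray
# (x, y) = t (1, rho), rho > 0, some t > 0 gives f > 0. With c00 < 0 this
# reduces to closed-form conditions on the coefficients:
#   c11 > 0                                  (xy term wins at large q), or
#   c11 = 0, c10 >= 0, c01 >= 0, not both 0  (a linear term never hurts), or
#   c11 < 0, c01 >= 0, c10 > 2 sqrt(c11 c00) (concave parabola still peaks
#                                             above 0 for every rho)
.universal_band_batch <- function(jmat, n, v_idx, w_idx, ndraws) {
  f_at <- function(x, y) {
    shift <- vector("list", n)
    for (i in seq_len(n)) shift[[i]] <- rep(0, ndraws)
    shift[[v_idx]] <- rep(x, ndraws)
    shift[[w_idx]] <- rep(y, ndraws)
    get_s <- .get_factory(jmat, n, shift)
    (-1)^(n + 1) * .detv(seq_len(n), seq_len(n), get_s)
  }
  c00 <- f_at(0, 0)
  c10 <- f_at(1, 0) - c00
  c01 <- f_at(0, 1) - c00
  c11 <- f_at(1, 1) - c10 - c01 - c00
  # structural zeros of the coefficients reappear as roundoff of either
  # sign; compare against degree-scaled tolerances instead of 0
  s <- apply(abs(jmat), 1L, max)
  t11 <- 1e-9 * s^(n - 2L)
  t1 <- 1e-9 * s^(n - 1L)
  z11 <- abs(c11) <= t11
  (c11 > t11) |
    (z11 & c10 >= -t1 & c01 >= -t1 & (c10 > t1 | c01 > t1)) |
    (c11 < -t11 & c01 >= -t1 & c00 < 0 &
       c10 > 2 * sqrt(pmax(c11 * c00, 0)) + t1)
}

# Existence search over sampled rate (and diffusion) parameters for one
# signed topology. what = "stable": find a Routh-Hurwitz-stable Jacobian.
# what = "turing": find a diffusion-driven-unstable (J, D) under the
# regime and instability criterion; candidates under "any" are confirmed
# with the eigenvalue-based dispersion test before acceptance (the "band"
# test is already exact algebra); the optional phase predicate must hold
# for the witness. Regime "universal" demands a single Jacobian draw that
# is unstable at every probe diffusion vector (diffusion-independent
# pattern-forming conditions, the Type III property).
.search_topology <- function(top, what = c("turing", "stable"),
                             regime = "free", budget = 20000L,
                             batch = 2500L, seed = 1L, phase_ok = NULL,
                             fixed_d = NULL, box_hi = 0.5, d_box = c(0, 1),
                             grid = default_q2_grid(),
                             criterion = "band",
                             probe_ratios = c(0.01, 0.1, 1, 10, 100),
                             max_confirm = 64L) {
  what <- match.arg(what)
  net <- top$network
  n <- nrow(net$nodes)
  diffusible <- net$nodes$diffusible
  cells <- net$cells
  signs <- top$signs
  values <- top$values %||% rep(NA_real_, length(cells))
  probes <- if (regime == "universal")
    .universal_probes(diffusible, probe_ratios)
  set.seed(seed)
  drawn <- 0L
  undecided <- FALSE
  while (drawn < budget) {
    nb <- min(batch, budget - drawn)
    jmat <- .draw_jbatch(nb, n, cells, signs, values, box_hi)
    a0 <- .charpoly_batch(.get_factory(jmat, n), n, nb)
    stable <- .rh_batch(a0)
    drawn <- drawn + nb
    if (what == "stable") {
      hit <- which(stable)
      if (length(hit)) {
        j <- matrix(jmat[hit[1L], ], n, n, byrow = TRUE)
        return(list(found = TRUE,
                    witness = list(J = j, D = NULL, seed = seed),
                    draws = drawn, undecided = FALSE))
      }
      next
    }
    idx <- which(stable)
    if (!length(idx)) next
    sub <- jmat[idx, , drop = FALSE]
    if (regime == "universal") {
      dif_idx <- which(diffusible)
      if (criterion == "band" && length(dif_idx) == 2L) {
        # exact ray test: diffusion-independent pattern-forming conditions
        get_s <- .get_factory(sub, n)
        nd <- which(!diffusible)
        cand <- !.block_unstable_batch(get_s, nd, length(idx)) &
          .universal_band_batch(sub, n, dif_idx[1L], dif_idx[2L],
                                length(idx))
      } else {
        cand <- rep(TRUE, length(idx))
        for (dv in probes) {
          todo <- which(cand)
          if (!length(todo)) break
          dmat_p <- matrix(rep(dv, each = length(todo)), length(todo), n)
          cand[todo] <- .instability_batch(sub[todo, , drop = FALSE],
                                           dmat_p, n, grid, length(todo),
                                           criterion)
        }
      }
      equal_d <- as.numeric(diffusible)
      dmat <- matrix(rep(equal_d, each = length(idx)), length(idx), n)
    } else {
      dmat <- .draw_dbatch(length(idx), diffusible, regime, d_box, fixed_d)
      cand <- .instability_batch(sub, dmat, n, grid, length(idx), criterion)
    }
    hits <- idx[cand]
    dhits <- which(cand)
    n_conf <- 0L
    for (h_i in seq_along(hits)) {
      if (n_conf >= max_confirm) break
      n_conf <- n_conf + 1L
      j <- matrix(jmat[hits[h_i], ], n, n, byrow = TRUE)
      d <- dmat[dhits[h_i], ]
      if (criterion == "any") {
        ok <- if (regime == "universal")
          all(vapply(probes, function(dv)
            is_turing_unstable(j, D = dv)$turing_unstable, logical(1L)))
        else is_turing_unstable(j, D = d)$turing_unstable
        if (!ok) next
      } else if (regime == "universal") {
        # the ray test is asymptotic in q^2; keep only witnesses whose
        # equal-diffusivity band falls inside the working wave-number range
        if (!is_turing_unstable(j, D = d, mode = "band")$turing_unstable)
          next
      }
      if (!is.null(phase_ok) && !phase_ok(j, d)) next
      return(list(found = TRUE, witness = list(J = j, D = d, seed = seed),
                  draws = drawn, undecided = FALSE))
    }
    if (length(hits) > max_confirm) undecided <- TRUE
  }
  list(found = FALSE, witness = NULL, draws = drawn, undecided = undecided)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
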