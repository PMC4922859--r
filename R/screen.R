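#' Construct a signed topology
#'
#' A topology is a network plus a sign per edge: +1 for activation, -1 for
#' inhibition. A k-edge network has 2^k topologies. Edges may additionally
#' carry fixed rate values (quantitative constraints); value-carrying edges
#' keep the value's sign.
#'
#' @param network an [rd_network].
#' @param signs numeric vector of +1/-1, one per edge, in the network's
#'   (row-major) edge order.
#' @param values optional numeric vector of fixed rates (NA = free
#'   magnitude), same order; non-NA entries must agree in sign with `signs`.
#' @return An object of class `rd_topology`.
#' @export
topology <- function(network, signs, values = NULL) {
  stopifnot(inherits(network, "rd_network"), length(signs) == network$k,
            all(signs %in% c(-1, 1)))
  if (!is.null(values)) {
    stopifnot(length(values) == network$k)
    fixed <- !is.na(values)
    if (any(sign(values[fixed]) != signs[fixed]))
      stop("fixed edge values conflict with the topology's signs")
  }
  structure(list(network = network, signs = as.numeric(signs),
                 values = values), class = "rd_topology")
}

#' @export
print.rd_topology <- function(x, ...) {
  lab <- format_edges(x$network)
  cat("<rd_topology>\n")
  cat(paste0("  ", ifelse(x$signs > 0, "+", "-"), " ", lab), sep = "\n")
  invisible(x)
}

#' Specify screen constraints
#'
#' Collects the qualitative and quantitative constraints of a screen:
#' forced or forbidden edges, fixed interaction signs, fixed rate values
#' (e.g. measured clearance rate constants), fixed diffusion coefficients,
#' and required phase relations between named nodes. Structural shortcuts
#' expand common biological rules: `no_diffusible_to_diffusible` forbids
#' direct edges between distinct diffusible nodes (signals interact only
#' through cell-autonomous factors), `diffusible_self_inhibition` requires
#' any self-edge on a diffusible node to be inhibitory (decay/clearance).
#'
#' @param nodes the [rd_nodes] the constraints refer to.
#' @param forced_edges,forbidden_edges two-column (`target`, `source`)
#'   matrices of node indices, or cell-index vectors.
#' @param sign_constraints data frame with columns `target`, `source`,
#'   `sign` (+1/-1); indices or labels.
#' @param value_constraints data frame with columns `target`, `source`,
#'   `value` (signed rate).
#' @param phase_constraints data frame with columns `a`, `b` (node labels
#'   or indices) and `relation` ("in-phase" or "out-of-phase").
#' @param fixed_diffusion named numeric vector of diffusion coefficients
#'   keyed by node label, or NULL.
#' @param no_diffusible_to_diffusible forbid edges between distinct
#'   diffusible nodes.
#' @param diffusible_self_inhibition force self-edges on diffusible nodes,
#'   when present, to be inhibitory.
#' @return An object of class `constraint_set`.
#' @export
constraint_set <- function(nodes, forced_edges = NULL, forbidden_edges = NULL,
                           sign_constraints = NULL, value_constraints = NULL,
                           phase_constraints = NULL, fixed_diffusion = NULL,
                           no_diffusible_to_diffusible = FALSE,
                           diffusible_self_inhibition = FALSE) {
  stopifnot(inherits(nodes, "rd_nodes"))
  n <- nrow(nodes)
  forced <- as_cells(forced_edges, n)
  forbidden <- as_cells(forbidden_edges, n)
  signs <- stats::setNames(numeric(0), character(0))
  if (!is.null(sign_constraints)) {
    cl <- cell_index(node_id(sign_constraints$target, nodes),
                     node_id(sign_constraints$source, nodes), n)
    signs <- stats::setNames(as.numeric(sign_constraints$sign),
                             as.character(cl))
  }
  values <- stats::setNames(numeric(0), character(0))
  if (!is.null(value_constraints)) {
    cl <- cell_index(node_id(value_constraints$target, nodes),
                     node_id(value_constraints$source, nodes), n)
    values <- stats::setNames(as.numeric(value_constraints$value),
                              as.character(cl))
  }
  if (no_diffusible_to_diffusible) {
    dif <- which(nodes$diffusible)
    extra <- c(outer(dif, dif, function(i, j) cell_index(i, j, n)))
    extra <- setdiff(extra, cell_index(dif, dif, n)) # keep self-edges
    forbidden <- sort(union(forbidden, extra))
  }
  if (diffusible_self_inhibition) {
    dif <- which(nodes$diffusible)
    for (cl in cell_index(dif, dif, n)) {
      key <- as.character(cl)
      if (key %in% names(signs) && signs[[key]] > 0)
        stop("diffusible_self_inhibition conflicts with a +1 sign constraint")
      signs[key] <- -1
    }
  }
  if (length(intersect(forced, forbidden)))
    stop("forced and forbidden edges overlap")
  if (length(intersect(as.integer(names(signs)), forbidden)))
    stop("sign constraints on forbidden edges")
  both <- intersect(names(signs), names(values))
  if (length(both) && any(sign(values[both]) != signs[both]))
    stop("conflicting sign and value constraints")
  for (key in names(values)) signs[key] <- sign(values[[key]])
  phase <- NULL
  if (!is.null(phase_constraints)) {
    phase <- data.frame(a = node_id(phase_constraints$a, nodes),
                        b = node_id(phase_constraints$b, nodes),
                        relation = as.character(phase_constraints$relation),
                        stringsAsFactors = FALSE)
    stopifnot(all(phase$relation %in% c("in-phase", "out-of-phase")))
  }
  if (!is.null(fixed_diffusion)) {
    stopifnot(!is.null(names(fixed_diffusion)),
              all(names(fixed_diffusion) %in% nodes$label))
  }
  structure(list(nodes = nodes, forced = forced, forbidden = forbidden,
                 signs = signs, values = values, phase = phase,
                 fixed_diffusion = fixed_diffusion), class = "constraint_set")
}

node_id <- function(x, nodes) {
  if (is.numeric(x)) return(as.integer(x))
  i <- match(as.character(x), nodes$label)
  if (anyNA(i)) stop("unknown node label(s): ",
                     paste(x[is.na(i)], collapse = ", "))
  i
}

empty_constraints <- function(nodes) constraint_set(nodes)

#' Enumerate the signed topologies of a network
#'
#' All sign assignments consistent with the sign and value constraints,
#' each exactly once; `2^(k - #constrained edges)` topologies. Free signs
#' are enumerated +1-first in row-major edge order, giving a deterministic
#' sign-bit-string order.
#'
#' @param net an [rd_network].
#' @param constraints optional [constraint_set()].
#' @return list of [topology()] objects.
#' @export
enumerate_topologies <- function(net, constraints = NULL) {
  k <- net$k
  cells <- net$cells
  signs0 <- rep(NA_real_, k)
  values <- rep(NA_real_, k)
  if (!is.null(constraints)) {
    key <- as.character(cells)
    csigns <- constraints$signs[key]
    signs0 <- ifelse(is.na(csigns), NA_real_, as.numeric(csigns))
    cvals <- constraints$values[key]
    values <- ifelse(is.na(cvals), NA_real_, as.numeric(cvals))
  }
  free <- which(is.na(signs0))
  n_free <- length(free)
  out <- vector("list", 2^n_free)
  for (b in seq_len(2^n_free)) {
    bits <- as.integer(intToBits(b - 1L))[seq_len(max(n_free, 1L))]
    s <- signs0
    if (n_free) s[free] <- ifelse(bits[seq_len(n_free)] == 0L, 1, -1)
    out[[b]] <- topology(net, s, if (all(is.na(values))) NULL else values)
  }
  out
}

# class-preserving permutations that also preserve the constraint structure
constraint_permutations <- function(nodes, constraints = NULL) {
  perms <- class_permutations(nodes$diffusible)
  if (is.null(constraints)) return(perms)
  n <- nrow(nodes)
  map_cells <- function(cells, p) {
    if (!length(cells)) return(integer(0))
    ts <- cell_from_index(cells, n)
    sort(cell_index(p[ts[, "target"]], p[ts[, "source"]], n))
  }
  map_one <- function(cl, p) {
    ts <- cell_from_index(cl, n)
    cell_index(p[ts[, "target"]], p[ts[, "source"]], n)
  }
  ok <- vapply(perms, function(p) {
    if (!identical(map_cells(constraints$forced, p), constraints$forced))
      return(FALSE)
    if (!identical(map_cells(constraints$forbidden, p),
                   constraints$forbidden))
      return(FALSE)
    for (key in names(constraints$signs)) {
      tgt <- constraints$signs[as.character(map_one(as.integer(key), p))]
      if (is.na(tgt) || tgt != constraints$signs[[key]]) return(FALSE)
    }
    for (key in names(constraints$values)) {
      tgt <- constraints$values[as.character(map_one(as.integer(key), p))]
      if (is.na(tgt) || tgt != constraints$values[[key]]) return(FALSE)
    }
    if (!is.null(constraints$phase)) {
      ph <- constraints$phase
      orig <- paste(pmin(ph$a, ph$b), pmax(ph$a, ph$b), ph$relation)
      mapped <- paste(pmin(p[ph$a], p[ph$b]), pmax(p[ph$a], p[ph$b]),
                      ph$relation)
      if (!setequal(orig, mapped)) return(FALSE)
    }
    if (!is.null(constraints$fixed_diffusion)) {
      dv <- rep(NA_real_, n)
      dv[match(names(constraints$fixed_diffusion), nodes$label)] <-
        constraints$fixed_diffusion
      if (!identical(dv[p], dv)) return(FALSE)
    }
    TRUE
  }, logical(1L))
  perms[ok]
}

#' Predicted phase relations of the emerging pattern
#'
#' The sign pattern of the fastest-growing spatial mode: signs of the real
#' parts of the dominant eigenvector of `J - q*^2 diag(D)` at the critical
#' wave number, normalized so the first diffusible node is positive. Nodes
#' sharing a sign are predicted to peak at the same spatial positions
#' (in-phase). When the dispersion maximum sits at the q -> infinity limit
#' the eigenvector is taken at a large finite q^2 instead.
#'
#' @param sys an [rd_system()] (should be Turing unstable).
#' @return integer vector of +1/-1 per node.
#' @examples
#' phase_pattern(rd_system(rbind(c(1, -1), c(3, -2)), c(1, 10))) # c(1, 1)
#' @export
phase_pattern <- function(sys) {
  stopifnot(inherits(sys, "rd_system"))
  disp <- dispersion(sys$J, sys$D)
  v <- Re(disp$eigvec_star)
  ref <- which(sys$diffusible)[1L]
  if (is.na(ref)) ref <- 1L
  anchor <- v[ref]
  if (abs(anchor) < 1e-12) anchor <- v[which.max(abs(v))]
  out <- ifelse(sign(v / anchor) >= 0, 1L, -1L)
  names(out) <- sys$labels
  out
}

phase_predicate <- function(constraints, net) {
  if (is.null(constraints) || is.null(constraints$phase)) return(NULL)
  ph <- constraints$phase
  function(J, D) {
    p <- phase_pattern(rd_system(J, D, labels = net$nodes$label))
    ok <- TRUE
    for (r in seq_len(nrow(ph))) {
      same <- p[ph$a[r]] == p[ph$b[r]]
      ok <- ok && if (ph$relation[r] == "in-phase") same else !same
    }
    ok
  }
}

values_for <- function(net, constraints) {
  if (is.null(constraints) || !length(constraints$values)) return(NULL)
  v <- constraints$values[as.character(net$cells)]
  if (all(is.na(v))) NULL else as.numeric(v)
}

fixed_d_for <- function(nodes, constraints) {
  if (is.null(constraints) || is.null(constraints$fixed_diffusion))
    return(NULL)
  dv <- rep(0, nrow(nodes))
  dv[nodes$diffusible] <- NA_real_
  idx <- match(names(constraints$fixed_diffusion), nodes$label)
  dv[idx] <- constraints$fixed_diffusion
  if (anyNA(dv)) stop("fixed_diffusion must cover every diffusible node")
  dv
}

#' Can a topology reach a stable homogeneous steady state?
#'
#' Samples rate magnitudes within the rate box (uniform and log-uniform
#' draws mixed, since the stability conditions are scale-free), respecting
#' the topology's signs, and reports whether any sample is Routh-Hurwitz
#' stable at q = 0. A witness Jacobian and the seed are recorded on
#' success.
#'
#' @param top a [topology()].
#' @param budget number of parameter draws.
#' @param seed RNG seed for the search.
#' @param box_hi upper rate-magnitude limit (rates live in
#'   (-box_hi, box_hi)).
#' @param ... further arguments passed to the internal search.
#' @return list with `stable`, `witness`, `draws`.
#' @export
topology_is_stable <- function(top, budget = 20000L, seed = 1L,
                               box_hi = 0.5, ...) {
  res <- .search_topology(top, what = "stable", budget = budget, seed = seed,
                          box_hi = box_hi, ...)
  list(stable = res$found, witness = res$witness, draws = res$draws)
}

#' Can a topology form a diffusion-driven pattern?
#'
#' Samples (rates, diffusion coefficients) under the requested diffusion
#' regime and reports whether any sample is Turing unstable. The default
#' criterion `"band"` asks for a finite-wavelength stationary instability
#' (see [is_turing_unstable()]); criterion `"any"` accepts every growing
#' mode, including capacitor-driven growth in the q -> infinity limit.
#'
#' For the `"universal"` regime under criterion `"any"`, the analytic
#' shortcut is attempted first: a stable Jacobian whose non-diffusible
#' sub-block is unstable certifies patterning for every combination of
#' positive diffusion coefficients. Under criterion `"band"` (and as the
#' numeric fallback) a probe set of diffusion ratios spanning equal,
#' much-smaller and much-larger diffusivities must all support patterning.
#'
#' @param top a [topology()].
#' @param regime one of `"free"`, `"equal"`, `"fixed"`, `"universal"`.
#' @param fixed_d diffusion coefficients for the `"fixed"` regime.
#' @param budget,seed,box_hi as in [topology_is_stable()].
#' @param criterion `"band"` (default) or `"any"`.
#' @param probe_ratios diffusion ratios probed by the `"universal"` regime
#'   (two diffusible nodes).
#' @param phase_ok optional predicate `function(J, D)` a witness must
#'   satisfy (phase constraints).
#' @param ... further arguments passed to the internal search.
#' @return list with `capable`, `witness`, `certificate` (TRUE when
#'   capability was certified analytically), `draws`, `undecided`.
#' @export
topology_turing_capable <- function(top, regime = "free", fixed_d = NULL,
                                    budget = 20000L, seed = 1L,
                                    box_hi = 0.5, criterion = "band",
                                    probe_ratios = c(0.01, 0.1, 1, 10, 100),
                                    phase_ok = NULL, ...) {
  if (regime == "universal" && criterion == "any") {
    cert <- .search_certificate(top, budget = budget, seed = seed,
                                box_hi = box_hi, phase_ok = phase_ok)
    if (cert$found)
      return(list(capable = TRUE, witness = cert$witness,
                  certificate = TRUE, draws = cert$draws,
                  undecided = FALSE))
  }
  res <- .search_topology(top, what = "turing", regime = regime,
                          probe_ratios = probe_ratios,
                          fixed_d = fixed_d, budget = budget, seed = seed,
                          box_hi = box_hi, criterion = criterion,
                          phase_ok = phase_ok, ...)
  list(capable = res$found, witness = res$witness, certificate = FALSE,
       draws = res$draws, undecided = res$undecided)
}

# search for the capacitor certificate: a Routh-Hurwitz-stable J whose
# non-diffusible sub-block has positive spectral abscissa; such a J is
# Turing unstable (criterion "any") for every positive diffusion vector
.search_certificate <- function(top, budget = 20000L, batch = 2500L,
                                seed = 1L, box_hi = 0.5, phase_ok = NULL) {
  net <- top$network
  n <- nrow(net$nodes)
  nd <- which(!net$nodes$diffusible)
  if (!length(nd))
    return(list(found = FALSE, witness = NULL, draws = 0L))
  values <- top$values %||% rep(NA_real_, net$k)
  set.seed(.sub_seed(seed, 999L))
  drawn <- 0L
  while (drawn < budget) {
    nb <- min(batch, budget - drawn)
    jmat <- .draw_jbatch(nb, n, net$cells, top$signs, values, box_hi)
    get0 <- .get_factory(jmat, n)
    a0 <- .charpoly_batch(get0, n, nb)
    hit <- which(.rh_batch(a0) & .block_unstable_batch(get0, nd, nb))
    drawn <- drawn + nb
    for (h in hit[seq_len(min(length(hit), 32L))]) {
      j <- matrix(jmat[h, ], n, n, byrow = TRUE)
      d <- as.numeric(net$nodes$diffusible)
      rep_ <- is_turing_unstable(j, D = d)
      if (!rep_$turing_unstable) next
      if (!is.null(phase_ok) && !phase_ok(j, d)) next
      return(list(found = TRUE,
                  witness = list(J = j, D = d, seed = seed,
                                 certificate = TRUE),
                  draws = drawn))
    }
  }
  list(found = FALSE, witness = NULL, draws = drawn)
}

#' Classify a network's diffusivity requirement
#'
#' Type III networks pattern for every combination of positive diffusion
#' coefficients (probed across diffusion ratios spanning four orders of
#' magnitude, or certified analytically under criterion `"any"`); Type II
#' networks pattern with equal diffusivities; Type I networks require
#' differential diffusivity. The network's label is the best label over
#' its surviving topologies.
#'
#' @param tops list of [topology()] objects (the network's surviving
#'   topologies).
#' @param budget,seed,box_hi,criterion,phase_ok see
#'   [topology_turing_capable()].
#' @param ... further arguments passed to the capability searches.
#' @return list with `type` ("I", "II" or "III") and per-topology labels.
#' @export
classify_network <- function(tops, budget = 20000L, seed = 1L, box_hi = 0.5,
                             criterion = "band", phase_ok = NULL, ...) {
  labels <- character(length(tops))
  for (t_i in seq_along(tops)) {
    eq <- topology_turing_capable(tops[[t_i]], regime = "equal",
                                  budget = budget,
                                  seed = .sub_seed(seed, t_i, 1L),
                                  box_hi = box_hi, criterion = criterion,
                                  phase_ok = phase_ok, ...)
    if (!eq$capable) { labels[t_i] <- "I"; next }
    un <- topology_turing_capable(tops[[t_i]], regime = "universal",
                                  budget = budget,
                                  seed = .sub_seed(seed, t_i, 2L),
                                  box_hi = box_hi, criterion = criterion,
                                  phase_ok = phase_ok, ...)
    labels[t_i] <- if (un$capable) "III" else "II"
  }
  lev <- c("I", "II", "III")
  list(type = lev[max(match(labels, lev))], topology_types = labels)
}

#' Robustness of a topology: relative Turing-space volume
#'
#' Monte-Carlo estimate of the fraction of the unit parameter box (rates
#' uniform in `(-0.5, 0.5)` restricted to the topology's signs, diffusion
#' coefficients uniform in `(0, 1)` per the regime) that satisfies both the
#' homogeneous-stability and the diffusion-instability condition. This is
#' the probability that randomly picked parameters form a pattern.
#'
#' @param top a [topology()].
#' @param regime diffusion regime (see [topology_turing_capable()];
#'   `"universal"` is evaluated as `"free"` for volume purposes).
#' @param n number of Monte-Carlo samples.
#' @param seed RNG seed.
#' @param rate_box,diffusion_box sampling boxes `(lo, hi)` for rate
#'   magnitudes and diffusion coefficients.
#' @param fixed_d fixed diffusion coefficients for the `"fixed"` regime.
#' @param criterion instability criterion, `"band"` or `"any"`.
#' @param grid q^2 grid used for the instability decision.
#' @return list with `estimate`, `se` (binomial standard error), `n`,
#'   `seed`.
#' @export
robustness <- function(top, regime = "free", n = 20000L, seed = 1L,
                       rate_box = c(-0.5, 0.5), diffusion_box = c(0, 1),
                       fixed_d = NULL, criterion = "band",
                       grid = default_q2_grid()) {
  net <- top$network
  nn <- nrow(net$nodes)
  if (regime == "universal") regime <- "free"
  values <- top$values %||% rep(NA_real_, net$k)
  set.seed(seed)
  jmat <- .draw_jbatch(n, nn, net$cells, top$signs, values, rate_box[2],
                       mix = FALSE)
  a0 <- .charpoly_batch(.get_factory(jmat, nn), nn, n)
  stable <- .rh_batch(a0)
  good <- rep(FALSE, n)
  idx <- which(stable)
  if (length(idx)) {
    dmat <- .draw_dbatch(length(idx), net$nodes$diffusible, regime,
                         diffusion_box, fixed_d, mix = FALSE)
    good[idx] <- .instability_batch(jmat[idx, , drop = FALSE], dmat, nn,
                                    grid, length(idx), criterion)
  }
  p <- mean(good)
  list(estimate = p, se = sqrt(p * (1 - p) / n), n = n, seed = seed)
}

#' Minimum diffusion ratio that allows patterning
#'
#' For a topology with exactly two diffusible nodes, finds the infimum of
#' the diffusion ratio `d = d2/d1` (second over first diffusible node) for
#' which the constrained Turing space is non-empty. When every edge rate is
#' fixed the feasibility test is deterministic; otherwise feasibility at a
#' ratio is decided by sampled search over the free rates. The boundary is
#' located by bisection between the last infeasible and first feasible
#' point of a logarithmic ratio scan. Returns 0 when patterning is
#' possible at every probed ratio (Type III behavior) and `NULL` when no
#' ratio is feasible.
#'
#' @param top a [topology()]; fixed rates are carried in `top$values`.
#' @param d_range ratio scan range.
#' @param n_scan number of logarithmic scan points.
#' @param tol absolute bisection tolerance on the ratio.
#' @param budget sampling budget per feasibility test (ignored when all
#'   rates are fixed).
#' @param seed RNG seed.
#' @param criterion instability criterion, `"band"` or `"any"`.
#' @param ... further arguments passed to the feasibility searches.
#' @return scalar ratio, 0, or NULL.
#' @export
min_diffusion_ratio <- function(top, d_range = c(1e-3, 1e3), n_scan = 49L,
                                tol = 1e-4, budget = 20000L, seed = 1L,
                                criterion = "band", ...) {
  net <- top$network
  diffusible <- which(net$nodes$diffusible)
  if (length(diffusible) != 2L)
    stop("min_diffusion_ratio requires exactly two diffusible nodes")
  nn <- nrow(net$nodes)
  all_fixed <- !is.null(top$values) && !anyNA(top$values)
  feas <- function(d) {
    dv <- rep(0, nn)
    dv[diffusible] <- c(1, d)
    if (all_fixed) {
      j <- matrix(0, nn, nn)
      ts <- cell_from_index(net$cells, nn)
      j[cbind(ts[, "target"], ts[, "source"])] <- top$values
      return(is_turing_unstable(j, D = dv, mode = "band")$turing_unstable)
    }
    .search_topology(top, what = "turing", regime = "fixed", fixed_d = dv,
                     budget = budget, seed = .sub_seed(seed, round(1e6 * d)),
                     criterion = criterion, ...)$found
  }
  scan <- exp(seq(log(d_range[1]), log(d_range[2]), length.out = n_scan))
  ok <- vapply(scan, feas, logical(1L))
  if (!any(ok)) return(NULL)
  first <- which(ok)[1L]
  if (first == 1L) return(0)
  lo <- scan[first - 1L]; hi <- scan[first]
  while (hi - lo > tol) {
    mid <- sqrt(lo * hi)
    if (feas(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Run the full screening pipeline
#'
#' Executes the six screening steps: (1) enumerate all k-edge networks
#' under the structural constraints, (2) keep strongly connected networks,
#' (3) de-duplicate isomorphic networks, (4) keep topologies that admit a
#' stable homogeneous steady state, (5) keep topologies that are unstable
#' to spatial perturbations (Turing capable under the regime and
#' instability criterion, and matching any phase constraints), (6)
#' classify each surviving network's diffusivity requirement, derive the
#' in-phase/out-of-phase pattern of every surviving topology and estimate
#' robustness.
#'
#' In the step-count table, the topology column counts raw sign
#' assignments through step 4; at step 5-6 it counts the distinct phase
#' signatures realized by each surviving network (sign assignments that
#' generate the same pattern phases describe the same reaction-diffusion
#' behavior; each network realizes at most `2^(N-1)` of them).
#'
#' @param nodes an [rd_nodes] object; at least two diffusible nodes.
#' @param k number of edges.
#' @param constraints optional [constraint_set()].
#' @param regime diffusion regime for the capability step (default
#'   `"free"`: each diffusible node's coefficient sampled independently).
#' @param criterion instability criterion, `"band"` (finite-wavelength
#'   stationary patterns; default) or `"any"`.
#' @param budget sampling budget per topology per search.
#' @param robustness_n Monte-Carlo samples per surviving topology for the
#'   robustness estimate (0 skips robustness).
#' @param seed master seed; every per-topology search derives its own
#'   reproducible sub-seed from it.
#' @param classify label surviving networks Type I/II/III (adds equal- and
#'   universal-regime searches per surviving topology).
#' @param max_topologies abort if a single network would contribute more
#'   than this many topologies (guards heavily unconstrained 5-node runs).
#' @param progress print step summaries as the screen runs.
#' @param ... further arguments passed to the topology searches.
#' @return An object of class `rd_catalog`: list with `entries` (one per
#'   surviving network), `steps` (the step-count table as a data frame),
#'   `seed`, and `regime`.
#' @export
run_pipeline <- function(nodes, k, constraints = NULL, regime = "free",
                         criterion = "band", budget = 20000L,
                         robustness_n = 2000L, seed = 1L, classify = TRUE,
                         max_topologies = 4096L, progress = FALSE, ...) {
  stopifnot(inherits(nodes, "rd_nodes"))
  if (sum(nodes$diffusible) < 2L)
    stop("at least two diffusible nodes are required to form a pattern")
  if (is.null(constraints)) constraints <- empty_constraints(nodes)
  fixed_d <- fixed_d_for(nodes, constraints)
  run_regime <- if (!is.null(fixed_d) && regime == "free") "fixed" else regime
  perms <- constraint_permutations(nodes, constraints)

  n_free_signs <- function(net) {
    key <- as.character(net$cells)
    sum(is.na(constraints$signs[key]))
  }
  say <- function(...) if (progress) message(sprintf(...))

  nets1 <- enumerate_networks(nodes, k, forced_edges = constraints$forced,
                              forbidden_edges = constraints$forbidden)
  t1 <- sum(vapply(nets1, function(nt) 2^n_free_signs(nt), numeric(1L)))
  say("step 1: %d networks / %d topologies", length(nets1), t1)
  if (!length(nets1))
    return(empty_catalog(nodes, k, regime, seed,
                         steps_table(0, t1, 0, 0, 0, 0, 0, 0, 0, 0)))

  nets2 <- Filter(passes_connectivity_filter, nets1)
  t2 <- sum(vapply(nets2, function(nt) 2^n_free_signs(nt), numeric(1L)))
  say("step 2: %d networks / %d topologies", length(nets2), t2)

  nets3 <- dedup_networks(nets2, perms)
  keys3 <- attr(nets3, "keys")
  t3 <- sum(vapply(nets3, function(nt) 2^n_free_signs(nt), numeric(1L)))
  say("step 3: %d networks / %d topologies", length(nets3), t3)

  entries <- list()
  n4_networks <- 0L; n4_topologies <- 0L
  n5_networks <- 0L; n5_patterns <- 0L
  for (net_i in seq_along(nets3)) {
    net <- nets3[[net_i]]
    tops <- enumerate_topologies(net, constraints)
    if (length(tops) > max_topologies)
      stop("network with ", length(tops), " topologies exceeds ",
           "max_topologies = ", max_topologies,
           "; add constraints or raise the cap")
    stable_tops <- list()
    for (t_i in seq_along(tops)) {
      st <- topology_is_stable(tops[[t_i]], budget = budget,
                               seed = .sub_seed(seed, net_i, t_i, 4L), ...)
      if (st$stable)
        stable_tops[[length(stable_tops) + 1L]] <- tops[[t_i]]
    }
    if (!length(stable_tops)) next
    n4_networks <- n4_networks + 1L
    n4_topologies <- n4_topologies + length(stable_tops)

    phase_ok <- phase_predicate(constraints, net)
    surv <- list()
    for (t_i in seq_along(stable_tops)) {
      cap <- topology_turing_capable(
        stable_tops[[t_i]], regime = run_regime, fixed_d = fixed_d,
        budget = budget, seed = .sub_seed(seed, net_i, t_i, 56L),
        criterion = criterion, phase_ok = phase_ok, ...)
      if (cap$capable)
        surv[[length(surv) + 1L]] <- list(top = stable_tops[[t_i]],
                                          witness = cap$witness,
                                          certificate = cap$certificate)
    }
    if (!length(surv)) next
    n5_networks <- n5_networks + 1L

    cls <- if (classify)
      classify_network(lapply(surv, `[[`, "top"), budget = budget,
                       seed = .sub_seed(seed, net_i, 77L),
                       criterion = criterion, phase_ok = phase_ok, ...)
    else list(type = NA_character_,
              topology_types = rep(NA_character_, length(surv)))
    topo_records <- lapply(seq_along(surv), function(t_i) {
      s <- surv[[t_i]]
      wit <- s$witness
      ph <- phase_pattern(rd_system(wit$J, wit$D,
                                    labels = net$nodes$label))
      rob <- if (robustness_n > 0L)
        robustness(s$top, regime = run_regime, n = robustness_n,
                   seed = .sub_seed(seed, net_i, t_i, 99L),
                   fixed_d = fixed_d, criterion = criterion)
      else list(estimate = NA_real_, se = NA_real_, n = 0L)
      list(signs = s$top$signs, values = s$top$values, witness = wit,
           certificate = s$certificate, phase = ph,
           type = cls$topology_types[t_i],
           robustness = rob$estimate, robustness_se = rob$se)
    })
    phases <- unique(vapply(topo_records,
                            function(tr) paste(tr$phase, collapse = ""),
                            character(1L)))
    n5_patterns <- n5_patterns + length(phases)
    entries[[length(entries) + 1L]] <- list(
      network = net, key = keys3[net_i], type = cls$type,
      n_phase_patterns = length(phases), topologies = topo_records)
    say("network %d/%d: %d surviving topologies (%d phase patterns), Type %s",
        net_i, length(nets3), length(surv), length(phases), cls$type)
  }
  steps <- steps_table(length(nets1), t1, length(nets2), t2,
                       length(nets3), t3, n4_networks, n4_topologies,
                       n5_networks, n5_patterns)
  structure(list(entries = entries, steps = steps, seed = seed,
                 regime = regime, criterion = criterion, nodes = nodes,
                 k = k, budget = budget), class = "rd_catalog")
}

steps_table <- function(n1, t1, n2, t2, n3, t3, n4, t4, n5, t5) {
  data.frame(
    step = c("1. minimal systems", "2. strongly connected",
             "3. non-symmetrical", "4. stable", "5-6. reaction-diffusion"),
    networks = c(n1, n2, n3, n4, n5),
    topologies = c(t1, t2, t3, t4, t5))
}

empty_catalog <- function(nodes, k, regime, seed, steps) {
  structure(list(entries = list(), steps = steps, seed = seed,
                 regime = regime, nodes = nodes, k = k),
            class = "rd_catalog")
}

#' @export
print.rd_catalog <- function(x, ...) {
  cat(sprintf("<rd_catalog> %d networks (seed %s, regime %s)\n",
              length(x$entries), format(x$seed), x$regime))
  print(x$steps, row.names = FALSE)
  if (length(x$entries)) {
    types <- vapply(x$entries, `[[`, character(1L), "type")
    tab <- table(types)
    cat("types:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Summarize a catalog as a data frame
#'
#' One row per surviving network: canonical key, Type label, number of
#' surviving sign assignments and distinct phase patterns, best robustness
#' estimate with its standard error, and robustness relative to the
#' catalog maximum.
#'
#' @param object an `rd_catalog`.
#' @param ... unused.
#' @return data frame.
#' @export
summary.rd_catalog <- function(object, ...) {
  if (!length(object$entries))
    return(data.frame(key = character(0), type = character(0),
                      n_topologies = integer(0), n_phase_patterns = integer(0),
                      robustness = numeric(0), robustness_se = numeric(0),
                      relative_robustness = numeric(0)))
  rows <- lapply(object$entries, function(e) {
    rob <- vapply(e$topologies, `[[`, numeric(1L), "robustness")
    best <- if (all(is.na(rob))) NA_integer_ else which.max(rob)
    data.frame(key = e$key, type = e$type,
               n_topologies = length(e$topologies),
               n_phase_patterns = e$n_phase_patterns,
               robustness = if (is.na(best)) NA_real_ else rob[best],
               robustness_se = if (is.na(best)) NA_real_
                               else e$topologies[[best]]$robustness_se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  mx <- suppressWarnings(max(out$robustness, na.rm = TRUE))
  out$relative_robustness <- if (is.finite(mx) && mx > 0)
    out$robustness / mx else NA_real_
  out
}
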