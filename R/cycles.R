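#' Find all feedback cycles of a network
#'
#' Enumerates every simple directed cycle, including self-loops (length-1
#' cycles), each reported once up to rotation: the node sequence starts at
#' the cycle's smallest node index. Sizes are tiny (N <= 5), so cycles are
#' found by brute force over node subsets and orderings.
#'
#' @param net an [rd_network] or a [topology()].
#' @return list of objects of class `rd_cycle`, each with fields `nodes`
#'   (the directed node sequence) and `length`.
#' @examples
#' nodes <- rd_nodes(c(TRUE, TRUE))
#' net <- rd_network(nodes, rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2)))
#' length(find_cycles(net)) # 3: two self-loops and one 2-cycle
#' @export
find_cycles <- function(net) {
  if (inherits(net, "rd_topology")) net <- net$network
  n <- nrow(net$nodes)
  a <- adjacency_matrix(net) # a[i, j]: j regulates i, arc j -> i
  out <- list()
  for (v in seq_len(n)) if (a[v, v]) out[[length(out) + 1L]] <- cycle_obj(v)
  for (len in 2:n) {
    if (len > n) break
    subs <- utils::combn(n, len)
    for (s_i in seq_len(ncol(subs))) {
      s <- subs[, s_i]
      first <- s[1L] # smallest; fixes the rotation
      rest <- s[-1L]
      for (p in all_permutations(length(rest))) {
        seqn <- c(first, rest[p])
        nxt <- c(seqn[-1L], first)
        if (all(a[cbind(nxt, seqn)] == 1L))
          out[[length(out) + 1L]] <- cycle_obj(seqn)
      }
    }
  }
  out
}

cycle_obj <- function(nodes) {
  structure(list(nodes = as.integer(nodes), length = length(nodes)),
            class = "rd_cycle")
}

#' @export
print.rd_cycle <- function(x, ...) {
  cat("<cycle>", paste(c(x$nodes, x$nodes[1L]), collapse = " -> "), "\n")
  invisible(x)
}

#' Gain of a cycle under a Jacobian
#'
#' Product of the J entries along the cycle; its sign is the cycle's net
#' sign (positive = net-activating, negative = net-inhibiting feedback).
#'
#' @param cycle an `rd_cycle`.
#' @param J Jacobian matrix.
#' @return scalar gain.
#' @export
cycle_gain <- function(cycle, J) {
  seqn <- cycle$nodes
  nxt <- c(seqn[-1L], seqn[1L])
  prod(J[cbind(nxt, seqn)])
}

# all ways to cover node set s exactly by vertex-disjoint cycles of the
# given cycle list; returns list of integer vectors (indices into cycles)
cycle_covers <- function(s, cycles) {
  if (!length(s)) return(list(integer(0)))
  anchor <- min(s)
  out <- list()
  for (c_i in seq_along(cycles)) {
    cn <- cycles[[c_i]]$nodes
    if (cn[1L] != anchor) next # cycles start at their min node
    if (!all(cn %in% s)) next
    for (rest in cycle_covers(setdiff(s, cn), cycles))
      out[[length(out) + 1L]] <- c(c_i, rest)
  }
  out
}

#' Characteristic-polynomial coefficient from feedback cycles
#'
#' Computes `a_m` of the characteristic polynomial of `J` (at q = 0) from
#' the network's feedback structure instead of determinants: each order-m
#' principal minor is expanded as a signed sum over vertex-disjoint cycle
#' covers, `(-1)^(m - #cycles)` times the product of cycle gains, and
#' `a_m = (-1)^m` times the sum over all m-node subsets. This identity is
#' what lets pattern-forming conditions be read in terms of stabilizing and
#' destabilizing feedback cycles rather than individual rates.
#'
#' @param J Jacobian matrix.
#' @param m coefficient order, `1 <= m <= N`.
#' @return scalar, equal to `char_poly_coeffs(J, 0, 0)$coefficients[m]`.
#' @examples
#' coeff_from_cycles(diag(c(-1, -2, -3)), 1) # 6
#' @export
coeff_from_cycles <- function(J, m) {
  J <- as.matrix(J)
  n <- nrow(J)
  stopifnot(m >= 1, m <= n)
  net <- rd_network(rd_nodes(rep(TRUE, n)), which(t(J) != 0))
  cycles <- find_cycles(net)
  subs <- utils::combn(n, m)
  total <- 0
  for (s_i in seq_len(ncol(subs))) {
    s <- subs[, s_i]
    for (cov in cycle_covers(s, cycles)) {
      gains <- prod(vapply(cov, function(ci) cycle_gain(cycles[[ci]], J),
                           numeric(1L)))
      total <- total + (-1)^(m - length(cov)) * gains
    }
  }
  (-1)^m * total
}

#' Feedback report of a signed topology
#'
#' Lists every feedback cycle with its net sign label (net-positive cycles
#' are destabilizing candidates, net-negative cycles stabilizing
#' candidates), which characteristic-polynomial coefficients `a_m` (and
#' hence which Routh-Hurwitz stability conditions) each cycle enters, and
#' whether the cycle is confined to non-diffusible nodes — such cycles
#' survive the q -> infinity limit and are the diffusion-independent
#' ("capacitor") contributors that underlie Type III patterning.
#'
#' @param top a [topology()].
#' @return An object of class `feedback_report`: a data frame with one row
#'   per cycle (`cycle`, `length`, `sign`, `role`, `coefficients`,
#'   `diffusion_independent`).
#' @export
feedback_report <- function(top) {
  stopifnot(inherits(top, "rd_topology"))
  net <- top$network
  n <- nrow(net$nodes)
  cycles <- find_cycles(net)
  signs <- sign_matrix(top)
  diffusible <- net$nodes$diffusible
  rows <- lapply(cycles, function(cy) {
    sg <- cycle_gain(cy, signs)
    data.frame(
      cycle = paste(net$nodes$label[c(cy$nodes, cy$nodes[1L])],
                    collapse = "->"),
      length = cy$length,
      sign = sg,
      role = if (sg > 0) "destabilizing" else "stabilizing",
      coefficients = NA_character_,
      diffusion_independent = all(!diffusible[cy$nodes]),
      stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, rows)
  # a cycle enters a_m when it takes part in a cycle cover of some m-subset
  enters <- matrix(FALSE, length(cycles), n)
  for (m in seq_len(n)) {
    subs <- utils::combn(n, m)
    for (s_i in seq_len(ncol(subs))) {
      for (cov in cycle_covers(subs[, s_i], cycles))
        enters[cov, m] <- TRUE
    }
  }
  rep_df$coefficients <- vapply(seq_along(cycles), function(i)
    paste0("a", which(enters[i, ]), collapse = ","), character(1L))
  structure(rep_df, class = c("feedback_report", "data.frame"))
}

sign_matrix <- function(top) {
  n <- nrow(top$network$nodes)
  m <- matrix(0, n, n)
  ts <- cell_from_index(top$network$cells, n)
  m[cbind(ts[, "target"], ts[, "source"])] <- top$signs
  m
}

#' @export
print.feedback_report <- function(x, ...) {
  cat("<feedback_report>", nrow(x), "cycles\n")
  print.data.frame(x)
  invisible(x)
}
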