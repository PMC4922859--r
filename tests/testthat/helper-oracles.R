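# Independent oracles and shared fixtures for the test suite. Everything
# here avoids the package's own code paths wherever it serves as a check:
# polynomial coefficients come from interpolation, stability from eigen(),
# cycle counts from a direct permutation search.

# characteristic-polynomial coefficients a_1..a_n of det(lambda I - M) by
# polynomial interpolation at n+1 sample points (Vandermonde solve)
poly_coeffs_oracle <- function(M) {
  n <- nrow(M)
  pts <- seq(0, n)
  vals <- vapply(pts, function(l) det(l * diag(n) - M), numeric(1L))
  V <- outer(pts, n:0, `^`)
  coef <- solve(V, vals) # monic: coef[1] == 1
  coef[-1L] / coef[1L]
}

# strict stability by eigenvalues
eigen_stable <- function(M, margin = 0) {
  max(Re(eigen(M, only.values = TRUE)$values)) < -margin
}

# number of simple directed cycles (self-loops included) by brute force:
# subsets of nodes x circular orderings, independent of the package
cycle_count_oracle <- function(adj) {
  n <- nrow(adj)
  perms_of <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  total <- sum(diag(adj) != 0)
  for (m in 2:n) {
    subs <- combn(n, m)
    for (s_i in seq_len(ncol(subs))) {
      s <- subs[, s_i]
      for (p in perms_of(s[-1L])) {
        seqn <- c(s[1L], p)
        nxt <- c(seqn[-1L], seqn[1L])
        if (all(adj[cbind(nxt, seqn)] != 0)) total <- total + 1L
      }
    }
  }
  total
}

# random Jacobian with a given support density
random_jacobian <- function(n, density = 1) {
  m <- matrix(stats::rnorm(n * n), n, n)
  m[stats::runif(n * n) > density] <- 0
  m
}

# canonical 2-node systems
ai_jacobian <- function() rbind(c(1, -1), c(3, -2)) # activator-inhibitor
sd_jacobian <- function() rbind(c(1, 1), c(-3, -2)) # substrate-depleted

two_nodes <- function() rd_nodes(c(TRUE, TRUE), labels = c("v", "w"))
three_nodes <- function() rd_nodes(c(TRUE, TRUE, FALSE),
                                   labels = c("v", "w", "u"))

complete_two_node <- function() {
  rd_network(two_nodes(), rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2)))
}

# activator-inhibitor topology on the complete 2-node network, row-major
# cell order (1,1), (1,2), (2,1), (2,2)
ai_topology <- function() topology(complete_two_node(), c(1, -1, 1, -1))
sd_topology <- function() topology(complete_two_node(), c(1, 1, -1, -1))

# closed-form 2-node stationary Turing conditions for J = [[a, b], [c, e]]
# with diffusion (dv, dw): stable (tr < 0, det > 0) and the determinant
# channel opens at finite q: dw a + dv e > 2 sqrt(dv dw det)
two_node_turing_oracle <- function(a, b, c, e, dv, dw) {
  tr <- a + e
  dt <- a * e - b * c
  (tr < 0) & (dt > 0) & (dw * a + dv * e > 2 * sqrt(pmax(dv * dw * dt, 0)))
}

# dense independent evaluation of the closed-form 2-node Turing volume for
# the activator-inhibitor sign pattern: rates uniform in the box, diffusion
# uniform in (0, 1); only the closed-form conditions are used
two_node_oracle_volume <- function(n, seed) {
  set.seed(seed)
  a <- runif(n, 0, 0.5); b <- runif(n, 0, 0.5)
  c2 <- runif(n, 0, 0.5); e <- runif(n, 0, 0.5)
  dv <- runif(n); dw <- runif(n)
  hit <- two_node_turing_oracle(a, -b, c2, -e, dv, dw)
  p <- mean(hit)
  list(estimate = p, se = sqrt(p * (1 - p) / n))
}
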