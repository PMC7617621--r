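# Fixture builders: a 10x10 reflecting arena (q = 0.2 per dimension) with
# one defect layout per heterogeneity class, plus brute-force oracles.

fixture_spec <- function(N = c(10, 10), q = c(0.2, 0.2), ...)
  lattice_spec(N = N, q = q, ...)

# impenetrable barrier pairs sealing the edges around a rectangular block
enclosure_pairs <- function(spec, rows, cols, alpha = 1,
                            op = build_transition_operator(spec)) {
  inside_ids <- site_id(spec, as.matrix(expand.grid(rows, cols)))
  inside <- logical(n_sites(spec))
  inside[inside_ids] <- TRUE
  pairs <- list()
  seen <- character(0)
  for (x in inside_ids) {
    for (y in setdiff(which(op[, x] > 0), x)) {
      if (inside[y]) next
      key <- paste(min(x, y), max(x, y))
      if (key %in% seen) next
      seen <- c(seen, key)
      pairs[[length(pairs) + 1L]] <- make_barrier(spec, x, y, alpha, op = op)
    }
  }
  pairs
}

# open partition: an impenetrable wall segment between columns c and c+1,
# spanning the given rows
wall_pairs <- function(spec, rows, col, op = build_transition_operator(spec)) {
  lapply(rows, function(r)
    make_barrier(spec, c(r, col), c(r, col + 1L), 1, op = op))
}

# one named layout per heterogeneity class on the 10x10 arena
fixture_layouts <- function(spec = fixture_spec(),
                            op = build_transition_operator(spec)) {
  list(
    homogeneous = het_set(spec),
    barriers = het_set(spec, c(wall_pairs(spec, 2:5, 3, op),
                               wall_pairs(spec, 7:9, 6, op))),
    enclosure = het_set(spec, enclosure_pairs(spec, 4:5, 8:9, op = op)),
    long_range = het_set(spec, list(
      make_long_range(spec, c(2, 2), c(9, 9), 1/2, op = op),
      make_long_range(spec, c(3, 8), c(8, 2), 1/2, op = op),
      make_long_range(spec, c(5, 4), c(10, 10), 1/2, op = op))),
    sticky = het_set(spec, list(
      make_sticky(spec, c(5, 8), 1/4, op = op),
      make_sticky(spec, c(3, 3), 1/4, op = op),
      make_sticky(spec, c(8, 5), 1/4, op = op))),
    slippery = het_set(spec, list(
      make_slippery(spec, c(5, 8), 1/2, op = op),
      make_slippery(spec, c(3, 3), 1/2, op = op),
      make_slippery(spec, c(8, 5), 1/2, op = op))))
}

# oracle: first-passage probabilities by iterating the perturbed operator
# with the target columns zeroed; F(t) = mass arriving at a target at t
oracle_fp_series <- function(A, n0_id, target_ids, T) {
  A[, target_ids] <- 0
  P <- iterate_master(A, n0_id, T)
  colSums(P[target_ids, -1L, drop = FALSE])
}

# oracle: stationary distribution by plain power iteration
oracle_stationary <- function(A, start, iters = 20000L, tol = 1e-13) {
  p <- numeric(nrow(A))
  p[start] <- 1
  for (i in seq_len(iters)) {
    p2 <- as.numeric(A %*% p)
    if (max(abs(p2 - p)) < tol) return(p2)
    p <- p2
  }
  p
}
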