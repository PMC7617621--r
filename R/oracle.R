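#' Iterate the Master equation directly
#'
#' Brute-force reference: repeated application of the (possibly perturbed)
#' transition operator to a localized initial condition. This is the primary
#' oracle against which the generating-function machinery is validated.
#'
#' @param A a (sparse) transition operator, columns indexed by origin.
#' @param n0 flat site id of the initial condition.
#' @param T number of steps.
#' @return a `n_sites x (T + 1)` dense matrix; column `t + 1` holds the
#'   occupation probabilities at time `t`.
#' @export
iterate_master <- function(A, n0, T) {
  stopifnot(T >= 0, length(n0) == 1L)
  n <- nrow(A)
  out <- matrix(0, n, T + 1L)
  phi <- numeric(n)
  phi[n0] <- 1
  out[, 1L] <- phi
  for (t in seq_len(T)) {
    phi <- as.numeric(A %*% phi)
    out[, t + 1L] <- phi
  }
  out
}

#' Monte Carlo first-passage sampling
#'
#' Samples `walkers` independent trajectories of the walk defined by the
#' operator `A` (categorical transitions per step, realized as multinomial
#' draws over the walkers occupying each site) and records the first time
#' any of the `targets` is hit. Walkers that have not hit a target by `T`
#' (or were removed by lattice absorption) are censored. An explicit seed is
#' required for reproducibility; there is no default.
#'
#' @param A transition operator (may be substochastic).
#' @param n0 flat site id of the start.
#' @param targets flat site ids of the targets.
#' @param walkers ensemble size (>= 1).
#' @param T time horizon.
#' @param seed integer RNG seed (mandatory).
#' @return an object of class `trajectory_ensemble`: list with `times`
#'   (integer first-passage times of uncensored walkers), `censored`
#'   (count), `walkers`, `T`, `seed`, and `estimate`, a data frame with
#'   columns `t`, `F_hat`, `stderr` (binomial standard errors).
#' @export
sample_first_passage <- function(A, n0, targets, walkers, T, seed) {
  if (missing(seed) || is.null(seed)) stop("an explicit `seed` is required")
  stopifnot(walkers >= 1, T >= 1)
  set.seed(as.integer(seed))
  n <- nrow(A)
  A <- methods::as(A, "CsparseMatrix")
  cols <- lapply(seq_len(n), function(j) {
    idx <- (A@p[j] + 1L):A@p[j + 1L]
    if (A@p[j] == A@p[j + 1L]) idx <- integer(0)
    dest <- A@i[idx] + 1L
    pr <- A@x[idx]
    loss <- 1 - sum(pr)
    if (loss > 1e-12) { dest <- c(dest, 0L); pr <- c(pr, loss) } # 0 = killed
    list(dest = dest, pr = pr)
  })
  counts <- integer(n)
  counts[n0] <- walkers
  killed <- 0L
  hits <- integer(T)
  for (t in seq_len(T)) {
    occupied <- which(counts > 0L)
    newc <- integer(n)
    for (s in occupied) {
      cl <- cols[[s]]
      if (!length(cl$dest)) { killed <- killed + counts[s]; next }
      draw <- as.integer(rmultinom(1L, counts[s], cl$pr))
      z <- cl$dest == 0L
      if (any(z)) killed <- killed + draw[z]
      newc[cl$dest[!z]] <- newc[cl$dest[!z]] + draw[!z]
    }
    arrived <- sum(newc[targets])
    hits[t] <- arrived
    newc[targets] <- 0L
    counts <- newc
    if (!sum(counts)) { if (t < T) hits[(t + 1L):T] <- 0L; break }
  }
  censored <- as.integer(walkers - sum(hits))
  f_hat <- hits / walkers
  est <- data.frame(t = seq_len(T), F_hat = f_hat,
                    stderr = sqrt(pmax(f_hat * (1 - f_hat), 0) / walkers))
  structure(list(times = rep.int(seq_len(T), hits), censored = censored,
                 walkers = walkers, T = T, seed = as.integer(seed),
                 estimate = est),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> %d walkers, horizon %d, seed %d\n",
              x$walkers, x$T, x$seed))
  cat(sprintf("  reached: %d (%.1f%%), censored: %d\n", length(x$times),
              100 * length(x$times) / x$walkers, x$censored))
  if (length(x$times))
    cat(sprintf("  mean first-passage (uncensored): %.2f steps\n",
                mean(x$times)))
  invisible(x)
}

#' Mean hitting times by absorbing-chain linear solve
#'
#' Exact reference for mean first-passage and exit times: solves
#' `(I - Q') m = 1` on the non-target sites, where `Q` is the operator with
#' the target columns removed. Sites from which the targets are unreachable
#' (or only reachable with probability < 1) receive `Inf`.
#'
#' @param A transition operator (columns of `targets` need not be zeroed;
#'   they are ignored).
#' @param targets flat site ids of the absorbing targets, or `NULL` to use
#'   the intrinsic absorption of a substochastic operator.
#' @return numeric vector of mean hitting times per site (0 at targets).
#' @export
solve_absorbing_means <- function(A, targets = NULL) {
  n <- nrow(A)
  if (!is.null(targets) && length(targets)) A[, targets] <- 0
  m <- rep(Inf, n)
  intrinsic <- is.null(targets)
  if (intrinsic) {
    # intrinsic absorption: fully zeroed columns are absorb-on-arrival sites
    # (the arrival step counts), partial deficits are face leaks
    cs <- Matrix::colSums(A)
    sink <- which(cs < 1 - 1e-12)
    if (!length(sink)) stop("no absorption: targets empty and operator ",
                            "probability-conserving")
    targets <- which(cs <= 1e-14)
    if (length(targets)) m[targets] <- 0
  } else {
    sink <- targets
    m[targets] <- 0
  }
  canreach <- .reachable(Matrix::t(A), sink)
  C <- setdiff(canreach, targets)
  if (!length(C)) return(m)
  QT <- Matrix::t(A[C, C, drop = FALSE])
  # hitting probability of the sink; only h = 1 sites have finite means
  inflow <- if (length(targets))
    as.numeric(Matrix::colSums(A[targets, C, drop = FALSE])) else 0
  if (intrinsic)
    inflow <- inflow + 1 - as.numeric(Matrix::colSums(A[, C, drop = FALSE]))
  h <- as.numeric(Matrix::solve(Diagonal(length(C)) - QT, inflow))
  good <- which(h >= 1 - 1e-9)
  if (!length(good)) return(m)
  G <- C[good]
  QG <- Matrix::t(A[G, G, drop = FALSE])
  m[G] <- as.numeric(Matrix::solve(Diagonal(length(G)) - QG, rep(1, length(G))))
  m
}
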