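#' First-passage generating function to a single target
#'
#' Renewal relation in the z domain:
#' \deqn{\tilde F_{n_0}(n, z) = \tilde\Phi_{n_0}(n, z) / \tilde\Phi_n(n, z),
#' \quad n \neq n_0,}
#' with the heterogeneous propagators of [heterogeneous_gf()].
#'
#' @param set a [het_set()] or `NULL`.
#' @param gf a [homogeneous_propagator_gf()].
#' @param n0 starting site; `n` target site (`n != n0`).
#' @param n target site.
#' @param z complex vector of evaluation points.
#' @param strict enforce the admissibility region for `z`.
#' @return complex vector.
#' @export
fp_gf_single <- function(set, gf, n0, n, z, strict = TRUE) {
  set <- .as_het_set(set, gf$spec)
  id_n <- site_id(gf$spec, n); id_0 <- site_id(gf$spec, n0)
  if (id_n == id_0) stop("n must differ from n0; use return_gf() for returns")
  .check_z(gf, z[z != 0], strict)
  B <- .het_block(set, gf, id_n, c(id_0, id_n), as.complex(z))
  drop(B[1L, 1L, ] / B[1L, 2L, ])
}

#' First-passage generating function to either of two targets
#'
#' Combines single-target first-passage generating functions:
#' \deqn{\tilde F_{n_0}(n_1, n_2, z) = \frac{\tilde F_{n_0}(n_1)[1 -
#' \tilde F_{n_1}(n_2)] + \tilde F_{n_0}(n_2)[1 - \tilde F_{n_2}(n_1)]}
#' {1 - \tilde F_{n_1}(n_2)\,\tilde F_{n_2}(n_1)}.}
#'
#' @inheritParams fp_gf_single
#' @param n1,n2 the two targets (distinct, both different from `n0`).
#' @return complex vector.
#' @export
fp_gf_two_targets <- function(set, gf, n0, n1, n2, z, strict = TRUE) {
  set <- .as_het_set(set, gf$spec)
  i0 <- site_id(gf$spec, n0); i1 <- site_id(gf$spec, n1)
  i2 <- site_id(gf$spec, n2)
  if (i1 == i2 || i1 == i0 || i2 == i0)
    stop("n0, n1, n2 must be three distinct sites")
  .check_z(gf, z[z != 0], strict)
  B <- .het_block(set, gf, c(i1, i2), c(i0, i1, i2), as.complex(z))
  F01 <- B[1L, 1L, ] / B[1L, 2L, ]
  F02 <- B[2L, 1L, ] / B[2L, 3L, ]
  F12 <- B[2L, 2L, ] / B[2L, 3L, ]
  F21 <- B[1L, 3L, ] / B[1L, 2L, ]
  den <- 1 - F12 * F21
  if (any(abs(den) < 1e-14))
    stop("two-target denominator vanishes (degenerate cross-passage)")
  drop((F01 * (1 - F12) + F02 * (1 - F21)) / den)
}

#' First-return generating function
#'
#' \deqn{\tilde R(n, z) = 1 - 1 / \tilde\Phi_n(n, z).}
#' Staying put counts as a return at `t = 1`.
#'
#' @inheritParams fp_gf_single
#' @param n the return site.
#' @return complex vector.
#' @export
return_gf <- function(set, gf, n, z, strict = TRUE) {
  set <- .as_het_set(set, gf$spec)
  id_n <- site_id(gf$spec, n)
  phi <- heterogeneous_gf(set, gf, id_n, id_n, z, strict = strict)
  if (any(abs(phi) < 1e-300)) stop("propagator vanishes at requested z")
  1 - 1 / phi
}

# --- means -----------------------------------------------------------------

.spec_of <- function(x) {
  if (inherits(x, "propagator_gf")) x$spec
  else if (inherits(x, "lattice_spec")) x
  else stop("expected a lattice_spec or propagator_gf")
}

# hitting probability of `targets` (columns already zeroed in Ap) from n0
.hit_probability <- function(Ap, targets, n0) {
  canreach <- .reachable(Matrix::t(Ap), targets)
  if (!(n0 %in% canreach)) return(0)
  C <- setdiff(canreach, targets)
  if (!length(C)) return(1)
  QT <- Matrix::t(Ap[C, C, drop = FALSE])
  inflow <- as.numeric(Matrix::colSums(Ap[targets, C, drop = FALSE]))
  h <- as.numeric(Matrix::solve(Diagonal(length(C)) - QT, inflow))
  if (n0 %in% targets) 1 else h[match(n0, C)]
}

.mean_result <- function(value, reach, method) {
  structure(value, reach_probability = reach, method = method)
}

#' Mean first-passage time under heterogeneities
#'
#' Computes the mean of the heterogeneous first-passage distribution from
#' `n0` to `n` by making the target absorbing and summing the survival
#' probability: the mean equals the survival generating function at `z = 1`,
#' evaluated exactly through sparse linear solves combined with the defect
#' correction. `method = "renewal"` instead differentiates the renewal-ratio
#' generating function at `z = 1` by central Richardson extrapolation; the
#' two agree to high accuracy and serve as mutual cross-checks.
#'
#' When the target cannot be reached with probability one, the returned
#' value is `Inf` and the attained reach probability is attached as
#' attribute `reach_probability`.
#'
#' @param set a [het_set()] or `NULL`.
#' @param x a [lattice_spec()] or [homogeneous_propagator_gf()].
#' @param n0 starting site; `n` target site.
#' @param n target site.
#' @param method `"survival"` (exact, default) or `"renewal"`.
#' @return numeric mean first-passage time in steps (possibly `Inf`), with
#'   attributes `reach_probability` and `method`.
#' @examples
#' sp <- lattice_spec(30, q = 2/3)
#' barrier <- make_barrier(sp, 4, 5, alpha_u = 0.975)
#' mfpt(het_set(sp, list(barrier)), sp, n0 = 8, n = 15) # 231: indifference
#' @export
mfpt <- function(set, x, n0, n, method = c("survival", "renewal")) {
  method <- match.arg(method)
  spec <- .spec_of(x)
  set <- .as_het_set(set, spec)
  id_0 <- site_id(spec, n0); id_n <- site_id(spec, n)
  if (id_0 == id_n) return(.mean_result(0, 1, method))
  if (method == "renewal") {
    gf <- if (inherits(x, "propagator_gf")) x
          else homogeneous_propagator_gf(spec)
    # the renewal ratio is analytic at z = 1 but has its nearest singularity
    # at 1/sigma_2 (subdominant eigenvalue); keep the whole stencil well
    # inside that disc
    h1 <- 1e-3
    if (gf$type == "separable") {
      s2 <- max(gf$sigma[gf$sigma < 1 - 1e-12])
      h1 <- max(min(h1, 0.05 * (1 / s2 - 1)), 1e-7)
    }
    val <- .gf_deriv1(function(z)
      Re(fp_gf_single(set, gf, id_0, id_n, z, strict = FALSE)),
      hs = h1 * c(1, 1 / 2, 1 / 4))
    return(.mean_result(val, NA_real_, "renewal"))
  }
  spec_abs <- spec
  spec_abs$absorbing_sites <- sort(unique(c(spec$absorbing_sites, id_n)))
  A <- build_transition_operator(spec_abs)
  set_r <- .restrict_set_to_absorbing(set, spec_abs$absorbing_sites)
  Ap <- apply_defects(set_r, A)
  reached <- .reachable(Ap, id_0)
  canreach <- .reachable(Matrix::t(Ap), id_n)
  if (!all(reached %in% canreach)) {
    reach <- .hit_probability(Ap, id_n, id_0)
    return(.mean_result(Inf, reach, "survival"))
  }
  st <- .defect_z1(set, spec_abs, id_0,
                   dead = setdiff(seq_len(nrow(Ap)), reached))
  reach <- .defect_z1_value(st, id_n)
  if (reach < 1 - 1e-9) return(.mean_result(Inf, reach, "survival"))
  .mean_result(st$survival, reach, "survival")
}

#' Mean exit time through absorbing boundaries
#'
#' The mean exit time is the survival generating function at `z = 1`,
#' \eqn{\mathfrak{E}_{n_0} = \tilde S_{n_0}(1)}, evaluated exactly (the
#' absorbing homogeneous propagator is finite at `z = 1`, so no limit is
#' needed). Requires at least one absorbing face or site in the lattice
#' specification. If the heterogeneities seal the walker off from every
#' absorbing location, `Inf` is returned with the exit probability attached.
#'
#' @inheritParams mfpt
#' @return numeric mean exit time in steps, attributes as in [mfpt()].
#' @export
met <- function(set, x, n0) {
  spec <- .spec_of(x)
  if (.is_conserving(spec))
    stop("mean exit time requires an absorbing boundary or site")
  set <- .as_het_set(set, spec)
  id_0 <- site_id(spec, n0)
  A <- build_transition_operator(spec)
  set_r <- .restrict_set_to_absorbing(set, .absorbed_ids(spec))
  Ap <- apply_defects(set_r, A)
  # sites from which absorption (face deficit or absorbing site) is reachable
  deficit <- which(Matrix::colSums(Ap) < 1 - 1e-12)
  reached <- .reachable(Ap, id_0)
  canexit <- .reachable(Matrix::t(Ap), deficit)
  if (!all(reached %in% canexit))
    return(.mean_result(Inf, NA_real_, "survival"))
  st <- .defect_z1(set, spec, id_0,
                   dead = setdiff(seq_len(nrow(Ap)), reached))
  .mean_result(st$survival, 1, "survival")
}

#' Mean return time under heterogeneities (Kac's lemma)
#'
#' For a probability-conserving walk the mean return time to `n` equals the
#' reciprocal stationary probability of `n` under the perturbed operator,
#' \eqn{\mathfrak{R}_n = 1/\pi(n)} (Kac's lemma); the stationary
#' distribution is obtained by an exact linear solve on the communicating
#' class of `n`. For symmetry-preserving sets this reproduces the
#' homogeneous mean return time unchanged. If heterogeneities make the chain
#' reducible, the class-restricted value is returned with a warning; if `n`
#' is transient (one-way escape), the mean return time is infinite.
#'
#' @inheritParams mfpt
#' @param n the return site.
#' @return numeric mean return time in steps.
#' @export
mrt <- function(set, x, n) {
  spec <- .spec_of(x)
  if (!.is_conserving(spec))
    stop("mean return time requires a probability-conserving walk")
  set <- .as_het_set(set, spec)
  id_n <- site_id(spec, n)
  Ap <- apply_defects(set)
  pi_n <- stationary_distribution(Ap, site = id_n)[id_n]
  if (pi_n <= 0) return(.mean_result(Inf, NA_real_, "kac"))
  .mean_result(1 / pi_n, 1, "kac")
}

#' Stationary distribution of a transition operator
#'
#' Exact stationary distribution by a linear solve. With `site` given, the
#' solve is restricted to the communicating class of that site; if the class
#' is not closed (the site is transient) a zero vector is returned with a
#' warning, and if it is closed but smaller than the lattice, the
#' class-restricted distribution is returned with a warning.
#'
#' @param A a (column-stochastic) sparse transition operator.
#' @param site optional flat site id selecting the communicating class
#'   (default 1).
#' @return numeric vector over all sites, summing to 1 on the class.
#' @export
stationary_distribution <- function(A, site = 1L) {
  n <- nrow(A)
  cls <- intersect(.reachable(A, site), .reachable(Matrix::t(A), site))
  out <- numeric(n)
  outmass <- sum(A[-cls, cls, drop = FALSE]) + 0
  if (length(cls) < n) {
    if (outmass > 1e-14) {
      warning("site is transient under the perturbed dynamics; ",
              "no stationary mass on its class")
      return(out)
    }
    warning("operator is reducible; returning the stationary ",
            "distribution of the communicating class of the site")
  }
  out[cls] <- .stationary_on_class(A, cls)
  out
}

# exact stationary distribution restricted to a closed communicating class
.stationary_on_class <- function(A, cls) {
  Acc <- A[cls, cls, drop = FALSE]
  m <- length(cls)
  # (A - I) pi = 0 with one row replaced by the normalization
  Mx <- rbind((Acc - Diagonal(m))[-m, , drop = FALSE],
              Matrix::sparseMatrix(i = rep(1L, m), j = seq_len(m),
                                   x = 1, dims = c(1L, m)))
  as.numeric(Matrix::solve(Mx, c(rep(0, m - 1L), 1)))
}

# long-time occupation distribution seen from `start`: the stationary
# distribution of the recurrent class the walk settles into (the chain
# restricted to states reachable from `start` must have a unique one)
.steady_state_from <- function(A, start) {
  n <- nrow(A)
  s <- start
  repeat {
    cls <- intersect(.reachable(A, s), .reachable(Matrix::t(A), s))
    if (sum(A[setdiff(seq_len(n), cls), cls, drop = FALSE]) <= 1e-14) break
    s <- setdiff(.reachable(A, s), cls)[1L]
  }
  out <- numeric(n)
  out[cls] <- .stationary_on_class(A, cls)
  out
}

# first derivative at z = 1 by central differences + Richardson in h^2
.gf_deriv1 <- function(fun, hs = c(1e-3, 5e-4, 2.5e-4)) {
  D <- vapply(hs, function(h) (fun(1 + h) - fun(1 - h)) / (2 * h), 0)
  x <- hs^2
  for (k in seq_len(length(D) - 1L)) # Neville elimination of h^2, h^4, ...
    for (i in seq_len(length(D) - k))
      D[i] <- (x[i + k] * D[i] - x[i] * D[i + 1L]) / (x[i + k] - x[i])
  D[1L]
}

# --- full first-passage results -------------------------------------------

#' First-passage distribution, mean and reach probability
#'
#' Inverts the first-passage generating function (single target via the
#' renewal relation, two targets via the combination formula) to the
#' time-domain distribution, and computes the mean and reach probability
#' through the absorbing-target survival machinery.
#'
#' @inheritParams fp_gf_single
#' @param targets one or two target sites (list of coordinate vectors, a
#'   matrix with one site per row, or a vector of flat ids).
#' @param T time horizon for the returned distribution.
#' @param ... passed to the generating-function inverter.
#' @return an object of class `fp_result`: list with `distribution` (a
#'   `walk_series` data frame), `mean`, `reach_probability`, `n0`,
#'   `targets`, `method`.
#' @export
first_passage <- function(set, gf, n0, targets, T, ...) {
  spec <- gf$spec
  set <- .as_het_set(set, spec)
  tid <- site_id(spec, targets)
  id_0 <- site_id(spec, n0)
  stopifnot(length(tid) %in% 1:2)
  fgf <- if (length(tid) == 1L)
    function(z) fp_gf_single(set, gf, id_0, tid, z, strict = FALSE)
  else
    function(z) fp_gf_two_targets(set, gf, id_0, tid[1L], tid[2L], z,
                                  strict = FALSE)
  dist <- .invert_gf(fgf, T, ...)
  spec_abs <- spec
  spec_abs$absorbing_sites <- sort(unique(c(spec$absorbing_sites, tid)))
  A <- build_transition_operator(spec_abs)
  set_r <- .restrict_set_to_absorbing(set, spec_abs$absorbing_sites)
  Ap <- apply_defects(set_r, A)
  reached <- .reachable(Ap, id_0)
  canreach <- .reachable(Matrix::t(Ap), tid)
  if (!all(reached %in% canreach)) {
    mean_t <- Inf
    reach <- .hit_probability(Ap, tid, id_0)
  } else {
    st <- .defect_z1(set, spec_abs, id_0,
                     dead = setdiff(seq_len(nrow(Ap)), reached))
    reach <- sum(vapply(tid, function(i) .defect_z1_value(st, i), 0))
    mean_t <- if (reach < 1 - 1e-9) Inf else st$survival
  }
  structure(list(distribution = dist, mean = mean_t,
                 reach_probability = reach, n0 = id_0, targets = tid,
                 method = "renewal-inversion + survival mean"),
            class = "fp_result")
}

#' @export
print.fp_result <- function(x, ...) {
  cat("<fp_result>\n")
  cat("  targets:          ", paste(x$targets, collapse = ", "), "\n")
  cat("  mean:             ", format(x$mean), "steps\n")
  cat("  reach probability:", format(x$reach_probability), "\n")
  cat("  distribution:      t = 0..", max(x$distribution$t),
      " (mass ", format(sum(x$distribution$probability)), ")\n", sep = "")
  invisible(x)
}

# --- 1D single-barrier closed forms ----------------------------------------

# complex-safe acosh, principal branch (Re >= 0)
.acosh_c <- function(w) log(w + sqrt(as.complex(w - 1)) * sqrt(as.complex(w + 1)))

#' First-passage generating function: 1D walk with one symmetric barrier
#'
#' Closed form for the lazy 1D walk (moving probability `q`) with a
#' reflecting boundary between sites 0 and 1, a target at `n > n0` and a
#' symmetric partially reflecting barrier `lambda` between `u` and `u + 1`.
#' Writing `zeta = acosh(1 - (1 - 1/z)/q)` and `x = exp(-zeta)`, the
#' reflecting-boundary propagator is the image sum
#' `phi(b, a) = (x^|b-a| + x^(b+a-1)) / (q z sinh zeta)`, and the single
#' defect pair gives
#' \deqn{\tilde F_{n_0}(n,z) = \tilde\Phi_{n_0}(n,z)/\tilde\Phi_n(n,z)}
#' with the rank-one defect correction evaluated explicitly. Both barrier
#' positions (`u < n0` and `u >= n0`) are covered by the same expression.
#'
#' @param n0 starting site; `n` target (`n > n0` >= 1).
#' @param n target site.
#' @param u barrier position (edge between `u` and `u + 1`, `1 <= u < n`).
#' @param lam symmetric barrier strength, `-(1 - q) < lam <= q/2`.
#' @param q moving probability in (0, 1].
#' @param z complex vector, `0 < |z| < 1`.
#' @return complex vector.
#' @export
fp_1d_barrier_gf <- function(n0, n, u, lam, q, z) {
  stopifnot(n0 >= 1, n > n0, u >= 1, q > 0, q <= 1)
  if (u >= n) stop("barrier must lie left of the target (u < n)")
  if (lam > q / 2 + 1e-15 || lam <= -(1 - q) - 1e-15)
    stop("lam must lie in (-(1 - q), q/2]")
  if (any(z == 0) || any(Mod(z) >= 1))
    stop("z must satisfy 0 < |z| < 1")
  zeta <- .acosh_c(1 - (1 - 1 / z) / q)
  x <- exp(-zeta)
  cc <- q * z * sinh(zeta)
  phi <- function(b, a) (x^abs(b - a) + x^(b + a - 1)) / cc
  v <- u + 1
  H <- lam * ((phi(u, u) - phi(u, v)) - (phi(v, u) - phi(v, v))) - 1 / z
  b_of <- function(s) lam * (phi(u, s) - phi(v, s))
  g_of <- function(m) phi(m, u) - phi(m, v)
  Phi <- function(m, s) phi(m, s) - g_of(m) * b_of(s) / H
  drop(Phi(n, n0) / Phi(n, n))
}

#' Mean first-passage time: 1D walk with one symmetric barrier
#'
#' Compact closed form for the geometry of [fp_1d_barrier_gf()]:
#' \deqn{\mathfrak{F}_{n_0\to n} = \mathcal{F}_{n_0 \to n} +
#' \frac{2\lambda}{q\,(q/2 - \lambda)}\,
#' \begin{cases} 0 & u < n_0 \\ u & u \ge n_0,\end{cases}}
#' with \eqn{\mathcal{F}} the homogeneous mean of
#' [homogeneous_mfpt_1d()]. A barrier anywhere between the reflecting
#' boundary and the starting site leaves the mean unchanged for every
#' admissible `lambda` (disorder indifference); between start and target it
#' shifts the mean linearly in `u`, diverging as `lambda -> q/2`.
#'
#' @inheritParams fp_1d_barrier_gf
#' @return mean first-passage time in steps (`Inf` for an impenetrable
#'   barrier between start and target).
#' @examples
#' mfpt_1d_barrier(8, 15, u = 3, lam = 0.325, q = 2/3) # 231
#' mfpt_1d_barrier(8, 15, u = 8, lam = 0.325, q = 2/3) # 1167
#' @export
mfpt_1d_barrier <- function(n0, n, u, lam, q) {
  stopifnot(n0 >= 1, n >= n0, u >= 1, q > 0, q <= 1)
  if (u >= n) stop("barrier must lie left of the target (u < n)")
  if (lam > q / 2 + 1e-15 || lam <= -(1 - q) - 1e-15)
    stop("lam must lie in (-(1 - q), q/2]")
  base <- homogeneous_mfpt_1d(n0, n, q)
  if (u < n0) {
    # disorder indifference holds on the open interval lam < q/2; exactly at
    # q/2 the wall cuts the walker off from the reflecting boundary and the
    # problem shifts by u (a genuine discontinuity of the mean)
    if (abs(lam - q / 2) < 1e-15)
      return(homogeneous_mfpt_1d(n0 - u, n - u, q))
    return(base)
  }
  if (abs(lam - q / 2) < 1e-15) return(Inf)
  base + 2 * lam / (q * (q / 2 - lam)) * u
}

#' Mean return time: 1D segment with one (possibly asymmetric) barrier
#'
#' Closed form for a reflecting segment of `N` sites with a barrier between
#' `u` and `u + 1` whose two directions have strengths `lam_up` (blocking
#' `u -> u + 1`) and `lam_down` (blocking `u + 1 -> u`):
#' piecewise in the return site `n`, with `p = q/2`,
#' \deqn{\mathfrak{R}_n = \frac{N (p - \lambda_{up}) - u (\lambda_{down} -
#' \lambda_{up})}{p - \lambda_{down}} \ (n \le u), \qquad
#' \mathfrak{R}_n = N - u\,\frac{\lambda_{down} - \lambda_{up}}
#' {p - \lambda_{up}} \ (n > u).}
#' For a symmetric barrier both branches reduce to `N` (Kac's lemma on the
#' unchanged uniform steady state).
#'
#' @param n return site.
#' @param N segment length.
#' @param u barrier edge position (`1 <= u < N`).
#' @param lam_up,lam_down directional barrier strengths (each `< q/2`).
#' @param q moving probability.
#' @return mean return time in steps.
#' @export
mrt_1d_barrier <- function(n, N, u, lam_up, lam_down, q) {
  stopifnot(n >= 1, n <= N, u >= 1, u < N, q > 0, q <= 1)
  p <- q / 2
  if (n <= u) (N * (p - lam_up) - u * (lam_down - lam_up)) / (p - lam_down)
  else N - u * (lam_down - lam_up) / (p - lam_up)
}
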