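#' Defect matrix of the generalized defect technique
#'
#' Builds the `M x M` matrix with entries
#' \deqn{H_{ij} = \lambda_{v_i,u_i}\,\tilde\varphi_{\langle u_j - v_j\rangle}
#' (u_i, z) - \lambda_{u_i,v_i}\,\tilde\varphi_{\langle u_j - v_j\rangle}
#' (v_i, z) - z^{-1}\delta_{ij},}
#' where \eqn{\tilde\varphi_{\langle u - v\rangle}(n, z) =
#' \tilde\varphi_u(n,z) - \tilde\varphi_v(n,z)} is a difference of
#' homogeneous propagator generating functions with the *source* at `u`
#' resp. `v`. The heterogeneous propagator is a ratio of determinants of
#' this matrix and a rank-one correction of it; [heterogeneous_gf()]
#' evaluates that ratio through a linear solve rather than determinants.
#'
#' @param set a [het_set()] with `M >= 1` pairs.
#' @param gf the [homogeneous_propagator_gf()] of the same lattice.
#' @param z a single non-zero evaluation point.
#' @return complex `M x M` matrix.
#' @export
build_H <- function(set, gf, z) {
  stopifnot(inherits(set, "het_set"), inherits(gf, "propagator_gf"),
            length(z) == 1L)
  if (z == 0) stop("H is not defined at z = 0; the propagator limit ",
                   "is handled by heterogeneous_gf() directly")
  if (!set$M) stop("heterogeneity set is empty")
  matrix(.build_H_block(set, gf, as.complex(z)), set$M, set$M)
}

# H for all z at once: array (M, M, nz); reuses a phi block over defect sites
.build_H_block <- function(set, gf, zs, B = NULL, idx = NULL) {
  M <- set$M
  if (is.null(B)) {
    sites <- unique(c(set$u, set$v))
    B <- .phi_block(gf, sites, sites, zs)
    idx <- stats::setNames(seq_along(sites), sites)
  }
  iu <- idx[as.character(set$u)]
  iv <- idx[as.character(set$v)]
  nz <- length(zs)
  H <- array(0i, c(M, M, nz))
  # phi_<uj-vj>(m) = B[m, uj] - B[m, vj]
  for (j in seq_len(M)) {
    duj <- B[iu, iu[j], , drop = FALSE] - B[iu, iv[j], , drop = FALSE]
    dvj <- B[iv, iu[j], , drop = FALSE] - B[iv, iv[j], , drop = FALSE]
    H[, j, ] <- set$lambda_vu * array(duj, c(M, nz)) -
      set$lambda_uv * array(dvj, c(M, nz))
  }
  dg <- matrix(rep(1 / zs, each = M), M, nz)
  for (i in seq_len(M)) H[i, i, ] <- H[i, i, ] - dg[i, ]
  H
}

# Workhorse: heterogeneous propagator GF for all (dest, source) combinations
# at all zs. Returns array (length(dests), length(sources), length(zs)).
.het_block <- function(set, gf, dests, sources, zs) {
  zs <- as.complex(zs)
  if (!set$M) return(.phi_block(gf, dests, sources, zs))
  sites <- unique(c(set$u, set$v, dests, sources))
  idx <- stats::setNames(seq_along(sites), sites)
  B <- .phi_block(gf, sites, sites, zs)
  H <- .build_H_block(set, gf, zs, B = B, idx = idx)
  iu <- idx[as.character(set$u)]; iv <- idx[as.character(set$v)]
  id <- idx[as.character(dests)]; is0 <- idx[as.character(sources)]
  nd <- length(dests); ns <- length(sources); nz <- length(zs)
  out <- array(0i, c(nd, ns, nz))
  for (k in seq_len(nz)) {
    Bk <- B[, , k]
    # b(s)_i = lambda_vu_i phi_s(u_i) - lambda_uv_i phi_s(v_i)
    bmat <- set$lambda_vu * Bk[iu, is0, drop = FALSE] -
      set$lambda_uv * Bk[iv, is0, drop = FALSE]       # M x ns
    gmat <- Bk[id, iu, drop = FALSE] - Bk[id, iv, drop = FALSE] # nd x M
    X <- tryCatch(solve(H[, , k], bmat), error = function(e) {
      cond <- tryCatch(kappa(H[, , k]), error = function(e2) NA_real_)
      stop(sprintf(paste0("defect matrix H numerically singular at ",
                          "z = %s (condition estimate %.2e)"),
                   format(zs[k]), cond), call. = FALSE)
    })
    out[, , k] <- Bk[id, is0, drop = FALSE] - gmat %*% X
  }
  out
}

#' Heterogeneous propagator generating function
#'
#' Evaluates \eqn{\tilde\Phi_{n_0}(n, z) = \tilde\varphi_{n_0}(n, z) - 1 +
#' |H(n, n_0)| / |H|}, the exact generating function of the occupation
#' probability of the walk perturbed by the defect set. Since
#' `H(n, n0) = H - b g'` is a rank-one correction, the determinant ratio
#' equals `1 - g' H^{-1} b` (matrix-determinant lemma) and is computed via a
#' pivoted linear solve, avoiding determinant overflow. At `z = 0` the
#' initial condition `delta(n, n0)` is returned directly.
#'
#' @param set a [het_set()] (or `NULL` for the homogeneous walk).
#' @param gf the [homogeneous_propagator_gf()] of the lattice.
#' @param n destination site (coordinates or flat id).
#' @param n0 source site.
#' @param z complex vector of evaluation points.
#' @param strict enforce the admissibility region for `z` (see [gf_eval()]).
#' @return complex vector, one value per element of `z`.
#' @export
heterogeneous_gf <- function(set, gf, n, n0, z, strict = TRUE) {
  stopifnot(inherits(gf, "propagator_gf"))
  set <- .as_het_set(set, gf$spec)
  id_n <- site_id(gf$spec, n); id_0 <- site_id(gf$spec, n0)
  out <- complex(length(z))
  zero <- z == 0
  out[zero] <- as.numeric(id_n == id_0)
  if (any(!zero)) {
    .check_z(gf, z[!zero], strict)
    out[!zero] <- .het_block(set, gf, id_n, id_0, z[!zero])[1L, 1L, ]
  }
  out
}

#' Time-domain heterogeneous propagator
#'
#' Occupation probabilities `Phi(n, t)`, `t = 0..T`, obtained by numerical
#' inversion of [heterogeneous_gf()] (see [series_coefficients()] for the
#' contour construction and tolerance checks).
#'
#' @inheritParams heterogeneous_gf
#' @param T time horizon.
#' @param ... passed to the inverter (`eps`, `K`, `im_tol`).
#' @return a `walk_series` data frame with columns `t`, `probability`.
#' @export
heterogeneous_timeseries <- function(set, gf, n, n0, T, ...) {
  set <- .as_het_set(set, gf$spec)
  id_n <- site_id(gf$spec, n); id_0 <- site_id(gf$spec, n0)
  .invert_gf(function(z) .het_block(set, gf, id_n, id_0, z)[1L, 1L, ],
             T, ...)
}

# ---------------------------------------------------------------------------
# z = 1 machinery (means): sparse solves against the absorbing operator.
#
# For a lattice with absorption (faces and/or absorbing sites), the
# homogeneous GF at z = 1 is phi~_{s}(m, 1) = [(I - A)^{-1}]_{m, s}; all
# quantities of the defect formula (H, b, g and survival sums) are assembled
# from a single sparse factorization with one right-hand side per defect
# site plus one for the source.
.defect_z1 <- function(set, spec_abs, n0_id, dead = integer(0)) {
  A <- build_transition_operator(spec_abs)
  # lambdas acting on the outgoing column of an absorbing site never fire;
  # neither do those of sites unreachable from n0 (`dead`, e.g. interiors
  # sealed off by impenetrable barriers). Dropping them leaves the dynamics
  # seen from n0 unchanged and keeps H regular at z = 1.
  set <- .restrict_set_to_absorbing(
    set, union(.absorbed_ids(spec_abs), dead))
  n <- nrow(A)
  M <- set$M
  src <- c(set$u, set$v, n0_id)
  E <- matrix(0, n, length(src))
  E[cbind(src, seq_along(src))] <- 1
  X <- as.matrix(Matrix::solve(Diagonal(n) - A, E))
  alive <- setdiff(seq_len(n), .absorbed_ids(spec_abs))
  colS <- colSums(X[alive, , drop = FALSE])
  i0 <- 2L * M + 1L
  if (!M)
    return(list(survival = colS[i0], X = X, set = set, alive = alive,
                correction = 0, src = src))
  iu <- seq_len(M); iv <- M + seq_len(M)
  H <- set$lambda_vu * (X[set$u, iu, drop = FALSE] -
                          X[set$u, iv, drop = FALSE]) -
    set$lambda_uv * (X[set$v, iu, drop = FALSE] -
                       X[set$v, iv, drop = FALSE]) -
    diag(M)
  b <- set$lambda_vu * X[set$u, i0] - set$lambda_uv * X[set$v, i0]
  Hib <- solve(H, b)
  gS <- colS[iu] - colS[iv]
  list(survival = colS[i0] - sum(gS * Hib), X = X, set = set, alive = alive,
       Hib = Hib, src = src)
}

# heterogeneous phi~ at z = 1 for one destination given a .defect_z1 result
.defect_z1_value <- function(st, dest_id, n0_col = length(st$src)) {
  val <- st$X[dest_id, n0_col]
  M <- st$set$M
  if (!M) return(val)
  g <- st$X[dest_id, seq_len(M)] - st$X[dest_id, M + seq_len(M)]
  val - sum(g * st$Hib)
}
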