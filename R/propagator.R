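#' Homogeneous propagator generating function
#'
#' Constructs an evaluator for the generating function (z-transform over
#' time) of the occupation probability of the homogeneous walk,
#' \deqn{\tilde\varphi_{n_0}(n, z) = \sum_k \frac{\psi_k(n)\,\psi_k(n_0)}
#' {1 - z\,\sigma_k},}
#' using the exact spectral decomposition of the transition operator. For
#' face-wise boundary conditions the decomposition is separable: each
#' dimension contributes the eigenbasis of its 1D operator (cosine-type for
#' reflecting, Fourier for periodic, sine-type for absorbing faces) and the
#' combined eigenvalue is the mean (average kernel) or product (product
#' kernel) of the per-dimension ones. With individually absorbing sites the
#' operator is no longer separable and evaluation falls back to dense linear
#' solves in `(I - zA)`.
#'
#' @param spec a [lattice_spec()].
#' @return an object of class `propagator_gf`.
#' @export
homogeneous_propagator_gf <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  if (!length(spec$absorbing_sites)) {
    eig <- lapply(seq_len(spec$d), function(i)
      eigen(.op_1d(spec$N[i], spec$q[i], spec$boundary[i]), symmetric = TRUE))
    sigma <- if (spec$kernel == "average") 0 else 1
    len <- 1L
    for (i in seq_len(spec$d)) {
      si <- eig[[i]]$values
      if (spec$kernel == "average")
        sigma <- rep(sigma, each = spec$N[i]) + rep(si, times = len)
      else
        sigma <- rep(sigma, each = spec$N[i]) * rep(si, times = len)
      len <- len * spec$N[i]
    }
    if (spec$kernel == "average") sigma <- sigma / spec$d
    structure(list(spec = spec, type = "separable",
                   V = lapply(eig, `[[`, "vectors"), sigma = sigma),
              class = "propagator_gf")
  } else {
    A <- build_transition_operator(spec)
    if (nrow(A) > 4000L)
      stop("dense-solve propagator limited to 4000 sites; ",
           "use the z = 1 first-passage routines for larger systems")
    structure(list(spec = spec, type = "operator", A = as.matrix(A)),
              class = "propagator_gf")
  }
}

#' @export
print.propagator_gf <- function(x, ...) {
  cat(sprintf("<propagator_gf> %s lattice (%s evaluation)\n",
              paste(x$spec$N, collapse = "x"), x$type))
  invisible(x)
}

# rows of the (separable) eigenbasis for a set of flat site ids: m x K matrix
.mode_rows <- function(gf, ids) {
  spec <- gf$spec
  coords <- site_coords(spec, ids)
  P <- matrix(1, length(ids), 1L)
  for (i in seq_len(spec$d)) {
    Vi <- gf$V[[i]]
    Ni <- spec$N[i]
    k <- ncol(P)
    P <- P[, rep(seq_len(k), each = Ni), drop = FALSE] *
      Vi[coords[, i], rep(seq_len(Ni), times = k), drop = FALSE]
  }
  P
}

# admissibility of evaluation points
.check_z <- function(gf, z, strict = TRUE) {
  if (!strict) return(invisible(TRUE))
  conserving <- .is_conserving(gf$spec)
  bad <- if (conserving) Mod(z) >= 1 - 1e-12 else Mod(z) > 1 + 1e-12
  if (any(bad))
    stop("z outside the admissible region (|z| < 1",
         if (!conserving) ", or |z| <= 1 with absorption", ")")
  invisible(TRUE)
}

# block of phi~ values: array (length(dests), length(sources), length(zs))
.phi_block <- function(gf, dests, sources, zs, chunk = 128L) {
  nd <- length(dests); ns <- length(sources); nz <- length(zs)
  if (gf$type == "separable") {
    Pd <- .mode_rows(gf, dests)
    Ps <- .mode_rows(gf, sources)
    C <- Pd[rep(seq_len(nd), times = ns), , drop = FALSE] *
      Ps[rep(seq_len(ns), each = nd), , drop = FALSE]
    out <- array(0i, c(nd, ns, nz))
    for (j0 in seq(1L, nz, by = chunk)) {
      j1 <- min(j0 + chunk - 1L, nz)
      Mz <- 1 / (1 - outer(gf$sigma, zs[j0:j1]))
      out[, , j0:j1] <- C %*% Mz
    }
    out
  } else {
    n <- nrow(gf$A)
    E <- diag(n)[, sources, drop = FALSE]
    out <- array(0i, c(nd, ns, nz))
    for (j in seq_len(nz)) {
      X <- solve(diag(n) - zs[j] * gf$A, E)
      out[, , j] <- X[dests, , drop = FALSE]
    }
    out
  }
}

#' Evaluate the homogeneous propagator generating function
#'
#' @param gf a [homogeneous_propagator_gf()] object.
#' @param n destination site (coordinates or flat id).
#' @param n0 source site.
#' @param z complex vector of evaluation points; strictly inside the unit
#'   disc for probability-conserving walks, `|z| <= 1` when absorption is
#'   present.
#' @param strict enforce the admissibility check (default). With
#'   `strict = FALSE` the finite spectral sum is evaluated as the analytic
#'   continuation of the series, which is used internally for derivatives at
#'   `z = 1`.
#' @return complex vector of values, one per element of `z`.
#' @export
gf_eval <- function(gf, n, n0, z, strict = TRUE) {
  stopifnot(inherits(gf, "propagator_gf"))
  .check_z(gf, z, strict)
  id_n <- site_id(gf$spec, n)
  id_0 <- site_id(gf$spec, n0)
  out <- .phi_block(gf, id_n, id_0, as.complex(z))[1L, 1L, ]
  if (all(Im(z) == 0)) out <- complex(real = Re(out), imaginary = Im(out))
  drop(out)
}

#' Homogeneous 1D mean first-passage time
#'
#' Closed form for the lazy 1D walk with a reflecting boundary between sites
#' 0 and 1 and target at `n >= n0`:
#' \deqn{\mathcal{F}_{n_0 \to n} = (n - n_0)(n + n_0 - 1)/q.}
#'
#' @param n0 starting site (>= 1).
#' @param n target site (>= n0).
#' @param q probability of moving, in (0, 1].
#' @return mean first-passage time in steps.
#' @examples
#' homogeneous_mfpt_1d(8, 15, 2/3) # 231
#' @export
homogeneous_mfpt_1d <- function(n0, n, q) {
  if (any(n < n0)) stop("formula requires n0 <= n")
  if (any(n0 < 1)) stop("sites are 1-based")
  if (any(q <= 0 | q > 1)) stop("q must lie in (0, 1]")
  (n - n0) * (n + n0 - 1) / q
}

#' Power-series coefficients of a generating function
#'
#' Numerically inverts a generating function to its first `T + 1`
#' power-series coefficients, i.e. the time-domain probabilities. The
#' function is evaluated on `K >= 4 (T + 1)` points of a circle of radius
#' `r = eps^(1/(T+1)) < 1` and inverted with a discrete Fourier sum plus
#' radius correction. Coefficients must be real up to `im_tol`; for
#' probability series they are clipped to `[0, 1]` only after that check.
#'
#' @param x a vectorized function of `z`, or a `propagator_gf` (then `n`,
#'   `n0` select the matrix element).
#' @param T time horizon (returns coefficients for `t = 0, ..., T`).
#' @param ... passed on between methods.
#' @param eps target truncation level fixing the contour radius.
#' @param K number of contour sample points (default `4 * (T + 1)`).
#' @param im_tol maximal tolerated imaginary residue.
#' @param probability check/clip coefficients as probabilities.
#' @return a data frame of class `walk_series` with columns `t` and
#'   `probability`.
#' @export
series_coefficients <- function(x, ..., T) UseMethod("series_coefficients")

#' @rdname series_coefficients
#' @export
series_coefficients.function <- function(x, ..., T, eps = 1e-8, K = NULL,
                                         im_tol = 1e-8, probability = TRUE) {
  .invert_gf(x, T, eps = eps, K = K, im_tol = im_tol,
             probability = probability)
}

#' @rdname series_coefficients
#' @param n,n0 destination and source sites for the propagator method.
#' @export
series_coefficients.propagator_gf <- function(x, n, n0, ..., T, eps = 1e-8,
                                              K = NULL, im_tol = 1e-8,
                                              probability = TRUE) {
  .invert_gf(function(z) gf_eval(x, n, n0, z), T, eps = eps, K = K,
             im_tol = im_tol, probability = probability)
}

.invert_gf <- function(g, T, eps = 1e-8, K = NULL, im_tol = 1e-8,
                       probability = TRUE) {
  stopifnot(T >= 0)
  if (is.null(K)) K <- 4L * (T + 1L)
  if (K < 4L * (T + 1L)) stop("K must be at least 4 (T + 1)")
  r <- eps^(1 / (T + 1))
  zs <- r * exp(2i * pi * (seq_len(K) - 1L) / K)
  vals <- g(zs)
  if (length(vals) != K) stop("generating function must be vectorized in z")
  if (any(!is.finite(vals)))
    stop("non-convergent generating-function evaluation on the contour")
  co <- stats::fft(vals) / (K * r^(0:(K - 1L)))
  co <- co[seq_len(T + 1L)]
  resid <- max(abs(Im(co)))
  # the radius correction amplifies round-off by up to r^-T ~ 1/eps, so the
  # residue check cannot be tighter than that floor
  im_tol <- max(im_tol, 1e-15 * r^-T)
  if (resid > im_tol)
    stop(sprintf(paste0("imaginary residue %.3e above tolerance %.3e in ",
                        "generating-function inversion (T = %d, K = %d, ",
                        "r = %.4f)"), resid, im_tol, T, K, r))
  co <- Re(co)
  if (probability) {
    over <- max(0, max(co) - 1, -min(co))
    if (over > 1e-6)
      stop(sprintf("coefficients outside [0, 1] by %.3e", over))
    co <- pmin(pmax(co, 0), 1)
  }
  structure(data.frame(t = 0:T, probability = co),
            class = c("walk_series", "data.frame"),
            radius = r, K = K, im_residue = resid)
}
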