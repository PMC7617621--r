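#' Heterogeneous connections (defect pairs)
#'
#' A defect pair perturbs the transitions between two sites `u` and `v`:
#' `lambda_vu` is subtracted from the jump probability `u -> v` (and added to
#' the staying probability of `u`), and `lambda_uv` likewise for `v -> u`.
#' Positive values impede crossing (barriers), negative values promote it by
#' drawing on the staying probability (antibarriers, long-range connections).
#' Probability is conserved by construction. Validity requires
#' `lambda_vu <= A[v, u]` and `lambda_uv <= A[u, v]` (no negative jump
#' probability) and, per site, a non-negative resulting staying probability.
#'
#' @param spec a [lattice_spec()].
#' @param u,v the two sites (coordinates or flat ids), `u != v`.
#' @param lambda_vu signed probability mass applied to the `u -> v`
#'   transition.
#' @param lambda_uv signed probability mass applied to the `v -> u`
#'   transition.
#' @param op optional precomputed transition operator (avoids rebuilding).
#' @return an object of class `defect_pair`.
#' @export
defect_pair <- function(spec, u, v, lambda_vu = 0, lambda_uv = 0, op = NULL) {
  uid <- site_id(spec, u)
  vid <- site_id(spec, v)
  stopifnot(length(uid) == 1L, length(vid) == 1L)
  if (uid == vid) stop("a defect pair needs two distinct sites")
  if (is.null(op)) op <- build_transition_operator(spec)
  if (lambda_vu > op[vid, uid] + 1e-12)
    stop(sprintf("lambda_vu = %g exceeds A[v,u] = %g", lambda_vu, op[vid, uid]))
  if (lambda_uv > op[uid, vid] + 1e-12)
    stop(sprintf("lambda_uv = %g exceeds A[u,v] = %g", lambda_uv, op[uid, vid]))
  structure(list(u = uid, v = vid, lambda_vu = lambda_vu,
                 lambda_uv = lambda_uv),
            class = "defect_pair")
}

#' @export
print.defect_pair <- function(x, ...) {
  cat(sprintf("<defect_pair> u=%d v=%d lambda_vu=%g lambda_uv=%g\n",
              x$u, x$v, x$lambda_vu, x$lambda_uv))
  invisible(x)
}

#' Collect defect pairs into a validated heterogeneity set
#'
#' Validates the collection: pairs must be unique as unordered site pairs
#' (duplicates raise an error rather than merging), every lambda must respect
#' the entry bound of its transition, and at every site the staying
#' probability after perturbation must remain non-negative.
#'
#' @param spec a [lattice_spec()].
#' @param pairs a list of [defect_pair()] objects (possibly nested, as
#'   returned by [make_sticky()] and friends), or `NULL` for the homogeneous
#'   walk.
#' @param drop_zero drop pairs whose both lambdas are zero (default `TRUE`);
#'   they have no effect but enlarge the defect matrix.
#' @return an object of class `het_set` with `M` pairs.
#' @export
het_set <- function(spec, pairs = NULL, drop_zero = TRUE) {
  stopifnot(inherits(spec, "lattice_spec"))
  pairs <- .flatten_pairs(pairs)
  M <- length(pairs)
  uid <- vapply(pairs, `[[`, 0L, "u")
  vid <- vapply(pairs, `[[`, 0L, "v")
  lvu <- vapply(pairs, `[[`, 0, "lambda_vu")
  luv <- vapply(pairs, `[[`, 0, "lambda_uv")
  if (drop_zero && M) {
    keep <- lvu != 0 | luv != 0
    uid <- uid[keep]; vid <- vid[keep]; lvu <- lvu[keep]; luv <- luv[keep]
    M <- sum(keep)
  }
  if (M) {
    key <- paste(pmin(uid, vid), pmax(uid, vid))
    if (anyDuplicated(key))
      stop("duplicate defect pair (unordered {u, v} must be unique): ",
           key[duplicated(key)][1L])
  }
  set <- structure(list(spec = spec, M = M, u = uid, v = vid,
                        lambda_vu = lvu, lambda_uv = luv),
                   class = "het_set")
  validate_het_set(set)
  set
}

.flatten_pairs <- function(pairs) {
  if (is.null(pairs)) return(list())
  if (inherits(pairs, "defect_pair")) return(list(pairs))
  out <- list()
  for (p in pairs) {
    if (inherits(p, "defect_pair")) out[[length(out) + 1L]] <- p
    else if (is.list(p)) out <- c(out, .flatten_pairs(p))
    else stop("`pairs` must contain defect_pair objects")
  }
  out
}

#' Validate a heterogeneity set against its lattice
#'
#' Checks the per-entry bounds (`lambda <= A` entrywise) and the per-site
#' staying-probability bound `A[u, u] + sum_w lambda_wu >= 0`.
#'
#' @param set a [het_set()].
#' @param op optional precomputed transition operator.
#' @return `set`, invisibly; errors name the offending site.
#' @export
validate_het_set <- function(set, op = NULL) {
  stopifnot(inherits(set, "het_set"))
  if (!set$M) return(invisible(set))
  if (is.null(op)) op <- build_transition_operator(set$spec)
  for (i in seq_len(set$M)) {
    if (set$lambda_vu[i] > op[set$v[i], set$u[i]] + 1e-12)
      stop(sprintf("pair %d: lambda_vu = %g exceeds A[v,u] = %g (site %d)",
                   i, set$lambda_vu[i], op[set$v[i], set$u[i]], set$u[i]))
    if (set$lambda_uv[i] > op[set$u[i], set$v[i]] + 1e-12)
      stop(sprintf("pair %d: lambda_uv = %g exceeds A[u,v] = %g (site %d)",
                   i, set$lambda_uv[i], op[set$u[i], set$v[i]], set$v[i]))
  }
  # staying-probability bound per site: outgoing lambdas add to the diagonal
  outgo <- tapply(c(set$lambda_vu, set$lambda_uv), c(set$u, set$v), sum)
  ids <- as.integer(names(outgo))
  stay <- Matrix::diag(op)[ids] + as.numeric(outgo)
  if (any(stay < -1e-12))
    stop("staying probability would become negative at site ",
         ids[which.min(stay)])
  invisible(set)
}

#' @export
print.het_set <- function(x, ...) {
  cat(sprintf("<het_set> M = %d defect pairs on a %s lattice\n",
              x$M, paste(x$spec$N, collapse = "x")))
  invisible(x)
}

# empty-set coercion helper
.as_het_set <- function(set, spec) {
  if (is.null(set)) return(het_set(spec))
  stopifnot(inherits(set, "het_set"))
  set
}

#' Partially reflecting barrier between two neighbours
#'
#' Sets `lambda_vu = alpha_v * A[v, u]` and `lambda_uv = alpha_u * A[u, v]`.
#' `alpha_u = alpha_v = 1` gives an impenetrable barrier; an asymmetric
#' choice such as `alpha_v = 1, alpha_u = 0` gives a one-way gate (movement
#' `v -> u` allowed, `u -> v` blocked).
#'
#' @param spec a [lattice_spec()].
#' @param u,v neighbouring sites.
#' @param alpha_u,alpha_v reflectivities in `[0, 1]`.
#' @param op optional precomputed transition operator.
#' @return a [defect_pair()].
#' @export
make_barrier <- function(spec, u, v, alpha_u = 1, alpha_v = alpha_u,
                         op = NULL) {
  stopifnot(alpha_u >= 0, alpha_u <= 1, alpha_v >= 0, alpha_v <= 1)
  if (is.null(op)) op <- build_transition_operator(spec)
  uid <- site_id(spec, u); vid <- site_id(spec, v)
  if (op[vid, uid] <= 0 || op[uid, vid] <= 0)
    stop("barrier requires nearest-neighbour sites (A[v,u] and A[u,v] > 0)")
  defect_pair(spec, uid, vid,
              lambda_vu = alpha_v * op[vid, uid],
              lambda_uv = alpha_u * op[uid, vid], op = op)
}

#' Antibarrier between two neighbours
#'
#' Opposite of a barrier: crossing is promoted by drawing on the staying
#' probabilities, `lambda_vu = -beta_v * A[u, u]` and
#' `lambda_uv = -beta_u * A[v, v]`.
#'
#' @inheritParams make_barrier
#' @param beta_u,beta_v proportions in `[0, 1]` of the staying probability
#'   moved onto the crossing.
#' @return a [defect_pair()].
#' @export
make_antibarrier <- function(spec, u, v, beta_u = 1, beta_v = beta_u,
                             op = NULL) {
  stopifnot(beta_u >= 0, beta_u <= 1, beta_v >= 0, beta_v <= 1)
  if (is.null(op)) op <- build_transition_operator(spec)
  uid <- site_id(spec, u); vid <- site_id(spec, v)
  if (op[vid, uid] <= 0 || op[uid, vid] <= 0)
    stop("antibarrier requires nearest-neighbour sites")
  defect_pair(spec, uid, vid,
              lambda_vu = -beta_v * op[uid, uid],
              lambda_uv = -beta_u * op[vid, vid], op = op)
}

#' Long-range connection between two non-neighbours
#'
#' Adds a jump channel between non-neighbouring sites `u` and `s`, funded by
#' the lazy (staying) probability: `lambda_su = -beta_s * A[u, u]` and
#' `lambda_us = -beta_u * A[s, s]`.
#'
#' @inheritParams make_barrier
#' @param s the distant site (`A[s, u] = A[u, s] = 0`).
#' @param beta_u,beta_s proportions in `[0, 1]` of the lazy probability
#'   rewired onto the long-range jump.
#' @return a [defect_pair()].
#' @export
make_long_range <- function(spec, u, s, beta_u = 1, beta_s = beta_u,
                            op = NULL) {
  stopifnot(beta_u >= 0, beta_u <= 1, beta_s >= 0, beta_s <= 1)
  if (is.null(op)) op <- build_transition_operator(spec)
  uid <- site_id(spec, u); sid <- site_id(spec, s)
  if (op[sid, uid] != 0 || op[uid, sid] != 0)
    stop("sites are neighbours; use make_barrier()/make_antibarrier()")
  defect_pair(spec, uid, sid,
              lambda_vu = -beta_s * op[uid, uid],
              lambda_uv = -beta_u * op[sid, sid], op = op)
}

#' Rewire a neighbour connection onto a distant site
#'
#' Removes the jump `u -> v` (a one-way impenetrable barrier,
#' `lambda_vu = A[v, u]`) and adds the same mass as a jump `u -> s`
#' (`lambda_su = -A[v, u]`), leaving the column sum of `u` unchanged.
#'
#' @inheritParams make_long_range
#' @param v the neighbour losing its incoming connection from `u`.
#' @return a list of two [defect_pair()] objects.
#' @export
make_rewire <- function(spec, u, v, s, op = NULL) {
  if (is.null(op)) op <- build_transition_operator(spec)
  uid <- site_id(spec, u); vid <- site_id(spec, v); sid <- site_id(spec, s)
  if (op[vid, uid] <= 0) stop("v must be a neighbour of u")
  if (op[sid, uid] != 0) stop("s must not be a neighbour of u")
  mass <- op[vid, uid]
  list(defect_pair(spec, uid, vid, lambda_vu = mass, op = op),
       defect_pair(spec, uid, sid, lambda_vu = -mass, op = op))
}

#' Sticky site
#'
#' One-way partially reflecting barriers between `w` and each of its `k`
#' actual neighbours: `lambda_{r_i, w} = alpha * A[r_i, w]`,
#' `lambda_{w, r_i} = 0`. The staying probability at `w` increases by
#' `alpha * sum_i A[r_i, w]`; jumps towards `w` are unaffected.
#'
#' @param spec a [lattice_spec()].
#' @param w the sticky site.
#' @param alpha stickiness in `[0, 1]`; `alpha = 1` removes all outgoing
#'   mass (a trap with no escape).
#' @param op optional precomputed transition operator.
#' @return a list of `k` [defect_pair()] objects.
#' @export
make_sticky <- function(spec, w, alpha, op = NULL) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (is.null(op)) op <- build_transition_operator(spec)
  wid <- site_id(spec, w)
  nb <- setdiff(which(op[, wid] > 0), wid)
  lapply(nb, function(r)
    defect_pair(spec, wid, r, lambda_vu = alpha * op[r, wid], op = op))
}

#' Slippery site
#'
#' Opposite of a sticky site: the staying probability of `w` is spread
#' equally over its `k` actual neighbours,
#' `lambda_{r_i, w} = -(beta / k) * A[w, w]`, which automatically respects
#' the staying-probability bound.
#'
#' @inheritParams make_sticky
#' @param beta slipperiness in `[0, 1]`; `beta = 1` removes the staying
#'   probability entirely.
#' @return a list of `k` [defect_pair()] objects.
#' @export
make_slippery <- function(spec, w, beta, op = NULL) {
  stopifnot(beta >= 0, beta <= 1)
  if (is.null(op)) op <- build_transition_operator(spec)
  wid <- site_id(spec, w)
  nb <- setdiff(which(op[, wid] > 0), wid)
  k <- length(nb)
  lapply(nb, function(r)
    defect_pair(spec, wid, r, lambda_vu = -(beta / k) * op[wid, wid],
                op = op))
}

#' Apply a heterogeneity set to a transition operator
#'
#' Produces the perturbed operator: for each pair,
#' `A[v, u] - lambda_vu` with `lambda_vu` added to `A[u, u]`, and
#' symmetrically for `lambda_uv`. Column sums are unchanged, so probability
#' conservation (or the absorbing deficit) is preserved exactly.
#'
#' @param set a [het_set()].
#' @param A the transition operator of `set$spec` (built if missing).
#' @return the perturbed sparse operator.
#' @export
apply_defects <- function(set, A = NULL) {
  stopifnot(inherits(set, "het_set"))
  if (is.null(A)) A <- build_transition_operator(set$spec)
  for (i in seq_len(set$M)) {
    u <- set$u[i]; v <- set$v[i]
    A[v, u] <- A[v, u] - set$lambda_vu[i]
    A[u, u] <- A[u, u] + set$lambda_vu[i]
    A[u, v] <- A[u, v] - set$lambda_uv[i]
    A[v, v] <- A[v, v] + set$lambda_uv[i]
  }
  neg <- which(A@x < -1e-12)
  if (length(neg))
    stop("perturbation produced a negative transition probability at site ",
         site_id(set$spec, 1L + (A@i[neg[1L]])))
  drop0(A)
}

#' Does a heterogeneity set preserve the homogeneous steady state?
#'
#' Tests the ratio condition
#' `A[u,v] / A[v,u] == (A[u,v] - lambda_uv) / (A[v,u] - lambda_vu)` for
#' every pair (cross-multiplied, with 0/0 treated as satisfied). When it
#' holds, the perturbed walk keeps the stationary distribution of the
#' homogeneous walk, and by Kac's lemma every mean return time is unchanged.
#'
#' @param set a [het_set()].
#' @param op optional precomputed transition operator.
#' @param tol numerical tolerance.
#' @return logical.
#' @export
is_symmetry_preserving <- function(set, op = NULL, tol = 1e-12) {
  stopifnot(inherits(set, "het_set"))
  if (!set$M) return(TRUE)
  if (is.null(op)) op <- build_transition_operator(set$spec)
  for (i in seq_len(set$M)) {
    auv <- op[set$u[i], set$v[i]]
    avu <- op[set$v[i], set$u[i]]
    if (abs(auv * set$lambda_vu[i] - avu * set$lambda_uv[i]) > tol)
      return(FALSE)
  }
  TRUE
}

# drop lambdas that would act on the zeroed columns of absorbing sites
.restrict_set_to_absorbing <- function(set, abs_ids) {
  if (!set$M || !length(abs_ids)) return(set)
  set$lambda_vu[set$u %in% abs_ids] <- 0
  set$lambda_uv[set$v %in% abs_ids] <- 0
  keep <- set$lambda_vu != 0 | set$lambda_uv != 0
  set$u <- set$u[keep]; set$v <- set$v[keep]
  set$lambda_vu <- set$lambda_vu[keep]; set$lambda_uv <- set$lambda_uv[keep]
  set$M <- sum(keep)
  set
}
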