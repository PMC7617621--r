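#' Brick-and-mortar (stratum corneum) scenario
#'
#' Declarative description of a 2D domain crossed from a reflecting top face
#' to an absorbing bottom face, obstructed by staggered rectangular "bricks"
#' outlined with (partially) reflecting barrier pairs — a lattice model of a
#' drug molecule traversing the stratum corneum. A rectangular puncture of
#' height `h` and width `w`, anchored at the top boundary and centred in the
#' periodic dimension, removes every barrier pair it touches (a microneedle
#' piercing the layer).
#'
#' Geometry: dimension 1 runs from the absorbing face at `n1 = 1` to the
#' reflecting face at `n1 = N[1]`; dimension 2 is periodic. Bricks of size
#' `brick = c(height, width)` are laid in layers separated by one mortar
#' row, starting at row 2; layers alternate a half-period column offset
#' (standard brick bond). `N[2]` must be a multiple of `brick[2] + 1`.
#'
#' @param N domain size `c(N1, N2)`.
#' @param brick brick size `c(height, width)` in sites.
#' @param h,w puncture height and width in sites (0 = intact layer).
#' @param alpha barrier reflectivity in `[0, 1]` (1 = impenetrable).
#' @param q diffusion parameters.
#' @return a `brick_mortar_config` list.
#' @export
brick_mortar_config <- function(N = c(13, 12), brick = c(3, 5), h = 0, w = 0,
                                alpha = 1, q = c(0.8, 0.8)) {
  stopifnot(length(N) == 2L, length(brick) == 2L, h >= 0, w >= 0,
            alpha >= 0, alpha <= 1)
  if (N[2] %% (brick[2] + 1L) != 0L)
    stop("N[2] must be a multiple of brick width + 1 (brick + mortar column)")
  layers <- (N[1] - brick[1] - 2L) %/% (brick[1] + 1L) + 1L
  if (layers < 1L) stop("domain too shallow for a single brick layer")
  structure(list(N = as.integer(N), brick = as.integer(brick),
                 h = as.integer(h), w = as.integer(w), alpha = alpha,
                 q = q, layers = layers,
                 bricks_per_layer = N[2] %/% (brick[2] + 1L)),
            class = "brick_mortar_config")
}

# cells (coordinate matrix) of all bricks in the configured bond pattern
.brick_cells <- function(cfg) {
  bh <- cfg$brick[1L]; bw <- cfg$brick[2L]
  period <- bw + 1L
  out <- NULL
  for (l in seq_len(cfg$layers) - 1L) {
    rows <- 2L + l * (bh + 1L) + seq_len(bh) - 1L
    off <- if (l %% 2L == 0L) 0L else period %/% 2L
    for (j in seq_len(cfg$bricks_per_layer) - 1L) {
      cols <- ((off + j * period + seq_len(bw) - 1L) %% cfg$N[2L]) + 1L
      out <- rbind(out, as.matrix(expand.grid(n1 = rows, n2 = cols)))
    }
  }
  out
}

#' Build the brick-and-mortar lattice and barrier set
#'
#' @param cfg a [brick_mortar_config()].
#' @return list with elements `spec` (mixed-boundary [lattice_spec()]),
#'   `set` (the barrier [het_set()]), `n0` (start site at the reflecting
#'   face, centre of the puncture) and `n_pairs`.
#' @export
build_brick_mortar <- function(cfg) {
  stopifnot(inherits(cfg, "brick_mortar_config"))
  spec <- lattice_spec(cfg$N, q = cfg$q,
                       boundary = c("absorbing_low", "periodic"))
  A <- build_transition_operator(spec)
  cells <- .brick_cells(cfg)
  inside <- logical(n_sites(spec))
  inside[site_id(spec, cells)] <- TRUE
  # puncture rectangle: h rows below the reflecting top face, centred cols
  punct <- logical(n_sites(spec))
  if (cfg$h > 0L && cfg$w > 0L) {
    rows <- (cfg$N[1L] - cfg$h + 1L):cfg$N[1L]
    c0 <- cfg$N[2L] %/% 2L
    cols <- (((c0 - (cfg$w - 1L) %/% 2L):(c0 + cfg$w %/% 2L)) - 1L) %%
      cfg$N[2L] + 1L
    punct[site_id(spec, as.matrix(expand.grid(n1 = rows, n2 = cols)))] <- TRUE
  }
  pairs <- list()
  seen <- character(0)
  ids <- which(inside)
  co <- site_coords(spec, ids)
  for (k in seq_along(ids)) {
    x <- ids[k]
    nbs <- .neighbour_ids(spec, co[k, ])
    for (y in nbs) {
      if (inside[y]) next
      key <- paste(min(x, y), max(x, y))
      if (key %in% seen) next
      seen <- c(seen, key)
      if (punct[x] || punct[y]) next
      pairs[[length(pairs) + 1L]] <-
        make_barrier(spec, x, y, alpha_u = cfg$alpha, op = A)
    }
  }
  list(spec = spec, set = het_set(spec, pairs),
       n0 = c(cfg$N[1L], cfg$N[2L] %/% 2L), n_pairs = length(pairs))
}

# 4-neighbourhood of a site under the spec's boundary conditions
.neighbour_ids <- function(spec, coord) {
  out <- integer(0)
  for (i in seq_len(spec$d)) {
    for (s in c(-1L, 1L)) {
      nb <- coord
      nb[i] <- nb[i] + s
      if (nb[i] < 1L || nb[i] > spec$N[i]) {
        if (spec$boundary[i] == "periodic")
          nb[i] <- ((nb[i] - 1L) %% spec$N[i]) + 1L
        else next
      }
      out <- c(out, site_id(spec, nb))
    }
  }
  unique(out)
}

#' Mean exit time as a function of puncture size
#'
#' Sweeps puncture heights and widths and computes the mean exit time
#' through the absorbing face from the top-centre start site for each
#' combination. For impenetrable bricks the exit time is non-monotone in
#' the puncture height (opening a brick layer temporarily traps the walker;
#' cutting through it creates a direct channel); for permeable bricks it
#' decreases monotonically.
#'
#' @param cfg a [brick_mortar_config()] (its `h`, `w` are ignored).
#' @param h_values,w_values integer vectors of puncture sizes to sweep.
#' @return data frame with columns `h`, `w`, `met`.
#' @export
met_vs_puncture <- function(cfg, h_values, w_values) {
  grid <- expand.grid(h = as.integer(h_values), w = as.integer(w_values))
  grid$met <- vapply(seq_len(nrow(grid)), function(i) {
    ci <- cfg
    ci$h <- grid$h[i]; ci$w <- grid$w[i]
    sc <- build_brick_mortar(ci)
    as.numeric(met(sc$set, sc$spec, sc$n0))
  }, 0)
  grid
}

# ---------------------------------------------------------------------------

#' Thigmotaxis scenario: annular preference in a circular arena
#'
#' A square reflecting domain containing two concentric circles around the
#' centre site. The outer circle of radius `R` is outlined with impenetrable
#' barriers (a circular arena); the inner circle of radius `r` carries
#' one-way partially reflecting barriers that leave outward movement free
#' but block inward movement with strength `alpha_i` — a walker drifts into
#' the annulus without resistance and tends to stay there, the stronger the
#' larger `alpha_i`. A lattice edge carries a barrier iff its endpoint site
#' centres lie on opposite sides of the circle (Euclidean distance to the
#' domain centre).
#'
#' @param N odd linear size of the square domain.
#' @param R outer (arena) radius in sites.
#' @param r inner radius, `r < R`.
#' @param alpha_i inward-blocking strength in `[0, 1]`.
#' @param q diffusion parameters.
#' @return a `thigmotaxis_config` list.
#' @export
thigmotaxis_config <- function(N = 21, R = 9.6, r = 5.8, alpha_i = 0.95,
                               q = c(0.8, 0.8)) {
  stopifnot(N %% 2L == 1L, r < R, 2 * R < N + 1, alpha_i >= 0, alpha_i <= 1)
  structure(list(N = as.integer(N), R = R, r = r, alpha_i = alpha_i, q = q),
            class = "thigmotaxis_config")
}

#' Build the thigmotaxis lattice and barrier set
#'
#' @param cfg a [thigmotaxis_config()].
#' @return list with `spec`, `set`, `n0` (the centre site) and the barrier
#'   pair counts `n_outer`, `n_inner`.
#' @export
build_thigmotaxis <- function(cfg) {
  stopifnot(inherits(cfg, "thigmotaxis_config"))
  spec <- lattice_spec(c(cfg$N, cfg$N), q = cfg$q)
  A <- build_transition_operator(spec)
  ctr <- (cfg$N + 1L) / 2
  dist_of <- function(co) sqrt((co[, 1L] - ctr)^2 + (co[, 2L] - ctr)^2)
  all_co <- site_coords(spec, seq_len(n_sites(spec)))
  dist <- dist_of(all_co)
  pairs <- list()
  seen <- character(0)
  n_outer <- 0L; n_inner <- 0L
  for (x in seq_len(n_sites(spec))) {
    for (y in .neighbour_ids(spec, all_co[x, ])) {
      if (y <= x) next
      key <- paste(x, y)
      if (key %in% seen) next
      seen <- c(seen, key)
      crosses_R <- xor(dist[x] <= cfg$R, dist[y] <= cfg$R)
      crosses_r <- xor(dist[x] <= cfg$r, dist[y] <= cfg$r)
      if (crosses_R) {
        pairs[[length(pairs) + 1L]] <- make_barrier(spec, x, y, 1, op = A)
        n_outer <- n_outer + 1L
      } else if (crosses_r && cfg$alpha_i > 0) {
        inner <- if (dist[x] <= cfg$r) x else y
        outer <- if (dist[x] <= cfg$r) y else x
        # block the inward move (outer -> inner); outward stays free
        pairs[[length(pairs) + 1L]] <- defect_pair(
          spec, u = outer, v = inner,
          lambda_vu = cfg$alpha_i * A[inner, outer], op = A)
        n_inner <- n_inner + 1L
      }
    }
  }
  list(spec = spec, set = het_set(spec, pairs),
       n0 = c((cfg$N + 1L) %/% 2L, (cfg$N + 1L) %/% 2L),
       n_outer = n_outer, n_inner = n_inner)
}

#' Steady-state mean-squared displacement
#'
#' \deqn{\mathfrak{M} = \sum_n \lVert n - n_0\rVert^2\, \mathfrak{R}_n^{-1}
#' = \sum_n \lVert n - n_0\rVert^2\, \pi(n),}
#' where \eqn{\pi} is the stationary distribution of the perturbed walk
#' (restricted to the communicating component of `n0`, e.g. the arena
#' inside the outer circle).
#'
#' @param set a [het_set()] (or `NULL`).
#' @param x a [lattice_spec()] or [homogeneous_propagator_gf()].
#' @param n0 reference site (coordinates or flat id).
#' @return squared displacement in site units.
#' @export
steady_state_msd <- function(set, x, n0) {
  spec <- .spec_of(x)
  set <- .as_het_set(set, spec)
  id_0 <- site_id(spec, n0)
  Ap <- apply_defects(set)
  pi_v <- .steady_state_from(Ap, id_0)
  co <- site_coords(spec, seq_len(n_sites(spec)))
  co0 <- site_coords(spec, id_0)
  d2 <- rowSums((co - matrix(co0, nrow(co), spec$d, byrow = TRUE))^2)
  sum(d2 * pi_v)
}

#' Saturated MSD as a function of the thigmotactic strength
#'
#' @param cfg a [thigmotaxis_config()] (its `alpha_i` is ignored).
#' @param alpha_values values of `alpha_i` to sweep.
#' @return data frame with columns `alpha_i`, `msd` and `ratio` (normalized
#'   by the barrier-free `alpha_i = 0` arena).
#' @export
thigmotaxis_msd_curve <- function(cfg, alpha_values) {
  msd <- vapply(alpha_values, function(a) {
    ci <- cfg; ci$alpha_i <- a
    sc <- build_thigmotaxis(ci)
    steady_state_msd(sc$set, sc$spec, sc$n0)
  }, 0)
  base_cfg <- cfg; base_cfg$alpha_i <- 0
  sc0 <- build_thigmotaxis(base_cfg)
  m0 <- steady_state_msd(sc0$set, sc0$spec, sc0$n0)
  data.frame(alpha_i = alpha_values, msd = msd, ratio = msd / m0)
}

# ---------------------------------------------------------------------------

#' Two-particle coalescence scenario
#'
#' Two particles A and B on a 1D reflecting segment of `N` sites, moving
#' simultaneously and independently with moving probability `q`, are
#' represented as a single walker on the 2D product lattice (`kernel =
#' "product"`, diagonal steps allowed). The diagonal `n1 = n2` is the bound
#' state (complex C). Inert interactions are encoded as barriers on the
#' combined lattice:
#' * `alpha_e` scales one-way barriers on every edge *entering* the
#'   diagonal (mutual exclusion impeding binding; 1 = particles never meet),
#' * `alpha_u` scales the openness of edges *leaving* the diagonal
#'   (barrier strength `1 - alpha_u`; 0 = irreversible binding),
#' * `alpha_c` scales the mobility *along* the diagonal (barrier strength
#'   `1 - alpha_c`; 0 = immobile complex).
#' `alpha_e = 0, alpha_u = alpha_c = 1` is exactly the homogeneous combined
#' walk.
#'
#' @param N segment length.
#' @param q moving probability of each particle.
#' @param alpha_e,alpha_u,alpha_c control parameters in `[0, 1]`.
#' @param target 1D site at which both particles must meet (default `N`).
#' @return a `coalescence_config` list.
#' @export
coalescence_config <- function(N = 15, q = 2/3, alpha_e = 0, alpha_u = 1,
                               alpha_c = 1, target = N) {
  stopifnot(N >= 3, q > 0, q <= 1,
            alpha_e >= 0, alpha_e <= 1, alpha_u >= 0, alpha_u <= 1,
            alpha_c >= 0, alpha_c <= 1, target >= 1, target <= N)
  structure(list(N = as.integer(N), q = q, alpha_e = alpha_e,
                 alpha_u = alpha_u, alpha_c = alpha_c,
                 target = as.integer(target)),
            class = "coalescence_config")
}

#' Build the combined-coalescence lattice and defect set
#'
#' @param cfg a [coalescence_config()].
#' @return list with `spec` (product-kernel 2D [lattice_spec()]), `set`,
#'   `n0 = c(1, N)` (particles maximally separated) and
#'   `target = c(target, target)` (both particles on the target site).
#' @export
build_coalescence <- function(cfg) {
  stopifnot(inherits(cfg, "coalescence_config"))
  N <- cfg$N
  spec <- lattice_spec(c(N, N), q = cfg$q, kernel = "product")
  A <- build_transition_operator(spec)
  pairs <- list()
  diag_ids <- site_id(spec, cbind(seq_len(N), seq_len(N)))
  on_diag <- logical(n_sites(spec))
  on_diag[diag_ids] <- TRUE
  for (m in seq_len(N)) {
    d <- diag_ids[m]
    nbs <- setdiff(which(A[, d] > 0), d)
    for (x in nbs[!on_diag[nbs]]) {
      lam_in <- cfg$alpha_e * A[d, x]        # x -> d : binding impeded
      lam_out <- (1 - cfg$alpha_u) * A[x, d] # d -> x : unbinding impeded
      if (lam_in != 0 || lam_out != 0)
        pairs[[length(pairs) + 1L]] <-
          defect_pair(spec, u = x, v = d, lambda_vu = lam_in,
                      lambda_uv = lam_out, op = A)
    }
    if (m < N && cfg$alpha_c < 1) {          # complex mobility along diagonal
      d2 <- diag_ids[m + 1L]
      lam <- (1 - cfg$alpha_c) * A[d2, d]
      pairs[[length(pairs) + 1L]] <-
        defect_pair(spec, u = d, v = d2, lambda_vu = lam, lambda_uv = lam,
                    op = A)
    }
  }
  list(spec = spec, set = het_set(spec, pairs),
       n0 = c(1L, N), target = c(cfg$target, cfg$target))
}

#' Coalescence MFPT ratio map
#'
#' Mean first-passage time for both particles to co-locate at the target,
#' normalized by the homogeneous combined walk (`alpha_e = 0`,
#' `alpha_u = alpha_c = 1`), over a grid of unbinding and complex-mobility
#' strengths.
#'
#' @param cfg a [coalescence_config()] (its `alpha_u`, `alpha_c` are swept).
#' @param alpha_u_values,alpha_c_values grid values in `[0, 1]`.
#' @return data frame with columns `alpha_u`, `alpha_c`, `mfpt`, `ratio`.
#' @export
coalescence_mfpt_map <- function(cfg, alpha_u_values, alpha_c_values) {
  hom <- build_coalescence(coalescence_config(N = cfg$N, q = cfg$q,
                                              target = cfg$target))
  f_hom <- as.numeric(mfpt(hom$set, hom$spec, hom$n0, hom$target))
  grid <- expand.grid(alpha_u = alpha_u_values, alpha_c = alpha_c_values)
  grid$mfpt <- vapply(seq_len(nrow(grid)), function(i) {
    ci <- cfg
    ci$alpha_u <- grid$alpha_u[i]; ci$alpha_c <- grid$alpha_c[i]
    sc <- build_coalescence(ci)
    as.numeric(mfpt(sc$set, sc$spec, sc$n0, sc$target))
  }, 0)
  grid$ratio <- grid$mfpt / f_hom
  grid
}
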