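#' Specify a homogeneous lattice random walk
#'
#' Defines a d-dimensional nearest-neighbour lazy walk on a finite lattice.
#' In each dimension `i` the walker jumps to either neighbour with
#' probability `q[i]/(2d)` ("average" kernel) and otherwise stays put, so the
#' bulk staying probability is `1 - mean(q)`. With the "product" kernel the d
#' coordinates move simultaneously and independently (each a 1D lazy walk
#' with parameter `q[i]`), which allows diagonal steps; this is the combined
#' walk used to represent two coalescing particles in one higher-dimensional
#' walker.
#'
#' Boundary handling per dimension:
#' * `"reflecting"`: the blocked jump folds back into the staying
#'   probability.
#' * `"periodic"`: jumps wrap around.
#' * `"absorbing_low"`, `"absorbing_high"`, `"absorbing_both"`: mass stepping
#'   off the face is removed (the column sum at face sites drops below 1);
#'   the opposite face reflects unless also absorbing.
#'
#' Additionally, individual sites may be declared absorbing via
#' `absorbing_sites`: their whole outgoing column is zeroed, i.e. the walker
#' is removed on arrival. This is the construction used for first-passage
#' targets.
#'
#' @param N integer vector, number of sites per dimension (each >= 2).
#' @param q numeric vector in (0, 1], diffusion parameter per dimension
#'   (recycled to length `length(N)`).
#' @param boundary character vector, boundary condition per dimension
#'   (recycled); one of `"reflecting"`, `"periodic"`, `"absorbing_low"`,
#'   `"absorbing_high"`, `"absorbing_both"`.
#' @param absorbing_sites optional list of site coordinate vectors (or a
#'   matrix with one site per row, or a vector of flat site ids) of
#'   individually absorbing sites.
#' @param kernel `"average"` (one coordinate moves per step) or `"product"`
#'   (all coordinates move simultaneously).
#' @return An object of class `lattice_spec`.
#' @examples
#' sp <- lattice_spec(N = c(10, 10), q = c(0.2, 0.2))
#' A <- build_transition_operator(sp)
#' @export
lattice_spec <- function(N, q = 1, boundary = "reflecting",
                         absorbing_sites = NULL,
                         kernel = c("average", "product")) {
  kernel <- match.arg(kernel)
  N <- as.integer(N)
  d <- length(N)
  if (d < 1L || any(is.na(N)) || any(N < 2L))
    stop("`N` must be a vector of integers >= 2")
  q <- rep_len(as.numeric(q), d)
  if (any(!is.finite(q)) || any(q <= 0) || any(q > 1))
    stop("all diffusion parameters `q` must lie in (0, 1]")
  boundary <- rep_len(as.character(boundary), d)
  kinds <- c("reflecting", "periodic", "absorbing_low", "absorbing_high",
             "absorbing_both")
  if (!all(boundary %in% kinds))
    stop("unknown boundary kind; use one of: ", paste(kinds, collapse = ", "))
  spec <- structure(
    list(N = N, d = d, q = q, boundary = boundary, kernel = kernel,
         absorbing_sites = integer(0)),
    class = "lattice_spec")
  if (!is.null(absorbing_sites) && length(absorbing_sites))
    spec$absorbing_sites <- sort(unique(site_id(spec, absorbing_sites)))
  spec
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec> %s lattice, %s kernel\n",
              paste(x$N, collapse = "x"), x$kernel))
  cat("  q:        ", paste(format(x$q), collapse = ", "), "\n")
  cat("  boundary: ", paste(x$boundary, collapse = ", "), "\n")
  if (length(x$absorbing_sites))
    cat("  absorbing sites:", length(x$absorbing_sites), "\n")
  invisible(x)
}

#' Number of sites of a lattice
#' @param spec a [lattice_spec()].
#' @return integer site count.
#' @export
n_sites <- function(spec) prod(spec$N)

# strides for row-major flattening (dimension 1 slowest, dimension d fastest)
.strides <- function(N) rev(cumprod(rev(c(N[-1L], 1L))))

#' Convert site coordinates to flat site ids
#'
#' Sites are 1-based in every dimension. Flattening is row-major with the
#' first dimension slowest. A length-d vector is a single site; a matrix
#' holds one site per row; a list holds coordinate vectors. Plain integers of
#' length != d are interpreted as already-flat ids.
#'
#' @param spec a [lattice_spec()].
#' @param n site coordinates (vector, matrix or list) or flat ids.
#' @return integer vector of site ids in `1:n_sites(spec)`.
#' @export
site_id <- function(spec, n) {
  d <- spec$d
  if (is.list(n)) n <- do.call(rbind, n)
  if (is.matrix(n)) {
    if (ncol(n) != d) stop("site matrix must have d = ", d, " columns")
  } else {
    n <- as.integer(n)
    if (length(n) == d && d > 1L) n <- matrix(n, nrow = 1L)
    else { # flat ids (always the case for d == 1)
      if (any(n < 1L | n > n_sites(spec))) stop("site id out of range")
      return(as.integer(n))
    }
  }
  storage.mode(n) <- "integer"
  if (any(n < 1L) || any(n > matrix(spec$N, nrow(n), d, byrow = TRUE)))
    stop("site coordinates out of lattice bounds")
  as.integer(1L + (n - 1L) %*% .strides(spec$N))
}

#' Convert flat site ids back to coordinates
#' @param spec a [lattice_spec()].
#' @param id integer vector of flat site ids.
#' @return integer matrix, one site per row.
#' @export
site_coords <- function(spec, id) {
  id0 <- as.integer(id) - 1L
  if (any(id0 < 0L | id0 >= n_sites(spec))) stop("site id out of range")
  s <- .strides(spec$N)
  out <- matrix(0L, length(id), spec$d)
  for (i in seq_len(spec$d)) {
    out[, i] <- id0 %/% s[i] + 1L
    id0 <- id0 %% s[i]
  }
  out
}

# 1D transition operator (dense), column = origin
.op_1d <- function(N, q, boundary) {
  A <- matrix(0, N, N)
  jump <- q / 2
  diag(A) <- 1 - q
  for (i in seq_len(N)) {
    if (i > 1L) A[i - 1L, i] <- A[i - 1L, i] + jump
    else switch(boundary,
      reflecting = , absorbing_high = { A[1L, 1L] <- A[1L, 1L] + jump },
      periodic = { A[N, 1L] <- A[N, 1L] + jump },
      NULL) # absorbing_low / absorbing_both: mass leaves the lattice
    if (i < N) A[i + 1L, i] <- A[i + 1L, i] + jump
    else switch(boundary,
      reflecting = , absorbing_low = { A[N, N] <- A[N, N] + jump },
      periodic = { A[1L, N] <- A[1L, N] + jump },
      NULL)
  }
  A
}

#' Build the homogeneous transition operator
#'
#' Assembles the sparse one-step transition operator of the homogeneous walk,
#' with columns indexed by the origin site and rows by the destination.
#' Columns sum to 1 except at absorbing faces/sites.
#'
#' @param spec a [lattice_spec()].
#' @return a sparse `dgCMatrix` of dimension `n_sites(spec)` squared.
#' @export
build_transition_operator <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  ops <- lapply(seq_len(spec$d), function(i)
    methods::as(methods::as(.op_1d(spec$N[i], spec$q[i], spec$boundary[i]),
                            "generalMatrix"), "CsparseMatrix"))
  A <- NULL
  if (spec$kernel == "average") {
    for (i in seq_len(spec$d)) {
      term <- Reduce(function(x, y) kronecker(x, y),
                     lapply(seq_len(spec$d), function(j)
                       if (j == i) ops[[j]] else Diagonal(spec$N[j])))
      A <- if (is.null(A)) term else A + term
    }
    A <- A / spec$d
  } else {
    A <- Reduce(function(x, y) kronecker(x, y), ops)
  }
  A <- methods::as(A, "CsparseMatrix")
  if (length(spec$absorbing_sites)) A[, spec$absorbing_sites] <- 0
  methods::as(drop0(A), "generalMatrix")
}

# drop explicit zeros, keep sparse class
drop0 <- function(A) Matrix::drop0(A)

# sites absorbed on arrival (columns zeroed)
.absorbed_ids <- function(spec) spec$absorbing_sites

# TRUE when no mass is ever lost
.is_conserving <- function(spec) {
  all(spec$boundary %in% c("reflecting", "periodic")) &&
    !length(spec$absorbing_sites)
}

# ids reachable from `start` following non-zero entries of sparse operator A
.reachable <- function(A, start) {
  n <- nrow(A)
  r <- logical(n)
  r[start] <- TRUE
  pattern <- methods::as(A, "lMatrix")
  repeat {
    nr <- as.logical((pattern %*% r) > 0) | r
    if (identical(nr, r)) break
    r <- nr
  }
  which(r)
}
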