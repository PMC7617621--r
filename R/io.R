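#' Read and write lattice specifications
#'
#' A [lattice_spec()] round-trips through JSON or YAML with fields `N`,
#' `q`, `boundary`, `kernel` and `absorbing_sites` (flat ids).
#'
#' @param spec a [lattice_spec()].
#' @param path file path; the format is inferred from the extension
#'   (`.json`, `.yaml`/`.yml`) unless `format` is given.
#' @param format `"json"` or `"yaml"`.
#' @return `read_lattice_spec` returns a [lattice_spec()];
#'   `write_lattice_spec` returns `path` invisibly.
#' @export
write_lattice_spec <- function(spec, path, format = NULL) {
  stopifnot(inherits(spec, "lattice_spec"))
  x <- list(N = spec$N, q = spec$q, boundary = spec$boundary,
            kernel = spec$kernel, absorbing_sites = spec$absorbing_sites)
  fmt <- format %||% .ext_format(path)
  if (fmt == "json")
    jsonlite::write_json(x, path, auto_unbox = FALSE, digits = NA)
  else yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_lattice_spec
#' @export
read_lattice_spec <- function(path, format = NULL) {
  fmt <- format %||% .ext_format(path)
  x <- if (fmt == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  lattice_spec(N = x$N, q = x$q, boundary = x$boundary,
               absorbing_sites = unlist(x$absorbing_sites),
               kernel = x$kernel %||% "average")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.ext_format <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
  else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml"
  else stop("cannot infer format from extension; pass `format`")
}

#' Read and write heterogeneity sets
#'
#' Serializes the resolved defect pairs as a JSON (or YAML) array of
#' `{u, v, lambda_vu, lambda_uv}` records with flat site ids.
#'
#' @param set a [het_set()].
#' @param path file path.
#' @param format `"json"` or `"yaml"` (inferred from the extension).
#' @param spec the [lattice_spec()] the pairs refer to (reading only).
#' @return `read_het_set` returns a validated [het_set()].
#' @export
write_het_set <- function(set, path, format = NULL) {
  stopifnot(inherits(set, "het_set"))
  x <- data.frame(u = set$u, v = set$v, lambda_vu = set$lambda_vu,
                  lambda_uv = set$lambda_uv)
  fmt <- format %||% .ext_format(path)
  if (fmt == "json") jsonlite::write_json(x, path, digits = NA)
  else yaml::write_yaml(lapply(seq_len(nrow(x)), function(i) as.list(x[i, ])),
                        path)
  invisible(path)
}

#' @rdname write_het_set
#' @export
read_het_set <- function(path, spec, format = NULL) {
  fmt <- format %||% .ext_format(path)
  x <- if (fmt == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else do.call(rbind.data.frame, yaml::read_yaml(path))
  op <- build_transition_operator(spec)
  pairs <- lapply(seq_len(nrow(x)), function(i)
    defect_pair(spec, x$u[i], x$v[i], x$lambda_vu[i], x$lambda_uv[i],
                op = op))
  het_set(spec, pairs)
}

#' Build defect pairs from a declarative description
#'
#' Each element of `defs` is a list with a `type` field — one of
#' `"barrier"`, `"antibarrier"`, `"gate"`, `"long_range"`, `"rewire"`,
#' `"sticky"`, `"slippery"`, `"pair"` — plus the parameters of the
#' corresponding builder (`u`, `v`, `s`, `w` as site coordinate vectors or
#' flat ids; `alpha*`, `beta*`, `lambda*` as numbers). A `"gate"` is a
#' barrier that only blocks `u -> v` (`alpha_v = alpha`, `alpha_u = 0`).
#'
#' @param spec a [lattice_spec()].
#' @param defs list of declarative defect descriptions.
#' @return a validated [het_set()].
#' @export
defects_from_config <- function(spec, defs) {
  op <- build_transition_operator(spec)
  pairs <- lapply(defs, function(d) {
    type <- d$type %||% stop("defect description needs a `type`")
    switch(type,
      barrier = make_barrier(spec, unlist(d$u), unlist(d$v),
                             alpha_u = d$alpha_u %||% d$alpha %||% 1,
                             alpha_v = d$alpha_v %||% d$alpha %||% 1,
                             op = op),
      gate = make_barrier(spec, unlist(d$u), unlist(d$v), alpha_u = 0,
                          alpha_v = d$alpha %||% 1, op = op),
      antibarrier = make_antibarrier(spec, unlist(d$u), unlist(d$v),
                                     beta_u = d$beta_u %||% d$beta %||% 1,
                                     beta_v = d$beta_v %||% d$beta %||% 1,
                                     op = op),
      long_range = make_long_range(spec, unlist(d$u), unlist(d$s),
                                   beta_u = d$beta_u %||% d$beta %||% 1,
                                   beta_s = d$beta_s %||% d$beta %||% 1,
                                   op = op),
      rewire = make_rewire(spec, unlist(d$u), unlist(d$v), unlist(d$s),
                           op = op),
      sticky = make_sticky(spec, unlist(d$w), alpha = d$alpha, op = op),
      slippery = make_slippery(spec, unlist(d$w), beta = d$beta, op = op),
      pair = defect_pair(spec, unlist(d$u), unlist(d$v),
                         lambda_vu = d$lambda_vu %||% 0,
                         lambda_uv = d$lambda_uv %||% 0, op = op),
      stop("unknown defect type: ", type))
  })
  het_set(spec, pairs)
}

#' Write a time series as CSV
#'
#' @param ts a `walk_series` data frame (columns `t`, `probability`) or the
#'   `estimate` element of a [sample_first_passage()] ensemble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(ts, path) {
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}

#' Write a first-passage summary as JSON
#'
#' @param fp an `fp_result` from [first_passage()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fp_summary <- function(fp, path) {
  stopifnot(inherits(fp, "fp_result"))
  jsonlite::write_json(
    list(mean = fp$mean, reach_probability = fp$reach_probability,
         n0 = fp$n0, targets = fp$targets, method = fp$method),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
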