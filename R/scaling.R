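#' Fit a per-variable scaling onto a strictly positive working range
#'
#' The concept decoder is multiplicative, and the GELU-activated concept is
#' bounded below near -0.17, so modelling happens in a sign-stable working
#' range: each variable is affinely mapped from its observed min-max range
#' onto `[eps_pos, 1]`. Constant variables map to the midpoint 0.5 with unit
#' scale so the inverse stays well defined. All metrics in this package are
#' reported after inverting the map.
#'
#' @param trajectories List of [trajectory] objects.
#' @param eps_pos Lower end of the working range (default 0.01).
#' @return An object of class `"scaling_spec"` with per-variable `offset` and
#'   `scale` such that `working = offset + scale * raw`.
#' @export
fit_scaling <- function(trajectories, eps_pos = 0.01) {
  stopifnot(eps_pos > 0, eps_pos < 1)
  vars <- trajectories[[1L]]$variables
  lo <- rep(Inf, length(vars)); hi <- rep(-Inf, length(vars))
  nobs <- integer(length(vars))
  for (tr in trajectories) {
    stopifnot(identical(tr$variables, vars))
    for (v in seq_along(vars)) {
      x <- tr$values[v, tr$mask[v, ]]
      if (length(x)) {
        lo[v] <- min(lo[v], min(x)); hi[v] <- max(hi[v], max(x))
        nobs[v] <- nobs[v] + length(x)
      }
    }
  }
  if (any(nobs == 0L))
    stop_tce("no observed values for variable(s): %s", paste(vars[nobs == 0L], collapse = ", "))
  scale <- ifelse(hi > lo, (1 - eps_pos) / (hi - lo), 1)
  offset <- ifelse(hi > lo, eps_pos - scale * lo, 0.5 - scale * lo)
  structure(list(variables = vars, offset = offset, scale = scale, eps_pos = eps_pos),
            class = "scaling_spec")
}

#' @export
print.scaling_spec <- function(x, ...) {
  cat(sprintf("<scaling_spec: %d variables -> [%g, 1]>\n", length(x$variables), x$eps_pos))
  invisible(x)
}

#' Apply or invert a fitted scaling
#'
#' @param spec A `"scaling_spec"` from [fit_scaling()].
#' @param x A [trajectory], or a numeric matrix/vector in variable order.
#' @return Same shape as `x`, transformed into (or back from) the working
#'   range.
#' @export
apply_scaling <- function(spec, x) scale_impl(spec, x, invert = FALSE)

#' @rdname apply_scaling
#' @export
invert_scaling <- function(spec, x) scale_impl(spec, x, invert = TRUE)

scale_impl <- function(spec, x, invert) {
  if (inherits(x, "trajectory")) {
    x$values <- scale_impl(spec, x$values, invert)
    x$values[!x$mask] <- 0
    return(x)
  }
  if (is.matrix(x)) {
    stopifnot(nrow(x) == length(spec$variables))
    if (invert) (x - spec$offset) / spec$scale else spec$offset + spec$scale * x
  } else {
    stopifnot(length(x) == length(spec$variables))
    if (invert) (x - spec$offset) / spec$scale else spec$offset + spec$scale * x
  }
}

#' Serialize / restore a scaling spec as JSON
#'
#' @param spec A `"scaling_spec"`.
#' @param path File path.
#' @return `write_scaling` returns `path` invisibly; `read_scaling` the spec.
#' @export
write_scaling <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaling
#' @export
read_scaling <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(variables = s$variables, offset = as.numeric(s$offset),
                 scale = as.numeric(s$scale), eps_pos = s$eps_pos),
            class = "scaling_spec")
}
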