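#' Construct a multivariate longitudinal trajectory
#'
#' A trajectory holds one entity's V x T matrix of continuous measurements,
#' its strictly increasing timestamps, and an observation mask. Timestamps
#' are either plain integer step indices (simulated data) or `POSIXct`
#' calendar times (clinical-style data).
#'
#' @param entity_id Character scalar identifying the entity.
#' @param values Numeric V x T matrix (rows = variables, columns = times).
#' @param times Strictly increasing numeric step indices or `POSIXct`
#'   timestamps, length T. Defaults to `0:(T-1)` step indices.
#' @param mask Logical V x T matrix, `TRUE` where observed. Defaults to all
#'   observed.
#' @param variables Character vector of V unique variable names. Defaults to
#'   the rownames of `values` or `"V1"..`.
#' @param conditions Optional character vector of length T giving the
#'   condition token in force at each step (`NA` for none).
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(entity_id, values, times = NULL, mask = NULL,
                       variables = NULL, conditions = NULL) {
  values <- as.matrix(values)
  V <- nrow(values); T_ <- ncol(values)
  if (is.null(variables)) variables <- rownames(values) %||% paste0("V", seq_len(V))
  if (is.null(times)) times <- seq_len(T_) - 1L
  if (is.null(mask)) mask <- matrix(TRUE, V, T_)
  mask <- matrix(as.logical(mask), V, T_)
  rownames(values) <- variables
  rownames(mask) <- variables
  obj <- structure(
    list(entity_id = as.character(entity_id), variables = as.character(variables),
         times = times, values = values, mask = mask, conditions = conditions),
    class = "trajectory")
  validate_trajectory(obj)
  obj
}

validate_trajectory <- function(x) {
  stopifnot(inherits(x, "trajectory"))
  V <- nrow(x$values); T_ <- ncol(x$values)
  if (V < 1L) stop_tce("trajectory '%s': needs at least one variable", x$entity_id)
  if (T_ < 2L) stop_tce("trajectory '%s': needs at least two time points", x$entity_id)
  if (anyDuplicated(x$variables)) stop_tce("trajectory '%s': duplicate variable names", x$entity_id)
  if (length(x$times) != T_) stop_tce("trajectory '%s': times/values length mismatch", x$entity_id)
  tn <- as.numeric(x$times)
  if (any(diff(tn) <= 0)) stop_tce("trajectory '%s': times must be strictly increasing", x$entity_id)
  if (!all(dim(x$mask) == c(V, T_))) stop_tce("trajectory '%s': mask dimension mismatch", x$entity_id)
  if (any(!is.finite(x$values[x$mask]))) stop_tce("trajectory '%s': non-finite observed value", x$entity_id)
  if (!is.null(x$conditions) && length(x$conditions) != T_)
    stop_tce("trajectory '%s': conditions length mismatch", x$entity_id)
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s': %d variables x %d times, %.1f%% observed>\n",
              x$entity_id, nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  invisible(x)
}

#' Read trajectories from long-format delimited text
#'
#' Expects one row per (entity, time, variable) cell. Cells absent from the
#' file are recorded as unobserved (`mask = FALSE`, value placeholder 0).
#' Gzip-compressed files are read transparently. Entities with fewer than two
#' time points are skipped with a warning.
#'
#' @param path Path to a CSV file (optionally `.gz`).
#' @param schema Named character vector mapping the roles `entity`, `time`,
#'   `variable`, `value` and optionally `observed` and `condition` to column
#'   names in the file.
#' @return A list of [trajectory] objects, one per entity.
#' @export
read_trajectories <- function(path,
                              schema = c(entity = "entity_id", time = "time",
                                         variable = "variable", value = "value",
                                         observed = "observed", condition = "condition")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("entity", "time", "variable", "value")
  for (role in need)
    if (!schema[[role]] %in% names(df))
      stop_tce("column '%s' (role %s) missing from %s", schema[[role]], role, path)
  ent <- as.character(df[[schema[["entity"]]]])
  tim <- df[[schema[["time"]]]]
  if (is.character(tim)) {
    tim_p <- as.POSIXct(tim, tz = "UTC")
    if (anyNA(tim_p)) stop_tce("unparseable timestamp at row %d", which(is.na(tim_p))[1L])
    tim <- tim_p
  }
  var <- as.character(df[[schema[["variable"]]]])
  val <- df[[schema[["value"]]]]
  if (!is.numeric(val)) {
    vnum <- suppressWarnings(as.numeric(val))
    if (anyNA(vnum) && any(!is.na(val) & is.na(vnum)))
      stop_tce("non-numeric value at row %d", which(!is.na(val) & is.na(vnum))[1L])
    val <- vnum
  }
  key <- paste(ent, as.numeric(tim), var, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop_tce("duplicate row for entity '%s', time %s, variable '%s'",
             ent[d], format(tim[d]), var[d])
  }
  obs_col <- schema[["observed"]]
  obs <- if (!is.na(obs_col) && obs_col %in% names(df)) as.logical(df[[obs_col]]) else rep(TRUE, nrow(df))
  cond_col <- schema[["condition"]]
  has_cond <- !is.na(cond_col) && cond_col %in% names(df)

  variables <- sort(unique(var))  # consistent order across entities
  out <- list()
  for (e in unique(ent)) {
    sel <- ent == e
    ut <- sort(unique(tim[sel]))
    if (length(ut) < 2L) {
      warning(sprintf("entity '%s' has fewer than 2 time points; skipped", e), call. = FALSE)
      next
    }
    V <- length(variables); T_ <- length(ut)
    vals <- matrix(0, V, T_, dimnames = list(variables, NULL))
    msk <- matrix(FALSE, V, T_)
    ridx <- match(var[sel], variables)
    cidx <- match(as.numeric(tim[sel]), as.numeric(ut))
    flat <- cbind(ridx, cidx)
    vals[flat] <- val[sel]
    msk[flat] <- obs[sel] & !is.na(val[sel])
    vals[!msk] <- 0
    conds <- NULL
    if (has_cond) {
      conds <- rep(NA_character_, T_)
      cc <- as.character(df[[cond_col]])[sel]
      conds[cidx] <- ifelse(cc == "" | is.na(cc), NA_character_, cc)
    }
    out[[e]] <- trajectory(e, vals, times = ut, mask = msk,
                           variables = variables, conditions = conds)
  }
  out
}

#' Write trajectories as long-format CSV
#'
#' Inverse of [read_trajectories()]: unobserved cells are omitted so that a
#' read/write/read cycle is idempotent.
#'
#' @param trajectories List of [trajectory] objects.
#' @param path Output path.
#' @param provenance Optional character vector (recycled per trajectory)
#'   written to a `provenance` column, e.g. `"observed"` or `"generated"`.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path, provenance = NULL) {
  rows <- lapply(seq_along(trajectories), function(k) {
    tr <- trajectories[[k]]
    obs <- which(tr$mask, arr.ind = TRUE)
    d <- data.frame(entity_id = tr$entity_id,
                    time = format_times(tr$times[obs[, 2L]]),
                    variable = tr$variables[obs[, 1L]],
                    ## 17 significant digits so doubles round-trip bit-exactly
                    value = sprintf("%.17g", tr$values[obs]),
                    observed = TRUE,
                    stringsAsFactors = FALSE)
    if (!is.null(tr$conditions)) d$condition <- tr$conditions[obs[, 2L]]
    if (!is.null(provenance)) d$provenance <- rep_len(provenance, length(trajectories))[k]
    d
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$entity_id, df$time, df$variable), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

format_times <- function(times) {
  if (inherits(times, "POSIXct")) format(times, "%Y-%m-%d %H:%M:%S", tz = "UTC") else times
}

#' Export trajectories in wide format
#'
#' One row per (entity, time), one column per variable; unobserved cells are
#' `NA`.
#'
#' @inheritParams write_trajectories
#' @return `path`, invisibly.
#' @export
write_trajectories_wide <- function(trajectories, path) {
  rows <- lapply(trajectories, function(tr) {
    v <- t(tr$values)
    v[t(!tr$mask)] <- NA
    d <- data.frame(entity_id = tr$entity_id, time = format_times(tr$times),
                    v, stringsAsFactors = FALSE, check.names = FALSE)
    names(d)[-(1:2)] <- tr$variables
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
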