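#' Enumerate edit windows for training and evaluation
#'
#' A window is a triple (history ending at position `i`, target position
#' `j = i + gap`, gap). Gap 1 is immediate editing (condition applied now,
#' effect at the next step); gap > 1 is delayed editing (condition scheduled
#' `gap` steps ahead, forecast in one generation step). Positions are 1-based
#' column indices into the trajectory.
#'
#' @param trajectory A [trajectory].
#' @param min_history Minimum number of history steps (positions `1..i`)
#'   required, at least 1.
#' @param horizon_set Integer vector of gaps to enumerate.
#' @return A data.frame with columns `entity_id`, `hist_end`, `target`,
#'   `gap`, `condition` (token in force on the step arriving at the target,
#'   `NA` if the trajectory carries no condition labels). Zero rows if the
#'   trajectory is too short.
#' @export
make_edit_windows <- function(trajectory, min_history = 1L, horizon_set = 1L) {
  stopifnot(is_count(min_history), min_history >= 1L, length(horizon_set) >= 1L)
  horizon_set <- sort(unique(as.integer(horizon_set)))
  stopifnot(all(horizon_set >= 1L))
  T_ <- ncol(trajectory$values)
  rows <- list()
  for (g in horizon_set) {
    if (T_ - g < min_history) next
    i <- min_history:(T_ - g)
    ## require at least one observed step in the history window
    obs_any <- cumsum(colSums(trajectory$mask) > 0L)[i] >= 1L
    i <- i[obs_any]
    if (!length(i)) next
    cond <- if (is.null(trajectory$conditions)) NA_character_ else trajectory$conditions[i + g - 1L]
    rows[[length(rows) + 1L]] <- data.frame(
      entity_id = trajectory$entity_id, hist_end = i, target = i + g, gap = g,
      condition = cond, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(entity_id = character(), hist_end = integer(),
                      target = integer(), gap = integer(), condition = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## enumerate windows across a collection
collect_windows <- function(trajectories, min_history, horizon_set) {
  out <- lapply(seq_along(trajectories), function(k) {
    w <- make_edit_windows(trajectories[[k]], min_history, horizon_set)
    if (nrow(w)) w$traj <- k
    w
  })
  out <- out[vapply(out, nrow, 1L) > 0L]
  if (!length(out))
    stop_tce("no edit windows: trajectories too short for min_history=%d", min_history)
  do.call(rbind, out)
}
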