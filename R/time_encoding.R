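## Time positional embeddings.
##
## h_t = E_year(t) + E_month(t) + E_date(t) + E_hour(t), all of dimension d_h.
## The year component is a fixed sinusoidal encoding of the year value
## (alternating sin/cos, geometric wavelengths, base 10000); month, date and
## hour are learned lookup tables over their finite ranges (12, 31, 24).
##
## Integer step indices (simulated data) are interpreted as hours from a
## fixed epoch: the hour index is t mod 24 and rolls over into the date and
## month indices, so embeddings stay injective over practical horizons.

## decompose timestamps into 1-based lookup indices + numeric year value
time_components <- function(times) {
  if (inherits(times, "POSIXct")) {
    lt <- as.POSIXlt(times, tz = "UTC")
    list(month = lt$mon + 1L, date = lt$mday, hour = lt$hour + 1L,
         year = lt$year + 1900)
  } else {
    t <- as.numeric(times)
    ## sub-hour resolution is not encoded
    t <- floor(t)
    list(month = (t %/% 744L) %% 12L + 1L,     # 744 = 24 * 31
         date  = (t %/% 24L) %% 31L + 1L,
         hour  = t %% 24L + 1L,
         year  = t %/% 8928L)                  # 8928 = 24 * 31 * 12
  }
}

## fixed sinusoidal encoding of the year value; rows = timestamps
year_sinusoid <- function(year, d_h) {
  half <- d_h %/% 2L
  freq <- 1 / 10000^((2 * (seq_len(half) - 1L)) / d_h)
  ang <- outer(year, freq)
  out <- matrix(0, length(year), d_h)
  out[, seq(1L, d_h, by = 2L)] <- sin(ang)
  out[, seq(2L, d_h, by = 2L)] <- cos(ang)
  out
}

## batch embedding from component indices; params carries Emonth/Edate/Ehour
time_embed <- function(params, comp, d_h) {
  year_sinusoid(comp$year, d_h) +
    params$Emonth[comp$month, , drop = FALSE] +
    params$Edate[comp$date, , drop = FALSE] +
    params$Ehour[comp$hour, , drop = FALSE]
}

#' Time positional embedding
#'
#' Embeds one or more timestamps into the model's hidden space by summing a
#' fixed sinusoidal year component with learned month, date and hour lookup
#' embeddings. Deterministic given the model parameters; resolution is one
#' hour (one integer step for step-indexed data).
#'
#' @param model A `"tce_model"` or fitted `"tcedit"` object.
#' @param times Timestamps: numeric step indices or `POSIXct`.
#' @return A `length(times)` x `d_h` matrix of embeddings.
#' @export
encode_time <- function(model, times) {
  time_embed(model$params, time_components(times), model$config$d_h)
}

#' Time-delta embedding
#'
#' `delta(t_i, t_j) = h_(t_j) - h_(t_i)`. Antisymmetric and additive by
#' construction: `delta(t,t) = 0`, `delta(a,b) = -delta(b,a)`, and
#' `delta(a,c) = delta(a,b) + delta(b,c)` (to machine precision).
#'
#' @inheritParams encode_time
#' @param t_i,t_j Timestamps (vectorized, equal length or length 1).
#' @return Matrix of `h_(t_j) - h_(t_i)` rows.
#' @export
time_delta <- function(model, t_i, t_j) {
  encode_time(model, t_j) - encode_time(model, t_i)
}

#' Combine a time delta with an adapted condition
#'
#' The time- and condition-specific embedding is the element-wise sum
#' `h_s^(t_j) = delta + h_s`.
#'
#' @param delta Numeric vector or single-row matrix from [time_delta()].
#' @param h_s Adapted condition representation from [adapt_condition()].
#' @return Numeric vector of the shared hidden dimension.
#' @export
combine_time_condition <- function(delta, h_s) {
  delta <- drop(delta); h_s <- drop(h_s)
  if (length(delta) != length(h_s))
    stop_tce("dimension mismatch: delta has length %d, h_s length %d",
             length(delta), length(h_s))
  delta + h_s
}
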