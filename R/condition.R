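#' Condition-embedding table
#'
#' A table of frozen condition embeddings `z_s`, standing in for a frozen
#' pretrained embedding model. Embeddings are never updated during training;
#' only the condition adapter that consumes them is. A reserved null token
#' (its own fixed embedding) represents "no condition", so pure forecasting
#' is distinguishable from an all-zero embedding.
#'
#' @param tokens Character vector of condition token ids.
#' @param d_z Embedding dimension.
#' @param seed Integer seed for the fixed random Gaussian embeddings.
#' @param null_token Reserved id for the null condition.
#' @return An object of class `"condition_table"`.
#' @export
condition_table <- function(tokens, d_z = 16L, seed = 1L, null_token = "<none>") {
  tokens <- unique(as.character(tokens))
  if (null_token %in% tokens) tokens <- setdiff(tokens, null_token)
  all_tok <- c(null_token, tokens)
  rng <- local({ set.seed(seed); matrix(stats::rnorm(length(all_tok) * d_z), length(all_tok), d_z) })
  rownames(rng) <- all_tok
  structure(list(tokens = all_tok, Z = rng, d_z = d_z, null_token = null_token),
            class = "condition_table")
}

#' @export
print.condition_table <- function(x, ...) {
  cat(sprintf("<condition_table: %d tokens (incl. null '%s'), d_z = %d>\n",
              length(x$tokens), x$null_token, x$d_z))
  invisible(x)
}

## token -> frozen embedding rows (n x d_z); NA/NULL -> null token
condition_rows <- function(table, tokens) {
  tokens <- as.character(tokens)
  tokens[is.na(tokens)] <- table$null_token
  idx <- match(tokens, table$tokens)
  if (anyNA(idx))
    stop_tce("unknown condition token(s) %s; known: %s",
             paste(unique(tokens[is.na(idx)]), collapse = ", "),
             paste(table$tokens, collapse = ", "))
  table$Z[idx, , drop = FALSE]
}

#' Adapt a condition token into the hidden space
#'
#' Looks up the frozen embedding `z_s` and applies the learned condition
#' adapter `h_s = GELU(W_a z_s + b_a)`.
#'
#' @param model A `"tce_model"` or fitted `"tcedit"` object.
#' @param token Condition token id, or `NULL`/`NA` for the null condition.
#' @param table Condition table; defaults to the one stored in the model.
#' @return Numeric vector `h_s` of dimension `d_h`.
#' @export
adapt_condition <- function(model, token = NULL, table = model$table) {
  z <- condition_rows(table, if (is.null(token)) NA_character_ else token)
  drop(gelu(z %*% model$params$Wa + rep(model$params$ba, each = nrow(z))))
}

#' Read / write a condition-embedding table as delimited text
#'
#' First column is the token id, remaining columns the embedding; the header
#' row carries the dimension.
#'
#' @param table A `"condition_table"`.
#' @param path File path.
#' @param null_token Null-token id expected on read.
#' @return `write_condition_table` returns `path` invisibly;
#'   `read_condition_table` a `"condition_table"`.
#' @export
write_condition_table <- function(table, path) {
  df <- data.frame(token = table$tokens, table$Z, stringsAsFactors = FALSE)
  names(df) <- c("token", paste0("z", seq_len(table$d_z)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_condition_table
#' @export
read_condition_table <- function(path, null_token = "<none>") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  Z <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(Z)) stop_tce("non-numeric embedding entries in %s", path)
  rownames(Z) <- df[[1L]]
  if (!null_token %in% df[[1L]]) stop_tce("null token '%s' missing from %s", null_token, path)
  structure(list(tokens = df[[1L]], Z = Z, d_z = ncol(Z), null_token = null_token),
            class = "condition_table")
}
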