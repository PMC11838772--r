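#' Save or load a fitted editor checkpoint
#'
#' Checkpoints are self-describing JSON: parameters plus a sidecar header of
#' architecture hyperparameters, variable names, the scaling spec (and its
#' hash) and the training seed, so that loading validates the architecture
#' before use.
#'
#' @param fit Fitted `"tcedit"`.
#' @param path Output `.json` path.
#' @return `save_tcedit` returns `path` invisibly; `load_tcedit` the
#'   restored fit.
#' @export
save_tcedit <- function(fit, path) {
  sc_file <- tempfile(fileext = ".json")
  write_scaling(fit$scaling, sc_file)
  obj <- list(
    header = list(config = fit$config, horizons = fit$horizons,
                  min_history = fit$min_history, lambda = fit$lambda,
                  seed = fit$control$seed,
                  scaling = unclass(fit$scaling),
                  scaling_hash = unname(tools::md5sum(sc_file)),
                  tokens = fit$table$tokens, null_token = fit$table$null_token),
    Z = unclass(as.data.frame(fit$table$Z)),
    params = lapply(fit$params, function(p)
      if (is.matrix(p)) list(dim = dim(p), x = as.numeric(p)) else list(dim = NULL, x = as.numeric(p))),
    report = fit$report[c("train_loss", "val_loss", "best_epoch", "best_val_loss")])
  unlink(sc_file)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_tcedit
#' @param variables When given, checked against the checkpoint's variable
#'   names; a mismatch is an error naming the differing fields.
#' @export
load_tcedit <- function(path, variables = NULL) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- s$header$config
  cfg$variables <- as.character(cfg$variables)
  if (!is.null(variables) && !identical(as.character(variables), cfg$variables))
    stop_tce("checkpoint mismatch in field 'variables': checkpoint has [%s], requested [%s]",
             paste(cfg$variables, collapse = ","), paste(variables, collapse = ","))
  params <- lapply(s$params, function(p) {
    if (!is.null(p$dim) && length(p$dim)) matrix(p$x, p$dim[1L], p$dim[2L]) else as.numeric(p$x)
  })
  Z <- as.matrix(as.data.frame(s$Z))
  rownames(Z) <- s$header$tokens
  table <- structure(list(tokens = s$header$tokens, Z = Z, d_z = ncol(Z),
                          null_token = s$header$null_token), class = "condition_table")
  scaling <- structure(list(variables = as.character(s$header$scaling$variables),
                            offset = as.numeric(s$header$scaling$offset),
                            scale = as.numeric(s$header$scaling$scale),
                            eps_pos = s$header$scaling$eps_pos), class = "scaling_spec")
  structure(list(params = params, config = cfg, table = table, scaling = scaling,
                 counters = new.env(parent = emptyenv()),
                 control = tce_control(seed = s$header$seed %||% 1L),
                 horizons = as.integer(s$header$horizons),
                 min_history = as.integer(s$header$min_history),
                 lambda = s$header$lambda %||% 0,
                 entities = list(train = character(), validation = character()),
                 report = s$report),
            class = c("tcedit", "tce_model"))
}
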