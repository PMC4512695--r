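#' Serialize ensembles and tables
#'
#' Ensembles are written as a CSV with a `time` column followed by one
#' column per replicate, plus a JSON sidecar holding the parameters and
#' seed, so every file is reproducible from its sidecar alone.
#' Autocorrelation, histogram, moment and validation tables are written
#' as plain TSV.
#'
#' @param ensemble a `noise_ensemble` or `trajectory_ensemble`.
#' @param path path of the CSV file; the sidecar is written next to it
#'   as `<path>.json`.
#' @return `write_ensemble` returns `path` invisibly; `read_ensemble`
#'   returns a list with `times`, `values` and the parsed sidecar
#'   `meta` (if present).
#' @export
write_ensemble <- function(ensemble, path) {
  v <- ensemble$values
  df <- data.frame(time = ensemble$times, t(v))
  names(df) <- c("time", paste0("rep", seq_len(nrow(v))))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(class = class(ensemble)[1], seed = ensemble$seed,
               n_reps = nrow(v))
  if (inherits(ensemble, "noise_ensemble")) {
    meta$params <- unclass(ensemble$params)
  } else {
    p <- ensemble$params
    meta$model <- ensemble$model
    meta$params <- list(C0 = p$C0, gamma = p$gamma, epsilon = p$epsilon,
                        G0 = p$G0, D = p$noise$D, tau_c = p$noise$tau_c)
    meta$diverged <- sum(ensemble$diverged)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  df <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  list(times = df$time,
       values = t(as.matrix(df[, -1, drop = FALSE])),
       meta = meta)
}

#' @rdname write_ensemble
#' @param x a data.frame (e.g. an `autocorr_table`, histogram, moment
#'   table or `validation_report`).
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
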