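# Plain-text formats: headerless CSV for matrices, wide CSV for time series
# (first column time in hours, then h1..hNh, v1..vNv), JSON for parameters
# and results.  Writers format floats at 17 significant digits so that
# write/read round trips are bit-exact.

#' Read or write a matrix as headerless CSV
#'
#' Binary-valued files are validated as infection matrices; any other
#' non-negative numeric content is returned as a quantitative network.
#'
#' @param path CSV file path.
#' @param M matrix to write.
#' @return `read_matrix_csv()` returns a numeric matrix with attribute
#'   `"kind"` set to `"infection"` or `"quantitative"`.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  rows <- utils::read.table(path, sep = ",", header = FALSE,
                            colClasses = "numeric")
  M <- as.matrix(rows)
  dimnames(M) <- NULL
  if (length(M) == 0) stop_input("empty matrix file: ", path)
  if (any(!is.finite(M))) stop_input("non-numeric entries in ", path)
  if (any(M < 0)) stop_input("negative entries in ", path)
  if (all(M %in% c(0, 1))) {
    attr(M, "kind") <- "infection"
  } else {
    attr(M, "kind") <- "quantitative"
  }
  M
}

#' @rdname read_matrix_csv
#' @export
write_matrix_csv <- function(M, path) {
  check_matrix(M, "M")
  lines <- apply(M, 1L, function(row) {
    paste(formatC(row, digits = 17, format = "g"), collapse = ",")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a community time series as wide CSV
#'
#' Column layout: `time` (hours), then one column per host (`h1`, `h2`,
#' ...) and per virus (`v1`, `v2`, ...).  Provenance metadata travels in a
#' JSON sidecar at `<path>.meta.json`.
#'
#' @param ts a `"community_ts"` object.
#' @param path CSV file path.
#' @return `read_timeseries_csv()` returns a `"community_ts"`.
#' @export
write_timeseries_csv <- function(ts, path) {
  stopifnot(inherits(ts, "community_ts"))
  tab <- cbind(time = ts$times, t(ts$H), t(ts$V))
  lines <- c(paste(colnames(tab), collapse = ","),
             apply(tab, 1L, function(row) {
               paste(formatC(row, digits = 17, format = "g"), collapse = ",")
             }))
  writeLines(lines, path)
  jsonlite::write_json(ts$meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_timeseries_csv
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  tab <- utils::read.csv(path, header = TRUE)
  if (nrow(tab) == 0) stop_input("time-series file has no data rows: ", path)
  if (names(tab)[1L] != "time") {
    stop_input("first column must be 'time': ", path)
  }
  h_cols <- grep("^h[0-9]+$", names(tab))
  v_cols <- grep("^v[0-9]+$", names(tab))
  if (length(h_cols) == 0 || length(v_cols) == 0) {
    stop_input("expected host columns h1.. and virus columns v1.. in ", path)
  }
  times <- tab$time
  if (any(diff(times) <= 0)) {
    stop_input("times must be strictly increasing in ", path)
  }
  Hm <- t(as.matrix(tab[h_cols])); Vm <- t(as.matrix(tab[v_cols]))
  if (any(Hm <= 0) || any(Vm <= 0)) {
    stop_input("densities must be strictly positive in ", path)
  }
  dimnames(Hm) <- list(names(tab)[h_cols], NULL)
  dimnames(Vm) <- list(names(tab)[v_cols], NULL)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(dt = stats::median(diff(times)), T = max(times), snr_db = Inf)
  }
  structure(list(times = times, H = Hm, V = Vm, meta = meta),
            class = "community_ts")
}

#' Write a fitted network to JSON
#'
#' Stores the reconstructed quantitative network, decay rates, objective,
#' condition number and (when available) the reconstruction error.
#'
#' @param fit an `"infnet_fit"`.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "infnet_fit"))
  doc <- list(M_tilde_rec = fit$M_tilde, m_rec = fit$m,
              objective = fit$objective, condition_number = fit$kappa,
              n_cols = fit$n_cols, n_experiments = fit$n_experiments,
              hosts = fit$hosts)
  if (!is.null(fit$error)) doc$error_rec <- fit$error
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
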