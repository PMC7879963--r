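# Readers and writers for the declarative model format and the shipped
# tabular schemas.  The model config dialect is YAML; numbers are written
# with 17 significant digits so every file round-trips losslessly.

#' Write / read a model spec as YAML
#'
#' The YAML document mirrors the [sf_spec()] structure: `stocks` and `flows`
#' as record lists, `parameters` as scalars or `{value, trend: {year: mult}}`
#' maps, and `aux`/`outputs` as name-to-expression maps. Expressions are
#' validated against the rate grammar at load.
#'
#' @param spec An `sf_spec`.
#' @param path File path.
#' @export
write_model_spec <- function(spec, path) {
  row_list <- function(df) lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  obj <- list(
    stocks = row_list(spec$stocks),
    flows = row_list(spec$flows),
    parameters = lapply(spec$parameters, function(p) {
      if (is.null(p$trend)) p$value
      else list(value = p$value, trend = as.list(p$trend))
    }),
    aux = as.list(spec$aux),
    outputs = as.list(spec$outputs))
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  bind_rows_ <- function(lst) {
    do.call(rbind, lapply(lst, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  sf_spec(stocks = bind_rows_(obj$stocks),
          flows = bind_rows_(obj$flows),
          parameters = obj$parameters,
          aux = unlist(obj$aux) %||% character(),
          outputs = unlist(obj$outputs) %||% character())
}

#' Tabular I/O with schema checks
#'
#' Thin wrappers around `data.table::fwrite()`/`fread()`: UTF-8 CSV with a
#' mandatory header row and lossless numeric round-trips.
#'
#' @param df Data frame to write.
#' @param path File path.
#' @export
write_table <- function(df, path) {
  df <- as.data.frame(df)
  # doubles serialized with 17 significant digits so round-trips are lossless
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_table
#' @param required Character vector of required column names; an absent
#'   column is an error naming it.
#' @export
read_table <- function(path, required = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- as.data.frame(data.table::fread(path, encoding = "UTF-8"))
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss))
      stop(sprintf("file '%s' is missing column(s): %s",
                   path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a surveillance CSV
#'
#' Columns `(measure, year, value, kind, source)`; all
#' [surveillance_panel()] invariants are enforced on load.
#'
#' @param path File path.
#' @export
read_surveillance <- function(path) {
  surveillance_panel(read_table(path, c("measure", "year", "value", "kind", "source")))
}

#' Read a parameter-bounds CSV
#'
#' Columns `(parameter, default, low, high)` plus optional `note`.
#'
#' @param path File path.
#' @export
read_bounds <- function(path) {
  parameter_bounds(read_table(path, c("parameter", "default", "low", "high")))
}

#' Export a trajectory as tidy CSV
#'
#' Columns `(measure, year, value)` covering derived outputs and stocks.
#'
#' @param traj An `sf_trajectory`.
#' @param path File path.
#' @export
write_trajectory_csv <- function(traj, path) {
  write_table(as.data.frame(traj, which = c("outputs", "stocks")), path)
}
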