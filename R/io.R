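# Serialization.  Strategies travel as two-column CSV (index_or_x, value) or
# as JSON carrying the grid and metadata; trajectories as tidy CSV.  Schema
# version "cadyn-strategy/1".

#' Write a strategy to CSV
#'
#' Columns: `index_or_x` (the CA level `j/M`) and `value`.  The schema is
#' the same for both games; the reader decides the kind.
#' @param strategy a `ca_strategy`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_strategy_csv <- function(strategy, path) {
  df <- data.frame(index_or_x = (0:strategy$M) / strategy$M,
                   value = strategy$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a strategy from CSV
#'
#' @param path file written by [write_strategy_csv()] (columns
#'   `index_or_x`, `value` on a uniform grid).
#' @param kind `"vector"` or `"function"`.
#' @return a `ca_strategy`.
#' @export
read_strategy_csv <- function(path, kind = c("vector", "function")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path)
  if (!all(c("index_or_x", "value") %in% names(df)))
    stop("expected columns 'index_or_x' and 'value'")
  df <- df[order(df$index_or_x), ]
  if (kind == "vector") vector_strategy(df$value)
  else function_strategy(df$value)
}

#' Serialize a strategy to JSON
#'
#' @param strategy a `ca_strategy`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when writing to a file).
#' @export
strategy_to_json <- function(strategy, path = NULL) {
  kind <- if (inherits(strategy, "vector_strategy")) "vector" else "function"
  obj <- list(schema = "cadyn-strategy/1", kind = kind, M = strategy$M,
              values = strategy$values)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a strategy from JSON
#' @param path file or JSON string produced by [strategy_to_json()].
#' @return a `ca_strategy`.
#' @export
strategy_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$schema, "cadyn-strategy/1"))
    stop("unrecognized strategy schema")
  if (identical(obj$kind, "vector")) vector_strategy(obj$values)
  else function_strategy(obj$values)
}

#' Write a trajectory as tidy CSV
#'
#' Emits a states file (columns `t`, `node_index_or_x`, `value`, long format)
#' and a diagnostics file (columns `t`, `mca`, `mass`, `l2_norm`,
#' `constraint_active`, `defeat_margin`).
#'
#' @param trajectory a `ca_trajectory` from [integrate_dynamics()].
#' @param states_path,diagnostics_path output files.
#' @return invisibly, a list with the two paths.
#' @export
write_trajectory_csv <- function(trajectory, states_path, diagnostics_path) {
  x <- (0:(ncol(trajectory$states) - 1L)) / (ncol(trajectory$states) - 1L)
  long <- data.frame(
    t = rep(trajectory$times, each = length(x)),
    node_index_or_x = rep(x, times = length(trajectory$times)),
    value = as.vector(t(trajectory$states)))
  utils::write.csv(long, states_path, row.names = FALSE)
  utils::write.csv(trajectory$diagnostics, diagnostics_path,
                   row.names = FALSE)
  invisible(list(states = states_path, diagnostics = diagnostics_path))
}

#' Read back a trajectory states CSV
#' @param states_path file written by [write_trajectory_csv()].
#' @return list with `times` and `states` (matrix, one row per time).
#' @export
read_trajectory_csv <- function(states_path) {
  df <- utils::read.csv(states_path)
  times <- unique(df$t)
  n <- length(unique(df$node_index_or_x))
  states <- matrix(df$value, nrow = length(times), ncol = n, byrow = TRUE)
  list(times = times, states = states)
}
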