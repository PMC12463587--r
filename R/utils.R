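# Shared helpers and global unit conventions.

# One calendar month in days; the single global constant used to map 28-day
# model cycles onto survival-model time (which is in months).
DAYS_PER_MONTH <- 365.25 / 12

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(..., call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_number <- function(x, what, lower = -Inf, upper = Inf) {
  if (!is_number(x) || x < lower || x > upper) {
    stop_config(sprintf("'%s' must be a single finite number in [%s, %s]",
                        what, format(lower), format(upper)))
  }
  invisible(x)
}

#' Retrieve a configuration value by dotted path
#'
#' @param config a nested list (typically a [cea_config()]).
#' @param path dotted path, e.g. `"prices.ramucirumab"`.
#' @return the value stored at `path`.
#' @export
config_get <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]])) {
      stop_config("no parameter at path '", path, "'")
    }
    node <- node[[k]]
  }
  node
}

#' Set a configuration value by dotted path
#'
#' @inheritParams config_get
#' @param value replacement value; must address an existing scalar entry.
#' @return the modified configuration.
#' @export
config_set <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  config_get(config, path)  # validate the path exists
  rec <- function(node, keys) {
    if (length(keys) == 1L) {
      node[[keys]] <- value
      return(node)
    }
    node[[keys[1]]] <- rec(node[[keys[1]]], keys[-1])
    node
  }
  rec(config, keys)
}
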