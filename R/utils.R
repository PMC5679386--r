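# Dotted-path access into the nested config list.
#
# Segments are list names or 1-based integer indices; `*` expands over every
# element at that level so one path can address, e.g., the well-state utility
# of every strategy at once.

split_path <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, nzchar(path))
  strsplit(path, ".", fixed = TRUE)[[1]]
}

expand_paths <- function(x, segs) {
  if (length(segs) == 0L) return(list(character(0)))
  seg <- segs[[1]]
  rest <- segs[-1]
  if (identical(seg, "*")) {
    keys <- names(x) %||% as.character(seq_along(x))
    if (is.null(x) || length(x) == 0L) return(list())
    out <- list()
    for (i in seq_along(x)) {
      key <- if (!is.null(names(x)) && nzchar(names(x)[i])) names(x)[i] else as.character(i)
      for (tail in expand_paths(x[[i]], rest)) {
        out[[length(out) + 1L]] <- c(key, tail)
      }
    }
    return(out)
  }
  child <- pluck_seg(x, seg)
  if (is.null(child) && length(rest) > 0L) {
    abort(sprintf("config path segment '%s' not found", seg), class = "radcea_path_error")
  }
  lapply(expand_paths(child, rest), function(tail) c(seg, tail))
}

pluck_seg <- function(x, seg) {
  if (grepl("^[0-9]+$", seg)) {
    i <- as.integer(seg)
    if (i < 1L || i > length(x)) return(NULL)
    x[[i]]
  } else {
    x[[seg]]
  }
}

get_at <- function(x, segs) {
  for (seg in segs) {
    x <- pluck_seg(x, seg)
  }
  x
}

set_at <- function(x, segs, value) {
  if (length(segs) == 0L) return(value)
  seg <- segs[[1]]
  key <- if (grepl("^[0-9]+$", seg)) as.integer(seg) else seg
  child <- pluck_seg(x, seg)
  x[[key]] <- set_at(child, segs[-1], value)
  x
}

#' Read a numeric scalar from a config by dotted path
#'
#' Paths are dot-separated sequences of list names or 1-based indices, e.g.
#' `"strategies.IORT.pooled_events.recurrence_death.value"`. A `*` segment
#' matches every element at that level; `config_get()` then requires all
#' matches to be equal and returns the common value.
#'
#' @param config A `radcea_config` (or any nested list).
#' @param path Dotted path string.
#' @return The value at the path.
#' @export
#' @examples
#' cfg <- iort_ebrt_fixture()
#' config_get(cfg, "economics.wtp")
#' config_get(cfg, "strategies.*.states.Well.utility")
config_get <- function(config, path) {
  hits <- expand_paths(config, split_path(path))
  if (length(hits) == 0L) {
    abort(sprintf("config path '%s' matches nothing", path), class = "radcea_path_error")
  }
  vals <- lapply(hits, function(segs) get_at(config, segs))
  if (length(vals) > 1L) {
    first <- vals[[1]]
    same <- vapply(vals, function(v) isTRUE(all.equal(v, first)), logical(1))
    if (!all(same)) {
      abort(sprintf("config path '%s' matches %d unequal values", path, length(vals)),
            class = "radcea_path_error")
    }
  }
  vals[[1]]
}

#' Set a numeric scalar in a config by dotted path
#'
#' The final path segment may name a field that does not exist yet, in which
#' case it is created (used, e.g., to inject a late-complication probability
#' override). A `*` segment sets every match to the same value.
#'
#' @inheritParams config_get
#' @param value Replacement value.
#' @return The modified config.
#' @export
config_set <- function(config, path, value) {
  segs <- split_path(path)
  parents <- expand_paths(config, segs[-length(segs)])
  if (length(parents) == 0L) {
    abort(sprintf("config path '%s' matches nothing", path), class = "radcea_path_error")
  }
  last <- segs[[length(segs)]]
  for (p in parents) {
    config <- set_at(config, c(p, last), value)
  }
  config
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
is_nonneg <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
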