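#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.  `seed = NULL` runs `code` unseeded.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Deterministic per-stage sub-seed derived from one root seed.  Keeps the
# result a positive 32-bit integer so it is portable to set.seed().
#' @noRd
sub_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629L) + 1L
}

#' @noRd
stop_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}

#' @noRd
assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid("`", name, "` must be a single positive finite number")
  }
  invisible(x)
}

# Resolve a per-level parameter that may be given as a scalar (recycled) or
# as a named vector keyed by level label.
#' @noRd
per_level <- function(x, levels, name) {
  if (length(x) == 1L && is.null(names(x))) {
    return(setNames(rep(as.numeric(x), length(levels)), levels))
  }
  if (is.null(names(x)) && length(x) == length(levels)) {
    return(setNames(as.numeric(x), levels))
  }
  if (!all(levels %in% names(x))) {
    stop_invalid("`", name, "` must be a scalar or named by: ",
                 paste(levels, collapse = ", "))
  }
  setNames(as.numeric(x[levels]), levels)
}
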