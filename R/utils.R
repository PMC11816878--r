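# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the previous state on exit, so library code never perturbs the
#' user's random stream. A `NULL` seed evaluates `code` with the RNG as-is.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  code
}

# Derive a child seed from a base seed; keeps results < 2^31 and distinct per
# pipeline stage. NULL stays NULL (unseeded).
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + offset) %% 2147483629L)
}

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= lower && x <= upper
  if (!ok) {
    stop_arg("`%s` must be a single number in [%s, %s], got %s",
             name, format(lower), format(upper),
             paste(format(x), collapse = ", "))
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_arg("`%s` must be TRUE or FALSE", name)
  }
  invisible(x)
}

# Binary label vector in {0, 1}; factors/logicals are coerced.
as_binary_labels <- function(y, name = "labels") {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!is.numeric(y) || anyNA(y) || !all(y %in% c(0, 1))) {
    stop_arg("`%s` must be binary (0 = benign/control, 1 = malignant/AD)", name)
  }
  as.integer(y)
}
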