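# Internal helpers shared across modules.

#' Evaluate an expression with a fixed RNG seed, restoring the caller's state
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Signal a classed error so callers (and the CLI) can map conditions to codes
#' @noRd
pe_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("painephys_", class), "painephys_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

pe_warn <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)

#' @noRd
assert_finite <- function(x, name = deparse(substitute(x))) {
  bad <- which(!is.finite(x))
  if (length(bad))
    pe_stop("nonfinite", "%s contains a non-finite value (first at index %d)",
            name, bad[1])
  invisible(x)
}

#' @noRd
assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    pe_stop("badarg", "%s must be a finite scalar in [%s, %s]", name, lower, upper)
  invisible(x)
}

#' Merge user-supplied values into a list of defaults, rejecting unknown keys
#' @noRd
merge_params <- function(defaults, user, what = "parameters") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    pe_stop("badarg", "unknown %s: %s", what, paste(unknown, collapse = ", "))
  defaults[names(user)] <- user
  defaults
}
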