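# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#' @noRd
nt_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "neurotraj_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Validate a probability (scalar or vector)
#' @noRd
check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    nt_stop(sprintf("`%s` must be probabilities in [0, 1]", name),
            "neurotraj_config_error")
  }
  invisible(x)
}

# Split a semicolon-joined field into a character set (empty string -> empty).
split_set <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1]]
}

join_set <- function(x) paste(x, collapse = ";")

# Deterministic local RNG: evaluate `expr` under `seed` without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
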