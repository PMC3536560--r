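logit <- function(p) log(p / (1 - p))

invlogit <- function(x) 1 / (1 + exp(-x))

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 &&
    abs(x - round(x)) < 1e-8
}

is_probability <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

match_target <- function(target) {
  target <- toupper(as.character(target)[1L])
  if (!target %in% c("PPV", "NPV")) {
    stop_validation("`target` must be \"PPV\" or \"NPV\"")
  }
  target
}

# Restore the caller's RNG state after seeded work so that library use does
# not silently advance or reset the session RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
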