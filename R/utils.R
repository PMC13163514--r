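# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so simulators never perturb user randomness.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
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
  }
  force(code)
}

# Deterministic per-stage sub-seed derived from one master seed.  Keeps every
# stochastic stage on its own stream while a single integer controls the run.
.derive_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483587L)
}

.assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
    stop(sprintf("`%s` must be a positive integer (got %s)", name,
                 paste(format(x), collapse = ",")), call. = FALSE)
  }
  invisible(as.integer(x))
}

.assert_fraction <- function(x, name, upper_open = TRUE) {
  ok <- is.numeric(x) && all(!is.na(x)) && all(x >= 0) &&
    if (upper_open) all(x < 1) else all(x <= 1)
  if (!ok) {
    stop(sprintf("`%s` must lie in [0,1%s)", name, if (upper_open) "" else "]"),
         call. = FALSE)
  }
  invisible(x)
}

# Most frequent value; ties broken towards the smallest dosage so imputation
# is deterministic.
.dosage_mode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  tab <- tabulate(x + 1L, nbins = 3L)
  which.max(tab) - 1
}
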