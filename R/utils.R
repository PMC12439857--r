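# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("co2gap_config_error", "error")))
}

stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("co2gap_schema_error", "error")))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_pair <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x))) {
    stop_config("`", name, "` must be a numeric pair c(min, max)")
  }
  if (x[1] > x[2]) stop_config("`", name, "`: min exceeds max (", x[1], " > ", x[2], ")")
  if (x[1] < lo || x[2] > hi) {
    stop_config("`", name, "` must lie within [", lo, ", ", hi, "]")
  }
  as.numeric(x)
}

runif_pair <- function(n, pair) stats::runif(n, pair[1], pair[2])

# sample one element from a set (safe for length-1 sets, unlike sample())
sample1 <- function(x) x[sample.int(length(x), 1L)]

# derive a stage seed from the global seed; keeps all streams tied to one seed
# while letting stages be re-run independently (values stay below 2^31)
derive_seed <- function(seed, stage) {
  offsets <- c(generator = 101L, folds = 211L, search = 307L, attribution = 401L,
               report = 503L)
  if (!stage %in% names(offsets)) stop_config("unknown seed stage: ", stage)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}
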