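# Internal helpers shared across modules.

# Positive scalar check with a readable error
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integerish = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name))
  if (strict_lower && x <= lower)
    abort(sprintf("`%s` must be > %s", name, lower))
  if (!strict_lower && x < lower)
    abort(sprintf("`%s` must be >= %s", name, lower))
  if (x > upper)
    abort(sprintf("`%s` must be <= %s", name, upper))
  if (integerish && x != round(x))
    abort(sprintf("`%s` must be a whole number", name))
  invisible(x)
}

# Derive a stage-specific seed from a global seed so that stages draw
# independent streams while staying reproducible. Kept below 2^31.
derive_seed <- function(seed, stage) {
  h <- rlang::hash(list(as.integer(seed), as.character(stage)))
  # fold the first 7 hex digits of the hash into a positive 32-bit integer
  as.integer(strtoi(substr(h, 1, 7), base = 16L) %% 2147483587L) + 1L
}

# Evaluate `expr` under a local RNG seed without touching the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Run manifest written next to every pipeline output
run_manifest <- function(stage, config, seed, counts = list()) {
  list(
    stage = stage,
    config_hash = rlang::hash(config),
    seed = seed,
    package = "rpekit",
    version = as.character(utils::packageVersion("rpekit")),
    counts = counts
  )
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
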