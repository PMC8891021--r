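# Internal helpers shared across modules.

# Classed errors so callers (and the pipeline) can distinguish configuration,
# data and numerical failures.
.tc_error <- function(class, msg) {
  stop(structure(
    class = c(class, "twincyto_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
.config_error <- function(msg) .tc_error("twincyto_config_error", msg)
.data_error <- function(msg) .tc_error("twincyto_data_error", msg)
.numeric_error <- function(msg) .tc_error("twincyto_numeric_error", msg)

# Derive a deterministic sub-seed for a named random substream, so that draws
# for e.g. batch factors are unaffected by how many cells are generated.
# Always < 2^31.
.substream <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 65521L
  s <- abs(as.integer(seed)) %% 1000003L
  as.integer((s * 2039 + h * 7919 + 17) %% 2147483647)
}

# Evaluate `code` under `set.seed(seed)` without disturbing the caller's RNG
# state.
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Type-7 (linear interpolation) percentile, the convention used throughout.
.pctl <- function(x, q) as.numeric(quantile(x, probs = q / 100, type = 7, names = FALSE))

.is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)

.assert_markers <- function(x, markers) {
  miss <- setdiff(markers, colnames(x))
  if (length(miss)) {
    .data_error(paste0("markers missing from matrix: ", paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}
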