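# Shared helpers: scale transforms, classed errors, seeded evaluation.

#' Logit2 / inverse-logit2 (M-value) transforms
#'
#' `logit2(p)` is `log2(p / (1 - p))`; `ilogit2(m)` inverts it. The M-value
#' scale is the variance-stabilized scale on which per-probe regression is
#' performed.
#'
#' @param p methylation fraction in (0, 1)
#' @param m M-value (any real)
#' @return numeric vector
#' @export
logit2 <- function(p) log2(p / (1 - p))

#' @rdname logit2
#' @export
ilogit2 <- function(m) 1 / (1 + 2^(-m))

# Condition constructors. Three families are distinguished so callers and
# tests can react to bad configuration vs bad data vs broken pipeline state.
stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("stressmeth_config_error", "stressmeth_error")))
}

stop_value <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("stressmeth_value_error", "stressmeth_error")))
}

stop_pipeline <- function(fmt, ..., data = NULL) {
  cond <- errorCondition(sprintf(fmt, ...),
                         class = c("stressmeth_pipeline_error", "stressmeth_error"))
  cond$data <- data
  stop(cond)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed)) {
    stop_config("seed must be a single integer, got %s", deparse(seed))
  }
  withr::with_seed(as.integer(seed), code)
}

# Derive a stage seed from a master seed, kept within 32-bit integer range.
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, preprocess = 211L, dml = 307L, enrich = 401L,
               expression = 503L, integrate = 601L, motif = 701L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483647)
}

# Reverse complement of plain character DNA (vectorized).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Merge user options over defaults, rejecting unknown names.
merge_config <- function(defaults, user, what) {
  if (is.null(user)) return(defaults)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) {
    stop_config("unknown %s option(s): %s", what, paste(bad, collapse = ", "))
  }
  defaults[names(user)] <- user
  defaults
}
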