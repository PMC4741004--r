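#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef lm runif rnorm setNames var
#' @importFrom utils read.csv write.csv head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib genotax, .registration = TRUE
NULL

# Logging goes to stderr so that stdout stays clean for results.
.log_level <- function() {
  lv <- Sys.getenv("GENOTAX_LOGLEVEL", "info")
  match(lv, c("debug", "info", "warn", "error"), nomatch = 2L)
}

gx_log <- function(level = "info", ...) {
  levels <- c("debug", "info", "warn", "error")
  if (match(level, levels, nomatch = 2L) >= .log_level()) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
  invisible(NULL)
}

# All randomized operations take an explicit seed and restore the caller's
# RNG state on exit; no function relies on global random state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
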