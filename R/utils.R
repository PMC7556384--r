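# internal plumbing: classed errors, seed management, logging

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ensembin_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so library functions do not
#' perturb the caller's random stream. A `NULL` seed evaluates the expression
#' against the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministically derive a sub-seed from a master seed, so that per-bin and
# per-component random streams are independent of one another: adding a bin or
# a grid cell never perturbs the randomness used elsewhere. Kept below 2^31.
spawn_seed <- function(seed, role, index = 0L) {
  codes <- c(disc = 1, reg = 2, clf = 3, res = 4, test = 5, cell = 6, sim = 7)
  if (!role %in% names(codes)) abort(paste0("unknown seed role: ", role),
                                     "ensembin_internal_error")
  m <- 2147483647  # 2^31 - 1
  s <- (abs(as.numeric(seed)) %% m)
  s <- (s * 48271 + codes[[role]] * 16807 + (as.numeric(index) %% m) * 69621) %% m
  as.integer(s + 1)
}

# stable non-negative integer hash of a string (target names -> sub-seeds)
string_hash <- function(x) {
  v <- utf8ToInt(x)
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

## logging ------------------------------------------------------------------

log_levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

log_threshold <- function() {
  lvl <- getOption("ensembin.log_level", "warn")
  if (!lvl %in% names(log_levels)) lvl <- "warn"
  log_levels[[lvl]]
}

log_msg <- function(level, fmt, ...) {
  if (log_levels[[level]] >= log_threshold()) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

## input validation ---------------------------------------------------------

check_response <- function(y) {
  if (!is.numeric(y) || length(y) < 1L) {
    abort("response must be a non-empty numeric vector", "ensembin_input_error")
  }
  if (anyNA(y)) abort("response contains missing values", "ensembin_input_error")
  invisible(y)
}

check_bin_count <- function(c, n) {
  if (length(c) != 1L || is.na(c) || c != round(c) || c < 1L) {
    abort("bin count c must be a single integer >= 1", "ensembin_invalid_bins")
  }
  if (c > n) {
    abort(sprintf("bin count c = %d exceeds the number of samples (%d)", c, n),
          "ensembin_invalid_bins")
  }
  invisible(as.integer(c))
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  if (!is.numeric(x)) abort("features must be numeric", "ensembin_input_error")
  x
}
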