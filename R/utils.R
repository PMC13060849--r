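# internal helpers shared across modules

#' @importFrom methods new validObject is slot
#' @importFrom stats median p.adjust phyper pt cor cor.test rnorm runif rbinom
#'   setNames complete.cases ks.test quantile coef resid
#' @importFrom utils read.delim write.table read.csv write.csv head
NULL

# case-normalized gene/protein identifier (gene-symbol convention)
.normId <- function(x) toupper(trimws(as.character(x)))

.stopParam <- function(field, msg) {
  stop(structure(
    class = c("surfkit_parameter_error", "error", "condition"),
    list(message = sprintf("invalid parameter '%s': %s", field, msg),
         call = sys.call(-1))
  ))
}

.stopData <- function(msg) {
  stop(structure(
    class = c("surfkit_data_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

.checkFraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    .stopParam(field, "must be a single value in [0, 1]")
  invisible(x)
}

.checkPositive <- function(x, field, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) .stopParam(field, if (strict) "must be > 0" else "must be >= 0")
  invisible(x)
}

.checkCount <- function(x, field, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x == round(x) && x >= min
  if (!ok) .stopParam(field, sprintf("must be an integer >= %d", min))
  invisible(as.integer(x))
}

# Deterministic per-operation seed stream: one global seed governs a sequence
# of sub-seeds so individual generator calls are independently reproducible.
# Kept below 2^31 - 1 (R integers are 32-bit).
.subSeed <- function(seed, op) {
  off <- sum(utf8ToInt(op)) %% 1000L
  as.integer((as.double(seed) * 7919 + off * 104729 + 17) %% 2147483647)
}

# median of present (non-missing) values; NA when none present
.presentMedian <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  median(x)
}
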