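# Internal helpers: logging, C-locale string ordering, pair normalization.

.LOG_LEVELS <- c(quiet = 0L, warning = 1L, info = 2L, debug = 3L)

#' Set or query the package log level
#'
#' Structured log lines are written to standard error. Levels, from least to
#' most verbose: \code{"quiet"}, \code{"warning"} (default), \code{"info"},
#' \code{"debug"}. Network construction logs path count, node count and stop
#' reason at \code{"info"}.
#'
#' @param level New level, or \code{NULL} to query.
#' @return The current level, invisibly when setting.
#' @export
evinetLogLevel <- function(level = NULL) {
    if (is.null(level))
        return(getOption("evinet.log_level", "warning"))
    level <- match.arg(level, names(.LOG_LEVELS))
    options(evinet.log_level = level)
    invisible(level)
}

.log <- function(level, fmt, ...) {
    current <- .LOG_LEVELS[[getOption("evinet.log_level", "warning")]]
    if (.LOG_LEVELS[[level]] <= current)
        message(sprintf("[evinet] %s %s", toupper(level), sprintf(fmt, ...)))
    invisible(NULL)
}

# C-locale (byte-order) sort, independent of the session locale.
.radixSort <- function(x) sort(x, method = "radix")

# Order-normalize an undirected pair of id vectors so that u <= v in
# C-locale order. Returns list(u, v, swapped).
.normalizePairs <- function(u, v) {
    lv <- .radixSort(unique(c(u, v)))
    ui <- match(u, lv)
    vi <- match(v, lv)
    swap <- ui > vi
    list(u = ifelse(swap, v, u), v = ifelse(swap, u, v), swapped = swap)
}

# Canonical undirected edge key.
.edgeKey <- function(u, v) {
    p <- .normalizePairs(u, v)
    paste(p$u, p$v, sep = "\t")
}

.isCount <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x >= 1 && x == floor(x)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
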