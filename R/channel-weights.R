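.WEIGHT_PRESETS <- c(NONE = 0, LOW = 0.5, DEFAULT = 1)

#' Construct channel weights
#'
#' Each evidence channel gets a multiplier in [0,1]; channels not named
#' default to 1. Multipliers may be given numerically or as the portal-style
#' presets \code{"NONE"} (0), \code{"LOW"} (0.5), \code{"DEFAULT"} (1).
#'
#' With all multipliers at 1 the reported combined score of each edge is used
#' as-is, preserving the database's own score semantics (which include a
#' prior correction that per-channel recombination cannot reproduce). As
#' soon as any multiplier differs from 1, effective scores switch to the
#' noisy-OR recombination \eqn{S = 1 - \prod_c (1 - m_c s_c)} over the
#' channels present on the edge. The two regimes differ even at multipliers
#' close to 1; see the package vignette.
#'
#' @param ... Named multipliers, e.g. \code{textmining = 0} or
#'   \code{database = "LOW"}.
#' @return A \linkS4class{ChannelWeights} object.
#' @examples
#' channelWeights()                      # defaults: combined score pass-through
#' channelWeights(textmining = "NONE")   # silence text mining
#' @export
channelWeights <- function(...) {
    args <- list(...)
    m <- stats::setNames(rep(1, length(EV_CHANNELS)), EV_CHANNELS)
    if (length(args)) {
        if (is.null(names(args)) || any(!nzchar(names(args))))
            .stopf("channel weights must be named")
        bad <- setdiff(names(args), EV_CHANNELS)
        if (length(bad))
            .stopf("unknown channel(s): %s", paste(bad, collapse = ", "))
        for (ch in names(args)) {
            val <- args[[ch]]
            if (is.character(val)) {
                if (!val %in% names(.WEIGHT_PRESETS))
                    .stopf("unknown preset '%s' (use NONE, LOW or DEFAULT)",
                           val)
                val <- .WEIGHT_PRESETS[[val]]
            }
            if (!is.numeric(val) || length(val) != 1L || is.na(val) ||
                val < 0 || val > 1)
                .stopf("multiplier for '%s' must be a number in [0,1]", ch)
            m[[ch]] <- val
        }
    }
    new("ChannelWeights", multipliers = m)
}

#' @rdname channelWeights
#' @param x A \linkS4class{ChannelWeights} object.
#' @export
multipliers <- function(x) x@multipliers

setMethod("show", "ChannelWeights", function(object) {
    m <- object@multipliers
    tweaked <- m[m != 1]
    if (!length(tweaked)) {
        cat("ChannelWeights: all channels at 1 (combined-score pass-through)\n")
    } else {
        cat("ChannelWeights (noisy-OR recombination):\n")
        for (ch in names(tweaked))
            cat(sprintf("  %s = %g\n", ch, tweaked[[ch]]))
    }
    invisible(NULL)
})

.isDefaultWeights <- function(weights) all(weights@multipliers == 1)

#' Effective evidence score of edges under channel weights
#'
#' With default weights the reported combined score is passed through
#' unchanged; otherwise the score is recombined as
#' \eqn{S = 1 - \prod_c (1 - m_c s_c)} over the channels present (score > 0)
#' on each edge.
#'
#' @param edge One or more edge rows as stored in \code{edges(graph)}.
#' @param weights A \linkS4class{ChannelWeights} object.
#' @return Numeric vector of effective scores in [0,1].
#' @examples
#' g <- toy1()
#' effectiveScore(edges(g), channelWeights())              # combined scores
#' effectiveScore(edges(g), channelWeights(experimental = 0))  # all silenced
#' @export
effectiveScore <- function(edge, weights = channelWeights()) {
    stopifnot(is(weights, "ChannelWeights"))
    if (.isDefaultWeights(weights))
        return(edge$combined)
    s <- as.matrix(edge[, EV_CHANNELS, drop = FALSE])
    m <- weights@multipliers[EV_CHANNELS]
    scaled <- sweep(s, 2L, m, `*`)
    # channels with score 0 contribute a factor of 1 either way
    1 - apply(1 - scaled, 1L, prod)
}

#' Edge weight from an effective score
#'
#' The path-search weight is \eqn{w = 1 - S}, so strongly evidenced edges
#' (high S) are preferred by shortest-path search.
#'
#' @param S Numeric scores in [0,1].
#' @return \code{1 - S}.
#' @examples
#' edgeWeight(c(0, 0.7, 1))
#' @export
edgeWeight <- function(S) {
    if (any(is.na(S)) || any(S < 0) || any(S > 1))
        .stopf("scores must lie in [0,1]")
    1 - S
}
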