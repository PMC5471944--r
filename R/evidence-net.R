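# Evidence-network assembly: iterative shortest-path accumulation with the
# distinct-node stopping rule, pair classification, and incremental
# "Next Shortest" exploration.

.PAIR_CATEGORIES <- c("direct", "1", "2", "3", "unreachable", "not_in_db")

.pathEdgeDf <- function(paths) {
    if (!length(paths))
        return(data.frame(u = character(), v = character(), score = numeric(),
                          stringsAsFactors = FALSE))
    us <- character(); vs <- character(); sc <- numeric()
    for (p in paths) {
        nn <- p@nodes
        if (length(nn) < 2L) next
        us <- c(us, nn[-length(nn)])
        vs <- c(vs, nn[-1L])
        sc <- c(sc, p@edgeScores)
    }
    pr <- .normalizePairs(us, vs)
    df <- data.frame(u = pr$u, v = pr$v, score = sc, stringsAsFactors = FALSE)
    df <- df[!duplicated(paste(df$u, df$v, sep = "\t")), , drop = FALSE]
    df <- df[order(df$u, df$v, method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
    df
}

.defaultRoles <- function(nodes, sources, target, isolated) {
    roles <- stats::setNames(rep("intermediate", length(nodes)), nodes)
    roles[isolated] <- "isolated"
    roles[sources] <- "source"
    roles[target] <- "target"
    roles
}

.newNetwork <- function(sources, target, paths, nodes, edges, isolated,
                        roles = NULL, annotations = NULL, stopReason) {
    nodes <- .radixSort(unique(nodes))
    if (is.null(roles))
        roles <- .defaultRoles(nodes, sources, target, isolated)
    if (is.null(annotations))
        annotations <- new("AnnotationTable")@entries
    net <- new("EvidenceNetwork", sources = .radixSort(unique(sources)),
               target = target, paths = paths, nodes = nodes, edges = edges,
               isolatedNodes = .radixSort(unique(isolated)),
               nodeRoles = roles[nodes], annotations = annotations,
               stopReason = stopReason)
    validObject(net)
    .log("info", "network %s -> %s: %d path(s), %d node(s), stop=%s",
         paste(net@sources, collapse = "+"), target, length(paths),
         length(nodes), stopReason)
    net
}

#' Build the evidence network for a drug-mediator pair
#'
#' Shortest paths from drug to mediator are found and merged iteratively
#' until no further path exists or the sub-network holds at least \code{N}
#' distinct nodes. \code{N} is a stopping condition, not a strict floor: the
#' last accepted path may push the node count past \code{N}. Paths with more
#' than \code{maxIntermediates} genes between the endpoints are never
#' considered.
#'
#' @param graph An \linkS4class{EvidenceGraph}.
#' @param drug Chemical node id (path source).
#' @param mediator Protein node id (path target).
#' @param N Distinct-node stopping threshold (default 10, chosen to keep
#'   networks interpretable).
#' @param maxIntermediates Cap on intermediate genes per path (default 3).
#' @param weights \linkS4class{ChannelWeights} used for edge scoring.
#' @param annotations Optional \linkS4class{AnnotationTable}; matching edge
#'   descriptions are attached to the result.
#' @return An \linkS4class{EvidenceNetwork}. A pair with no qualifying path
#'   yields an empty-path network (drug and mediator retained as isolated
#'   nodes), not an error.
#' @examples
#' net <- buildEvidenceNetwork(toy1(), "D", "M", N = 4)
#' sort(net@nodes)  # A B D M
#' @export
buildEvidenceNetwork <- function(graph, drug, mediator, N = 10,
                                 maxIntermediates = 3,
                                 weights = channelWeights(),
                                 annotations = NULL) {
    .assertNode(graph, drug, "drug node")
    .assertNode(graph, mediator, "mediator node")
    if (.nodeKind(graph, drug) != "chemical")
        .stopf("drug '%s' is not a chemical node", drug)
    if (.nodeKind(graph, mediator) != "protein")
        .stopf("mediator '%s' is not a protein node", mediator)
    if (!.isCount(N)) .stopf("N must be a positive integer")
    ctx <- .pathContext(graph, weights)
    st <- .yenInit(ctx, match(drug, ctx$ids), match(mediator, ctx$ids),
                   maxIntermediates + 1)
    paths <- list()
    seenNodes <- character()
    stopReason <- "exhausted"
    repeat {
        if (length(seenNodes) >= N) {
            stopReason <- "n_reached"
            break
        }
        p <- .yenNext(st)
        if (is.null(p)) break
        wp <- .wrapPath(ctx, p)
        paths[[length(paths) + 1L]] <- wp
        seenNodes <- unique(c(seenNodes, wp@nodes))
    }
    if (!length(paths)) stopReason <- "no_path"
    edgeDf <- .pathEdgeDf(paths)
    iso <- setdiff(c(drug, mediator), c(edgeDf$u, edgeDf$v))
    .newNetwork(sources = drug, target = mediator, paths = paths,
                nodes = c(seenNodes, drug, mediator), edges = edgeDf,
                isolated = iso,
                annotations = .annotationsForEdges(annotations, edgeDf),
                stopReason = stopReason)
}

#' Number of intermediate genes on a path
#'
#' Nodes strictly between the endpoints; the quantity drug-mediator pairs are
#' classified by.
#'
#' @param path A \linkS4class{WeightedPath} with at least one edge.
#' @return Nonnegative integer.
#' @examples
#' intermediateCount(shortestPath(toy1(), "D", "M"))  # 1
#' @export
intermediateCount <- function(path) {
    stopifnot(is(path, "WeightedPath"))
    if (length(path@nodes) < 2L)
        .stopf("path must have at least one edge")
    length(path@nodes) - 2L
}

#' Classify a drug-mediator pair by evidence distance
#'
#' Categories: \code{not_in_db} (either endpoint missing from the graph),
#' \code{direct} (a drug-mediator edge exists, even when a multi-hop path is
#' lighter), \code{1}/\code{2}/\code{3} (intermediate-gene count of the
#' weight-shortest path), and \code{unreachable} (no path, or only paths with
#' more than three intermediates — pairs that far apart are considered
#' unrelated).
#'
#' @inheritParams buildEvidenceNetwork
#' @return Factor of length 1 with levels \code{direct, 1, 2, 3,
#'   unreachable, not_in_db}.
#' @examples
#' classifyPair(toy1(), "D", "M")  # direct: the D-M edge exists
#' @export
classifyPair <- function(graph, drug, mediator, weights = channelWeights()) {
    cat0 <- function(x) factor(x, levels = .PAIR_CATEGORIES)
    if (!.hasNode(graph, drug) || !.hasNode(graph, mediator))
        return(cat0("not_in_db"))
    if (hasEdge(graph, drug, mediator))
        return(cat0("direct"))
    sp <- shortestPath(graph, drug, mediator, weights)
    if (is.null(sp))
        return(cat0("unreachable"))
    ic <- intermediateCount(sp)
    if (ic >= 1L && ic <= 3L) cat0(as.character(ic)) else cat0("unreachable")
}

#' Classify many drug-mediator pairs
#'
#' @param graph An \linkS4class{EvidenceGraph}.
#' @param pairs data.frame with columns \code{drug_id}, \code{mediator_id}.
#' @param weights \linkS4class{ChannelWeights}.
#' @return \code{pairs} with a \code{category} factor column appended.
#' @export
classifyPairs <- function(graph, pairs, weights = channelWeights()) {
    stopifnot(all(c("drug_id", "mediator_id") %in% names(pairs)))
    pairs$category <- factor(vapply(seq_len(nrow(pairs)), function(i)
        as.character(classifyPair(graph, pairs$drug_id[i],
                                  pairs$mediator_id[i], weights)),
        character(1L)), levels = .PAIR_CATEGORIES)
    pairs
}

#' Incremental path exploration ("Next Shortest")
#'
#' \code{pathSession} initializes a K-shortest-paths enumeration for one
#' query; each \code{nextShortest} call returns the next-ranked path, or
#' \code{NULL} once the supply is exhausted. Re-initialize with different
#' \code{weights} to re-rank paths under new channel preferences.
#'
#' @inheritParams buildEvidenceNetwork
#' @param maxIntermediates Hop cap as in \code{\link{kShortestPaths}};
#'   default unlimited.
#' @return \code{pathSession}: a \linkS4class{PathSession};
#'   \code{nextShortest}: a \linkS4class{WeightedPath} or \code{NULL}.
#' @examples
#' s <- pathSession(toy1(), "D", "M")
#' pathNodes(nextShortest(s))  # "D" "A" "M"
#' pathNodes(nextShortest(s))  # "D" "B" "M"
#' @name nextShortest
#' @export
pathSession <- function(graph, drug, mediator, weights = channelWeights(),
                        maxIntermediates = Inf) {
    .assertNode(graph, drug, "drug node")
    .assertNode(graph, mediator, "mediator node")
    ctx <- .pathContext(graph, weights)
    st <- .yenInit(ctx, match(drug, ctx$ids), match(mediator, ctx$ids),
                   maxIntermediates + 1)
    st$wrapCtx <- ctx
    new("PathSession", drug = drug, mediator = mediator, state = st)
}

#' @rdname nextShortest
#' @param session A \linkS4class{PathSession}.
#' @export
setMethod("nextShortest", "PathSession", function(session) {
    st <- session@state
    p <- .yenNext(st)
    if (is.null(p)) return(NULL)
    .wrapPath(st$wrapCtx, p)
})

#' Accessors for EvidenceNetwork
#'
#' @param x An \linkS4class{EvidenceNetwork}.
#' @name EvidenceNetwork-accessors
NULL

#' @rdname EvidenceNetwork-accessors
#' @export
setMethod("networkPaths", "EvidenceNetwork", function(x) x@paths)

#' @rdname EvidenceNetwork-accessors
#' @export
setMethod("nodes", "EvidenceNetwork", function(x, ...) x@nodes)

#' @rdname EvidenceNetwork-accessors
#' @export
setMethod("edges", "EvidenceNetwork", function(x, ...) x@edges)

#' @rdname EvidenceNetwork-accessors
#' @export
setMethod("isolatedNodes", "EvidenceNetwork", function(x) x@isolatedNodes)

#' @rdname EvidenceNetwork-accessors
#' @export
setMethod("nodeRoles", "EvidenceNetwork", function(x) x@nodeRoles)

#' @rdname EvidenceNetwork-accessors
#' @export
setMethod("stopReason", "EvidenceNetwork", function(x) x@stopReason)

setMethod("show", "EvidenceNetwork", function(object) {
    cat(sprintf("EvidenceNetwork: %s -> %s\n",
                paste(object@sources, collapse = ", "), object@target))
    cat(sprintf("  %d path(s), %d node(s), %d edge(s); stop: %s\n",
                length(object@paths), length(object@nodes),
                nrow(object@edges), object@stopReason))
    if (length(object@isolatedNodes))
        cat(sprintf("  isolated: %s\n",
                    paste(object@isolatedNodes, collapse = ", ")))
    invisible(NULL)
})
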