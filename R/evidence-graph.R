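# EvidenceGraph construction and accessors.

.emptyEdges <- function() {
    df <- data.frame(u = character(), v = character(),
                     stringsAsFactors = FALSE)
    for (ch in EV_CHANNELS) df[[ch]] <- numeric()
    df$combined <- numeric()
    df
}

.emptyAliases <- function()
    data.frame(node_id = character(), alias_type = character(),
               alias_value = character(), stringsAsFactors = FALSE)

# Fill missing channel columns with 0, order-normalize pairs, drop self-loops
# (logged), sort rows canonically.
.canonEdges <- function(edges) {
    if (is.null(edges) || !nrow(edges)) return(.emptyEdges())
    loops <- edges$u == edges$v
    if (any(loops)) {
        .log("warning", "dropping %d self-loop edge(s)", sum(loops))
        edges <- edges[!loops, , drop = FALSE]
    }
    if (!nrow(edges)) return(.emptyEdges())
    p <- .normalizePairs(edges$u, edges$v)
    edges$u <- p$u
    edges$v <- p$v
    for (ch in EV_CHANNELS) if (is.null(edges[[ch]])) edges[[ch]] <- 0
    if (is.null(edges$combined)) edges$combined <- 0
    edges <- edges[, c("u", "v", EV_CHANNELS, "combined")]
    o <- order(edges$u, edges$v, method = "radix")
    edges <- edges[o, , drop = FALSE]
    rownames(edges) <- NULL
    edges
}

.canonNodes <- function(nodes) {
    if (is.null(nodes) || !nrow(nodes))
        return(data.frame(id = character(), kind = character(),
                          stringsAsFactors = FALSE))
    nodes <- unique(nodes[, c("id", "kind")])
    o <- order(nodes$id, method = "radix")
    nodes <- nodes[o, , drop = FALSE]
    rownames(nodes) <- NULL
    nodes
}

#' Construct an EvidenceGraph
#'
#' Low-level constructor; most users will obtain graphs from
#' \code{\link{parseProteinLinks}}, \code{\link{parseChemicalLinks}},
#' \code{\link{readEvidenceGraph}} or \code{\link{toy1}}. Edge rows are
#' order-normalized and self-loops dropped with a logged warning.
#'
#' @param nodes data.frame with columns \code{id}, \code{kind}
#'   (\code{"protein"} or \code{"chemical"}).
#' @param edges data.frame with columns \code{u}, \code{v}, any subset of
#'   \code{\link{evidenceChannels}} and \code{combined}; missing score
#'   columns are filled with 0.
#' @param aliases Optional data.frame (\code{node_id}, \code{alias_type},
#'   \code{alias_value}).
#' @return An \linkS4class{EvidenceGraph}.
#' @examples
#' g <- evidenceGraph(
#'     nodes = data.frame(id = c("9606.A", "9606.B"), kind = "protein"),
#'     edges = data.frame(u = "9606.A", v = "9606.B",
#'                        experimental = 0.7, combined = 0.7))
#' numEdges(g)
#' @export
evidenceGraph <- function(nodes, edges = NULL, aliases = NULL) {
    g <- new("EvidenceGraph",
             nodes = .canonNodes(nodes),
             edges = .canonEdges(edges),
             aliases = if (is.null(aliases)) .emptyAliases() else
                 aliases[, c("node_id", "alias_type", "alias_value")])
    validObject(g)
    g
}

#' Accessors for EvidenceGraph
#'
#' @param x An \linkS4class{EvidenceGraph}.
#' @param ... Unused.
#' @param value Replacement alias table.
#' @return \code{nodes}: data.frame of node ids and kinds; \code{edges}:
#'   the order-normalized edge table; \code{aliases}: the alias table;
#'   \code{chemicalNodes}/\code{proteinNodes}: character vectors of ids.
#' @name EvidenceGraph-accessors
#' @examples
#' g <- toy1()
#' numNodes(g)       # 6
#' chemicalNodes(g)  # "D" "E"
NULL

#' @rdname EvidenceGraph-accessors
#' @export
setMethod("nodes", "EvidenceGraph", function(x, ...) x@nodes)

#' @rdname EvidenceGraph-accessors
#' @export
setMethod("edges", "EvidenceGraph", function(x, ...) x@edges)

#' @rdname EvidenceGraph-accessors
#' @export
setMethod("aliases", "EvidenceGraph", function(x) x@aliases)

#' @rdname EvidenceGraph-accessors
#' @export
setReplaceMethod("aliases", "EvidenceGraph", function(x, value) {
    stopifnot(all(c("node_id", "alias_type", "alias_value") %in% names(value)))
    x@aliases <- value[, c("node_id", "alias_type", "alias_value")]
    validObject(x)
    x
})

#' @rdname EvidenceGraph-accessors
#' @export
setMethod("numNodes", "EvidenceGraph", function(x) nrow(x@nodes))

#' @rdname EvidenceGraph-accessors
#' @export
setMethod("numEdges", "EvidenceGraph", function(x) nrow(x@edges))

#' @rdname EvidenceGraph-accessors
#' @export
setMethod("chemicalNodes", "EvidenceGraph",
    function(x) x@nodes$id[x@nodes$kind == "chemical"])

#' @rdname EvidenceGraph-accessors
#' @export
setMethod("proteinNodes", "EvidenceGraph",
    function(x) x@nodes$id[x@nodes$kind == "protein"])

#' Query a single undirected edge
#'
#' \code{hasEdge} tests adjacency; \code{getEdge} returns the edge row (or a
#' zero-row data.frame). Both are symmetric: \code{(u,v)} and \code{(v,u)}
#' refer to the same edge.
#'
#' @param x An \linkS4class{EvidenceGraph}.
#' @param u,v Node ids.
#' @name hasEdge
#' @examples
#' g <- toy1()
#' hasEdge(g, "M", "D")   # TRUE, order-insensitive
NULL

#' @rdname hasEdge
#' @export
setMethod("hasEdge", "EvidenceGraph", function(x, u, v) {
    key <- .edgeKey(u, v)
    key %in% paste(x@edges$u, x@edges$v, sep = "\t")
})

#' @rdname hasEdge
#' @export
setMethod("getEdge", "EvidenceGraph", function(x, u, v) {
    key <- .edgeKey(u, v)
    hit <- paste(x@edges$u, x@edges$v, sep = "\t") == key
    x@edges[hit, , drop = FALSE]
})

setMethod("show", "EvidenceGraph", function(object) {
    cat(sprintf("EvidenceGraph: %d nodes (%d chemical, %d protein), %d edges\n",
                numNodes(object), length(chemicalNodes(object)),
                length(proteinNodes(object)), numEdges(object)))
    if (nrow(object@aliases))
        cat(sprintf("  aliases: %d entries\n", nrow(object@aliases)))
    invisible(NULL)
})

# Membership / kind helpers used across modules.
.hasNode <- function(graph, id) id %in% graph@nodes$id

.nodeKind <- function(graph, id) {
    i <- match(id, graph@nodes$id)
    graph@nodes$kind[i]
}

.assertNode <- function(graph, id, what = "node") {
    if (length(id) != 1L || is.na(id) || !.hasNode(graph, id))
        .stopf("%s '%s' not found in graph", what, as.character(id)[1L])
    invisible(id)
}
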