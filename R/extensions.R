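# Evidence-network extensions: single-source (k closest drugs to a
# mediator), pathway-weighted (merging subnetworks for each DDN neighbor of
# the mediator with master-graph edge induction), and condition-specific
# networks (sensitive vs non-sensitive neighbor subsets).

#' Construct a DDN neighbor context
#'
#' Records a mediator's direct neighbors in the differential dependency
#' network, each labeled by the condition its edge is specific to:
#' \code{sensitive}, \code{non_sensitive}, or \code{shared} (present in both
#' condition-specific dependency networks).
#'
#' @param mediator Mediator node id.
#' @param neighbors Character vector of neighbor ids (gene/protein ids).
#' @param conditions Character vector (recycled if length 1) of condition
#'   labels.
#' @return A \linkS4class{DDNContext}.
#' @examples
#' ddnContext("M", c("A", "B"), c("sensitive", "shared"))
#' @export
ddnContext <- function(mediator, neighbors = character(),
                       conditions = character()) {
    if (length(conditions) == 1L && length(neighbors) > 1L)
        conditions <- rep(conditions, length(neighbors))
    stopifnot(length(neighbors) == length(conditions))
    ctx <- new("DDNContext", mediator = mediator,
               neighbors = data.frame(id = as.character(neighbors),
                                      condition = as.character(conditions),
                                      stringsAsFactors = FALSE))
    validObject(ctx)
    ctx
}

#' Read DDN neighbor contexts from a TSV file
#'
#' Columns: \code{mediator}, \code{neighbor}, \code{condition} (one of
#' \code{sensitive}, \code{non_sensitive}, \code{shared}).
#'
#' @param file Path or connection.
#' @return Named list of \linkS4class{DDNContext}, one per mediator.
#' @export
readDDNContexts <- function(file) {
    df <- utils::read.table(file, sep = "\t", header = TRUE,
                            colClasses = "character", quote = "")
    need <- c("mediator", "neighbor", "condition")
    if (!all(need %in% names(df)))
        .stopf("DDN file must have columns: %s", paste(need, collapse = ", "))
    out <- lapply(split(df, df$mediator), function(d)
        ddnContext(d$mediator[1L], d$neighbor, d$condition))
    out[.radixSort(names(out))]
}

# Map DDN neighbor ids onto graph nodes via the alias table (alias_type
# "name" or "cid"), falling back to direct id match. Unmapped ids are
# retained (flagged) so they can become isolated nodes.
.mapNeighborIds <- function(graph, ids) {
    if (!length(ids))
        return(data.frame(id = character(), node = character(),
                          mapped = logical(), stringsAsFactors = FALSE))
    al <- graph@aliases
    mapOne <- function(id) {
        if (.hasNode(graph, id)) return(id)
        hit <- al$node_id[al$alias_value == id]
        if (length(hit)) return(.radixSort(hit)[1L])
        NA_character_
    }
    node <- vapply(ids, mapOne, character(1L))
    unmapped <- ids[is.na(node)]
    if (length(unmapped))
        .log("warning", "DDN neighbor(s) not in graph, kept isolated: %s",
             paste(unmapped, collapse = ", "))
    data.frame(id = ids, node = ifelse(is.na(node), ids, node),
               mapped = !is.na(node), stringsAsFactors = FALSE)
}

#' Single-source evidence network: k closest drugs to a mediator
#'
#' Ranks all chemical nodes by shortest-path weight to the mediator (ties
#' broken by id), selects the \code{kDrugs} closest, builds an evidence
#' network from each to the mediator and merges them. Useful when the
#' original drug is absent from the database: networks seeded from the
#' mediator suggest substitute or combination compounds.
#'
#' @inheritParams buildEvidenceNetwork
#' @param mediator Protein node id (target of all paths).
#' @param kDrugs Number of closest chemicals to include.
#' @param maxIntermediates Per-path hop cap; default unlimited since closest
#'   drugs are ranked by weight, not hop count.
#' @return An \linkS4class{EvidenceNetwork} with the selected chemicals as
#'   sources. If no chemical can reach the mediator the result has no paths
#'   and no sources.
#' @examples
#' net <- singleSourceNetwork(toy1(), "M", kDrugs = 2)
#' net@sources  # "D" "E"
#' @export
singleSourceNetwork <- function(graph, mediator, kDrugs, N = 10,
                                weights = channelWeights(),
                                maxIntermediates = Inf,
                                annotations = NULL) {
    .assertNode(graph, mediator, "mediator node")
    if (!.isCount(kDrugs)) .stopf("kDrugs must be a positive integer")
    ctx <- .pathContext(graph, weights)
    dist <- .dijkstra(ctx, match(mediator, ctx$ids))
    chem <- chemicalNodes(graph)
    cd <- dist[match(chem, ctx$ids)]
    reach <- is.finite(cd)
    chem <- chem[reach]
    cd <- cd[reach]
    if (!length(chem)) {
        return(.newNetwork(sources = character(), target = mediator,
                           paths = list(), nodes = mediator,
                           edges = .pathEdgeDf(list()), isolated = mediator,
                           stopReason = "no_path"))
    }
    o <- order(cd, chem, method = "radix")
    sel <- chem[o][seq_len(min(kDrugs, length(chem)))]
    nets <- lapply(sel, function(d)
        buildEvidenceNetwork(graph, d, mediator, N = N,
                             maxIntermediates = maxIntermediates,
                             weights = weights))
    paths <- do.call(c, lapply(nets, networkPaths))
    edgeDf <- .pathEdgeDf(paths)
    nodesAll <- unique(c(unlist(lapply(nets, nodes)), mediator, sel))
    iso <- setdiff(nodesAll, c(edgeDf$u, edgeDf$v))
    .newNetwork(sources = sel, target = mediator, paths = paths,
                nodes = nodesAll, edges = edgeDf, isolated = iso,
                annotations = .annotationsForEdges(annotations, edgeDf),
                stopReason = if (length(paths)) "n_reached" else "no_path")
}

#' Pathway-weighted evidence network
#'
#' Preserves the pathway context of the mediator's differential dependency
#' network: an evidence subnetwork is built from the drug to the mediator and
#' to each DDN neighbor; the merged node set is the union of all subnetwork
#' nodes plus the mediator and every neighbor; finally, for every pair of
#' nodes in the merged set, the master graph is checked and the edge induced
#' if present. A neighbor with no path to the drug (or absent from the graph
#' entirely) is still included, recorded in \code{isolatedNodes}.
#'
#' @inheritParams buildEvidenceNetwork
#' @param ddn A \linkS4class{DDNContext} whose mediator is the target.
#' @param neighborRole Role recorded for connected DDN neighbors in
#'   \code{nodeRoles} (used by the condition-specific wrapper).
#' @return An \linkS4class{EvidenceNetwork} with master-graph-induced edges.
#' @examples
#' net <- pathwayWeightedNetwork(toy1(), "D",
#'                               ddnContext("M", "A", "shared"), N = 4)
#' @export
pathwayWeightedNetwork <- function(graph, drug, ddn, N = 10,
                                   maxIntermediates = 3,
                                   weights = channelWeights(),
                                   annotations = NULL,
                                   neighborRole = "intermediate") {
    stopifnot(is(ddn, "DDNContext"))
    .assertNode(graph, drug, "drug node")
    mediator <- ddn@mediator
    .assertNode(graph, mediator, "mediator node")
    nb <- .mapNeighborIds(graph, ddn@neighbors$id)
    targets <- unique(c(mediator, nb$node[nb$mapped]))
    nets <- lapply(targets, function(tg)
        buildEvidenceNetwork(graph, drug, tg, N = N,
                             maxIntermediates = maxIntermediates,
                             weights = weights))
    names(nets) <- targets
    paths <- do.call(c, lapply(nets, networkPaths))
    connected <- unique(unlist(lapply(nets, function(nt)
        unique(unlist(lapply(networkPaths(nt), pathNodes))))))
    # merged set: all distinct subnetwork nodes + the mediator + all neighbors
    nodesAll <- unique(c(connected, mediator, drug, nb$node))
    # induce every master-graph edge among the merged node set
    inGraph <- nodesAll[nodesAll %in% graph@nodes$id]
    e <- graph@edges
    keep <- e$u %in% inGraph & e$v %in% inGraph
    ind <- e[keep, , drop = FALSE]
    edgeDf <- data.frame(u = ind$u, v = ind$v,
                         score = effectiveScore(ind, weights),
                         stringsAsFactors = FALSE)
    edgeDf <- edgeDf[order(edgeDf$u, edgeDf$v, method = "radix"), ,
                     drop = FALSE]
    rownames(edgeDf) <- NULL
    # neighbors that contributed no path stay as (possibly) isolated nodes
    iso <- setdiff(nodesAll, c(connected, drug, mediator))
    roles <- .defaultRoles(nodesAll, drug, mediator, iso)
    connectedNb <- intersect(nb$node, connected)
    roles[connectedNb] <- neighborRole
    .newNetwork(sources = drug, target = mediator, paths = paths,
                nodes = nodesAll, edges = edgeDf, isolated = iso,
                roles = roles,
                annotations = .annotationsForEdges(annotations, edgeDf),
                stopReason = if (length(paths)) "n_reached" else "no_path")
}

#' Condition-specific evidence networks
#'
#' Builds two pathway-weighted networks for one drug-mediator pair: the
#' sensitive network uses DDN neighbors whose edges are specific to the
#' sensitive condition (plus shared neighbors unless
#' \code{specificOnly = TRUE}), the non-sensitive network analogously. Each
#' network's \code{nodeRoles} marks its condition-specific neighbors as
#' \code{neighbor-sensitive} / \code{neighbor-non-sensitive}.
#'
#' @inheritParams pathwayWeightedNetwork
#' @param specificOnly Drop shared neighbors from both networks (mirrors
#'   figures that display only condition-specific edges).
#' @return Named list with elements \code{sensitive} and
#'   \code{non_sensitive}, each an \linkS4class{EvidenceNetwork}.
#' @examples
#' ddn <- ddnContext("M", c("A", "B"), c("sensitive", "non_sensitive"))
#' nets <- conditionSpecificNetworks(toy1(), "D", ddn, N = 4)
#' names(nets)
#' @export
conditionSpecificNetworks <- function(graph, drug, ddn, N = 10,
                                      maxIntermediates = 3,
                                      weights = channelWeights(),
                                      annotations = NULL,
                                      specificOnly = FALSE) {
    stopifnot(is(ddn, "DDNContext"))
    pick <- function(cond) {
        keep <- ddn@neighbors$condition %in%
            c(cond, if (!specificOnly) "shared")
        ddnContext(ddn@mediator, ddn@neighbors$id[keep],
                   ddn@neighbors$condition[keep])
    }
    buildSide <- function(cond, role) {
        sub <- pick(cond)
        net <- pathwayWeightedNetwork(graph, drug, sub, N = N,
                                      maxIntermediates = maxIntermediates,
                                      weights = weights,
                                      annotations = annotations)
        specific <- sub@neighbors$id[sub@neighbors$condition == cond]
        nbMap <- .mapNeighborIds(graph, specific)
        mark <- intersect(nbMap$node, net@nodes)
        mark <- setdiff(mark, c(net@sources, net@target))
        net@nodeRoles[mark] <- role
        net
    }
    list(sensitive = buildSide("sensitive", "neighbor-sensitive"),
         non_sensitive = buildSide("non_sensitive",
                                   "neighbor-non-sensitive"))
}
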