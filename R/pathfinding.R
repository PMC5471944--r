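# Exact shortest / K-shortest loopless path search on an EvidenceGraph.
#
# All search runs on an integer-indexed context whose node order is the
# C-locale sort of node ids, so "lexicographically smallest" on id sequences
# equals numeric order on index sequences. Tie-breaking is fully
# deterministic: among equal-weight paths the lexicographically smallest
# node-id sequence wins.

.W_EPS <- 1e-9

# Precompute adjacency + per-edge weights for one (graph, weights) pair.
.pathContext <- function(graph, weights) {
    ids <- graph@nodes$id                  # radix-sorted by construction
    n <- length(ids)
    e <- graph@edges
    S <- effectiveScore(e, weights)
    w <- 1 - S
    ui <- match(e$u, ids)
    vi <- match(e$v, ids)
    nbr <- vector("list", n)
    nbrW <- vector("list", n)
    nbrS <- vector("list", n)
    nbrE <- vector("list", n)
    for (i in seq_len(n)) {
        nbr[[i]] <- integer()
        nbrW[[i]] <- numeric()
        nbrS[[i]] <- numeric()
        nbrE[[i]] <- integer()
    }
    for (r in seq_len(nrow(e))) {
        a <- ui[r]; b <- vi[r]
        nbr[[a]] <- c(nbr[[a]], b); nbrW[[a]] <- c(nbrW[[a]], w[r])
        nbrS[[a]] <- c(nbrS[[a]], S[r]); nbrE[[a]] <- c(nbrE[[a]], r)
        nbr[[b]] <- c(nbr[[b]], a); nbrW[[b]] <- c(nbrW[[b]], w[r])
        nbrS[[b]] <- c(nbrS[[b]], S[r]); nbrE[[b]] <- c(nbrE[[b]], r)
    }
    for (i in seq_len(n)) {                # ascending neighbor order
        o <- order(nbr[[i]])
        nbr[[i]] <- nbr[[i]][o]; nbrW[[i]] <- nbrW[[i]][o]
        nbrS[[i]] <- nbrS[[i]][o]; nbrE[[i]] <- nbrE[[i]][o]
    }
    emap <- stats::setNames(seq_len(nrow(e)),
                            paste(pmin(ui, vi), pmax(ui, vi), sep = "|"))
    list(ids = ids, n = n, nbr = nbr, nbrW = nbrW, nbrS = nbrS, nbrE = nbrE,
         ew = w, es = S, emap = emap)
}

.edgeIdx <- function(ctx, i, j)
    unname(ctx$emap[paste(min(i, j), max(i, j), sep = "|")])

# Plain Dijkstra distances from src; banned nodes/edges are excluded.
# O(n^2) scan-based extraction: deterministic and ample at desk scale.
.dijkstra <- function(ctx, src, bannedNodes = integer(), bannedEdges = integer()) {
    n <- ctx$n
    dist <- rep(Inf, n)
    dist[src] <- 0
    done <- logical(n)
    done[bannedNodes] <- TRUE
    banE <- logical(length(ctx$ew))
    banE[bannedEdges] <- TRUE
    repeat {
        u <- 0L
        best <- Inf
        for (i in seq_len(n)) if (!done[i] && dist[i] < best) {
            best <- dist[i]; u <- i
        }
        if (u == 0L) break
        done[u] <- TRUE
        nb <- ctx$nbr[[u]]
        for (j in seq_along(nb)) {
            v <- nb[j]
            if (done[v] || banE[ctx$nbrE[[u]][j]]) next
            alt <- dist[u] + ctx$nbrW[[u]][j]
            if (alt < dist[v]) dist[v] <- alt
        }
    }
    dist
}

# Lexicographically smallest minimum-weight loopless path from s to t.
# Every minimum-weight path uses only "tight" edges (d_s[u] + w + d_t[v] equal
# to the s-t distance), and every loopless all-tight s-t path attains the
# minimum; a DFS over tight edges taking neighbors in ascending order, with
# backtracking for visited-node dead ends, therefore yields the
# lexicographically least optimum.
.lexShortestPath <- function(ctx, s, t, bannedNodes = integer(),
                             bannedEdges = integer()) {
    if (s == t)
        return(list(nodes = s, w = 0, S = numeric()))
    ds <- .dijkstra(ctx, s, bannedNodes, bannedEdges)
    if (!is.finite(ds[t])) return(NULL)
    dt <- .dijkstra(ctx, t, bannedNodes, bannedEdges)
    D <- ds[t]
    banE <- logical(length(ctx$ew))
    banE[bannedEdges] <- TRUE
    visited <- logical(ctx$n)
    visited[bannedNodes] <- TRUE
    pathS <- numeric()
    walk <- function(u, acc) {
        if (u == t) return(list(u))
        visited[u] <<- TRUE
        nb <- ctx$nbr[[u]]
        for (j in seq_along(nb)) {
            v <- nb[j]
            if (visited[v] || banE[ctx$nbrE[[u]][j]]) next
            w <- ctx$nbrW[[u]][j]
            if (acc + w + dt[v] > D + .W_EPS) next   # not tight
            res <- walk(v, acc + w)
            if (!is.null(res)) {
                pathS <<- c(ctx$nbrS[[u]][j], pathS)
                visited[u] <<- FALSE
                return(c(u, res))
            }
        }
        visited[u] <<- FALSE
        NULL
    }
    p <- walk(s, 0)
    if (is.null(p)) return(NULL)          # cannot happen; defensive
    list(nodes = unlist(p), w = D, S = pathS)
}

.lexLessInt <- function(a, b) {
    n <- min(length(a), length(b))
    for (i in seq_len(n)) if (a[i] != b[i]) return(a[i] < b[i])
    length(a) < length(b)
}

# (weight, lexicographic) order on search entries.
.entryLess <- function(a, b) {
    if (a$w < b$w - .W_EPS) return(TRUE)
    if (a$w > b$w + .W_EPS) return(FALSE)
    .lexLessInt(a$nodes, b$nodes)
}

# Exact best loopless path with at most maxEdges edges: uniform-cost search
# over loopless paths ordered by (weight, lexicographic sequence). Since
# extending a path never decreases this order, the first goal pop is optimal.
# Used for hop-bounded spur searches, where depth is small by construction.
.boundedBest <- function(ctx, s, t, maxEdges, bannedNodes = integer(),
                         bannedEdges = integer()) {
    if (s == t)
        return(list(nodes = s, w = 0, S = numeric()))
    if (maxEdges < 1) return(NULL)
    banE <- logical(length(ctx$ew))
    banE[bannedEdges] <- TRUE
    banN <- logical(ctx$n)
    banN[bannedNodes] <- TRUE
    queue <- list(list(nodes = s, w = 0, S = numeric()))
    while (length(queue)) {
        bi <- 1L
        for (i in seq_along(queue))
            if (i > 1L && .entryLess(queue[[i]], queue[[bi]])) bi <- i
        cur <- queue[[bi]]
        queue[[bi]] <- NULL
        u <- cur$nodes[length(cur$nodes)]
        if (u == t) return(cur)
        if (length(cur$nodes) - 1L >= maxEdges) next
        nb <- ctx$nbr[[u]]
        for (j in seq_along(nb)) {
            v <- nb[j]
            if (banN[v] || v %in% cur$nodes || banE[ctx$nbrE[[u]][j]]) next
            queue[[length(queue) + 1L]] <-
                list(nodes = c(cur$nodes, v), w = cur$w + ctx$nbrW[[u]][j],
                     S = c(cur$S, ctx$nbrS[[u]][j]))
        }
    }
    NULL
}

.spurSearch <- function(ctx, s, t, maxEdges, bannedNodes = integer(),
                        bannedEdges = integer()) {
    if (is.infinite(maxEdges))
        .lexShortestPath(ctx, s, t, bannedNodes, bannedEdges)
    else
        .boundedBest(ctx, s, t, maxEdges, bannedNodes, bannedEdges)
}

# ---- modified Yen's K shortest loopless paths, as an iterator ------------
#
# Standard Yen candidate generation, modified in two ways: the
# max-intermediates cap is enforced inside the enumeration (spur searches are
# hop-bounded by the room the root prefix leaves), and all ordering ties are
# broken lexicographically so runs are reproducible.

.yenInit <- function(ctx, s, t, maxEdges) {
    st <- new.env(parent = emptyenv())
    st$ctx <- ctx; st$s <- s; st$t <- t; st$maxEdges <- maxEdges
    st$A <- list()
    st$B <- list()
    st$seen <- character()
    st$exhausted <- FALSE
    st
}

.yenNext <- function(st) {
    if (st$exhausted) return(NULL)
    ctx <- st$ctx
    if (!length(st$A)) {
        p <- .spurSearch(ctx, st$s, st$t, st$maxEdges)
        if (is.null(p)) {
            st$exhausted <- TRUE
            return(NULL)
        }
        st$A <- list(p)
        st$seen <- paste(p$nodes, collapse = ",")
        return(p)
    }
    prev <- st$A[[length(st$A)]]
    L <- length(prev$nodes)
    if (L >= 2L) {
        rootW <- 0
        for (i in seq_len(L - 1L)) {
            spurNode <- prev$nodes[i]
            root <- prev$nodes[seq_len(i)]
            bannedEdges <- integer()
            for (p in st$A) {
                if (length(p$nodes) > i &&
                    identical(p$nodes[seq_len(i)], root))
                    bannedEdges <- c(bannedEdges,
                                     .edgeIdx(ctx, p$nodes[i], p$nodes[i + 1L]))
            }
            bannedNodes <- root[-i]
            remaining <- st$maxEdges - (i - 1L)
            if (remaining >= 1) {
                sp <- .spurSearch(ctx, spurNode, st$t, remaining,
                                  bannedNodes, unique(bannedEdges))
                if (!is.null(sp)) {
                    cand <- list(nodes = c(root[-i], sp$nodes),
                                 w = rootW + sp$w,
                                 S = c(prev$S[seq_len(i - 1L)], sp$S))
                    key <- paste(cand$nodes, collapse = ",")
                    if (!(key %in% st$seen)) {
                        st$B[[length(st$B) + 1L]] <- cand
                        st$seen <- c(st$seen, key)
                    }
                }
            }
            rootW <- rootW + ctx$ew[.edgeIdx(ctx, prev$nodes[i],
                                             prev$nodes[i + 1L])]
        }
    }
    if (!length(st$B)) {
        st$exhausted <- TRUE
        return(NULL)
    }
    bi <- 1L
    for (i in seq_along(st$B))
        if (i > 1L && .entryLess(st$B[[i]], st$B[[bi]])) bi <- i
    nxt <- st$B[[bi]]
    st$B[[bi]] <- NULL
    st$A[[length(st$A) + 1L]] <- nxt
    nxt
}

.wrapPath <- function(ctx, p) {
    new("WeightedPath", nodes = ctx$ids[p$nodes],
        totalWeight = if (length(p$S)) sum(1 - p$S) else 0,
        edgeScores = p$S)
}

#' Weight-shortest path between two nodes
#'
#' Dijkstra search under the weight \eqn{w = 1 - S} per edge, where S is the
#' effective evidence score under \code{weights}. Among equal-weight optima
#' the lexicographically smallest node-id sequence is returned, so results
#' are reproducible.
#'
#' @param graph An \linkS4class{EvidenceGraph}.
#' @param src,dst Node ids.
#' @param weights A \linkS4class{ChannelWeights}; default uses each edge's
#'   reported combined score.
#' @return A \linkS4class{WeightedPath}, or \code{NULL} when \code{dst} is
#'   unreachable. \code{src == dst} yields the single-node path of weight 0.
#' @examples
#' shortestPath(toy1(), "D", "M")   # D A M, weight 0.3
#' @seealso \code{\link{kShortestPaths}}
#' @export
shortestPath <- function(graph, src, dst, weights = channelWeights()) {
    .assertNode(graph, src, "source node")
    .assertNode(graph, dst, "target node")
    ctx <- .pathContext(graph, weights)
    p <- .lexShortestPath(ctx, match(src, ctx$ids), match(dst, ctx$ids))
    if (is.null(p)) return(NULL)
    .wrapPath(ctx, p)
}

#' K shortest loopless paths (modified Yen enumeration)
#'
#' Enumerates loopless paths in nondecreasing total weight (ties broken by
#' lexicographically smallest node sequence). Paths whose intermediate-node
#' count would exceed \code{maxIntermediates} are pruned inside the
#' enumeration — spur searches are hop-bounded — so \code{k} counts accepted
#' paths. Fewer than \code{k} paths are returned when the supply is
#' exhausted.
#'
#' @inheritParams shortestPath
#' @param k Maximum number of paths (\code{k >= 1}).
#' @param maxIntermediates Cap on nodes strictly between the endpoints;
#'   \code{Inf} for unlimited.
#' @return List of \linkS4class{WeightedPath} in rank order.
#' @examples
#' ks <- kShortestPaths(toy1(), "D", "M", k = 3)
#' vapply(ks, totalWeight, 0)  # 0.3 0.4 0.7
#' @export
kShortestPaths <- function(graph, src, dst, k, weights = channelWeights(),
                           maxIntermediates = Inf) {
    .assertNode(graph, src, "source node")
    .assertNode(graph, dst, "target node")
    if (!.isCount(k)) .stopf("k must be a positive integer")
    if (!(is.numeric(maxIntermediates) && length(maxIntermediates) == 1L &&
          (is.infinite(maxIntermediates) || maxIntermediates >= 0)))
        .stopf("maxIntermediates must be a nonnegative number or Inf")
    ctx <- .pathContext(graph, weights)
    st <- .yenInit(ctx, match(src, ctx$ids), match(dst, ctx$ids),
                   maxIntermediates + 1)
    out <- list()
    for (i in seq_len(k)) {
        p <- .yenNext(st)
        if (is.null(p)) break
        out[[length(out) + 1L]] <- .wrapPath(ctx, p)
    }
    out
}

#' Accessors for WeightedPath
#'
#' @param x A \linkS4class{WeightedPath}.
#' @name WeightedPath-accessors
NULL

#' @rdname WeightedPath-accessors
#' @export
setMethod("pathNodes", "WeightedPath", function(x) x@nodes)

#' @rdname WeightedPath-accessors
#' @export
setMethod("totalWeight", "WeightedPath", function(x) x@totalWeight)

#' @rdname WeightedPath-accessors
#' @export
setMethod("edgeScores", "WeightedPath", function(x) x@edgeScores)

setMethod("show", "WeightedPath", function(object) {
    cat(sprintf("WeightedPath: %s  (weight %.4g)\n",
                paste(object@nodes, collapse = " - "), object@totalWeight))
    invisible(NULL)
})
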