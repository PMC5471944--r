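# Synthetic fixtures: the fixed TOY-1 worked-example graph and a seeded
# generator of STITCH/STRING-dialect flat files, so every module is testable
# without database downloads.

#' The TOY-1 worked-example graph
#'
#' Six nodes — chemicals D and E, proteins A, B, C, M (C isolated) — and
#' seven edges with combined scores D-A 0.9, A-M 0.8, D-B 0.7, B-M 0.9,
#' A-B 0.5, D-M 0.2, E-B 0.6, each score carried in the experimental
#' channel. The direct D-M edge is deliberately weaker than the two-hop
#' routes, so "direct relation" and "lightest path" disagree — the case the
#' pair classifier must handle.
#'
#' There are exactly five simple D-to-M paths, with weights 0.3 (D-A-M),
#' 0.4 (D-B-M), 0.7 (D-A-B-M), 0.8 (D-M) and 1.0 (D-B-A-M).
#'
#' @return An \linkS4class{EvidenceGraph}.
#' @examples
#' numNodes(toy1())  # 6
#' @export
toy1 <- function() {
    nodes <- data.frame(
        id = c("D", "E", "A", "B", "C", "M"),
        kind = c("chemical", "chemical", "protein", "protein", "protein",
                 "protein"),
        stringsAsFactors = FALSE)
    s <- c(0.9, 0.8, 0.7, 0.9, 0.5, 0.2, 0.6)
    edges <- data.frame(
        u = c("D", "A", "D", "B", "A", "D", "E"),
        v = c("A", "M", "B", "M", "B", "M", "B"),
        experimental = s, combined = s, stringsAsFactors = FALSE)
    evidenceGraph(nodes, edges)
}

#' Specify a synthetic fixture graph
#'
#' @param nProteins,nChemicals Node counts.
#' @param edgeDensity Probability that an admissible node pair receives an
#'   edge (protein-protein, chemical-protein and chemical-chemical pairs are
#'   all admissible).
#' @param scoreDistribution List with elements \code{zeroProb} (chance a
#'   channel is absent from an edge) and \code{shape1}, \code{shape2} (Beta
#'   parameters for present channel scores, quantized to the 1/1000 grid).
#'   Defaults: 0.6, 2, 2 — most edges carry one or two informative channels
#'   with mid-range scores, loosely echoing public STITCH/STRING score
#'   profiles without mimicking their degree structure.
#' @param seed Integer seed; (spec, seed) determines the files byte for
#'   byte.
#' @return A \linkS4class{FixtureSpec}.
#' @examples
#' fixtureSpec(5, 1, edgeDensity = 1, seed = 7)
#' @export
fixtureSpec <- function(nProteins, nChemicals, edgeDensity,
                        scoreDistribution = list(zeroProb = 0.6, shape1 = 2,
                                                 shape2 = 2),
                        seed = 1L) {
    spec <- new("FixtureSpec", nProteins = as.integer(nProteins),
                nChemicals = as.integer(nChemicals),
                edgeDensity = as.numeric(edgeDensity),
                scoreDistribution = scoreDistribution,
                seed = as.integer(seed))
    validObject(spec)
    spec
}

.withFixtureRNG <- function(seed, expr) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", globalenv())
        on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                add = TRUE)
    }
    # pinned generator so fixtures are stable across platforms and R sessions
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
    force(expr)
}

.sampleChannelScores <- function(nEdges, channels, dist) {
    m <- matrix(0, nrow = nEdges, ncol = length(channels),
                dimnames = list(NULL, channels))
    for (j in seq_along(channels)) {
        present <- stats::runif(nEdges) >= dist$zeroProb
        raw <- stats::rbeta(nEdges, dist$shape1, dist$shape2)
        m[, j] <- ifelse(present, round(raw * 1000) / 1000, 0)
    }
    # noisy-OR of the channels, quantized back to the grid
    comb <- 1 - apply(1 - m, 1L, prod)
    cbind(m, combined = round(comb * 1000) / 1000)
}

#' Generate synthetic STITCH/STRING-dialect flat files
#'
#' Writes protein-protein, chemical-protein and chemical-chemical link files
#' (plus alias table and manifest) for a random graph drawn from
#' \code{spec}. The same (spec, seed) always produces byte-identical files.
#' Requests that would exceed one million edges are refused.
#'
#' @param spec A \linkS4class{FixtureSpec}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @seealso \code{\link{fixtureGraph}} to get the parsed graph directly.
#' @export
generateFixtureFiles <- function(spec, dir) {
    stopifnot(is(spec, "FixtureSpec"))
    np <- spec@nProteins
    nc <- spec@nChemicals
    nPairs <- np * (np - 1) / 2 + nc * (nc - 1) / 2 + np * nc
    if (nPairs * spec@edgeDensity > 1e6)
        .stopf("spec would generate > 1e6 edges; refusing (desk-scale guard)")
    prot <- if (np) sprintf("9606.ENSP%08d", seq_len(np)) else character()
    chem <- if (nc) sprintf("CIDm%08d", seq_len(nc)) else character()
    dist <- spec@scoreDistribution
    pairsOf <- function(a, b = NULL) {
        if (is.null(b)) {
            if (length(a) < 2L) return(NULL)
            cmb <- utils::combn(a, 2L)
            data.frame(u = cmb[1L, ], v = cmb[2L, ], stringsAsFactors = FALSE)
        } else {
            if (!length(a) || !length(b)) return(NULL)
            expand.grid(u = a, v = b, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
        }
    }
    graph <- .withFixtureRNG(spec@seed, {
        sections <- list(
            pp = list(pairs = pairsOf(prot), channels = PROTEIN_CHANNELS),
            cp = list(pairs = pairsOf(chem, prot),
                      channels = CHEMPROT_CHANNELS),
            cc = list(pairs = pairsOf(chem), channels = CHEMCHEM_CHANNELS))
        edgeList <- list()
        for (nm in names(sections)) {
            p <- sections[[nm]]$pairs
            if (is.null(p) || !nrow(p)) next
            keep <- stats::runif(nrow(p)) < spec@edgeDensity
            p <- p[keep, , drop = FALSE]
            if (!nrow(p)) next
            sc <- .sampleChannelScores(nrow(p), sections[[nm]]$channels, dist)
            df <- cbind(p, as.data.frame(sc))
            edgeList[[nm]] <- df
        }
        edgeList
    })
    nodes <- data.frame(id = c(prot, chem),
                        kind = rep(c("protein", "chemical"), c(np, nc)),
                        stringsAsFactors = FALSE)
    edges <- NULL
    if (length(graph)) {
        for (df in graph) {
            for (ch in EV_CHANNELS) if (is.null(df[[ch]])) df[[ch]] <- 0
            df <- df[, c("u", "v", EV_CHANNELS, "combined")]
            edges <- rbind(edges, df)
        }
    }
    g <- evidenceGraph(nodes, edges)
    writeFlatFiles(g, dir)
}

#' Generate and parse a synthetic fixture graph
#'
#' Convenience wrapper: \code{\link{generateFixtureFiles}} into a temporary
#' directory followed by \code{\link{readEvidenceGraph}}.
#'
#' @param spec A \linkS4class{FixtureSpec}.
#' @return An \linkS4class{EvidenceGraph}.
#' @export
fixtureGraph <- function(spec) {
    dir <- tempfile("evinet-fixture-")
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
    generateFixtureFiles(spec, dir)
    readEvidenceGraph(dir)
}

setMethod("show", "FixtureSpec", function(object) {
    cat(sprintf(
        "FixtureSpec: %d proteins, %d chemicals, density %.3g, seed %d\n",
        object@nProteins, object@nChemicals, object@edgeDensity,
        object@seed))
    invisible(NULL)
})
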