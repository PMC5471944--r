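# Independent oracles for path search: exhaustive simple-path enumeration
# over the raw edge table, sorted by (total weight, lexicographic node
# sequence). Deliberately shares no code with the package's search.

oracleSimplePaths <- function(g, src, dst, weights = channelWeights(),
                              maxIntermediates = Inf) {
    e <- edges(g)
    S <- effectiveScore(e, weights)
    nbr <- list()
    addN <- function(a, b, s) {
        nbr[[a]] <<- rbind(nbr[[a]],
                           data.frame(n = b, s = s, stringsAsFactors = FALSE))
    }
    for (i in seq_len(nrow(e))) {
        addN(e$u[i], e$v[i], S[i])
        addN(e$v[i], e$u[i], S[i])
    }
    out <- list()
    rec <- function(path, sc) {
        last <- path[length(path)]
        if (last == dst) {
            if (length(path) - 2L <= maxIntermediates)
                out[[length(out) + 1L]] <<- list(nodes = path,
                                                 w = sum(1 - sc), S = sc)
            return(invisible())
        }
        if (length(path) - 1L >= maxIntermediates + 1L) return(invisible())
        a <- nbr[[last]]
        if (is.null(a)) return(invisible())
        for (j in seq_len(nrow(a)))
            if (!(a$n[j] %in% path)) rec(c(path, a$n[j]), c(sc, a$s[j]))
    }
    if (src == dst) return(list(list(nodes = src, w = 0, S = numeric())))
    rec(src, numeric())
    if (!length(out)) return(out)
    # "\r" sorts below every printable byte, so the pasted key order equals
    # lexicographic order on node sequences (prefix before extension)
    keys <- vapply(out, function(p) paste(p$nodes, collapse = "\r"), "")
    ord <- order(round(vapply(out, `[[`, 0, "w"), 9L), keys,
                 method = "radix")
    out[ord]
}

oracleShortest <- function(g, src, dst, weights = channelWeights()) {
    o <- oracleSimplePaths(g, src, dst, weights)
    if (length(o)) o[[1L]] else NULL
}

# Random heterogeneous test graph built directly from an edge table,
# bypassing the fixture generator and file parsers.
randomTestGraph <- function(n, density, nChem = 1L, allZeroOk = FALSE) {
    ids <- c(sprintf("CIDm%07d0", seq_len(nChem)),
             sprintf("9606.P%03d", seq_len(n - nChem)))
    kind <- rep(c("chemical", "protein"), c(nChem, n - nChem))
    pairs <- t(utils::combn(ids, 2L))
    keep <- stats::runif(nrow(pairs)) < density
    nodes <- data.frame(id = ids, kind = kind, stringsAsFactors = FALSE)
    if (!any(keep)) return(evidenceGraph(nodes))
    ne <- sum(keep)
    exper <- sample(0:1000, ne, replace = TRUE) / 1000
    text <- sample(0:1000, ne, replace = TRUE) / 1000
    comb <- round((1 - (1 - exper) * (1 - text)) * 1000) / 1000
    if (!allZeroOk) comb[comb == 0] <- 0.001
    evidenceGraph(nodes,
                  data.frame(u = pairs[keep, 1L], v = pairs[keep, 2L],
                             experimental = exper, textmining = text,
                             combined = comb, stringsAsFactors = FALSE))
}

pathString <- function(p) paste(pathNodes(p), collapse = "-")

expect_same_paths <- function(got, oracle) {
    expect_equal(length(got), length(oracle))
    for (i in seq_along(oracle)) {
        expect_identical(pathNodes(got[[i]]), oracle[[i]]$nodes)
        expect_equal(totalWeight(got[[i]]), oracle[[i]]$w, tolerance = 1e-9)
    }
}
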