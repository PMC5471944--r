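# Edge scoring, weights and exact path search.

test_that("effective score passes combined through at default weights", {
    e <- edges(toy1())
    expect_equal(effectiveScore(e, channelWeights()), e$combined)
})

test_that("effective score recombines by noisy-OR under custom weights", {
    ed <- data.frame(u = "a", v = "b", experimental = 0.5, textmining = 0.5,
                     combined = 0.9)
    for (ch in setdiff(evidenceChannels(), c("experimental", "textmining")))
        ed[[ch]] <- 0
    # textmining silenced: 1 - (1-0.5)(1-0) = 0.5
    expect_equal(effectiveScore(ed, channelWeights(textmining = 0)), 0.5)
    # both at full strength: 1 - 0.25 = 0.75
    expect_equal(effectiveScore(ed, channelWeights(textmining = 1,
                                                   experimental = 0.999)),
                 1 - (1 - 0.999 * 0.5) * 0.5)
    only_tm <- ed
    only_tm$experimental <- 0
    only_tm$textmining <- 0.9
    expect_equal(effectiveScore(only_tm, channelWeights(textmining = 0)), 0)
})

test_that("presets map NONE/LOW/DEFAULT to 0/0.5/1 and reject junk", {
    w <- channelWeights(textmining = "NONE", database = "LOW",
                        experimental = "DEFAULT")
    expect_equal(unname(multipliers(w)[c("textmining", "database",
                                         "experimental")]),
                 c(0, 0.5, 1))
    expect_error(channelWeights(textmining = "HIGH"), "preset")
    expect_error(channelWeights(frobnication = 1), "unknown channel")
    expect_error(channelWeights(textmining = 1.5), "0,1")
})

test_that("edge weight is 1 - S and validates its domain", {
    expect_equal(edgeWeight(c(0, 0.7, 1)), c(1, 0.3, 0))
    expect_error(edgeWeight(1.2), "0,1")
    expect_error(edgeWeight(-0.1), "0,1")
})

test_that("TOY-1 shortest path is D-A-M at weight 0.3", {
    p <- shortestPath(toy1(), "D", "M")
    expect_identical(pathNodes(p), c("D", "A", "M"))
    expect_equal(totalWeight(p), 0.3)
    # agrees with the exhaustive oracle
    o <- oracleShortest(toy1(), "D", "M")
    expect_identical(o$nodes, pathNodes(p))
})

test_that("degenerate queries: src == dst, disconnected, unknown ids", {
    g <- toy1()
    self <- shortestPath(g, "D", "D")
    expect_identical(pathNodes(self), "D")
    expect_equal(totalWeight(self), 0)
    expect_null(shortestPath(g, "D", "C"))
    expect_error(shortestPath(g, "D", "nope"), "not found")
    expect_identical(kShortestPaths(g, "D", "C", k = 5), list())
})

test_that("TOY-1 K-shortest enumeration matches the brute-force oracle", {
    g <- toy1()
    o <- oracleSimplePaths(g, "D", "M")
    expect_equal(length(o), 5L)
    expect_equal(vapply(o, `[[`, 0, "w"), c(0.3, 0.4, 0.7, 0.8, 1.0))

    expect_same_paths(kShortestPaths(g, "D", "M", k = 3), o[1:3])
    expect_same_paths(kShortestPaths(g, "D", "M", k = 10), o)
    expect_identical(pathString(kShortestPaths(g, "D", "M", k = 10)[[5]]),
                     "D-B-A-M")

    # hop cap enforced inside the enumeration
    capped <- kShortestPaths(g, "D", "M", k = 10, maxIntermediates = 1)
    expect_identical(vapply(capped, pathString, ""),
                     c("D-A-M", "D-B-M", "D-M"))
    expect_same_paths(capped,
                      oracleSimplePaths(g, "D", "M", maxIntermediates = 1))
})

test_that("K-shortest equals exhaustive enumeration on random graphs", {
    set.seed(101)
    for (rep in 1:25) {
        g <- randomTestGraph(sample(4:9, 1L), 0.45)
        src <- chemicalNodes(g)[1L]
        dst <- rev(proteinNodes(g))[1L]
        o <- oracleSimplePaths(g, src, dst)
        expect_same_paths(kShortestPaths(g, src, dst, k = 100000), o)
        mi <- sample(1:3, 1L)
        expect_same_paths(
            kShortestPaths(g, src, dst, k = 100000, maxIntermediates = mi),
            oracleSimplePaths(g, src, dst, maxIntermediates = mi))
    }
})

test_that("k = 1 agrees with shortestPath whenever a path exists", {
    set.seed(55)
    for (rep in 1:10) {
        g <- randomTestGraph(6, 0.5)
        src <- chemicalNodes(g)[1L]
        dst <- rev(proteinNodes(g))[1L]
        sp <- shortestPath(g, src, dst)
        ks <- kShortestPaths(g, src, dst, k = 1)
        if (is.null(sp)) {
            expect_length(ks, 0L)
        } else {
            expect_identical(pathNodes(ks[[1L]]), pathNodes(sp))
            expect_equal(totalWeight(ks[[1L]]), totalWeight(sp))
        }
    }
})

test_that("outputs are loopless with nondecreasing weights", {
    set.seed(77)
    for (rep in 1:8) {
        g <- randomTestGraph(7, 0.5)
        ks <- kShortestPaths(g, chemicalNodes(g)[1L],
                             rev(proteinNodes(g))[1L], k = 100000)
        ws <- vapply(ks, totalWeight, 0)
        expect_true(all(diff(ws) >= -1e-9))
        for (p in ks) expect_false(anyDuplicated(pathNodes(p)) > 0)
    }
})

test_that("raising a channel multiplier never hurts scores, weights or paths", {
    set.seed(303)
    for (rep in 1:8) {
        g <- randomTestGraph(7, 0.5)
        if (!numEdges(g)) next
        m1 <- runif(1, 0, 0.9)
        m2 <- runif(1, m1, 1)
        wlo <- channelWeights(experimental = m1, textmining = 0.8)
        whi <- channelWeights(experimental = m2, textmining = 0.8)
        slo <- effectiveScore(edges(g), wlo)
        shi <- effectiveScore(edges(g), whi)
        expect_true(all(shi - slo >= -1e-12))
        expect_true(all(edgeWeight(shi) - edgeWeight(slo) <= 1e-12))
        src <- chemicalNodes(g)[1L]
        dst <- rev(proteinNodes(g))[1L]
        plo <- shortestPath(g, src, dst, wlo)
        phi <- shortestPath(g, src, dst, whi)
        if (!is.null(plo))
            expect_true(totalWeight(phi) <= totalWeight(plo) + 1e-9)
    }
})

test_that("silencing a channel equals deleting it from every edge", {
    set.seed(404)
    for (rep in 1:6) {
        g <- randomTestGraph(7, 0.5)
        if (!numEdges(g)) next
        # same weights on both graphs so both sides recombine by noisy-OR
        w <- channelWeights(textmining = 0, experimental = 0.9)
        gDel <- evidenceGraph(nodes(g),
                              transform(edges(g), textmining = 0),
                              aliases(g))
        src <- chemicalNodes(g)[1L]
        dst <- rev(proteinNodes(g))[1L]
        a <- kShortestPaths(g, src, dst, k = 1000, weights = w)
        b <- kShortestPaths(gDel, src, dst, k = 1000, weights = w)
        expect_identical(lapply(a, pathNodes), lapply(b, pathNodes))
        expect_equal(vapply(a, totalWeight, 0), vapply(b, totalWeight, 0))
    }
})

test_that("equal-weight paths break ties toward the smaller node sequence", {
    nodes <- data.frame(id = c("CIDmQ", "9606.A", "9606.B", "9606.T"),
                        kind = c("chemical", rep("protein", 3L)))
    s <- 0.5
    g <- evidenceGraph(nodes, data.frame(
        u = c("CIDmQ", "CIDmQ", "9606.A", "9606.B"),
        v = c("9606.A", "9606.B", "9606.T", "9606.T"),
        experimental = s, combined = s))
    p <- shortestPath(g, "CIDmQ", "9606.T")
    expect_identical(pathNodes(p), c("CIDmQ", "9606.A", "9606.T"))
    ks <- kShortestPaths(g, "CIDmQ", "9606.T", k = 5)
    expect_identical(vapply(ks, pathString, ""),
                     c("CIDmQ-9606.A-9606.T", "CIDmQ-9606.B-9606.T"))
})

test_that("zero-weight edges (S = 1) are traversed correctly", {
    nodes <- data.frame(id = c("CIDmQ", "9606.A", "9606.T"),
                        kind = c("chemical", "protein", "protein"))
    g <- evidenceGraph(nodes, data.frame(
        u = c("CIDmQ", "9606.A", "CIDmQ"),
        v = c("9606.A", "9606.T", "9606.T"),
        experimental = c(1, 1, 0.5), combined = c(1, 1, 0.5)))
    p <- shortestPath(g, "CIDmQ", "9606.T")
    expect_identical(pathNodes(p), c("CIDmQ", "9606.A", "9606.T"))
    expect_equal(totalWeight(p), 0)
})
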