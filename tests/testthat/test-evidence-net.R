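# Evidence-network assembly, stopping rule, classification, Next Shortest.

test_that("TOY-1 networks stop once N distinct nodes accumulate", {
    g <- toy1()
    net4 <- buildEvidenceNetwork(g, "D", "M", N = 4, maxIntermediates = 3)
    expect_identical(vapply(networkPaths(net4), pathString, ""),
                     c("D-A-M", "D-B-M"))
    expect_setequal(nodes(net4), c("D", "A", "B", "M"))
    expect_identical(stopReason(net4), "n_reached")

    net3 <- buildEvidenceNetwork(g, "D", "M", N = 3)
    expect_identical(vapply(networkPaths(net3), pathString, ""), "D-A-M")
    expect_setequal(nodes(net3), c("D", "A", "M"))
})

test_that("network edges are exactly the union of accepted path edges", {
    g <- toy1()
    net <- buildEvidenceNetwork(g, "D", "M", N = 4)
    expect_setequal(paste(edges(net)$u, edges(net)$v),
                    c("A D", "A M", "B D", "B M"))
    # scores carry the effective score of each edge
    expect_equal(edges(net)$score[edges(net)$u == "A" &
                                  edges(net)$v == "D"], 0.9)
})

test_that("disconnected pairs yield an empty-path network, not an error", {
    net <- buildEvidenceNetwork(toy1(), "D", "C", N = 5)
    expect_length(networkPaths(net), 0L)
    expect_identical(stopReason(net), "no_path")
    expect_setequal(nodes(net), c("D", "C"))
    expect_setequal(isolatedNodes(net), c("D", "C"))
})

test_that("stopping rule holds across fixture sweeps", {
    set.seed(202)
    for (rep in 1:12) {
        g <- randomTestGraph(sample(5:9, 1L), 0.4)
        src <- chemicalNodes(g)[1L]
        dst <- rev(proteinNodes(g))[1L]
        N <- sample(3:7, 1L)
        net <- buildEvidenceNetwork(g, src, dst, N = N)
        ps <- networkPaths(net)
        if (!length(ps)) next
        withoutLast <- unique(unlist(lapply(ps[-length(ps)], pathNodes)))
        expect_true(length(withoutLast) < N ||
                    stopReason(net) == "exhausted")
        if (stopReason(net) == "n_reached")
            expect_gte(length(unique(unlist(lapply(ps, pathNodes)))), N)
    }
})

test_that("intermediate counts come from nodes strictly between endpoints", {
    mk <- function(nn) new("WeightedPath", nodes = nn,
                           totalWeight = (length(nn) - 1) * 0.5,
                           edgeScores = rep(0.5, length(nn) - 1))
    expect_equal(intermediateCount(mk(c("D", "M"))), 0L)
    expect_equal(intermediateCount(mk(c("D", "A", "M"))), 1L)
    expect_equal(intermediateCount(mk(c("D", "A", "B", "M"))), 2L)
    expect_error(intermediateCount(new("WeightedPath", nodes = "D",
                                       totalWeight = 0,
                                       edgeScores = numeric())),
                 "at least one edge")
})

test_that("classification prioritizes direct edges over lighter paths", {
    g <- toy1()
    # D-M edge exists (combined 0.2) even though D-A-M is lighter
    expect_identical(as.character(classifyPair(g, "D", "M")), "direct")

    # remove the direct edge: shortest is D-A-M, one intermediate
    e <- edges(g)
    gNo <- evidenceGraph(nodes(g), e[!(e$u == "D" & e$v == "M"), ])
    expect_identical(as.character(classifyPair(gNo, "D", "M")), "1")

    expect_identical(as.character(classifyPair(g, "CIDmZZ", "M")),
                     "not_in_db")
    expect_identical(as.character(classifyPair(g, "D", "C")), "unreachable")
})

test_that("direct classification matches graph adjacency exhaustively", {
    g <- toy1()
    for (d in chemicalNodes(g))
        for (m in proteinNodes(g))
            expect_identical(as.character(classifyPair(g, d, m)) == "direct",
                             hasEdge(g, d, m),
                             info = paste(d, m))
})

test_that("a pair beyond three intermediates classifies as unreachable", {
    # chain: drug - p1 - p2 - p3 - p4 - target (4 intermediates)
    ids <- c("CIDmQ", sprintf("9606.P%d", 1:5))
    g <- evidenceGraph(
        data.frame(id = ids, kind = c("chemical", rep("protein", 5L))),
        data.frame(u = ids[-length(ids)], v = ids[-1L],
                   experimental = 0.9, combined = 0.9))
    expect_identical(as.character(classifyPair(g, "CIDmQ", "9606.P5")),
                     "unreachable")
    expect_identical(as.character(classifyPair(g, "CIDmQ", "9606.P4")), "3")
})

test_that("a population's category histogram matches hand-computed counts", {
    g <- toy1()
    pairs <- expand.grid(drug_id = chemicalNodes(g),
                         mediator_id = proteinNodes(g),
                         stringsAsFactors = FALSE)
    out <- classifyPairs(g, pairs)
    # hand audit of toy1: D adjacent to A,B,M; E adjacent to B; D-C and E-C
    # disconnected; E-M shortest is E-B-M (0.5, one intermediate); E-A
    # shortest by weight is E-B-M-A (0.7, two intermediates), beating the
    # two-edge E-B-A (0.9)
    want <- c(direct = 4L, `1` = 1L, `2` = 1L, `3` = 0L,
              unreachable = 2L, not_in_db = 0L)
    expect_equal(as.vector(table(out$category)), unname(want))
})

test_that("Next Shortest sessions stream the K-shortest sequence", {
    g <- toy1()
    s <- pathSession(g, "D", "M")
    got <- c(pathString(nextShortest(s)), pathString(nextShortest(s)),
             pathString(nextShortest(s)))
    expect_identical(got, c("D-A-M", "D-B-M", "D-A-B-M"))
    nextShortest(s); nextShortest(s)
    expect_null(nextShortest(s))     # supply exhausted
    expect_null(nextShortest(s))     # stays exhausted

    # re-initializing under new weights recomputes the ordering
    sw <- pathSession(g, "D", "M", channelWeights(experimental = 0))
    p1 <- nextShortest(sw)
    expect_equal(totalWeight(p1), 1)   # every edge silenced to S = 0
    o <- oracleSimplePaths(g, "D", "M", channelWeights(experimental = 0))
    expect_identical(pathNodes(p1), o[[1L]]$nodes)
})

test_that("sessions agree with kShortestPaths on random graphs", {
    set.seed(505)
    for (rep in 1:5) {
        g <- randomTestGraph(7, 0.45)
        src <- chemicalNodes(g)[1L]
        dst <- rev(proteinNodes(g))[1L]
        ks <- kShortestPaths(g, src, dst, k = 6)
        s <- pathSession(g, src, dst)
        for (i in seq_along(ks))
            expect_identical(pathNodes(nextShortest(s)),
                             pathNodes(ks[[i]]))
    }
})

test_that("annotations attach to network edges when supplied", {
    tab <- loadAnnotations(textConnection(c(
        "A\tD\tbinding assay", "M\tA\tkinase substrate",
        "C\tD\tirrelevant pair")))
    net <- buildEvidenceNetwork(toy1(), "D", "M", N = 3, annotations = tab)
    expect_setequal(net@annotations$description,
                    c("binding assay", "kinase substrate"))
})
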