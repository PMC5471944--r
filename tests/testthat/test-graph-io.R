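# Flat-file parsing, merging and round-trips.

protHeader <- paste("protein1 protein2 neighborhood fusion cooccurence",
                    "coexpression experimental database textmining",
                    "combined_score")
chemHeader <- paste("chemical protein experimental prediction database",
                    "textmining combined_score")

test_that("detailed protein links parse with /1000 scaling and header-driven columns", {
    g <- parseProteinLinks(textConnection(c(
        protHeader,
        "9606.A 9606.B 0 0 0 150 700 900 0 921")))
    e <- edges(g)
    expect_equal(nrow(e), 1L)
    expect_equal(e$coexpression, 0.15)
    expect_equal(e$experimental, 0.7)
    expect_equal(e$database, 0.9)
    expect_equal(e$combined, 0.921)
    expect_equal(e$neighborhood, 0)
    expect_setequal(nodes(g)$kind, "protein")

    # header order, not position, decides the mapping
    g2 <- parseProteinLinks(textConnection(c(
        "protein1 protein2 database experimental combined_score",
        "9606.A 9606.B 900 700 921")))
    expect_equal(edges(g2)$experimental, 0.7)
    expect_equal(edges(g2)$database, 0.9)
})

test_that("symmetric duplicate rows collapse; conflicting scores are an error", {
    g <- parseProteinLinks(textConnection(c(
        "protein1 protein2 experimental combined_score",
        "9606.A 9606.B 700 700",
        "9606.B 9606.A 700 700")))
    expect_equal(numEdges(g), 1L)
    expect_true(hasEdge(g, "9606.B", "9606.A"))

    expect_error(parseProteinLinks(textConnection(c(
        "protein1 protein2 experimental combined_score",
        "9606.A 9606.B 700 700",
        "9606.B 9606.A 800 800"))), "conflicting")
})

test_that("malformed lines and out-of-range scores report the line number", {
    expect_error(parseProteinLinks(textConnection(c(
        "protein1 protein2 experimental combined_score",
        "9606.A 9606.B 700"))), "line 2")
    expect_error(parseProteinLinks(textConnection(c(
        "protein1 protein2 experimental combined_score",
        "9606.A 9606.B 1700 1700"))), "outside")
    expect_error(parseProteinLinks(textConnection(c(
        "protein1 protein2 experimental frobnication combined_score",
        "9606.A 9606.B 1 2 3"))), "unknown column")
})

test_that("header-only stream yields an empty graph", {
    g <- parseProteinLinks(textConnection(protHeader))
    expect_equal(numNodes(g), 0L)
    expect_equal(numEdges(g), 0L)
})

test_that("chemical links tag chemicals and keep all-zero edges", {
    g <- parseChemicalLinks(textConnection(c(
        chemHeader,
        "CIDm00000001 9606.A 0 0 850 0 862",
        "CIDm00000002 9606.A 0 0 0 0 0")))
    expect_setequal(chemicalNodes(g), c("CIDm00000001", "CIDm00000002"))
    e <- getEdge(g, "CIDm00000001", "9606.A")
    expect_equal(e$database, 0.85)
    expect_equal(e$combined, 0.862)
    z <- getEdge(g, "CIDm00000002", "9606.A")
    expect_equal(nrow(z), 1L)
    expect_equal(z$combined, 0)
})

test_that("stereospecific CIDs ids merge into CIDm with per-channel maximum", {
    g <- parseChemicalLinks(textConnection(c(
        chemHeader,
        "CIDs00000001 9606.A 400 0 850 0 862",
        "CIDm00000001 9606.A 600 0 300 100 700")))
    expect_identical(chemicalNodes(g), "CIDm00000001")
    e <- getEdge(g, "CIDm00000001", "9606.A")
    # element-wise max computed by hand
    expect_equal(e$experimental, 0.6)
    expect_equal(e$database, 0.85)
    expect_equal(e$textmining, 0.1)
    expect_equal(e$combined, 0.862)
})

test_that("merge is idempotent, commutative, associative, max-resolving", {
    mk <- function(comb) {
        evidenceGraph(
            data.frame(id = c("9606.A", "9606.B"), kind = "protein"),
            data.frame(u = "9606.A", v = "9606.B", experimental = comb,
                       combined = comb))
    }
    a <- mk(0.5); b <- mk(0.7)
    ab <- mergeGraphs(list(a, b))
    expect_equal(edges(ab)$combined, 0.7)
    expect_equal(edges(mergeGraphs(list(a, a))), edges(a))
    expect_equal(edges(mergeGraphs(list(b, a))), edges(ab))
    c3 <- mk(0.6)
    left <- mergeGraphs(list(mergeGraphs(list(a, b)), c3))
    right <- mergeGraphs(list(a, mergeGraphs(list(b, c3))))
    expect_equal(edges(left), edges(right))

    # parts sharing a protein union into one node
    chem <- parseChemicalLinks(textConnection(c(
        chemHeader, "CIDm00000009 9606.A 0 0 850 0 850")))
    merged <- mergeGraphs(list(a, chem))
    expect_equal(sum(nodes(merged)$id == "9606.A"), 1L)
    expect_equal(numEdges(merged), 2L)
})

test_that("write-then-parse is the identity on fixture graphs", {
    set.seed(11)
    for (rep in 1:5) {
        g <- fixtureGraph(fixtureSpec(5, 3, 0.6, seed = rep))
        dir <- tempfile()
        writeFlatFiles(g, dir)
        g2 <- readEvidenceGraph(dir)
        expect_equal(nodes(g2), nodes(g))
        expect_equal(edges(g2), edges(g))
        unlink(dir, recursive = TRUE)
    }
    # toy1 round-trips too (scores already on the 1/1000 grid)
    dir <- tempfile()
    writeFlatFiles(toy1(), dir)
    back <- readEvidenceGraph(dir)
    expect_equal(edges(back), edges(toy1()))
    expect_equal(nodes(back), nodes(toy1()))
    unlink(dir, recursive = TRUE)
})

test_that("querying an edge is order-insensitive", {
    g <- toy1()
    expect_identical(getEdge(g, "D", "M"), getEdge(g, "M", "D"))
    expect_true(hasEdge(g, "M", "D"))
    expect_false(hasEdge(g, "C", "D"))
})

test_that("self-loop rows are dropped", {
    g <- parseProteinLinks(textConnection(c(
        "protein1 protein2 experimental combined_score",
        "9606.A 9606.A 700 700",
        "9606.A 9606.B 500 500")))
    expect_equal(numEdges(g), 1L)
    expect_false(hasEdge(g, "9606.A", "9606.A"))
})

test_that("taxon filtering keeps chemicals and matching proteins", {
    g <- mergeGraphs(list(
        parseProteinLinks(textConnection(c(
            "protein1 protein2 experimental combined_score",
            "9606.A 10090.B 500 500",
            "9606.A 9606.C 600 600"))),
        parseChemicalLinks(textConnection(c(
            chemHeader, "CIDm00000001 10090.B 0 0 850 0 850")))))
    f <- filterTaxon(g, 9606)
    expect_setequal(nodes(f)$id, c("9606.A", "9606.C", "CIDm00000001"))
    expect_equal(numEdges(f), 1L)
})

test_that("annotation tables order-normalize and accumulate", {
    tab <- loadAnnotations(textConnection(c(
        "9606.A\t9606.B\tcoexpression in liver",
        "9606.B\t9606.A\tinhibition assay")))
    expect_length(annotationsFor(tab, "9606.A", "9606.B"), 2L)
    expect_length(annotationsFor(tab, "9606.B", "9606.A"), 2L)
    expect_length(annotationsFor(tab, "9606.A", "9606.Z"), 0L)

    empty <- loadAnnotations(textConnection(character()))
    expect_equal(nrow(empty@entries), 0L)

    expect_error(loadAnnotations(textConnection("A\tB")), "expected 3")
})
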