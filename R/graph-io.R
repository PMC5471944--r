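# Parsing and writing of STRING/STITCH-dialect flat files.
#
# Supported dialects (column names are read from the header; order follows
# the header, not fixed positions):
#   protein.links.detailed : protein1 protein2 <7 STRING channels> combined_score
#   protein.links (combined-only): protein1 protein2 combined_score
#   chemical_protein.links.detailed:
#       chemical protein experimental prediction database textmining combined_score
#   chemical_chemical.links.detailed:
#       chemical1 chemical2 similarity experimental prediction database
#       textmining combined_score
# Scores are integers in [0,1000]; internally divided by 1000 into [0,1].

.readLinkLines <- function(file) {
    lines <- if (inherits(file, "connection")) readLines(file) else
        readLines(file)
    lines[nzchar(trimws(lines))]
}

.splitWs <- function(x) strsplit(trimws(x), "[ \t]+")

# Parse the numeric body shared by all dialects. Returns a numeric matrix
# (already /1000) with one column per score column.
.parseScores <- function(fields, scoreCols, lineNos) {
    m <- matrix(NA_real_, nrow = length(fields), ncol = length(scoreCols),
                dimnames = list(NULL, scoreCols))
    for (j in seq_along(scoreCols)) {
        raw <- vapply(fields, `[[`, "", j + 2L)
        val <- suppressWarnings(as.numeric(raw))
        bad <- is.na(val) | val != floor(val)
        if (any(bad))
            .stopf("line %d: score '%s' is not an integer",
                   lineNos[which(bad)[1L]], raw[which(bad)[1L]])
        out <- val < 0 | val > 1000
        if (any(out))
            .stopf("line %d: score %s outside [0,1000]",
                   lineNos[which(out)[1L]], raw[which(out)[1L]])
        m[, j] <- val / 1000
    }
    m
}

.parseLinkTable <- function(file, expectedFirst2, allowedChannels, what) {
    lines <- .readLinkLines(file)
    if (!length(lines))
        .stopf("%s: empty stream (missing header line)", what)
    header <- .splitWs(lines[1L])[[1L]]
    if (length(header) < 3L)
        .stopf("%s: header must have at least 3 columns", what)
    if (!identical(header[1:2], expectedFirst2))
        .stopf("%s: header must start with '%s %s' (got '%s %s')", what,
               expectedFirst2[1L], expectedFirst2[2L], header[1L], header[2L])
    if (header[length(header)] != "combined_score")
        .stopf("%s: last header column must be 'combined_score'", what)
    channelCols <- header[-c(1L, 2L, length(header))]
    unknown <- setdiff(channelCols, allowedChannels)
    if (length(unknown))
        .stopf("%s: unknown column(s) in header: %s", what,
               paste(unknown, collapse = ", "))
    if (anyDuplicated(header))
        .stopf("%s: duplicated header column", what)
    body <- lines[-1L]
    if (!length(body))
        return(list(u = character(), v = character(),
                    scores = matrix(numeric(), 0, length(header) - 2L,
                        dimnames = list(NULL, c(channelCols,
                                                "combined_score"))),
                    channels = channelCols))
    fields <- .splitWs(body)
    lineNos <- seq_along(body) + 1L
    nf <- lengths(fields)
    bad <- nf != length(header)
    if (any(bad))
        .stopf("%s: line %d has %d fields, expected %d", what,
               lineNos[which(bad)[1L]], nf[which(bad)[1L]], length(header))
    scores <- .parseScores(fields, c(channelCols, "combined_score"), lineNos)
    list(u = vapply(fields, `[[`, "", 1L),
         v = vapply(fields, `[[`, "", 2L),
         scores = scores, channels = channelCols)
}

# Assemble an EvidenceGraph from parsed columns. `conflict` controls what
# happens when the same undirected pair appears with differing scores:
# "error" (STRING lists each pair twice with identical scores) or "max"
# (per-channel maximum; used when CIDs->CIDm remapping merges rows).
.linksToGraph <- function(tab, kindU, kindV, conflict, what) {
    scoreCols <- colnames(tab$scores)
    edges <- data.frame(u = tab$u, v = tab$v, stringsAsFactors = FALSE)
    for (j in scoreCols) edges[[j]] <- tab$scores[, j]
    names(edges)[names(edges) == "combined_score"] <- "combined"
    kinds <- c(stats::setNames(rep(kindU, length(tab$u)), tab$u),
               stats::setNames(rep(kindV, length(tab$v)), tab$v))
    kinds <- kinds[!duplicated(names(kinds))]
    loops <- edges$u == edges$v
    if (any(loops)) {
        .log("warning", "%s: dropping %d self-loop line(s)", what, sum(loops))
        edges <- edges[!loops, , drop = FALSE]
    }
    if (nrow(edges)) {
        p <- .normalizePairs(edges$u, edges$v)
        edges$u <- p$u
        edges$v <- p$v
        key <- paste(edges$u, edges$v, sep = "\t")
        if (anyDuplicated(key)) {
            sc <- as.matrix(edges[, c(setdiff(scoreCols, "combined_score"),
                                      "combined")])
            grp <- split(seq_len(nrow(edges)), key)
            if (conflict == "error") {
                for (i in grp) {
                    if (length(i) > 1L &&
                        any(apply(sc[i, , drop = FALSE], 2L,
                                  function(col) any(col != col[1L])))) {
                        .stopf("%s: pair '%s %s' listed with conflicting scores",
                               what, edges$u[i[1L]], edges$v[i[1L]])
                    }
                }
                edges <- edges[!duplicated(key), , drop = FALSE]
            } else {
                merged <- lapply(grp, function(i) {
                    e <- edges[i[1L], , drop = FALSE]
                    e[1L, colnames(sc)] <- apply(sc[i, , drop = FALSE], 2L,
                                                 max)
                    e
                })
                edges <- do.call(rbind, merged)
            }
        }
    }
    nodes <- data.frame(id = names(kinds), kind = unname(kinds),
                        stringsAsFactors = FALSE)
    evidenceGraph(nodes, edges)
}

#' Parse STRING-style protein-protein link files
#'
#' Reads a whitespace-delimited flat file with a header line. STRING lists
#' every pair twice (once per direction); the two rows are collapsed into one
#' undirected edge, and rows for the same pair with conflicting scores raise
#' an error. Integer scores in [0,1000] are scaled into [0,1].
#'
#' @param file Path or connection.
#' @param dialect \code{"detailed"} (seven STRING evidence channels plus
#'   \code{combined_score}) or \code{"combined-only"} (three columns).
#' @return A partial \linkS4class{EvidenceGraph} (protein nodes only).
#' @examples
#' con <- textConnection(c(
#'     "protein1 protein2 coexpression experimental database combined_score",
#'     "9606.A 9606.B 150 700 900 921"))
#' g <- parseProteinLinks(con)
#' edges(g)$combined  # 0.921
#' @seealso \code{\link{parseChemicalLinks}}, \code{\link{mergeGraphs}}
#' @export
parseProteinLinks <- function(file, dialect = c("detailed", "combined-only")) {
    dialect <- match.arg(dialect)
    allowed <- if (dialect == "detailed") PROTEIN_CHANNELS else character()
    tab <- .parseLinkTable(file, c("protein1", "protein2"), allowed,
                           "protein links")
    if (dialect == "combined-only" && length(tab$channels))
        .stopf("protein links: combined-only dialect admits no channel columns")
    .linksToGraph(tab, "protein", "protein", "error", "protein links")
}

#' Parse STITCH-style chemical link files
#'
#' Chemical-protein files have header \code{chemical protein experimental
#' prediction database textmining combined_score}; chemical-chemical files
#' add a \code{similarity} channel. Stereospecific chemical ids
#' (\code{CIDs...}) are remapped to their merged form (\code{CIDm...}) at
#' parse time, so stereoisomers and salt forms collapse onto one node;
#' colliding rows merge by per-channel maximum.
#'
#' @param file Path or connection.
#' @param kind \code{"chemical-protein"} or \code{"chemical-chemical"}.
#' @return A partial \linkS4class{EvidenceGraph}.
#' @examples
#' con <- textConnection(c(
#'  "chemical protein experimental prediction database textmining combined_score",
#'  "CIDm00000001 9606.A 0 0 850 0 862"))
#' g <- parseChemicalLinks(con)
#' chemicalNodes(g)  # "CIDm00000001"
#' @export
parseChemicalLinks <- function(file,
        kind = c("chemical-protein", "chemical-chemical")) {
    kind <- match.arg(kind)
    if (kind == "chemical-protein") {
        tab <- .parseLinkTable(file, c("chemical", "protein"),
                               CHEMPROT_CHANNELS, "chemical-protein links")
        tab$u <- .mergeStereoIds(tab$u)
        .linksToGraph(tab, "chemical", "protein", "max",
                      "chemical-protein links")
    } else {
        tab <- .parseLinkTable(file, c("chemical1", "chemical2"),
                               CHEMCHEM_CHANNELS, "chemical-chemical links")
        tab$u <- .mergeStereoIds(tab$u)
        tab$v <- .mergeStereoIds(tab$v)
        .linksToGraph(tab, "chemical", "chemical", "max",
                      "chemical-chemical links")
    }
}

# CIDs... (stereospecific) -> CIDm... (merged) remapping.
.mergeStereoIds <- function(ids) sub("^CIDs", "CIDm", ids)

#' Merge partial evidence graphs
#'
#' Node and edge sets are unioned. When the same undirected edge occurs in
#' several parts, channel scores merge by element-wise maximum and the
#' reported combined score by maximum, making the merge commutative,
#' associative and idempotent.
#'
#' @param parts List of \linkS4class{EvidenceGraph} objects.
#' @return A single merged \linkS4class{EvidenceGraph}.
#' @examples
#' g <- mergeGraphs(list(toy1(), toy1()))
#' numEdges(g) == numEdges(toy1())
#' @export
mergeGraphs <- function(parts) {
    stopifnot(is.list(parts), length(parts) >= 1L,
              all(vapply(parts, is, TRUE, "EvidenceGraph")))
    nodes <- do.call(rbind, lapply(parts, nodes))
    dupIds <- unique(nodes$id[duplicated(nodes$id)])
    for (id in dupIds) {
        k <- unique(nodes$kind[nodes$id == id])
        if (length(k) > 1L)
            .stopf("node '%s' has conflicting kinds across parts", id)
    }
    nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
    edges <- do.call(rbind, lapply(parts, edges))
    if (nrow(edges)) {
        key <- paste(edges$u, edges$v, sep = "\t")
        if (anyDuplicated(key)) {
            sc <- as.matrix(edges[, c(EV_CHANNELS, "combined")])
            grp <- split(seq_len(nrow(edges)), key)
            merged <- lapply(grp, function(i) {
                e <- edges[i[1L], , drop = FALSE]
                e[1L, colnames(sc)] <- apply(sc[i, , drop = FALSE], 2L, max)
                e
            })
            edges <- do.call(rbind, merged)
        }
    }
    al <- unique(do.call(rbind, lapply(parts, aliases)))
    evidenceGraph(nodes, edges, al)
}

#' Restrict protein nodes to one taxon
#'
#' Keeps chemical nodes and protein nodes whose id starts with
#' \code{"<taxon>."} (STRING convention, e.g. \code{9606.} for human), plus
#' all surviving edges.
#'
#' @param graph An \linkS4class{EvidenceGraph}.
#' @param taxon NCBI taxon id as character or integer.
#' @return Filtered \linkS4class{EvidenceGraph}.
#' @export
filterTaxon <- function(graph, taxon) {
    keep <- graph@nodes$kind == "chemical" |
        startsWith(graph@nodes$id, paste0(taxon, "."))
    ids <- graph@nodes$id[keep]
    e <- graph@edges
    e <- e[e$u %in% ids & e$v %in% ids, , drop = FALSE]
    al <- graph@aliases
    evidenceGraph(graph@nodes[keep, , drop = FALSE], e,
                  al[al$node_id %in% ids, , drop = FALSE])
}

# ---- writing -------------------------------------------------------------

.fmtScore <- function(s) as.character(as.integer(round(s * 1000)))

.writeSection <- function(edges, channels, firstTwo, path) {
    header <- paste(c(firstTwo, channels, "combined_score"), collapse = " ")
    if (!nrow(edges)) {
        writeLines(header, path)
        return(invisible(path))
    }
    extra <- setdiff(EV_CHANNELS, channels)
    nonrep <- as.matrix(edges[, extra, drop = FALSE])
    if (length(nonrep) && any(nonrep > 0))
        .stopf("edge %s-%s has a nonzero score in a channel not representable in the '%s' dialect",
               edges$u[which(rowSums(nonrep) > 0)[1L]],
               edges$v[which(rowSums(nonrep) > 0)[1L]], firstTwo[1L])
    chMat <- matrix(unlist(lapply(channels,
                                  function(ch) .fmtScore(edges[[ch]]))),
                    nrow = nrow(edges))
    rows <- cbind(edges$u, edges$v, chMat, .fmtScore(edges$combined))
    writeLines(c(header, apply(rows, 1L, paste, collapse = " ")), path)
    invisible(path)
}

#' Write an evidence graph as STITCH/STRING-dialect flat files
#'
#' Produces one file per edge-type section (protein-protein,
#' chemical-protein, chemical-chemical) plus an alias TSV and a small
#' versioned manifest, forming the portable on-disk graph store read back by
#' \code{\link{readEvidenceGraph}}. Scores are re-quantized to the 1/1000
#' grid, so write-then-parse is the identity for graphs already on that grid.
#'
#' @param graph An \linkS4class{EvidenceGraph}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @seealso \code{\link{readEvidenceGraph}}
#' @export
writeFlatFiles <- function(graph, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    kind <- stats::setNames(graph@nodes$kind, graph@nodes$id)
    e <- graph@edges
    ku <- kind[e$u]
    kv <- kind[e$v]
    pp <- e[ku == "protein" & kv == "protein", , drop = FALSE]
    cc <- e[ku == "chemical" & kv == "chemical", , drop = FALSE]
    cp <- e[ku != kv, , drop = FALSE]
    # chemical listed first in the chemical-protein section
    if (nrow(cp)) {
        flip <- kind[cp$u] != "chemical"
        tmp <- cp$u[flip]; cp$u[flip] <- cp$v[flip]; cp$v[flip] <- tmp
        cp <- cp[order(cp$u, cp$v, method = "radix"), , drop = FALSE]
    }
    .writeSection(pp, PROTEIN_CHANNELS, c("protein1", "protein2"),
                  file.path(dir, "protein_links_detailed.txt"))
    .writeSection(cp, CHEMPROT_CHANNELS, c("chemical", "protein"),
                  file.path(dir, "chemical_protein_links_detailed.txt"))
    .writeSection(cc, CHEMCHEM_CHANNELS, c("chemical1", "chemical2"),
                  file.path(dir, "chemical_chemical_links_detailed.txt"))
    al <- graph@aliases[order(graph@aliases$node_id, graph@aliases$alias_type,
                              graph@aliases$alias_value, method = "radix"), ,
                        drop = FALSE]
    utils::write.table(al, file.path(dir, "aliases.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    # isolated nodes never appear in a link file; record them in the manifest
    connected <- unique(c(e$u, e$v))
    iso <- graph@nodes[!(graph@nodes$id %in% connected), , drop = FALSE]
    manifest <- list(format = "evinet-graph-store", version = 1L,
                     isolated_nodes = as.list(stats::setNames(iso$kind,
                                                              iso$id)))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
               file.path(dir, "store.json"))
    invisible(dir)
}

#' Read a graph store written by writeFlatFiles
#'
#' @param dir Directory containing the flat files and manifest.
#' @return An \linkS4class{EvidenceGraph}.
#' @export
readEvidenceGraph <- function(dir) {
    parts <- list()
    pp <- file.path(dir, "protein_links_detailed.txt")
    cp <- file.path(dir, "chemical_protein_links_detailed.txt")
    cc <- file.path(dir, "chemical_chemical_links_detailed.txt")
    if (file.exists(pp)) parts <- c(parts, list(parseProteinLinks(pp)))
    if (file.exists(cp)) parts <- c(parts, list(parseChemicalLinks(cp)))
    if (file.exists(cc))
        parts <- c(parts, list(parseChemicalLinks(cc, "chemical-chemical")))
    if (!length(parts))
        .stopf("no link files found under '%s'", dir)
    g <- mergeGraphs(parts)
    manifestPath <- file.path(dir, "store.json")
    if (file.exists(manifestPath)) {
        manifest <- jsonlite::fromJSON(manifestPath)
        iso <- manifest$isolated_nodes
        if (length(iso)) {
            add <- data.frame(id = names(iso),
                              kind = unlist(iso, use.names = FALSE),
                              stringsAsFactors = FALSE)
            g <- evidenceGraph(rbind(nodes(g), add), edges(g), aliases(g))
        }
    }
    aliasPath <- file.path(dir, "aliases.tsv")
    if (file.exists(aliasPath)) {
        al <- utils::read.table(aliasPath, sep = "\t", header = TRUE,
                                colClasses = "character", quote = "")
        if (nrow(al)) aliases(g) <- al
    }
    g
}

#' Read a chemical alias table
#'
#' TSV with columns \code{node_id}, \code{alias_type}
#' (\code{inchikey}/\code{name}/\code{cid}), \code{alias_value}.
#'
#' @param file Path or connection.
#' @return data.frame suitable for \code{aliases(graph) <- value}.
#' @export
readAliasTable <- function(file) {
    al <- utils::read.table(file, sep = "\t", header = TRUE,
                            colClasses = "character", quote = "")
    need <- c("node_id", "alias_type", "alias_value")
    if (!all(need %in% names(al)))
        .stopf("alias table must have columns: %s", paste(need, collapse = ", "))
    al[, need]
}
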