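# Serialization of evidence networks for interactive viewers:
# Cytoscape.js-style elements JSON and GraphML. Both writers sort elements,
# so identical inputs produce byte-identical output.

.NODE_ROLES <- c("source", "target", "intermediate", "isolated",
                 "neighbor-sensitive", "neighbor-non-sensitive")

.OPACITY_FLOOR <- 0.1

.viewerOpacity <- function(score) pmin(1, pmax(.OPACITY_FLOOR, score))

.nodeKindOr <- function(graph, id, default = "protein") {
    if (is.null(graph)) return(default)
    k <- .nodeKind(graph, id)
    if (is.na(k)) default else k
}

.edgeLink <- function(u, v, template)
    gsub("{v}", v, gsub("{u}", u, template, fixed = TRUE), fixed = TRUE)

#' Export an evidence network as Cytoscape.js elements JSON
#'
#' Produces the graph-JSON shape consumed by Cytoscape.js: a sorted list of
#' node records (id, kind, label, role) and edge records (endpoints,
#' effective score, display opacity, evidence summary, outbound database
#' link). Edge opacity equals the effective score clipped to
#' [0.1, 1] so weakly evidenced edges stay visible. Output is deterministic.
#'
#' @param net An \linkS4class{EvidenceNetwork}.
#' @param annotations Optional \linkS4class{AnnotationTable}; per-edge
#'   descriptions become the \code{evidence} field (the network's own
#'   attached annotations are used otherwise).
#' @param graph Optional master \linkS4class{EvidenceGraph}, used to resolve
#'   node kinds for nodes the network itself cannot classify.
#' @param linkTemplate Template for per-edge outbound links into the public
#'   interaction databases; \code{{u}}/\code{{v}} are replaced by the
#'   endpoint ids.
#' @return A length-1 character vector of JSON text.
#' @examples
#' net <- buildEvidenceNetwork(toy1(), "D", "M", N = 4)
#' doc <- toViewerJSON(net, graph = toy1())
#' validateViewerDocument(doc)
#' @seealso \code{\link{toGraphML}}, \code{\link{validateViewerDocument}}
#' @export
toViewerJSON <- function(net, annotations = NULL, graph = NULL,
        linkTemplate = "https://string-db.org/cgi/link?id={u}&partner={v}") {
    stopifnot(is(net, "EvidenceNetwork"))
    ann <- if (!is.null(annotations)) annotations@entries else net@annotations
    annKey <- paste(ann$u, ann$v, sep = "\t")
    ids <- .radixSort(net@nodes)
    nodeRecs <- lapply(ids, function(id) {
        role <- net@nodeRoles[[id]]
        kind <- if (id %in% net@sources) "chemical" else
            .nodeKindOr(graph, id)
        list(data = list(id = id, kind = kind, label = id, role = role))
    })
    e <- net@edges
    edgeRecs <- lapply(seq_len(nrow(e)), function(i) {
        u <- e$u[i]; v <- e$v[i]
        descr <- ann$description[annKey == paste(u, v, sep = "\t")]
        list(data = list(
            id = paste(u, v, sep = "|"), source = u, target = v,
            score = e$score[i], opacity = .viewerOpacity(e$score[i]),
            evidence = paste(descr, collapse = "; "),
            link = .edgeLink(u, v, linkTemplate)))
    })
    doc <- list(format = "cytoscape-js", version = 1L,
                elements = list(nodes = nodeRecs, edges = edgeRecs))
    as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE))
}

#' Validate a viewer JSON document
#'
#' Checks the document against the schema shipped at
#' \code{system.file("extdata", "viewer-schema.json", package = "evinet")}:
#' element structure, role enum, score/opacity ranges, the opacity floor,
#' and that every edge references an existing node record.
#'
#' @param json JSON text as returned by \code{\link{toViewerJSON}}.
#' @return \code{TRUE} invisibly; otherwise an error describing the first
#'   violation.
#' @export
validateViewerDocument <- function(json) {
    doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
    schemaPath <- system.file("extdata", "viewer-schema.json",
                              package = "evinet")
    schema <- jsonlite::fromJSON(schemaPath, simplifyVector = FALSE)
    .checkSchema(doc, schema, "$")
    nodeIds <- vapply(doc$elements$nodes, function(n) n$data$id, "")
    for (ed in doc$elements$edges) {
        if (!(ed$data$source %in% nodeIds) || !(ed$data$target %in% nodeIds))
            .stopf("edge %s references a missing node record", ed$data$id)
        if (abs(ed$data$opacity - .viewerOpacity(ed$data$score)) > 1e-9)
            .stopf("edge %s: opacity must be score clipped to [0.1, 1]",
                   ed$data$id)
    }
    invisible(TRUE)
}

# Minimal JSON-schema checker covering the keywords the shipped schema uses:
# type, required, properties, items, enum, minimum, maximum.
.checkSchema <- function(x, schema, where) {
    ty <- schema$type
    if (!is.null(ty)) {
        ok <- switch(ty,
            object = is.list(x) && (is.null(names(x)) == (length(x) == 0L) ||
                                    !is.null(names(x))),
            array = is.list(x) && is.null(names(x)),
            string = is.character(x) && length(x) == 1L,
            number = is.numeric(x) && length(x) == 1L,
            integer = is.numeric(x) && length(x) == 1L &&
                x == floor(x),
            TRUE)
        if (!ok) .stopf("schema violation at %s: expected %s", where, ty)
    }
    for (req in schema$required)
        if (!req %in% names(x))
            .stopf("schema violation at %s: missing required '%s'", where, req)
    if (!is.null(schema$enum) && !(x %in% unlist(schema$enum)))
        .stopf("schema violation at %s: '%s' not in enum", where, x)
    if (!is.null(schema$minimum) && is.numeric(x) && x < schema$minimum)
        .stopf("schema violation at %s: %g below minimum", where, x)
    if (!is.null(schema$maximum) && is.numeric(x) && x > schema$maximum)
        .stopf("schema violation at %s: %g above maximum", where, x)
    if (!is.null(schema$properties))
        for (nm in names(schema$properties))
            if (nm %in% names(x))
                .checkSchema(x[[nm]], schema$properties[[nm]],
                             paste0(where, ".", nm))
    if (!is.null(schema$items))
        for (i in seq_along(x))
            .checkSchema(x[[i]], schema$items, sprintf("%s[%d]", where, i))
    invisible(TRUE)
}

#' Export an evidence network as GraphML
#'
#' Standard GraphML with node attributes \code{kind} and \code{role} and
#' edge attributes \code{score} and \code{opacity}; node and edge elements
#' are sorted, so output is deterministic and re-parseable by common graph
#' tools (e.g. igraph's GraphML reader).
#'
#' @inheritParams toViewerJSON
#' @return A length-1 character vector of XML text.
#' @export
toGraphML <- function(net, graph = NULL) {
    stopifnot(is(net, "EvidenceNetwork"))
    doc <- xml2::xml_new_root("graphml",
        xmlns = "http://graphml.graphdrawing.org/xmlns")
    keys <- list(
        c("d_kind", "node", "kind", "string"),
        c("d_role", "node", "role", "string"),
        c("d_score", "edge", "score", "double"),
        c("d_opacity", "edge", "opacity", "double"))
    for (k in keys)
        xml2::xml_add_child(doc, "key", id = k[1L], "for" = k[2L],
                            "attr.name" = k[3L], "attr.type" = k[4L])
    gr <- xml2::xml_add_child(doc, "graph", id = "eviNet",
                              edgedefault = "undirected")
    for (id in .radixSort(net@nodes)) {
        nd <- xml2::xml_add_child(gr, "node", id = id)
        kind <- if (id %in% net@sources) "chemical" else .nodeKindOr(graph, id)
        xml2::xml_add_child(nd, "data", kind, key = "d_kind")
        xml2::xml_add_child(nd, "data", net@nodeRoles[[id]], key = "d_role")
    }
    e <- net@edges
    for (i in seq_len(nrow(e))) {
        ed <- xml2::xml_add_child(gr, "edge", source = e$u[i],
                                  target = e$v[i])
        xml2::xml_add_child(ed, "data", format(e$score[i], digits = 15),
                            key = "d_score")
        xml2::xml_add_child(ed, "data",
                            format(.viewerOpacity(e$score[i]), digits = 15),
                            key = "d_opacity")
    }
    as.character(doc)
}

#' Write network exports to files
#'
#' @param net An \linkS4class{EvidenceNetwork}.
#' @param file Output path.
#' @param ... Passed to \code{\link{toViewerJSON}} / \code{\link{toGraphML}}.
#' @return \code{file}, invisibly.
#' @rdname writeViewerJSON
#' @export
writeViewerJSON <- function(net, file, ...) {
    writeLines(toViewerJSON(net, ...), file)
    invisible(file)
}

#' @rdname writeViewerJSON
#' @export
writeGraphML <- function(net, file, ...) {
    writeLines(toGraphML(net, ...), file)
    invisible(file)
}
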