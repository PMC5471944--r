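#' @rdname EvidenceGraph-accessors
#' @export
setGeneric("nodes", function(x, ...) standardGeneric("nodes"))

#' @rdname EvidenceGraph-accessors
#' @export
setGeneric("edges", function(x, ...) standardGeneric("edges"))

#' @rdname EvidenceGraph-accessors
#' @export
setGeneric("aliases", function(x) standardGeneric("aliases"))

#' @rdname EvidenceGraph-accessors
#' @export
setGeneric("aliases<-", function(x, value) standardGeneric("aliases<-"))

#' @rdname EvidenceGraph-accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname EvidenceGraph-accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname EvidenceGraph-accessors
#' @export
setGeneric("chemicalNodes", function(x) standardGeneric("chemicalNodes"))

#' @rdname EvidenceGraph-accessors
#' @export
setGeneric("proteinNodes", function(x) standardGeneric("proteinNodes"))

#' @rdname hasEdge
#' @export
setGeneric("hasEdge", function(x, u, v) standardGeneric("hasEdge"))

#' @rdname hasEdge
#' @export
setGeneric("getEdge", function(x, u, v) standardGeneric("getEdge"))

#' @rdname nextShortest
#' @export
setGeneric("nextShortest", function(session) standardGeneric("nextShortest"))

#' @rdname loadAnnotations
#' @export
setGeneric("annotationsFor", function(x, u, v)
    standardGeneric("annotationsFor"))

#' @rdname WeightedPath-accessors
#' @export
setGeneric("pathNodes", function(x) standardGeneric("pathNodes"))

#' @rdname WeightedPath-accessors
#' @export
setGeneric("totalWeight", function(x) standardGeneric("totalWeight"))

#' @rdname WeightedPath-accessors
#' @export
setGeneric("edgeScores", function(x) standardGeneric("edgeScores"))

#' @rdname EvidenceNetwork-accessors
#' @export
setGeneric("networkPaths", function(x) standardGeneric("networkPaths"))

#' @rdname EvidenceNetwork-accessors
#' @export
setGeneric("isolatedNodes", function(x) standardGeneric("isolatedNodes"))

#' @rdname EvidenceNetwork-accessors
#' @export
setGeneric("nodeRoles", function(x) standardGeneric("nodeRoles"))

#' @rdname EvidenceNetwork-accessors
#' @export
setGeneric("stopReason", function(x) standardGeneric("stopReason"))
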