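#' @import methods
NULL

.NODE_KINDS <- c("protein", "chemical")

#' EvidenceGraph: a heterogeneous chemical-protein interaction graph
#'
#' Undirected graph whose nodes are proteins (e.g. \code{"9606.ENSP..."}) or
#' chemicals (e.g. \code{"CIDm00000001"}) and whose edges carry per-channel
#' evidence scores in [0,1] plus the database's reported combined score.
#' Edge rows are order-normalized (\code{u < v} in C-locale byte order) and
#' deduplicated, so the pair (u,v) appears at most once.
#'
#' @slot nodes data.frame with columns \code{id}, \code{kind}.
#' @slot edges data.frame with columns \code{u}, \code{v}, one numeric column
#'   per \code{\link{evidenceChannels}}, and \code{combined}.
#' @slot aliases data.frame with columns \code{node_id}, \code{alias_type},
#'   \code{alias_value} (e.g. InChIKey entries used for chemical matching).
#' @aliases EvidenceGraph
#' @exportClass EvidenceGraph
setClass("EvidenceGraph",
    representation(nodes = "data.frame", edges = "data.frame",
                   aliases = "data.frame"),
    prototype(
        nodes = data.frame(id = character(), kind = character(),
                           stringsAsFactors = FALSE),
        edges = local({
            df <- data.frame(u = character(), v = character(),
                             stringsAsFactors = FALSE)
            for (ch in c("neighborhood", "fusion", "cooccurence",
                         "coexpression", "experimental", "database",
                         "textmining", "prediction", "similarity"))
                df[[ch]] <- numeric()
            df$combined <- numeric()
            df
        }),
        aliases = data.frame(node_id = character(), alias_type = character(),
                             alias_value = character(),
                             stringsAsFactors = FALSE)))

setValidity("EvidenceGraph", function(object) {
    n <- object@nodes
    e <- object@edges
    msgs <- character()
    if (!all(c("id", "kind") %in% names(n)))
        return("nodes must have columns id, kind")
    if (anyDuplicated(n$id))
        msgs <- c(msgs, "duplicate node ids")
    if (any(!nzchar(n$id)))
        msgs <- c(msgs, "empty node id")
    if (!all(n$kind %in% .NODE_KINDS))
        msgs <- c(msgs, "node kind must be 'protein' or 'chemical'")
    # Real STITCH chemical ids start with "CID"; such ids must be chemicals.
    # (Synthetic fixtures may tag other ids as chemicals explicitly.)
    if (any(startsWith(n$id, "CID") & n$kind != "chemical"))
        msgs <- c(msgs, "CID-prefixed node ids must have kind 'chemical'")
    need <- c("u", "v", EV_CHANNELS, "combined")
    if (!all(need %in% names(e)))
        return(paste("edges must have columns:", paste(need, collapse = ", ")))
    if (nrow(e)) {
        if (!all(c(e$u, e$v) %in% n$id))
            msgs <- c(msgs, "edge endpoint not in node set")
        if (any(e$u == e$v))
            msgs <- c(msgs, "self-loop edge present")
        sc <- as.matrix(e[, c(EV_CHANNELS, "combined")])
        if (any(is.na(sc)) || any(sc < 0) || any(sc > 1))
            msgs <- c(msgs, "edge scores must be in [0,1]")
        p <- .normalizePairs(e$u, e$v)
        if (any(p$swapped))
            msgs <- c(msgs, "edges not order-normalized (u < v expected)")
        if (anyDuplicated(paste(e$u, e$v, sep = "\t")))
            msgs <- c(msgs, "duplicate undirected edge")
    }
    if (!all(c("node_id", "alias_type", "alias_value") %in%
             names(object@aliases)))
        msgs <- c(msgs, "aliases must have columns node_id, alias_type, alias_value")
    if (length(msgs)) msgs else TRUE
})

#' ChannelWeights: per-channel multipliers for edge re-scoring
#'
#' Multipliers in [0,1] applied to channel sub-scores before recombination.
#' Presets mirror the interactive portal settings: \code{"NONE"} = 0,
#' \code{"LOW"} = 0.5, \code{"DEFAULT"} = 1. With every multiplier at 1 the
#' database's reported combined score is used unchanged; otherwise the
#' effective score is the noisy-OR recombination
#' \eqn{S = 1 - \prod_c (1 - m_c s_c)} over channels present on the edge.
#'
#' @slot multipliers Named numeric vector over all evidence channels.
#' @aliases ChannelWeights
#' @exportClass ChannelWeights
setClass("ChannelWeights", representation(multipliers = "numeric"))

setValidity("ChannelWeights", function(object) {
    m <- object@multipliers
    if (!identical(sort(names(m)), sort(EV_CHANNELS)))
        return("multipliers must be named with exactly the evidence channels")
    if (any(is.na(m)) || any(m < 0) || any(m > 1))
        return("multipliers must lie in [0,1]")
    TRUE
})

#' WeightedPath: a loopless path with its evidence weight
#'
#' @slot nodes Ordered character vector of node ids; consecutive nodes are
#'   adjacent in the graph the path was computed on, and no node repeats.
#' @slot totalWeight Sum of per-edge weights \eqn{w = 1 - S}.
#' @slot edgeScores Effective score S of each edge, in path order.
#' @aliases WeightedPath
#' @exportClass WeightedPath
setClass("WeightedPath",
    representation(nodes = "character", totalWeight = "numeric",
                   edgeScores = "numeric"))

setValidity("WeightedPath", function(object) {
    if (anyDuplicated(object@nodes))
        return("path revisits a node")
    if (length(object@edgeScores) != max(0L, length(object@nodes) - 1L))
        return("edgeScores length must be (number of nodes) - 1")
    if (length(object@totalWeight) != 1L || is.na(object@totalWeight) ||
        object@totalWeight < -1e-12)
        return("totalWeight must be a single nonnegative number")
    if (length(object@edgeScores) &&
        abs(object@totalWeight - sum(1 - object@edgeScores)) > 1e-9)
        return("totalWeight must equal sum of (1 - S) over edges")
    TRUE
})

#' AnnotationTable: free-text evidence descriptions per edge
#'
#' Keys are order-normalized node pairs; several descriptions may accumulate
#' for one pair. Stands in for the evidence-description database the public
#' STITCH/STRING distributions ship separately.
#'
#' @slot entries data.frame with columns \code{u}, \code{v},
#'   \code{description}.
#' @aliases AnnotationTable
#' @exportClass AnnotationTable
setClass("AnnotationTable", representation(entries = "data.frame"),
    prototype(entries = data.frame(u = character(), v = character(),
                                   description = character(),
                                   stringsAsFactors = FALSE)))

setValidity("AnnotationTable", function(object) {
    e <- object@entries
    if (!all(c("u", "v", "description") %in% names(e)))
        return("entries must have columns u, v, description")
    if (nrow(e) && any(.normalizePairs(e$u, e$v)$swapped))
        return("entries not order-normalized")
    TRUE
})

#' EvidenceNetwork: the merged best-evidence sub-network for a query
#'
#' Result of iterative shortest-path accumulation between source chemical(s)
#' and a target mediator, possibly augmented with DDN neighbors and induced
#' master-graph edges (pathway-weighted form).
#'
#' @slot sources Chemical node ids the paths start from (empty only for an
#'   empty-path single-source query).
#' @slot target The mediator node id.
#' @slot paths List of \linkS4class{WeightedPath}, in acceptance order.
#' @slot nodes All node ids in the network.
#' @slot edges data.frame with columns \code{u}, \code{v}, \code{score}
#'   (effective score under the weights the network was built with).
#' @slot isolatedNodes Nodes retained without any connecting path (e.g. DDN
#'   neighbors that could not be linked to the drug).
#' @slot nodeRoles Named character vector: role per node, one of
#'   \code{source}, \code{target}, \code{intermediate}, \code{isolated},
#'   \code{neighbor-sensitive}, \code{neighbor-non-sensitive}.
#' @slot annotations data.frame (\code{u}, \code{v}, \code{description}) of
#'   evidence descriptions attached to edges of this network.
#' @slot stopReason Why path accumulation stopped: \code{"n_reached"},
#'   \code{"exhausted"} or \code{"no_path"}.
#' @aliases EvidenceNetwork
#' @exportClass EvidenceNetwork
setClass("EvidenceNetwork",
    representation(sources = "character", target = "character",
                   paths = "list", nodes = "character",
                   edges = "data.frame", isolatedNodes = "character",
                   nodeRoles = "character", annotations = "data.frame",
                   stopReason = "character"))

setValidity("EvidenceNetwork", function(object) {
    msgs <- character()
    if (length(object@target) != 1L)
        return("target must be a single node id")
    e <- object@edges
    if (!all(c("u", "v", "score") %in% names(e)))
        return("edges must have columns u, v, score")
    if (nrow(e) && !all(c(e$u, e$v) %in% object@nodes))
        msgs <- c(msgs, "edge endpoint not in network nodes")
    for (p in object@paths) {
        if (length(object@sources) && !(p@nodes[1L] %in% object@sources))
            msgs <- c(msgs, "path does not start at a source")
        if (!all(p@nodes %in% object@nodes))
            msgs <- c(msgs, "path node missing from network nodes")
    }
    if (!all(object@isolatedNodes %in% object@nodes))
        msgs <- c(msgs, "isolated node missing from network nodes")
    if (length(msgs)) unique(msgs) else TRUE
})

#' DDNContext: a mediator's direct neighbors in a differential dependency
#' network
#'
#' Neighbors come from the condition-specific dependency networks estimated
#' separately for drug-sensitive and non-sensitive samples; each is labeled
#' \code{sensitive}, \code{non_sensitive} (specific to one condition) or
#' \code{shared}.
#'
#' @slot mediator The mediator node id (or gene symbol before mapping).
#' @slot neighbors data.frame with columns \code{id}, \code{condition}.
#' @aliases DDNContext
#' @exportClass DDNContext
setClass("DDNContext",
    representation(mediator = "character", neighbors = "data.frame"))

.DDN_CONDITIONS <- c("sensitive", "non_sensitive", "shared")

setValidity("DDNContext", function(object) {
    nb <- object@neighbors
    if (length(object@mediator) != 1L || !nzchar(object@mediator))
        return("mediator must be a single non-empty id")
    if (!all(c("id", "condition") %in% names(nb)))
        return("neighbors must have columns id, condition")
    if (object@mediator %in% nb$id)
        return("mediator must not appear in its own neighbor list")
    if (nrow(nb) && !all(nb$condition %in% .DDN_CONDITIONS))
        return("neighbor condition must be sensitive, non_sensitive or shared")
    TRUE
})

#' ChemicalRecord: normalized chemical identity
#'
#' @slot inputSmiles SMILES as given.
#' @slot desaltedSmiles Largest fragment after salt stripping.
#' @slot inchikey 27-character InChIKey (14-10-1 hyphenated blocks).
#' @slot connectivityBlock First 14 characters of the InChIKey; encodes
#'   connectivity only, hence stereo-independent.
#' @aliases ChemicalRecord
#' @exportClass ChemicalRecord
setClass("ChemicalRecord",
    representation(inputSmiles = "character", desaltedSmiles = "character",
                   inchikey = "character", connectivityBlock = "character"))

setValidity("ChemicalRecord", function(object) {
    if (!grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", object@inchikey))
        return("inchikey must match the 14-10-1 uppercase hyphenated format")
    if (!identical(object@connectivityBlock, substr(object@inchikey, 1L, 14L)))
        return("connectivityBlock must equal the first 14 inchikey characters")
    TRUE
})

#' PathSession: incremental "Next Shortest" exploration state
#'
#' Holds the state of an in-progress K-shortest-paths enumeration for one
#' (graph, drug, mediator, weights) query so paths can be pulled one at a
#' time with \code{\link{nextShortest}}.
#'
#' @slot drug,mediator Query endpoints.
#' @slot state Environment holding enumeration internals.
#' @aliases PathSession
#' @exportClass PathSession
setClass("PathSession",
    representation(drug = "character", mediator = "character",
                   state = "environment"))

#' FixtureSpec: parameters for the synthetic flat-file generator
#'
#' @slot nProteins,nChemicals Node counts.
#' @slot edgeDensity Probability in [0,1] that any admissible pair gets an
#'   edge.
#' @slot scoreDistribution List of per-channel sampling parameters; see
#'   \code{\link{fixtureSpec}}.
#' @slot seed Integer seed; the same (spec, seed) yields byte-identical files.
#' @aliases FixtureSpec
#' @exportClass FixtureSpec
setClass("FixtureSpec",
    representation(nProteins = "integer", nChemicals = "integer",
                   edgeDensity = "numeric", scoreDistribution = "list",
                   seed = "integer"))

setValidity("FixtureSpec", function(object) {
    if (object@nProteins < 0L || object@nChemicals < 0L)
        return("node counts must be nonnegative")
    if (object@edgeDensity < 0 || object@edgeDensity > 1)
        return("edgeDensity must be in [0,1]")
    TRUE
})
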