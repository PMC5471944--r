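#' Load an edge-evidence annotation table
#'
#' Reads a 3-column delimited file (node-id-1, node-id-2, description) into
#' an \linkS4class{AnnotationTable}. Pair keys are order-normalized, so rows
#' for (A,B) and (B,A) accumulate under one undirected key.
#'
#' @param file Path or connection; tab-separated, UTF-8, no header.
#' @return An \linkS4class{AnnotationTable}.
#' @examples
#' tab <- loadAnnotations(textConnection(
#'     "9606.A\t9606.B\tcoexpression in liver"))
#' annotationsFor(tab, "9606.B", "9606.A")
#' @name loadAnnotations
#' @export
loadAnnotations <- function(file) {
    lines <- if (inherits(file, "connection")) readLines(file) else
        readLines(file)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(new("AnnotationTable"))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(fields) != 3L
    if (any(bad))
        .stopf("annotation table: line %d has %d columns, expected 3",
               which(bad)[1L], lengths(fields)[which(bad)[1L]])
    u <- vapply(fields, `[[`, "", 1L)
    v <- vapply(fields, `[[`, "", 2L)
    p <- .normalizePairs(u, v)
    entries <- data.frame(u = p$u, v = p$v,
                          description = vapply(fields, `[[`, "", 3L),
                          stringsAsFactors = FALSE)
    entries <- entries[order(entries$u, entries$v, method = "radix"), ,
                       drop = FALSE]
    rownames(entries) <- NULL
    new("AnnotationTable", entries = entries)
}

#' @describeIn loadAnnotations Descriptions recorded for an undirected pair;
#'   a pair absent from the table yields \code{character(0)}, not an error.
#' @param x An \linkS4class{AnnotationTable}.
#' @param u,v Node ids (order-insensitive).
#' @export
setMethod("annotationsFor", "AnnotationTable", function(x, u, v) {
    key <- .edgeKey(u, v)
    e <- x@entries
    e$description[paste(e$u, e$v, sep = "\t") == key]
})

setMethod("show", "AnnotationTable", function(object) {
    cat(sprintf("AnnotationTable: %d description(s) over %d pair(s)\n",
                nrow(object@entries),
                length(unique(paste(object@entries$u, object@entries$v)))))
    invisible(NULL)
})

# Subset of annotations touching a set of undirected edges (u/v columns).
.annotationsForEdges <- function(annotations, edgeDf) {
    if (is.null(annotations) || !nrow(annotations@entries) || !nrow(edgeDf))
        return(new("AnnotationTable")@entries)
    keys <- paste(edgeDf$u, edgeDf$v, sep = "\t")
    e <- annotations@entries
    e[paste(e$u, e$v, sep = "\t") %in% keys, , drop = FALSE]
}
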