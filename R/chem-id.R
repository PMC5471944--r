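# Chemical identifier normalization: salt stripping, InChIKey hashing,
# connectivity-block matching against graph aliases.
#
# The cheminformatics backend sits behind a four-function interface
# (canonicalize, fragment split, heavy-atom count, standard InChIKey) so the
# rest of the package never loads chemistry machinery. The default backend
# shells out to Open Babel's `obabel`; a different toolkit can be plugged in
# via options(evinet.chem_backend = <list of functions>).

#' Is a chemistry backend available?
#'
#' @return \code{TRUE} when InChIKey generation is possible (by default:
#'   \code{obabel} found on the PATH).
#' @export
hasChemistryBackend <- function() {
    be <- getOption("evinet.chem_backend", NULL)
    if (!is.null(be)) return(TRUE)
    nzchar(Sys.which("obabel"))
}

.chemBackend <- function() {
    be <- getOption("evinet.chem_backend", NULL)
    if (!is.null(be)) return(be)
    if (!nzchar(Sys.which("obabel")))
        .stopf("no chemistry backend: obabel not found on PATH")
    list(canonicalize = .obCanonical,
         fragments = .smilesFragments,
         heavyAtoms = .obHeavyAtoms,
         inchikey = .obInChIKey)
}

.obabel <- function(smiles, outFormat, extraArgs = character()) {
    out <- suppressWarnings(system2("obabel",
        c("-ismi", paste0("-o", outFormat), extraArgs),
        input = smiles, stdout = TRUE, stderr = FALSE))
    out <- trimws(out)
    out <- out[nzchar(out)]
    if (!length(out))
        .stopf("chemistry error: cannot parse SMILES '%s'", smiles)
    out[1L]
}

.obCanonical <- function(smiles) {
    # 'can' output is "SMILES\t<title>"; keep the first field
    strsplit(.obabel(smiles, "can"), "[ \t]")[[1L]][1L]
}

.obInChIKey <- function(smiles) .obabel(smiles, "inchikey")

# Heavy atoms from the InChI formula layer: sum of non-hydrogen element
# counts (e.g. C2H4O2 -> 4, ClH -> 1, Na -> 1).
.obHeavyAtoms <- function(smiles) {
    inchi <- .obabel(smiles, "inchi")
    formula <- strsplit(inchi, "/", fixed = TRUE)[[1L]][2L]
    if (is.na(formula)) return(0L)  # e.g. bare proton
    total <- 0L
    for (part in strsplit(formula, ".", fixed = TRUE)[[1L]]) {
        toks <- regmatches(part, gregexpr("[A-Z][a-z]?[0-9]*", part))[[1L]]
        for (tok in toks) {
            el <- sub("[0-9]*$", "", tok)
            cnt <- sub("^[A-Za-z]+", "", tok)
            cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
            if (el != "H") total <- total + cnt
        }
    }
    total
}

# SMILES dot-disconnection: "." never occurs inside brackets, so a plain
# split yields the fragments.
.smilesFragments <- function(smiles) strsplit(smiles, ".", fixed = TRUE)[[1L]]

#' Strip salts/counterions from a SMILES string
#'
#' Multi-fragment (dot-separated) SMILES are reduced to the fragment with
#' the greatest heavy-atom count — the standard desalting convention under
#' which all salt forms of a compound coincide. Ties go to the
#' lexicographically smallest canonical fragment, so the result is
#' deterministic.
#'
#' @param smiles A SMILES string, possibly multi-fragment.
#' @return Single-fragment SMILES.
#' @examples
#' \dontrun{
#' stripSalts("CCO.Cl")             # "CCO"
#' stripSalts("[Na+].CC(=O)[O-]")   # "CC(=O)[O-]"
#' }
#' @export
stripSalts <- function(smiles) {
    stopifnot(is.character(smiles), length(smiles) == 1L)
    be <- .chemBackend()
    frags <- be$fragments(smiles)
    if (length(frags) == 1L) {
        be$heavyAtoms(frags)   # validates parsability
        return(frags)
    }
    counts <- vapply(frags, be$heavyAtoms, integer(1L))
    top <- frags[counts == max(counts)]
    if (length(top) == 1L) return(top)
    canon <- vapply(top, be$canonicalize, character(1L))
    top[order(canon, method = "radix")][1L]
}

#' Hash a SMILES string into a ChemicalRecord
#'
#' Desalts the input, optionally removes stereo descriptors, and computes the
#' standard InChIKey. With \code{stereo = "strip"} (the default used for
#' matching), stereoisomers share a key; independently, the first 14
#' characters of any InChIKey (the connectivity block) are already
#' stereo-agnostic, and \code{\link{matchChemical}} matches on that block.
#'
#' @param smiles A SMILES string.
#' @param stereo \code{"keep"} or \code{"strip"}.
#' @return A \linkS4class{ChemicalRecord}.
#' @examples
#' \dontrun{
#' toInChIKey("CCO")@inchikey   # "LFQSCWFLJHTTHZ-UHFFFAOYSA-N"
#' }
#' @export
toInChIKey <- function(smiles, stereo = c("strip", "keep")) {
    stereo <- match.arg(stereo)
    be <- .chemBackend()
    desalted <- stripSalts(smiles)
    keyInput <- if (stereo == "strip") .stripStereoSmiles(desalted) else
        desalted
    key <- be$inchikey(keyInput)
    rec <- new("ChemicalRecord", inputSmiles = smiles,
               desaltedSmiles = desalted, inchikey = key,
               connectivityBlock = substr(key, 1L, 14L))
    validObject(rec)
    rec
}

# Remove stereo descriptors: tetrahedral marks (@, @@) and double-bond
# direction bonds (/ and \, which revert to plain single bonds).
.stripStereoSmiles <- function(smiles) gsub("[@/\\\\]", "", smiles)

#' Match a drug SMILES to a chemical node
#'
#' Normalizes the query (desalting + stereo-agnostic InChIKey) and matches
#' its 14-character connectivity block against \code{inchikey} entries of the
#' graph's alias table — consistent with the merged (CIDm) chemical ids,
#' which also collapse stereoisomers and salt forms.
#'
#' @param smiles Query SMILES.
#' @param graph An \linkS4class{EvidenceGraph} whose alias table holds
#'   InChIKey entries (\code{alias_type == "inchikey"}).
#' @return The matched node id, or \code{NA_character_} when not found
#'   (not-found is a value, not an error).
#' @export
matchChemical <- function(smiles, graph) {
    rec <- toInChIKey(smiles, stereo = "strip")
    al <- graph@aliases
    keys <- al[al$alias_type == "inchikey", , drop = FALSE]
    hit <- keys$node_id[substr(keys$alias_value, 1L, 14L) ==
                        rec@connectivityBlock]
    if (!length(hit)) return(NA_character_)
    hit <- .radixSort(unique(hit))
    if (length(hit) > 1L)
        .log("warning", "connectivity block %s matches %d nodes; taking %s",
             rec@connectivityBlock, length(hit), hit[1L])
    hit[1L]
}

setMethod("show", "ChemicalRecord", function(object) {
    cat(sprintf("ChemicalRecord: %s\n  desalted: %s\n  inchikey: %s\n",
                object@inputSmiles, object@desaltedSmiles, object@inchikey))
    invisible(NULL)
})
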