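# Evidence-channel vocabulary. STRING protein links and STITCH chemical links
# carry different channel subsets; the union below is the in-memory schema.
# "cooccurence" keeps the databases' historical spelling.
EV_CHANNELS <- c("neighborhood", "fusion", "cooccurence", "coexpression",
                 "experimental", "database", "textmining", "prediction",
                 "similarity")

PROTEIN_CHANNELS  <- c("neighborhood", "fusion", "cooccurence", "coexpression",
                       "experimental", "database", "textmining")
CHEMPROT_CHANNELS <- c("experimental", "prediction", "database", "textmining")
CHEMCHEM_CHANNELS <- c("similarity", "experimental", "prediction", "database",
                       "textmining")

#' Evidence channel names
#'
#' The union vocabulary of evidence channels used across the supported
#' STRING/STITCH flat-file dialects. Protein-protein edges use the seven
#' STRING channels; chemical-protein edges use
#' \{experimental, prediction, database, textmining\}; chemical-chemical edges
#' add \code{similarity}.
#'
#' @return Character vector of channel names.
#' @examples
#' evidenceChannels()
#' @export
evidenceChannels <- function() EV_CHANNELS
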