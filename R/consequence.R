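#' @keywords internal
consequence_levels <- c("LOF", "MISSENSE", "INFRAME_INDEL", "OTHER")

# Sequence-Ontology term -> consequence class. The LOF list is exactly the six
# loss-of-function categories used for candidate selection: stop gained, stop
# lost, start lost, splice acceptor, splice donor, frameshift.
so_class_map <- c(
  frameshift_variant      = "LOF",
  stop_gained             = "LOF",
  stop_lost               = "LOF",
  start_lost              = "LOF",
  splice_acceptor_variant = "LOF",
  splice_donor_variant    = "LOF",
  missense_variant        = "MISSENSE",
  inframe_insertion       = "INFRAME_INDEL",
  inframe_deletion        = "INFRAME_INDEL"
)

#' Classify a Sequence-Ontology consequence term
#'
#' Maps VEP-style consequence strings onto the four classes used throughout
#' the pipeline: `LOF` (stop gained/lost, start lost, splice acceptor/donor,
#' frameshift), `MISSENSE`, `INFRAME_INDEL`, and `OTHER`. Compound
#' annotations (terms joined with `&` or `,`, as VEP emits) take the most
#' severe class, ordered LOF > MISSENSE > INFRAME_INDEL > OTHER. Unknown
#' terms fall through to `OTHER`.
#'
#' @param raw_term Character vector of Sequence-Ontology-style terms.
#' @return Character vector of classes (one of
#'   `r paste(consequence_levels, collapse = ", ")`).
#' @examples
#' classify_consequence(c("stop_gained", "missense_variant&splice_region_variant"))
#' @export
classify_consequence <- function(raw_term) {
  if (any(!nzchar(raw_term) | is.na(raw_term))) {
    stop("consequence terms must be non-empty strings", call. = FALSE)
  }
  vapply(strsplit(raw_term, "[&,]"), function(terms) {
    cls <- so_class_map[trimws(terms)]
    cls[is.na(cls)] <- "OTHER"
    consequence_levels[min(match(cls, consequence_levels))]
  }, character(1))
}
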