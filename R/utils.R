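# Internal helpers shared across modules.

# Closed vocabulary of signaling interaction types. GErel types (expression,
# repression) are parsed but removed during refinement to avoid redundancy
# with the regulatory layer; "unknown" marks relations without a usable
# subtype and is removed during refinement too.
kegg_relation_types <- function() {
  c(
    "activation", "binding/association", "compound", "dephosphorylation",
    "dissociation", "expression", "indirect effect", "inhibition",
    "phosphorylation", "repression", "state change", "ubiquitination",
    "within_group", "ppi"
  )
}

# Subtypes represented as undirected interactions. Everything else keeps the
# KGML entry1 -> entry2 direction.
undirected_relation_types <- function() {
  c("binding/association", "dissociation", "within_group", "ppi")
}

#' Default mapping from interaction type to signaling layer index
#'
#' Signaling components of multilinks are integers `S` in `[0, 11]`, with
#' `S = 0` reserved for "no signaling edge". The default assignment covers the
#' eleven interaction types of the refined signaling layer; `within_group`
#' edges (complete graphs over disaggregated gene groups) map to the
#' binding/association index, reflecting their physical-association meaning.
#'
#' @return Named integer vector mapping type name to layer index in `[1, 11]`.
#' @export
default_type_index <- function() {
  c(
    "activation"          = 1L,
    "binding/association" = 2L,
    "within_group"        = 2L,
    "compound"            = 3L,
    "dephosphorylation"   = 4L,
    "dissociation"        = 5L,
    "indirect effect"     = 6L,
    "inhibition"          = 7L,
    "phosphorylation"     = 8L,
    "ppi"                 = 9L,
    "state change"        = 10L,
    "ubiquitination"      = 11L
  )
}

# Layer labels by S index (1..11), plus the collapsed and regulatory layers.
layer_labels <- function() {
  c(
    "activation", "binding_association", "compound", "dephosphorylation",
    "dissociation", "indirect_effect", "inhibition", "phosphorylation",
    "ppi", "state_change", "ubiquitination"
  )
}

# Ordered-position key for (from, to) pairs in an n-node index space.
# Doubles are exact for the sizes handled here (n * n < 2^53).
pair_key <- function(from, to, n) {
  (as.numeric(from) - 1) * n + as.numeric(to)
}

# Unordered variant: key of the (min, max) orientation.
upair_key <- function(from, to, n) {
  pair_key(pmin(from, to), pmax(from, to), n)
}

# Stable, platform-independent polynomial hash of a string, in [0, 2^31 - 2].
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% m
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a
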