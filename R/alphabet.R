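#' The 20 canonical amino-acid one-letter codes
#'
#' Alphabetical order; this is the alphabet over which column frequencies
#' and Schneider entropy are defined.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHAR <- "-"

#' @keywords internal
is_canonical_seq <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  all(chars %in% AA_STANDARD)
}

#' @keywords internal
noncanonical_letters <- function(seq) {
  chars <- unique(strsplit(seq, "", fixed = TRUE)[[1]])
  setdiff(chars, AA_STANDARD)
}
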