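#' The seven-group reduced amino-acid alphabet
#'
#' The 20 standard amino acids clustered into seven classes by the dipole and
#' volume of their side chains, the grouping commonly used for conjoint-triad
#' and CTD-style sequence descriptors. Residues in the same class are treated
#' as interchangeable by every descriptor in this package.
#'
#' @return A named integer vector of length 20 mapping one-letter residue
#'   codes to group indices 1-7: `{A,G,V}=1`, `{C}=2`, `{M,S,T,Y}=3`,
#'   `{F,I,L,P}=4`, `{H,N,Q,W}=5`, `{K,R}=6`, `{D,E}=7`.
#' @examples
#' group_alphabet()[c("A", "E")]
#' @export
group_alphabet <- function() {
  c(
    A = 1L, G = 1L, V = 1L,
    C = 2L,
    M = 3L, S = 3L, T = 3L, Y = 3L,
    F = 4L, I = 4L, L = 4L, P = 4L,
    H = 5L, N = 5L, Q = 5L, W = 5L,
    K = 6L, R = 6L,
    D = 7L, E = 7L
  )
}

#' Encode an amino-acid sequence in the seven-group alphabet
#'
#' Replaces every residue by its physicochemical group index (see
#' [group_alphabet()]). This is the first step of MLD featurization; all
#' downstream composition/transition/distribution statistics are computed on
#' the group codes, never on the raw residues.
#'
#' @param seq A single amino-acid string over the 20 standard one-letter
#'   codes (case-insensitive).
#' @param alphabet Named integer vector mapping residues to groups; defaults
#'   to [group_alphabet()].
#' @return An integer vector of group codes in 1-7, one per residue.
#' @examples
#' paste(group_encode("GGYCCCYYGYYYGCCGGYYGCG"), collapse = "")
#' @export
group_encode <- function(seq, alphabet = group_alphabet()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) {
    abort("cannot group-encode an empty sequence", class = "mldppi_error_validation")
  }
  codes <- unname(alphabet[chars])
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    abort(
      sprintf("unmapped residue '%s' at position %d", chars[bad], bad),
      class = "mldppi_error_validation"
    )
  }
  codes
}
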