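# Composition / transition / distribution statistics over group-encoded
# regions. All values are percentages on the 0-100 scale. The number of
# groups is fixed at 7 by the reduced alphabet.

N_GROUPS <- 7L

# Unordered group pairs in the fixed reporting order (1,2),(1,3),...,(6,7),
# and the descriptor names, computed once at load time.
GROUP_PAIRS <- local({
  p <- utils::combn(N_GROUPS, 2L)
  list(g = p[1, ], h = p[2, ], key = (p[1, ] - 1L) * N_GROUPS + p[2, ])
})
CTD_NAMES <- local({
  d <- as.vector(t(outer(seq_len(N_GROUPS), c("first", "25", "50", "75", "100"),
                         function(g, m) paste0("D", g, ".", m))))
  list(
    composition = paste0("C", seq_len(N_GROUPS)),
    transition = paste0("T", GROUP_PAIRS$g, ".", GROUP_PAIRS$h),
    distribution = d
  )
})

group_pairs <- function() {
  tibble(g = GROUP_PAIRS$g, h = GROUP_PAIRS$h)
}

# Unnamed fast paths used by the encoder's inner loop.
composition_raw <- function(codes) {
  100 * tabulate(codes, nbins = N_GROUPS) / length(codes)
}

transition_raw <- function(codes) {
  L <- length(codes)
  if (L == 1L) {
    return(numeric(length(GROUP_PAIRS$key)))
  }
  a <- codes[-L]
  b <- codes[-1]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  hetero <- lo != hi
  key <- (lo - 1L) * N_GROUPS + hi
  counts <- tabulate(match(key[hetero], GROUP_PAIRS$key),
                     nbins = length(GROUP_PAIRS$key))
  100 * counts / (L - 1L)
}

DIST_Q <- c(0.25, 0.5, 0.75, 1.0)

distribution_raw <- function(codes) {
  L <- length(codes)
  out <- numeric(5L * N_GROUPS)
  for (g in seq_len(N_GROUPS)) {
    pos <- which(codes == g)
    n <- length(pos)
    if (n > 0L) {
      # small epsilon guards floor() against binary representation of q * n
      idx <- c(1L, pmax(1L, as.integer(DIST_Q * n + 1e-9)))
      out[(5L * (g - 1L) + 1L):(5L * g)] <- 100 * pos[idx] / L
    }
  }
  out
}

#' Composition descriptor
#'
#' Percentage of region residues falling in each of the seven groups:
#' `C[g] = 100 * count(g) / region_length`. Sums to 100 for any non-empty
#' region.
#'
#' @param codes Integer vector of group codes (1-7) for one region.
#' @return Named numeric vector of 7 percentages (`C1`..`C7`).
#' @examples
#' composition(group_encode("GGYCCCYYGYYYGCCGGYYGCG"))[1:3]
#' @export
composition <- function(codes) {
  if (length(codes) == 0L) {
    abort("composition of an empty region is undefined", class = "mldppi_error_validation")
  }
  setNames(composition_raw(codes), CTD_NAMES$composition)
}

#' Transition descriptor
#'
#' For each unordered group pair (g, h), the percentage of adjacent residue
#' pairs that alternate between the two groups in either order, out of the
#' `L - 1` adjacencies in a region of length L. A region of length 1 has no
#' adjacencies and reports all zeros.
#'
#' @param codes Integer vector of group codes for one region.
#' @return Named numeric vector of 21 percentages (`T1.2`, `T1.3`, ...,
#'   `T6.7`), in the fixed pair order (1,2),(1,3),...,(6,7).
#' @examples
#' transition(group_encode("GGYCCCYYGYYYGCCGGYYGCG"))[c("T1.2", "T1.3", "T2.3")]
#' @export
transition <- function(codes) {
  if (length(codes) == 0L) {
    abort("transition of an empty region is undefined", class = "mldppi_error_validation")
  }
  setNames(transition_raw(codes), CTD_NAMES$transition)
}

#' Distribution descriptor
#'
#' For each group, the normalized positions (percent of region length) at
#' which the first, 25%, 50%, 75% and last occurrence of the group sit. With
#' n occurrences at region positions `p_1 < ... < p_n`, the milestone for
#' quantile q is `p_i` with `i = max(1, floor(q * n))`, and the reported
#' value is `100 * p_i / region_length`. A group absent from the region
#' reports five zeros.
#'
#' @param codes Integer vector of group codes for one region.
#' @return Named numeric vector of 35 percentages (`D<g>.first`, `D<g>.25`,
#'   `D<g>.50`, `D<g>.75`, `D<g>.100` for g in 1..7).
#' @examples
#' distribution(group_encode("GGYCCCYYGYYYGCCGGYYGCG"))[1:5]
#' @export
distribution <- function(codes) {
  if (length(codes) == 0L) {
    abort("distribution of an empty region is undefined", class = "mldppi_error_validation")
  }
  setNames(distribution_raw(codes), CTD_NAMES$distribution)
}

#' Full 63-value CTD descriptor for one region
#'
#' Concatenates [composition()] (7), [transition()] (21) and [distribution()]
#' (35) in that fixed order.
#'
#' @param codes Integer vector of group codes for one region.
#' @return Named numeric vector of 63 percentages.
#' @export
ctd_descriptor <- function(codes) {
  c(composition(codes), transition(codes), distribution(codes))
}

ctd_descriptor_raw <- function(codes) {
  c(composition_raw(codes), transition_raw(codes), distribution_raw(codes))
}
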