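#' Enumerate contiguous multi-scale region masks
#'
#' A protein sequence is divided into `n_segments` equal-length segments and a
#' region is any contiguous run of segments, written as a binary mask (e.g.
#' `0011` = the final half of a four-segment sequence). Discontinuous
#' segment combinations are never used. The full-sequence mask (all ones) is
#' excluded by default, which for four segments gives the canonical 9 regions
#' and hence 9 x 63 = 567 descriptors per protein.
#'
#' @param n_segments Number of equal-length segments, between 2 and 8.
#' @param include_full Also include the all-ones mask (the whole sequence)?
#' @return A tibble with one row per region, ordered by run length then run
#'   start: `region` (1-based index), `mask` (character, e.g. `"0110"`),
#'   `seg_start`, `seg_end` (first and last selected segment).
#' @examples
#' build_region_masks(4)           # 9 regions
#' build_region_masks(2)           # "10", "01"
#' @export
build_region_masks <- function(n_segments = 4L, include_full = FALSE) {
  n_segments <- as.integer(n_segments)
  if (is.na(n_segments) || n_segments < 2L || n_segments > 8L) {
    abort("n_segments must be an integer in 2..8", class = "mldppi_error_config")
  }
  runs <- tidyr::expand_grid(len = seq_len(n_segments), start = seq_len(n_segments)) |>
    dplyr::filter(.data$start + .data$len - 1L <= n_segments)
  if (!include_full) {
    runs <- dplyr::filter(runs, .data$len < n_segments)
  }
  runs <- dplyr::arrange(runs, .data$len, .data$start)
  mask_chr <- purrr::map2_chr(runs$start, runs$len, function(s, l) {
    bits <- rep("0", n_segments)
    bits[s:(s + l - 1L)] <- "1"
    paste(bits, collapse = "")
  })
  tibble(
    region = seq_len(nrow(runs)),
    mask = mask_chr,
    seg_start = runs$start,
    seg_end = runs$start + runs$len - 1L
  )
}

#' Count of raw binary segment combinations
#'
#' Number of binary masks over `n_segments` segments excluding the all-zero
#' and all-one masks (2^S - 2). This counts discontinuous combinations too,
#' so it exceeds the number of contiguous regions actually encoded for S > 3;
#' it is exposed for reporting the resolution of a given bit width.
#'
#' @param n_segments Number of segments.
#' @return An integer.
#' @examples
#' n_binary_combinations(5)  # 30
#' @export
n_binary_combinations <- function(n_segments) {
  2L^as.integer(n_segments) - 2L
}

#' Equal-length segment boundaries
#'
#' Partitions positions `1..length` into `n_segments` consecutive intervals of
#' (as near as possible) equal size: segment k covers
#' `floor((k-1) L / n) + 1 .. floor(k L / n)`. The intervals are non-empty,
#' non-overlapping, and cover the sequence exactly.
#'
#' @param length Sequence length (residues); must be `>= n_segments`.
#' @param n_segments Number of segments.
#' @return A tibble with columns `segment`, `start`, `end` (1-based inclusive).
#' @examples
#' segment_boundaries(22, 4)
#' @export
segment_boundaries <- function(length, n_segments = 4L) {
  length <- as.integer(length)
  n_segments <- as.integer(n_segments)
  if (is.na(length) || length < 1L) {
    abort("length must be a positive integer", class = "mldppi_error_config")
  }
  if (length < n_segments) {
    abort(
      sprintf("sequence of length %d is too short to split into %d segments", length, n_segments),
      class = "mldppi_error_validation"
    )
  }
  k <- seq_len(n_segments)
  tibble(
    segment = k,
    start = ((k - 1L) * length) %/% n_segments + 1L,
    end = (k * length) %/% n_segments
  )
}

#' Extract the sub-sequence selected by a region mask
#'
#' Given group codes, the segment boundaries, and one contiguous mask (as a
#' `seg_start`/`seg_end` pair or a `"0011"`-style string), returns the slice
#' from the start of the first selected segment to the end of the last.
#'
#' @param codes Integer vector of group codes for the whole sequence.
#' @param mask A mask string such as `"0011"`, or a length-2 integer vector
#'   `c(seg_start, seg_end)`.
#' @param boundaries A tibble from [segment_boundaries()] whose segment count
#'   matches the mask length.
#' @return The integer sub-vector of `codes` covered by the region.
#' @examples
#' b <- segment_boundaries(22, 4)
#' length(extract_region(group_encode(strrep("A", 22)), "0011", b))  # 11
#' @export
extract_region <- function(codes, mask, boundaries) {
  if (is.character(mask)) {
    bits <- strsplit(mask, "", fixed = TRUE)[[1]]
    if (length(bits) != nrow(boundaries)) {
      abort("mask length must equal the number of segments", class = "mldppi_error_config")
    }
    set <- which(bits == "1")
    if (length(set) == 0L || any(diff(set) != 1L)) {
      abort("mask must select one contiguous non-empty run of segments",
            class = "mldppi_error_config")
    }
    seg_start <- set[1]
    seg_end <- set[length(set)]
  } else {
    seg_start <- mask[1]
    seg_end <- mask[2]
  }
  codes[boundaries$start[seg_start]:boundaries$end[seg_end]]
}
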