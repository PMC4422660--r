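#' Encoder configuration
#'
#' Bundles the parameters that determine the MLD feature layout. Two feature
#' vectors are comparable only if they were produced under identical
#' configurations; the layout version is recorded alongside so mixed layouts
#' are rejected rather than silently concatenated.
#'
#' @param n_segments Number of equal-length segments (2-8). The default 4
#'   yields 9 regions and a 567-dimensional protein vector.
#' @param include_full Include the whole sequence as a tenth region?
#' @param ambiguity Policy for non-standard residues when reading FASTA; one
#'   of `"skip_record"`, `"map_to_nearest"`, `"reject"` (see [read_fasta()]).
#' @param min_length Minimum residue count for a protein to be retained.
#' @return A list of class `mld_encoder_config`.
#' @export
encoder_config <- function(n_segments = 4L, include_full = FALSE,
                           ambiguity = c("skip_record", "map_to_nearest", "reject"),
                           min_length = 50L) {
  ambiguity <- match.arg(ambiguity)
  masks <- build_region_masks(n_segments, include_full)
  structure(
    list(
      n_segments = as.integer(n_segments),
      include_full = isTRUE(include_full),
      ambiguity = ambiguity,
      min_length = as.integer(min_length),
      n_regions = nrow(masks),
      dimension = 63L * nrow(masks),
      layout_version = MLD_LAYOUT_VERSION
    ),
    class = "mld_encoder_config"
  )
}

#' @export
print.mld_encoder_config <- function(x, ...) {
  cat(sprintf(
    "<mld_encoder_config> %d segments, %d regions, %d features/protein (%s)\n",
    x$n_segments, x$n_regions, x$dimension, x$layout_version
  ))
  invisible(x)
}

mld_feature_names <- function(config) {
  masks <- build_region_masks(config$n_segments, config$include_full)
  block <- unlist(CTD_NAMES, use.names = FALSE)
  unlist(purrr::map2(masks$region, masks$mask, function(r, m) {
    paste0("R", sprintf("%02d", r), ".", m, ".", block)
  }))
}

# Unnamed encoder core shared by encode_protein() and mld_featurize().
encode_protein_raw <- function(codes, masks, n_segments) {
  bounds <- segment_boundaries(length(codes), n_segments)
  unlist(lapply(seq_len(nrow(masks)), function(i) {
    ctd_descriptor_raw(
      codes[bounds$start[masks$seg_start[i]]:bounds$end[masks$seg_end[i]]]
    )
  }), use.names = FALSE)
}

#' Encode one protein as its MLD feature vector
#'
#' Computes the 63-value CTD descriptor on every contiguous multi-scale
#' region of the group-encoded sequence and concatenates them in region
#' order: 567 values for the default four-segment layout. The function is
#' pure — identical sequence and configuration give bit-identical output.
#'
#' @param seq An amino-acid string (standard residues only), or an already
#'   group-encoded integer vector.
#' @param config An [encoder_config()].
#' @return Named numeric vector of length `config$dimension`, values in
#'   \[0, 100\].
#' @examples
#' length(encode_protein("GGYCCCYYGYYYGCCGGYYGCG"))  # 567
#' @export
encode_protein <- function(seq, config = encoder_config()) {
  codes <- if (is.character(seq)) group_encode(seq) else as.integer(seq)
  if (length(codes) < config$n_segments) {
    abort(
      sprintf("sequence of length %d is too short for %d segments",
              length(codes), config$n_segments),
      class = "mldppi_error_validation"
    )
  }
  masks <- build_region_masks(config$n_segments, config$include_full)
  setNames(encode_protein_raw(codes, masks, config$n_segments),
           mld_feature_names(config))
}

#' Featurize a table of proteins
#'
#' Tibble-first wrapper around [encode_protein()]: one row in, one feature
#' row out.
#'
#' @param proteins A tibble with columns `id` and `sequence` (as returned by
#'   [read_fasta()]).
#' @param config An [encoder_config()].
#' @return A tibble with `id` followed by the `config$dimension` numeric
#'   feature columns. Carries the layout version and configuration in
#'   attributes `mld_config`.
#' @examples
#' prots <- tibble::tibble(id = "p1", sequence = "GGYCCCYYGYYYGCCGGYYGCG")
#' dim(mld_featurize(prots))  # 1 x 568
#' @export
mld_featurize <- function(proteins, config = encoder_config()) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  masks <- build_region_masks(config$n_segments, config$include_full)
  too_short <- nchar(proteins$sequence) < config$n_segments
  if (any(too_short)) {
    abort(sprintf("sequence '%s' is too short for %d segments",
                  proteins$id[which(too_short)[1]], config$n_segments),
          class = "mldppi_error_validation")
  }
  mat <- vapply(proteins$sequence, function(s) {
    encode_protein_raw(group_encode(s), masks, config$n_segments)
  }, numeric(config$dimension), USE.NAMES = FALSE)
  mat <- t(mat)
  colnames(mat) <- mld_feature_names(config)
  out <- dplyr::bind_cols(tibble(id = proteins$id), as_tibble(mat))
  attr(out, "mld_config") <- config
  out
}

#' Concatenate two protein feature vectors into a pair vector
#'
#' A protein pair is represented by protein A's vector followed by protein
#' B's, in the order the pair was listed (no symmetrization): 1134 values
#' under the default layout.
#'
#' @param vec_a,vec_b Numeric feature vectors from [encode_protein()], equal
#'   length and produced under the same configuration.
#' @return Numeric vector of length `2 * length(vec_a)`, names prefixed
#'   `A.` / `B.`.
#' @export
encode_pair <- function(vec_a, vec_b) {
  if (length(vec_a) != length(vec_b)) {
    abort("pair members have mismatched feature dimensions",
          class = "mldppi_error_config")
  }
  if (!is.null(names(vec_a)) && !is.null(names(vec_b)) &&
      !identical(names(vec_a), names(vec_b))) {
    abort("pair members were encoded under different layouts",
          class = "mldppi_error_config")
  }
  c(setNames(vec_a, paste0("A.", names(vec_a))),
    setNames(vec_b, paste0("B.", names(vec_b))))
}

#' Build the pair feature table for a labelled pair list
#'
#' Joins each pair's two protein feature rows from [mld_featurize()] output
#' and concatenates them (A features then B features). Optionally augments
#' the training set with the swapped orientation of every pair.
#'
#' @param pairs A tibble with columns `id_a`, `id_b`, `label` (see
#'   [read_pairs()]).
#' @param features Output of [mld_featurize()] covering every id in `pairs`.
#' @param augment_swapped Also emit each pair in B,A orientation (doubles the
#'   row count)? Default `FALSE`.
#' @return A tibble with `id_a`, `id_b`, `label`, then `2 * p` feature
#'   columns prefixed `A.` and `B.`.
#' @export
pair_features <- function(pairs, features, augment_swapped = FALSE) {
  stopifnot(all(c("id_a", "id_b", "label") %in% names(pairs)))
  missing <- setdiff(unique(c(pairs$id_a, pairs$id_b)), features$id)
  if (length(missing) > 0L) {
    abort(sprintf("no feature row for protein id(s): %s",
                  paste(head(missing, 5L), collapse = ", ")),
          class = "mldppi_error_validation")
  }
  if (augment_swapped) {
    swapped <- dplyr::rename(pairs, id_a = "id_b", id_b = "id_a")
    pairs <- dplyr::bind_rows(pairs, swapped)
  }
  fmat <- as.matrix(features[, -1, drop = FALSE])
  rownames(fmat) <- features$id
  a <- fmat[pairs$id_a, , drop = FALSE]
  b <- fmat[pairs$id_b, , drop = FALSE]
  colnames(a) <- paste0("A.", colnames(fmat))
  colnames(b) <- paste0("B.", colnames(fmat))
  out <- dplyr::bind_cols(
    tibble(id_a = pairs$id_a, id_b = pairs$id_b, label = as.integer(pairs$label)),
    as_tibble(a), as_tibble(b)
  )
  attr(out, "mld_config") <- attr(features, "mld_config")
  out
}

# Columns of a pair-feature tibble that are features (not identifiers/label).
feature_columns <- function(data) {
  setdiff(names(data), c("id_a", "id_b", "id", "label"))
}
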