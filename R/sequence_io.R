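STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read protein sequences from a FASTA file
#'
#' Reads a multi-record FASTA (wrapped or unwrapped) into a tibble of
#' validated protein records. Sequences are upper-cased and checked against
#' the 20 standard one-letter codes; how non-standard residues are handled is
#' an explicit policy, never a silent default:
#'
#' * `"skip_record"` (default): drop any record containing a non-standard
#'   residue, with a warning naming it.
#' * `"map_to_nearest"`: substitute the common ambiguity codes by their
#'   nearest standard residue (B to D, Z to E, U to C); records containing X
#'   or any other unknown code are still skipped, with a warning.
#' * `"reject"`: error on the first non-standard residue, naming the residue
#'   and its position.
#'
#' @param path Path to a FASTA file.
#' @param ambiguity Residue policy, see above.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header, unique), `sequence`, `length`.
#' @export
read_fasta <- function(path, ambiguity = c("skip_record", "map_to_nearest", "reject")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path), class = "mldppi_error_io")
  }
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)))
  if (length(content) == 0L) {
    abort(sprintf("empty FASTA file: %s", path), class = "mldppi_error_io")
  }
  if (!startsWith(trimws(lines[content[1]]), ">")) {
    abort(
      sprintf("malformed FASTA (%s): sequence data before any '>' header at line %d",
              path, content[1]),
      class = "mldppi_error_io"
    )
  }
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicate sequence id(s): %s", paste(unique(dup), collapse = ", ")),
          class = "mldppi_error_validation")
  }
  sequences <- unname(toupper(as.character(seqs)))
  keep <- rep(TRUE, length(ids))
  for (i in seq_along(sequences)) {
    s <- sequences[i]
    if (ambiguity == "map_to_nearest") {
      s <- chartr("BZU", "DEC", s)
    }
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- which(!(chars %in% STANDARD_AA))
    if (length(bad) > 0L) {
      if (ambiguity == "reject") {
        abort(
          sprintf("record '%s': forbidden residue '%s' at position %d",
                  ids[i], chars[bad[1]], bad[1]),
          class = "mldppi_error_validation"
        )
      }
      warn(sprintf("skipping record '%s': non-standard residue '%s' at position %d",
                   ids[i], chars[bad[1]], bad[1]))
      keep[i] <- FALSE
    }
    sequences[i] <- s
  }
  out <- tibble(id = ids, sequence = sequences, length = nchar(sequences))[keep, ]
  if (nrow(out) == 0L) {
    warn(sprintf("no records retained from %s under policy '%s'", path, ambiguity))
  }
  out
}

#' Write protein records to FASTA
#'
#' @param proteins A tibble with columns `id` and `sequence`.
#' @param path Output file path.
#' @param width Line-wrap width for sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  lines <- purrr::map2(proteins$id, proteins$sequence, function(id, s) {
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read a labelled protein-pair list
#'
#' Parses a two-protein-plus-label table (`id_a`, `id_b`, `label`), tab- or
#' comma-delimited (auto-detected from the first line); a header row is
#' detected by a non-numeric third column and skipped. Every id must resolve
#' to a record in `proteins` and every label must be 0 or 1.
#'
#' @param path Path to the pair file.
#' @param proteins A tibble of protein records (from [read_fasta()]) used to
#'   validate ids.
#' @return A tibble with columns `id_a`, `id_b`, `label` (integer 0/1).
#' @export
read_pairs <- function(path, proteins) {
  if (!file.exists(path)) {
    abort(sprintf("pair file not found: %s", path), class = "mldppi_error_io")
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) {
    warn(sprintf("empty pair file: %s", path))
    return(tibble(id_a = character(), id_b = character(), label = integer()))
  }
  delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  has_header <- {
    third <- strsplit(first, delim, fixed = TRUE)[[1]][3]
    is.na(suppressWarnings(as.numeric(third)))
  }
  raw <- readr::read_delim(
    path, delim = delim,
    col_names = c("id_a", "id_b", "label"),
    col_types = readr::cols(.default = readr::col_character()),
    skip = if (has_header) 1L else 0L,
    progress = FALSE
  )
  if (nrow(raw) == 0L) {
    warn(sprintf("empty pair file: %s", path))
    return(tibble(id_a = character(), id_b = character(), label = integer()))
  }
  lab <- suppressWarnings(as.numeric(raw$label))
  bad_lab <- which(is.na(lab) | !(lab %in% c(0, 1)))
  if (length(bad_lab) > 0L) {
    abort(
      sprintf("label outside {0,1} at line %d: '%s'",
              bad_lab[1] + has_header, raw$label[bad_lab[1]]),
      class = "mldppi_error_validation"
    )
  }
  known <- proteins$id
  for (col in c("id_a", "id_b")) {
    bad <- which(!(raw[[col]] %in% known))
    if (length(bad) > 0L) {
      abort(
        sprintf("unknown protein id '%s' at line %d", raw[[col]][bad[1]], bad[1] + has_header),
        class = "mldppi_error_validation"
      )
    }
  }
  tibble(id_a = raw$id_a, id_b = raw$id_b, label = as.integer(lab))
}

#' Drop proteins shorter than a minimum length
#'
#' Standard dataset-hygiene step: benchmark PPI sets typically exclude
#' proteins under 50 residues. Order is preserved and the number of removals
#' is reported.
#'
#' @param proteins A tibble of protein records.
#' @param min_len Minimum residue count to keep (default 50).
#' @return The filtered tibble.
#' @export
filter_min_length <- function(proteins, min_len = 50L) {
  stopifnot(min_len >= 1L)
  keep <- proteins$length >= min_len
  if (any(!keep)) {
    inform(sprintf("removed %d protein(s) shorter than %d residues", sum(!keep), min_len))
  }
  proteins[keep, ]
}
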