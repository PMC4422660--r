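# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain loops and exhaustive enumeration only.

oracle_composition <- function(codes) {
  out <- numeric(7)
  for (g in 1:7) {
    n <- 0
    for (c in codes) if (c == g) n <- n + 1
    out[g] <- 100 * n / length(codes)
  }
  out
}

oracle_transition <- function(codes) {
  out <- numeric(21)
  if (length(codes) < 2) return(out)
  k <- 0
  for (g in 1:6) {
    for (h in (g + 1):7) {
      k <- k + 1
      n <- 0
      for (i in 1:(length(codes) - 1)) {
        if ((codes[i] == g && codes[i + 1] == h) ||
            (codes[i] == h && codes[i + 1] == g)) {
          n <- n + 1
        }
      }
      out[k] <- 100 * n / (length(codes) - 1)
    }
  }
  out
}

oracle_distribution <- function(codes) {
  out <- numeric(35)
  L <- length(codes)
  for (g in 1:7) {
    pos <- c()
    for (i in seq_len(L)) if (codes[i] == g) pos <- c(pos, i)
    n <- length(pos)
    vals <- numeric(5)
    if (n > 0) {
      idx <- c(1,
               max(1, floor(0.25 * n + 1e-9)),
               max(1, floor(0.50 * n + 1e-9)),
               max(1, floor(0.75 * n + 1e-9)),
               n)
      vals <- 100 * pos[idx] / L
    }
    out[(5 * (g - 1) + 1):(5 * g)] <- vals
  }
  out
}

# All binary masks of width n whose set bits form one contiguous run,
# found by exhaustive enumeration over the 2^n bit vectors.
oracle_contiguous_masks <- function(n, include_full = FALSE) {
  found <- character()
  for (v in 1:(2^n - 1)) {
    bits <- as.integer(intToBits(v))[n:1]
    set <- which(bits == 1)
    contiguous <- all(diff(set) == 1)
    full <- length(set) == n
    if (contiguous && (include_full || !full)) {
      found <- c(found, paste(bits, collapse = ""))
    }
  }
  found
}

random_region <- function(len) sample.int(7L, len, replace = TRUE)

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

# Tiny linearly separable pair-feature table: the label is carried by two
# feature columns with well-separated class means, plus noise columns.
toy_separable <- function(n = 20, p_noise = 8, seed = 99) {
  set.seed(seed)
  label <- rep(c(0L, 1L), length.out = n)
  signal <- matrix(rnorm(2 * n, mean = ifelse(label == 1, 3, -3), sd = 0.3), ncol = 2)
  noise <- matrix(rnorm(n * p_noise), ncol = p_noise)
  m <- cbind(signal, noise)
  colnames(m) <- paste0("f", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(label = label), tibble::as_tibble(m))
}

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
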