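test_that("the canonical 22-mer reproduces every published descriptor value", {
  codes <- group_encode("GGYCCCYYGYYYGCCGGYYGCG")
  expect_equal(paste(codes, collapse = ""), "1132223313331221133121")

  comp <- composition(codes)
  expect_equal(round(unname(comp[1:3]), 2), c(36.36, 27.27, 36.36))
  expect_equal(unname(comp[4:7]), rep(0, 4))

  tran <- transition(codes)
  expect_equal(round(tran[["T1.2"]]), 19)          # 4/21, printed as 19%
  expect_equal(round(tran[["T1.3"]], 2), 28.57)    # 6/21
  expect_equal(round(tran[["T2.3"]], 2), 9.52)     # 2/21
  expect_equal(sum(tran > 0), 3L)

  dist <- distribution(codes)
  d <- function(g) round(unname(dist[(5 * (g - 1) + 1):(5 * g)]), 2)
  expect_equal(d(1), c(4.55, 9.09, 59.09, 77.27, 100.00))
  expect_equal(d(2), c(18.18, 18.18, 27.27, 63.64, 95.45))
  expect_equal(d(3), c(13.64, 31.82, 45.45, 54.55, 86.36))
  expect_true(worked_example(quiet = TRUE)$ok)
})

test_that("group encoding matches a per-character table lookup", {
  expect_equal(group_encode("A"), 1L)
  expect_equal(group_encode("E"), 7L)
  expect_equal(group_encode("ckw"), c(2L, 6L, 5L))  # case-insensitive

  table5 <- c(A = 1, G = 1, V = 1, C = 2, M = 3, S = 3, T = 3, Y = 3,
              F = 4, I = 4, L = 4, P = 4, H = 5, N = 5, Q = 5, W = 5,
              K = 6, R = 6, D = 7, E = 7)
  set.seed(21)
  for (rep in 1:5) {
    s <- random_protein(100)
    manual <- vapply(strsplit(s, "")[[1]], function(ch) table5[[ch]], numeric(1))
    expect_equal(group_encode(s), as.integer(manual))
  }

  expect_error(group_encode("AAXAA"), "'X' at position 3",
               class = "mldppi_error_validation")
  expect_error(group_encode(""), class = "mldppi_error_validation")
})

test_that("region masks are exactly the contiguous runs, in run-length order", {
  m4 <- build_region_masks(4)
  expect_equal(nrow(m4), 9L)
  expect_equal(m4$mask, c("1000", "0100", "0010", "0001",
                          "1100", "0110", "0011", "1110", "0111"))

  expect_equal(build_region_masks(2)$mask, c("10", "01"))
  expect_equal(nrow(build_region_masks(5)), 14L)
  expect_equal(build_region_masks(4, include_full = TRUE)$mask[10], "1111")

  # oracle equivalence: exhaustive enumeration + contiguity test, n = 2..8
  for (n in 2:8) {
    expect_equal(nrow(build_region_masks(n)), n * (n + 1) / 2 - 1)
    expect_setequal(build_region_masks(n)$mask, oracle_contiguous_masks(n))
    expect_setequal(build_region_masks(n, TRUE)$mask, oracle_contiguous_masks(n, TRUE))
  }

  expect_error(build_region_masks(1), class = "mldppi_error_config")
  expect_error(build_region_masks(9), class = "mldppi_error_config")
  expect_equal(n_binary_combinations(5), 30L)
})

test_that("segment boundaries partition the sequence into equal floors", {
  b <- segment_boundaries(22, 4)
  expect_equal(b$start, c(1L, 6L, 12L, 17L))
  expect_equal(b$end, c(5L, 11L, 16L, 22L))

  b8 <- segment_boundaries(8, 4)
  expect_equal(b8$start, c(1L, 3L, 5L, 7L))
  expect_equal(b8$end, c(2L, 4L, 6L, 8L))

  set.seed(5)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    L <- sample(n:500, 1)
    b <- segment_boundaries(L, n)
    expect_equal(b$start[1], 1L)
    expect_equal(b$end[n], L)
    expect_true(all(b$end >= b$start))                    # non-empty
    if (n > 1) expect_equal(b$start[-1], b$end[-n] + 1L)  # gap-free
  }
  expect_error(segment_boundaries(3, 4), "too short", class = "mldppi_error_validation")
})

test_that("extract_region slices the contiguous run a mask selects", {
  codes <- group_encode("GGYCCCYYGYYYGCCGGYYGCG")
  b <- segment_boundaries(22, 4)
  expect_equal(extract_region(codes, "0011", b), codes[12:22])  # final 50%
  expect_equal(extract_region(codes, "0111", b), codes[6:22])   # final 75%
  expect_equal(extract_region(codes, "1111", b), codes)
  expect_error(extract_region(codes, "0101", b), "contiguous",
               class = "mldppi_error_config")
  expect_error(extract_region(codes, "00110", b), class = "mldppi_error_config")
})

test_that("C/T/D agree with brute-force counting oracles on random regions", {
  set.seed(7)
  for (i in 1:500) {
    codes <- random_region(sample(1:80, 1))
    comp <- composition(codes)
    tran <- transition(codes)
    dist <- distribution(codes)

    expect_equal(unname(comp), oracle_composition(codes))
    expect_equal(unname(tran), oracle_transition(codes))
    expect_equal(unname(dist), oracle_distribution(codes))

    # structural invariants
    expect_equal(sum(comp), 100, tolerance = 1e-9)
    expect_true(sum(tran) <= 100 + 1e-9)
    for (g in 1:7) {
      dg <- unname(dist[(5 * (g - 1) + 1):(5 * g)])
      expect_true(all(diff(dg) >= -1e-12))
      expect_true(all(dg >= 0 & dg <= 100))
      expect_equal(all(dg == 0), !(g %in% codes))
    }
  }
})

test_that("degenerate regions have the documented descriptor values", {
  expect_equal(unname(composition(rep(1L, 17))), c(100, rep(0, 6)))
  expect_equal(unname(transition(rep(4L, 30))), rep(0, 21))
  expect_equal(unname(transition(2L)), rep(0, 21))  # length-1 region

  # single occurrence at the last position: all five milestones at 100%
  codes <- c(rep(1L, 9), 5L)
  expect_equal(unname(distribution(codes)[21:25]), rep(100, 5))

  expect_error(composition(integer()), class = "mldppi_error_validation")
})

test_that("encode_protein has the versioned 63-per-region layout", {
  v <- encode_protein("GGYCCCYYGYYYGCCGGYYGCG")
  expect_length(v, 567L)
  expect_length(ctd_descriptor(random_region(10)), 63L)

  # first block is the CTD of segment S1 alone
  codes <- group_encode("GGYCCCYYGYYYGCCGGYYGCG")
  expect_equal(unname(v[1:63]), unname(ctd_descriptor(codes[1:5])))
  # last block is segment S2..S4, the final 75%
  expect_equal(unname(v[505:567]), unname(ctd_descriptor(codes[6:22])))

  cfg5 <- encoder_config(n_segments = 5)
  expect_length(encode_protein(random_protein(60), cfg5), 63L * 14L)
  expect_length(encode_protein(random_protein(60), encoder_config(include_full = TRUE)),
                63L * 10L)

  expect_error(encode_protein("AAA"), "too short", class = "mldppi_error_validation")
})

test_that("encoded values stay in [0, 100] and encoding is pure", {
  set.seed(13)
  for (i in 1:500) {
    v <- encode_protein(random_protein(sample(4:120, 1)))
    expect_true(all(v >= 0 & v <= 100))
  }
  s <- random_protein(90)
  expect_identical(encode_protein(s), encode_protein(s))
})

test_that("pair vectors concatenate A then B with dimension 2p", {
  a <- encode_protein(random_protein(70))
  b <- encode_protein(random_protein(55))
  ab <- encode_pair(a, b)
  expect_length(ab, 1134L)
  expect_equal(unname(ab[1:567]), unname(a))
  expect_equal(unname(ab[568:1134]), unname(b))

  vv <- encode_pair(a, a)
  expect_equal(unname(vv[1:567]), unname(vv[568:1134]))

  ba <- encode_pair(b, a)
  expect_equal(unname(ab), unname(c(ba[568:1134], ba[1:567])))

  expect_error(encode_pair(a, a[1:100]), "mismatched", class = "mldppi_error_config")
  short <- encode_protein(random_protein(60), encoder_config(n_segments = 2))
  expect_error(encode_pair(a, short), class = "mldppi_error_config")
})

test_that("mld_featurize and pair_features build the labelled feature table", {
  set.seed(31)
  proteins <- tibble::tibble(
    id = c("x", "y", "z"),
    sequence = vapply(c(60, 80, 100), random_protein, character(1))
  )
  feats <- mld_featurize(proteins)
  expect_equal(dim(feats), c(3L, 568L))
  expect_equal(unname(unlist(feats[1, -1])), unname(encode_protein(proteins$sequence[1])))

  pairs <- tibble::tibble(id_a = c("x", "y"), id_b = c("y", "z"), label = c(1L, 0L))
  pf <- pair_features(pairs, feats)
  expect_equal(dim(pf), c(2L, 3L + 1134L))
  expect_equal(unname(unlist(pf[1, 4:570])), unname(encode_protein(proteins$sequence[1])))

  aug <- pair_features(pairs, feats, augment_swapped = TRUE)
  expect_equal(nrow(aug), 4L)
  expect_equal(unname(unlist(aug[3, 571:1137])), unname(unlist(aug[1, 4:570])))

  expect_error(pair_features(tibble::tibble(id_a = "x", id_b = "nope", label = 1L), feats),
               "nope", class = "mldppi_error_validation")
})
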