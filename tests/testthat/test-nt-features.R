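test_that("nucleotide k-mer block has the printed width and window counts", {
  v <- kmer_nt(CTD_EXAMPLE)
  expect_length(v, 750L)

  single <- kmer_nt("AAA", ks = 3L)
  expect_equal(unname(single[["kmer3.AAA"]]), 1)
  expect_equal(sum(single), 1)

  v6 <- kmer_nt("ATGATG", ks = 3L)
  expect_equal(unname(v6[c("kmer3.ATG", "kmer3.TGA", "kmer3.GAT")]),
               c(2 / 4, 1 / 4, 1 / 4))
  expect_equal(sum(v6 > 0), 3L)
})

test_that("k-mer frequencies sum to one per k-block in windows mode", {
  set.seed(11)
  for (i in 1:20) {
    v <- kmer_nt(random_nt(sample(10:120, 1)))
    expect_equal(sum(v[startsWith(names(v), "kmer3.")]), 1, tolerance = 1e-9)
    expect_equal(sum(v[startsWith(names(v), "kmer4.")]), 1, tolerance = 1e-9)
  }
})

test_that("length-based k-mer denominator is L-k-1 clamped to 1", {
  v <- kmer_nt("ATGATG", ks = 3L, denominator_mode = "length_based")
  expect_equal(unname(v[["kmer3.ATG"]]), 2 / 2)   # denom = 6 - 3 - 1
  v2 <- kmer_nt("ATGA", ks = 4L, denominator_mode = "length_based")
  expect_equal(unname(v2[["kmer4.ATGA"]]), 1)     # denom clamped to 1
})

test_that("k-mer rejects out-of-alphabet symbols and warns on short input", {
  expect_error(kmer_nt("ATGZ"), "alphabet")
  expect_warning(v <- kmer_nt("AT", ks = c(3L, 4L)), "shorter")
  expect_equal(sum(v), 0)
})

test_that("Fickett score reflects frame asymmetry and stays in range", {
  homo <- strrep("A", 33)
  counts <- oracle_frame_counts(homo, "A")
  expect_equal(counts, c(11, 11, 11))
  expect_gt(fickett_score(homo), 0)
  expect_error(fickett_score("AT"), "at least 3")

  max_w <- sum(c(0.26, 0.18, 0.31, 0.33, 0.11, 0.12, 0.15, 0.14))
  set.seed(13)
  for (i in 1:30) {
    s <- random_nt(sample(33:150, 1))
    val <- fickett_score(s)
    expect_gte(val, 0)
    expect_lte(val, max_w)
  }
})

test_that("Fickett frame tallies agree with a brute-force position count", {
  set.seed(17)
  for (i in 1:10) {
    s <- random_nt(33)
    for (b in c("A", "C", "G", "T")) {
      ch <- strsplit(s, "")[[1]]
      direct <- vapply(0:2, function(f) {
        sum(ch[(seq_along(ch) - 1L) %% 3L == f] == b)
      }, numeric(1))
      expect_equal(oracle_frame_counts(s, b), direct)
    }
  }
})

test_that("CTD reproduces the printed worked example", {
  v <- ctd_nt(CTD_EXAMPLE)
  expect_length(v, 30L)
  expect_equal(unname(v[["ctd.comp_A"]]), 10 / 33)
  expect_equal(unname(v[["ctd.comp_T"]]), 7 / 33)
  expect_equal(unname(v[["ctd.comp_G"]]), 9 / 33)
  expect_equal(unname(v[["ctd.comp_C"]]), 7 / 33)
  expect_equal(unname(v[["ctd.trans_AT"]]), 4 / 32)
  expect_equal(unname(v[["ctd.trans_AC"]]), 2 / 32)
  expect_equal(unname(v[["ctd.trans_AG"]]), 9 / 32)
  expect_equal(unname(v[["ctd.trans_GC"]]), 2 / 32)
  expect_equal(unname(v[paste0("ctd.dist_A", 0:4)]),
               c(1, 5, 13, 24, 30) / 33)
  expect_equal(unname(v[paste0("ctd.dist_T", 0:4)]),
               c(2, 2, 9, 18, 21) / 33, tolerance = 1e-12)
  expect_equal(round(unname(v[paste0("ctd.dist_T", 0:4)]), 3),
               c(0.061, 0.061, 0.273, 0.545, 0.636))
  expect_equal(round(unname(v[paste0("ctd.dist_G", 0:4)]), 3),
               c(0.091, 0.121, 0.515, 0.788, 0.970))
  expect_equal(round(unname(v[paste0("ctd.dist_C", 0:4)]), 3),
               c(0.212, 0.212, 0.424, 0.606, 1.000))
})

test_that("CTD distribution endpoints are the first and last occurrence", {
  set.seed(19)
  for (i in 1:20) {
    s <- random_nt(sample(20:100, 1))
    v <- ctd_nt(s)
    ch <- strsplit(s, "")[[1]]
    for (b in c("A", "T", "G", "C")) {
      pos <- which(ch == b)
      if (length(pos) == 0) next
      expect_equal(unname(v[[paste0("ctd.dist_", b, "0")]]),
                   pos[1] / nchar(s))
      expect_equal(unname(v[[paste0("ctd.dist_", b, "4")]]),
                   pos[length(pos)] / nchar(s))
      expect_true(all(diff(v[paste0("ctd.dist_", b, 0:4)]) >= 0))
    }
  }
})

test_that("nt encoders match brute-force recomputation on random sORFs", {
  set.seed(23)
  for (i in 1:40) {
    s <- random_nt(sample(33:300, 1))
    expect_equal(unname(kmer_nt(s, ks = 3L)),
                 unname(oracle_kmer(s, 3L, c("A", "C", "G", "T", "N"))),
                 tolerance = 1e-12)
    expect_equal(unname(ctd_nt(s)), oracle_ctd(s), tolerance = 1e-12)
  }
})

test_that("fused nucleotide encoding is 781-dim, stable, and N-aware", {
  v1 <- encode_nt(CTD_EXAMPLE)
  v2 <- encode_nt(CTD_EXAMPLE)
  expect_length(v1, 781L)
  expect_identical(v1, v2)

  allN <- strrep("N", 40)
  vN <- encode_nt(allN)
  kmer_part <- vN[startsWith(names(vN), "kmer3.")]
  expect_equal(unname(kmer_part[["kmer3.NNN"]]), 1)
  expect_equal(sum(vN[startsWith(names(vN), "ctd.comp_")]), 0)
})
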