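test_that("AAC is the residue frequency vector in canonical order", {
  expect_equal(unname(aac("AAAA")[["aac.A"]]), 1)
  expect_equal(sum(aac("AAAA")), 1)
  expect_length(aac("ACDE"), 20L)
  v <- aac("ACDE")
  expect_equal(unname(v[c("aac.A", "aac.C", "aac.D", "aac.E")]), rep(0.25, 4))
  # X counts toward length but not toward any residue
  expect_equal(sum(aac("AAXX")), 0.5)
  expect_error(aac("ABZ"), "invalid residue")
})

test_that("property tables are standardized and distance matrices valid", {
  p <- aa_property_tables()
  for (tb in p) {
    expect_length(tb, 20L)
    expect_equal(mean(tb), 0, tolerance = 1e-9)
    expect_equal(mean(tb^2), 1, tolerance = 1e-9)
  }
  for (m in aa_distance_matrices()) {
    expect_identical(dim(m), c(20L, 20L))
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(0, 20))
  }
})

test_that("PAAC collapses to scaled composition on a homopolymer", {
  v <- paac("AAAAAAAAAA")
  expect_length(v, 23L)
  expect_equal(unname(v[["paac.A"]]), 1)
  expect_equal(unname(v[paste0("paac.theta", 1:3)]), rep(0, 3))
  expect_error(paac("MAK", lag = 3L), "length > lag")
})

test_that("APAAC homopolymer correlation tails are the squared property", {
  pep <- "AAAAAAAAAA"
  v <- apaac(pep)
  expect_length(v, 26L)
  p <- aa_property_tables()
  tau_expect <- rep(c(p$hydrophobicity[["A"]]^2, p$hydrophilicity[["A"]]^2), 3)
  denom <- 1 + 0.05 * sum(tau_expect)
  expect_equal(unname(v[21:26]), 0.05 * tau_expect / denom, tolerance = 1e-12)
})

test_that("QSOrder homopolymer order terms vanish with zero self-distance", {
  v <- qsorder("AAAAAAAAAA")
  expect_length(v, 46L)
  expect_equal(sum(v[grepl("tau", names(v))]), 0)
  expect_equal(sum(v), 2)   # two blocks, each normalized to 1
})

test_that("aa encoders match direct formula evaluation on random peptides", {
  tables <- aa_property_tables()
  matrices <- aa_distance_matrices()
  set.seed(29)
  for (i in 1:25) {
    pep <- random_aa(sample(10:100, 1))
    expect_equal(unname(aac(pep)), unname(oracle_aac(pep)),
                 tolerance = 1e-12)
    expect_equal(unname(paac(pep)),
                 unname(oracle_paac(pep, 3L, 0.05, tables)),
                 tolerance = 1e-12)
    expect_equal(unname(apaac(pep)),
                 unname(oracle_apaac(pep, 3L, 0.05, tables)),
                 tolerance = 1e-12)
    expect_equal(unname(qsorder(pep)),
                 unname(oracle_qsorder(pep, 3L, 0.05, matrices)),
                 tolerance = 1e-12)
  }
})

test_that("order-weighted vectors sum to one and stay nonnegative", {
  set.seed(31)
  for (i in 1:15) {
    pep <- random_aa(sample(10:60, 1))
    expect_equal(sum(paac(pep)), 1, tolerance = 1e-9)
    expect_equal(sum(apaac(pep)), 1, tolerance = 1e-9)
    expect_equal(sum(qsorder(pep)), 2, tolerance = 1e-9)
    expect_true(all(paac(pep) >= 0))
    expect_true(all(qsorder(pep) >= 0))
    expect_true(all(apaac(pep)[1:20] >= 0))
  }
})

test_that("increasing the weight shrinks occupied composition descriptors", {
  set.seed(37)
  pep <- random_aa(20)
  occupied <- aac(pep) > 0
  # paac/qsorder order terms are sums of squares, hence positive here, so
  # a larger weight strictly deflates every nonzero composition entry
  for (fn in list(paac, qsorder)) {
    lo <- fn(pep, w = 0.05)[1:20]
    hi <- fn(pep, w = 0.5)[1:20]
    expect_true(all(hi[occupied] < lo[occupied]))
    expect_true(all(hi[!occupied] == 0 & lo[!occupied] == 0))
  }
  # apaac correlation terms are centered products and may be negative;
  # the deflation direction follows the sign of their sum
  ch <- strsplit(pep, "")[[1]]
  tabs <- aa_property_tables()[c("hydrophobicity", "hydrophilicity")]
  tau_sum <- sum(vapply(1:3, function(d) {
    sum(vapply(tabs, function(tb) {
      mean(tb[ch[1:(20 - d)]] * tb[ch[(1 + d):20]])
    }, numeric(1)))
  }, numeric(1)))
  lo <- apaac(pep, w = 0.05)[1:20]
  hi <- apaac(pep, w = 0.5)[1:20]
  direction <- sign(tau_sum)
  if (direction > 0) {
    expect_true(all(hi[occupied] < lo[occupied]))
  } else if (direction < 0) {
    expect_true(all(hi[occupied] > lo[occupied]))
  }
})

test_that("aa k-mer block is 841 wide with exact 2-mer frequencies", {
  v <- kmer_aa("AAAA")
  expect_length(v, 841L)
  expect_equal(unname(v[["aakmer2.AA"]]), 1)
  expect_equal(sum(v[startsWith(names(v), "aakmer2.")]), 1)

  set.seed(43)
  for (i in 1:10) {
    pep <- random_aa(15)
    full <- kmer_aa(pep, mode = "full")
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    expect_equal(unname(full$kmer2),
                 unname(oracle_kmer(pep, 2L, aas)), tolerance = 1e-12)
    # hashed 4-mer mass equals the exact 4-mer mass
    compat <- kmer_aa(pep)
    expect_equal(sum(compat[startsWith(names(compat), "aakmer4.")]),
                 sum(full$kmer4), tolerance = 1e-12)
  }
  expect_error(kmer_aa("MAK"), "at least 4")
})

test_that("4-mer hashing is a stable deterministic bucket assignment", {
  w <- c("MKLV", "ACDE", "WYYW", "MKLV")
  b1 <- sepstack:::hash_bucket(w)
  b2 <- sepstack:::hash_bucket(w)
  expect_identical(b1, b2)
  expect_identical(b1[1], b1[4])
  expect_true(all(b1 >= 1L & b1 <= 441L))
})

test_that("fused amino-acid encoding is 956-dim with stable block offsets", {
  pep <- random_aa(30)
  v <- encode_aa(pep)
  expect_length(v, 956L)
  expect_identical(v, encode_aa(pep))
  prefixes <- c("aac." = 20L, "apaac." = 26L, "paac." = 23L, "qso." = 46L,
                "aakmer" = 841L)
  for (nm in names(prefixes)) {
    expect_identical(sum(startsWith(names(v), nm)),
                     as.integer(prefixes[[nm]]))
  }
  expect_error(encode_aa("MK"), "too short")
})
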