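# Amino-acid encoders: AAC, PAAC, APAAC, quasi-sequence-order and the
# combined 2-mer/4-mer block.
#
# X is tolerated everywhere: it is excluded from composition numerators and
# contributes zero to all property/distance correlation sums, but still
# counts toward sequence length where a length normalizer is used.

aa_check <- function(seq) {
  ch <- seq_chars(seq)
  bad <- setdiff(unique(ch), c(AA_ALPHABET, "X"))
  if (length(bad)) stop("invalid residue(s): ", paste(bad, collapse = ","))
  ch
}

#' Amino-acid composition (AAC)
#'
#' Frequency of each of the 20 canonical residues, in
#' `ACDEFGHIKLMNPQRSTVWY` order. `X` is excluded from the numerators but
#' included in the length, so the vector sums to 1 only for X-free input.
#'
#' @param seq Peptide string.
#' @return Named numeric vector of length 20.
#' @export
aac <- function(seq) {
  ch <- aa_check(seq)
  tab <- table(factor(ch, levels = AA_ALPHABET))
  stats::setNames(as.numeric(tab) / length(ch), paste0("aac.", AA_ALPHABET))
}

# Per-residue standardized property matrix (rows = positions, cols =
# properties); X rows are NA and handled by the callers.
property_profile <- function(ch, tables) {
  sapply(tables, function(tb) unname(tb[ch]))
}

#' Pseudo-amino-acid composition (PAAC)
#'
#' Sequence-order factors `theta_d`, d = 1..lag, are the mean (over the
#' `L - d` residue pairs and over the standardized property set) squared
#' property difference between residues `i` and `i + d`. The descriptor is
#' `f_u / (1 + w * sum(theta))` for the 20 residue frequencies followed by
#' `w * theta_d / (1 + w * sum(theta))` for the lag tail. Pairs involving
#' `X` contribute zero to `theta`.
#'
#' @param seq Peptide string with `nchar(seq) > lag`.
#' @param lag Sequence-order bound (default 3).
#' @param w Weighting factor (default 0.05).
#' @param tables Property tables from [aa_property_tables()].
#' @return Named numeric vector of length `20 + lag`.
#' @export
paac <- function(seq, lag = 3L, w = 0.05, tables = aa_property_tables()) {
  ch <- aa_check(seq)
  L <- length(ch)
  if (L <= lag) stop("paac needs length > lag = ", lag,
                     " (minimum ", lag + 1L, " residues)")
  stopifnot(lag >= 1L, w > 0)
  P <- property_profile(ch, tables)
  theta <- vapply(seq_len(lag), function(d) {
    diffs <- (P[1:(L - d), , drop = FALSE] - P[(1 + d):L, , drop = FALSE])^2
    diffs[is.na(diffs)] <- 0
    sum(rowMeans(diffs)) / (L - d)
  }, numeric(1))
  f <- as.numeric(table(factor(ch, levels = AA_ALPHABET))) / L
  denom <- 1 + w * sum(theta)
  stats::setNames(c(f / denom, w * theta / denom),
                  c(paste0("paac.", AA_ALPHABET), paste0("paac.theta", seq_len(lag))))
}

#' Amphiphilic pseudo-amino-acid composition (APAAC)
#'
#' Amphiphilic correlation factors are computed separately for standardized
#' hydrophobicity and hydrophilicity at each lag d = 1..lag as the mean
#' product `H(i) * H(i+d)` over the `L - d` pairs (zero for pairs with
#' `X`), giving `2 * lag` tail terms; normalization as in [paac()]. The
#' tail terms can be negative because the properties are centered.
#'
#' @inheritParams paac
#' @return Named numeric vector of length `20 + 2 * lag`.
#' @export
apaac <- function(seq, lag = 3L, w = 0.05, tables = aa_property_tables()) {
  ch <- aa_check(seq)
  L <- length(ch)
  if (L <= lag) stop("apaac needs length > lag = ", lag,
                     " (minimum ", lag + 1L, " residues)")
  stopifnot(lag >= 1L, w > 0)
  props <- tables[c("hydrophobicity", "hydrophilicity")]
  tau <- numeric(0)
  tau_names <- character(0)
  for (d in seq_len(lag)) {
    for (pn in names(props)) {
      h <- unname(props[[pn]][ch])
      prod <- h[1:(L - d)] * h[(1 + d):L]
      prod[is.na(prod)] <- 0
      tau <- c(tau, sum(prod) / (L - d))
      tau_names <- c(tau_names, paste0("apaac.tau", d, ".", substr(pn, 1, 4)))
    }
  }
  f <- as.numeric(table(factor(ch, levels = AA_ALPHABET))) / L
  denom <- 1 + w * sum(tau)
  stats::setNames(c(f / denom, w * tau / denom),
                  c(paste0("apaac.", AA_ALPHABET), tau_names))
}

#' Quasi-sequence-order descriptor (QSOrder)
#'
#' For each of two residue distance matrices (physicochemical first, then
#' chemical), the order-coupling numbers `tau_d = sum_i d(s_i, s_{i+d})^2`
#' for d = 1..lag are combined with the residue counts `N_r`:
#' 20 composition-type descriptors `N_r / (sum(N) + w * sum(tau))` followed
#' by lag order-type descriptors `w * tau_d / (sum(N) + w * sum(tau))`.
#' The two matrix blocks are concatenated. `X` pairs contribute zero.
#'
#' @inheritParams paac
#' @param matrices List of two distance matrices from
#'   [aa_distance_matrices()].
#' @return Named numeric vector of length `2 * (20 + lag)`.
#' @export
qsorder <- function(seq, lag = 3L, w = 0.05,
                    matrices = aa_distance_matrices()) {
  ch <- aa_check(seq)
  L <- length(ch)
  if (L <= lag) stop("qsorder needs length > lag = ", lag,
                     " (minimum ", lag + 1L, " residues)")
  stopifnot(lag >= 1L, w > 0)
  counts <- as.numeric(table(factor(ch, levels = AA_ALPHABET)))
  out <- numeric(0)
  for (mn in names(matrices)) {
    m <- matrices[[mn]]
    tau <- vapply(seq_len(lag), function(d) {
      a <- ch[1:(L - d)]; b <- ch[(1 + d):L]
      ok <- a != "X" & b != "X"
      if (!any(ok)) return(0)
      sum(m[cbind(a[ok], b[ok])]^2)
    }, numeric(1))
    denom <- sum(counts) + w * sum(tau)
    block <- c(counts / denom, w * tau / denom)
    names(block) <- paste0("qso.", mn, ".",
                           c(AA_ALPHABET, paste0("tau", seq_len(lag))))
    out <- c(out, block)
  }
  out
}

# Stable non-cryptographic polynomial string hash (base 31, fixed salt),
# used to fold exact 4-mer identities into a fixed number of buckets.
KMER_HASH_SALT <- 7919L
KMER_HASH_BUCKETS <- 441L

hash_bucket <- function(strings, buckets = KMER_HASH_BUCKETS,
                        salt = KMER_HASH_SALT) {
  vapply(strings, function(s) {
    h <- salt
    for (code in utf8ToInt(s)) h <- (h * 31L + code) %% 1048573L
    (h %% buckets) + 1L
  }, integer(1), USE.NAMES = FALSE)
}

#' Amino-acid k-mer frequency block
#'
#' `compat841` mode (the pipeline default) returns the full 400
#' 2-mer frequencies over the 20-letter alphabet followed by 4-mer
#' frequencies folded into 441 buckets by a stable salted string hash —
#' 841 values in all, a fixed-width stand-in for the intractably wide
#' exact 4-mer space. `full` mode returns the exact 2-mer block plus the
#' exact (sparse, nonzero-only) 4-mer counts. Windows containing `X` are
#' skipped; the denominator follows `denominator_mode` as in [kmer_nt()].
#'
#' @param seq Peptide string, length >= 4.
#' @param mode `"compat841"` or `"full"`.
#' @param denominator_mode `"windows"` or `"length_based"`.
#' @return `compat841`: named numeric vector of length 841. `full`: list
#'   with dense `kmer2` (400) and named sparse `kmer4` frequencies.
#' @export
kmer_aa <- function(seq, mode = c("compat841", "full"),
                    denominator_mode = c("windows", "length_based")) {
  mode <- match.arg(mode)
  denominator_mode <- match.arg(denominator_mode)
  aa_check(seq)
  L <- nchar(seq)
  if (L < 4L) stop("kmer_aa needs at least 4 residues")
  denom <- function(k) {
    if (denominator_mode == "windows") L - k + 1L else max(L - k - 1L, 1L)
  }
  w2 <- kmer_windows(seq, 2L)
  w2 <- w2[!grepl("X", w2, fixed = TRUE)]
  lev2 <- all_kmers(AA_ALPHABET, 2L)
  f2 <- as.numeric(table(factor(w2, levels = lev2))) / denom(2L)
  names(f2) <- paste0("aakmer2.", lev2)
  w4 <- kmer_windows(seq, 4L)
  w4 <- w4[!grepl("X", w4, fixed = TRUE)]
  if (mode == "compat841") {
    f4 <- numeric(KMER_HASH_BUCKETS)
    if (length(w4)) {
      tab <- table(hash_bucket(w4))
      f4[as.integer(names(tab))] <- as.numeric(tab) / denom(4L)
    }
    names(f4) <- paste0("aakmer4.b", seq_len(KMER_HASH_BUCKETS))
    c(f2, f4)
  } else {
    tab <- table(w4)
    list(kmer2 = f2,
         kmer4 = stats::setNames(as.numeric(tab) / denom(4L), names(tab)))
  }
}

#' Encode a peptide into its five feature blocks
#'
#' Concatenates, in fixed order, AAC (20), APAAC (26), PAAC (23), QSOrder
#' (46) and the combined 2-mer/4-mer block (841) into a 956-dimensional
#' named vector.
#'
#' @param seq Peptide string (>= 10 residues recommended; hard minimum 4
#'   plus `lag + 1`).
#' @param lag Sequence-order bound for PAAC/APAAC/QSOrder.
#' @param w Weighting factor for PAAC/APAAC/QSOrder.
#' @param denominator_mode Passed to [kmer_aa()].
#' @return Named numeric vector of length 956.
#' @export
encode_aa <- function(seq, lag = 3L, w = 0.05, denominator_mode = "windows") {
  mins <- c(aac = 1L, apaac = lag + 1L, paac = lag + 1L,
            qsorder = lag + 1L, kmer = 4L)
  short <- names(mins)[nchar(seq) < mins]
  if (length(short)) {
    stop("peptide too short (", nchar(seq), " aa) for encoder(s): ",
         paste(short, collapse = ", "))
  }
  c(aac(seq),
    apaac(seq, lag = lag, w = w),
    paac(seq, lag = lag, w = w),
    qsorder(seq, lag = lag, w = w),
    kmer_aa(seq, mode = "compat841", denominator_mode = denominator_mode))
}
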