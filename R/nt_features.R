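# Nucleotide encoders: combined k-mer frequencies, Fickett TESTCODE score,
# and composition/transition/distribution (CTD).

all_kmers <- function(alphabet, k) {
  grids <- rev(rep(list(alphabet), k))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

seq_chars <- function(seq) strsplit(seq, "")[[1]]

kmer_windows <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, 1:(L - k + 1L), k:L)
}

#' Nucleotide k-mer frequency vector
#'
#' Frequencies of every k-mer over the 5-letter alphabet `A,C,G,T,N` in
#' lexicographic-by-alphabet order, one block per `k`, concatenated. The
#' default denominator is the number of windows `L - k + 1`
#' (`denominator_mode = "windows"`); `"length_based"` uses `L - k - 1`
#' clamped to at least 1, an alternative length normalization kept for
#' compatibility.
#'
#' @param seq Nucleotide string.
#' @param ks Integer vector of k values (default `c(3, 4)`).
#' @param alphabet Ordered symbol vector (default `A,C,G,T,N`).
#' @param denominator_mode `"windows"` or `"length_based"`.
#' @return Named numeric vector of length `sum(length(alphabet)^ks)`.
#' @export
kmer_nt <- function(seq, ks = c(3L, 4L), alphabet = NT_ALPHABET,
                    denominator_mode = c("windows", "length_based")) {
  denominator_mode <- match.arg(denominator_mode)
  stopifnot(length(ks) >= 1L, all(ks >= 1L), !anyDuplicated(alphabet))
  ch <- seq_chars(seq)
  if (any(!ch %in% alphabet)) {
    stop("symbol outside alphabet: ",
         paste(setdiff(ch, alphabet), collapse = ","))
  }
  L <- nchar(seq)
  if (L < max(ks)) {
    warning("sequence shorter than max k; short k-blocks are all zero")
  }
  out <- lapply(ks, function(k) {
    lev <- all_kmers(alphabet, k)
    v <- stats::setNames(numeric(length(lev)), paste0("kmer", k, ".", lev))
    w <- kmer_windows(seq, k)
    if (length(w)) {
      denom <- if (denominator_mode == "windows") L - k + 1L else max(L - k - 1L, 1L)
      tab <- table(factor(w, levels = lev))
      v[] <- as.numeric(tab) / denom
    }
    v
  })
  unlist(out)
}

fickett_lookup <- function(value, para, prob) {
  prob[which(value >= para)[1L]]
}

#' Fickett TESTCODE coding-potential score
#'
#' For each base, the codon-frame positional asymmetry statistic
#' `MAX(B1,B2,B3)/(MIN(B1,B2,B3)+1)` (frame counts at 0-based positions
#' congruent to 0/1/2 mod 3) and the base content fraction are mapped
#' through the classical TESTCODE probability lookup tables; the score is
#' the weighted sum of the eight probabilities. `N` positions count toward
#' sequence length but toward no base.
#'
#' @param seq Nucleotide string, length >= 3.
#' @return Scalar score.
#' @export
fickett_score <- function(seq) {
  L <- nchar(seq)
  if (L < 3L) stop("fickett_score needs at least 3 nt")
  ch <- seq_chars(seq)
  frame <- (seq_along(ch) - 1L) %% 3L
  score <- 0
  for (b in NT_BASES) {
    counts <- vapply(0:2, function(f) sum(ch == b & frame == f), numeric(1))
    pos_stat <- max(counts) / (min(counts) + 1)
    content <- sum(ch == b) / L
    score <- score +
      fickett_lookup(pos_stat, FICKETT_POSITION_PARA, FICKETT_POSITION_PROB[[b]]) *
        FICKETT_POSITION_WEIGHT[[b]] +
      fickett_lookup(content, FICKETT_CONTENT_PARA, FICKETT_CONTENT_PROB[[b]]) *
        FICKETT_CONTENT_WEIGHT[[b]]
  }
  unname(score)
}

#' Nucleotide composition/transition/distribution descriptor
#'
#' 30 values in fixed order: composition of A, T, G, C (count/L); the six
#' unordered adjacent hetero-pair transition frequencies AT, AC, AG, TG,
#' TC, GC over the L-1 adjacent positions; and for each base the five
#' positional quantiles of its occurrences — with `c` occurrences at
#' 1-based positions `p_1..p_c`, the slots are `p_idx / L` at occurrence
#' indices `1, max(1, floor(0.25 c)), max(1, floor(0.5 c)),
#' max(1, floor(0.75 c)), c`. An absent base contributes zeros.
#'
#' @param seq Nucleotide string, length >= 2.
#' @return Named numeric vector of length 30.
#' @export
ctd_nt <- function(seq) {
  L <- nchar(seq)
  if (L < 2L) stop("ctd_nt needs at least 2 nt")
  ch <- seq_chars(seq)
  comp <- vapply(c("A", "T", "G", "C"), function(b) sum(ch == b) / L, numeric(1))
  names(comp) <- paste0("ctd.comp_", c("A", "T", "G", "C"))

  left <- ch[-L]; right <- ch[-1L]
  pairs <- c("AT", "AC", "AG", "TG", "TC", "GC")
  trans <- vapply(pairs, function(p) {
    x <- substr(p, 1L, 1L); y <- substr(p, 2L, 2L)
    sum((left == x & right == y) | (left == y & right == x)) / (L - 1L)
  }, numeric(1))
  names(trans) <- paste0("ctd.trans_", pairs)

  dist <- numeric(0)
  for (b in c("A", "T", "G", "C")) {
    p <- which(ch == b)
    cc <- length(p)
    slots <- if (cc == 0L) rep(0, 5) else {
      idx <- c(1L, pmax(1L, floor(c(0.25, 0.5, 0.75) * cc)), cc)
      p[idx] / L
    }
    names(slots) <- paste0("ctd.dist_", b, 0:4)
    dist <- c(dist, slots)
  }
  c(comp, trans, dist)
}

#' Encode a nucleotide sORF into its three feature blocks
#'
#' Concatenates, in fixed order, the combined 3-mer+4-mer block (750), the
#' Fickett score (1) and CTD (30) into a 781-dimensional named vector.
#'
#' @param seq Nucleotide string.
#' @param denominator_mode Passed to [kmer_nt()].
#' @return Named numeric vector of length 781.
#' @export
encode_nt <- function(seq, denominator_mode = "windows") {
  c(kmer_nt(seq, denominator_mode = denominator_mode),
    c(fickett = fickett_score(seq)),
    ctd_nt(seq))
}
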