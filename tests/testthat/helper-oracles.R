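# Shared fixtures: random sequence generators and independent brute-force
# oracles for the encoders and metrics. The oracles deliberately use naive
# loops and direct formula transcription, never the package's own
# implementation paths.

random_nt <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                               collapse = "")

random_aa <- function(L) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], L, TRUE),
        collapse = "")
}

# The printed CTD worked example (33 nt).
CTD_EXAMPLE <- "ATGGATCCTAGAACCTGTTCTAGAAGGAGACGC"

oracle_kmer <- function(seq, k, alphabet, mode = "windows") {
  L <- nchar(seq)
  kmers <- expand.grid(rep(list(alphabet), k), stringsAsFactors = FALSE)
  kmers <- apply(kmers[, rev(seq_len(k)), drop = FALSE], 1L, paste0,
                 collapse = "")
  denom <- if (mode == "windows") L - k + 1L else max(L - k - 1L, 1L)
  vapply(kmers, function(km) {
    hits <- 0L
    for (i in seq_len(max(L - k + 1L, 0L))) {
      if (substr(seq, i, i + k - 1L) == km) hits <- hits + 1L
    }
    hits / denom
  }, numeric(1))
}

oracle_ctd <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  out <- numeric(0)
  for (b in c("A", "T", "G", "C")) out <- c(out, sum(ch == b) / L)
  for (p in c("AT", "AC", "AG", "TG", "TC", "GC")) {
    x <- substr(p, 1, 1); y <- substr(p, 2, 2)
    hits <- 0L
    for (i in 1:(L - 1L)) {
      if ((ch[i] == x && ch[i + 1L] == y) || (ch[i] == y && ch[i + 1L] == x)) {
        hits <- hits + 1L
      }
    }
    out <- c(out, hits / (L - 1L))
  }
  for (b in c("A", "T", "G", "C")) {
    pos <- which(ch == b)
    cc <- length(pos)
    if (cc == 0L) { out <- c(out, rep(0, 5)); next }
    for (q in c(0, 0.25, 0.5, 0.75, 1)) {
      idx <- if (q == 0) 1L else if (q == 1) cc else max(1L, floor(q * cc))
      out <- c(out, pos[idx] / L)
    }
  }
  out
}

oracle_frame_counts <- function(seq, base) {
  ch <- strsplit(seq, "")[[1]]
  vapply(0:2, function(f) {
    sum(ch[seq_along(ch) %% 3L == (f + 1L) %% 3L] == base)
  }, numeric(1))
}

# Independent transcription of the TESTCODE scoring walk: explicit frame
# tallies and a linear scan of the probability bins.
oracle_fickett <- function(seq) {
  pos_para <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
  con_para <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0)
  pos_prob <- list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  pos_w <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
  con_prob <- list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.35, 0.31, 0.17, 0.20),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  con_w <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  lookup <- function(value, para, prob) {
    for (j in seq_along(para)) if (value >= para[j]) return(prob[j])
    prob[length(prob)]
  }
  total <- 0
  for (b in c("A", "C", "G", "T")) {
    fc <- oracle_frame_counts(seq, b)
    stat <- max(fc) / (min(fc) + 1)
    content <- sum(strsplit(seq, "")[[1]] == b) / nchar(seq)
    total <- total + lookup(stat, pos_para, pos_prob[[b]]) * pos_w[[b]] +
      lookup(content, con_para, con_prob[[b]]) * con_w[[b]]
  }
  total
}

oracle_aac <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(aas, function(a) sum(ch == a) / length(ch), numeric(1))
}

oracle_paac <- function(seq, lag, w, tables) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  theta <- numeric(lag)
  for (d in seq_len(lag)) {
    acc <- 0
    for (i in 1:(L - d)) {
      s <- 0
      for (tb in tables) s <- s + (tb[[ch[i]]] - tb[[ch[i + d]]])^2
      acc <- acc + s / length(tables)
    }
    theta[d] <- acc / (L - d)
  }
  f <- oracle_aac(seq)
  denom <- 1 + w * sum(theta)
  c(f / denom, w * theta / denom)
}

oracle_apaac <- function(seq, lag, w, tables) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  props <- tables[c("hydrophobicity", "hydrophilicity")]
  tau <- numeric(0)
  for (d in seq_len(lag)) {
    for (tb in props) {
      acc <- 0
      for (i in 1:(L - d)) acc <- acc + tb[[ch[i]]] * tb[[ch[i + d]]]
      tau <- c(tau, acc / (L - d))
    }
  }
  f <- oracle_aac(seq)
  denom <- 1 + w * sum(tau)
  c(f / denom, w * tau / denom)
}

oracle_qsorder <- function(seq, lag, w, matrices) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  counts <- vapply(aas, function(a) sum(ch == a), numeric(1))
  out <- numeric(0)
  for (m in matrices) {
    tau <- numeric(lag)
    for (d in seq_len(lag)) {
      acc <- 0
      for (i in 1:(L - d)) acc <- acc + m[ch[i], ch[i + d]]^2
      tau[d] <- acc
    }
    denom <- sum(counts) + w * sum(tau)
    out <- c(out, counts / denom, w * tau / denom)
  }
  out
}

oracle_metrics <- function(tp, tn, fp, fn) {
  sn <- if (tp + fn == 0) 0 else tp / (tp + fn)
  sp <- if (fp + tn == 0) 0 else tn / (fp + tn)
  acc <- (tp + tn) / (tp + fp + fn + tn)
  pre <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  den <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  c(SN = sn, SP = sp, MCC = mcc, ACC = acc, PRE = pre, F1 = f1)
}

# Pairwise (Mann-Whitney) AUC: probability a random positive outscores a
# random negative, ties counted half.
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Small labeled confusion fixture: scores placed deterministically around
# the 0.5 threshold to realize exact TP/TN/FP/FN counts.
confusion_scores <- function(tp, tn, fp, fn) {
  y <- c(rep(1, tp), rep(0, tn), rep(1, fn), rep(0, fp))
  s <- c(rep(0.9, tp), rep(0.1, tn), rep(0.1, fn), rep(0.9, fp))
  list(y = y, s = s)
}
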