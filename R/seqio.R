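# Paired FASTA / label-table input-output and dataset plumbing.
#
# A dataset is a plain data.frame with columns id, nt, aa and optionally
# label (0/1). FASTA parsing and writing go through Biostrings; validation,
# alphabet normalization and pairing live here.

#' Read a FASTA file of nucleotide or amino-acid sequences
#'
#' Headers are `>`-lines; the record id is the header token up to the first
#' whitespace; wrapped sequence lines are joined and case-folded to upper.
#' Characters outside the alphabet (`ACGTN` for `nt`, the 20 canonical
#' residues plus `X` for `aa`) are mapped to the unknown symbol (`N`/`X`)
#' with a warning when `map_unknown = TRUE` (the default), otherwise raise
#' an error naming the record.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nt"` or `"aa"`.
#' @param map_unknown Map out-of-alphabet characters to `N`/`X` instead of
#'   erroring.
#' @return Named character vector of sequences, in order of appearance.
#' @export
read_fasta <- function(path, alphabet = c("nt", "aa"), map_unknown = TRUE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("malformed FASTA header: empty id in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("empty FASTA record: ", ids[nchar(seqs) == 0L][1L])
  }
  names(seqs) <- ids
  allowed <- if (alphabet == "nt") NT_ALPHABET else c(AA_ALPHABET, "X")
  unknown_sym <- if (alphabet == "nt") "N" else "X"
  bad <- vapply(seqs, function(s) {
    ch <- unique(strsplit(s, "")[[1]])
    any(!ch %in% allowed)
  }, logical(1))
  if (any(bad)) {
    if (!map_unknown) {
      id1 <- ids[bad][1L]
      ch <- setdiff(unique(strsplit(seqs[[which(bad)[1L]]], "")[[1]]), allowed)
      stop("invalid character(s) ", paste(ch, collapse = ","),
           " in record ", id1)
    }
    warning(sum(bad), " record(s) contained out-of-alphabet characters; ",
            "mapped to ", unknown_sym)
    pat <- paste0("[^", paste(allowed, collapse = ""), "]")
    seqs[bad] <- gsub(pat, unknown_sym, seqs[bad])
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Pair nucleotide and peptide records by id
#'
#' One record per id present in both maps, in the nucleotide map's order;
#' ids present in only one map are reported via message.
#'
#' @param nt_map,aa_map Named character vectors from [read_fasta()].
#' @param labels Optional named integer vector (0/1) of labels by id.
#' @param strict If `TRUE`, require `nchar(nt)` to be `3*nchar(aa)` or
#'   `3*(nchar(aa)+1)`; otherwise mismatches only warn.
#' @return A data.frame with columns `id`, `nt`, `aa` and, when labels are
#'   supplied, `label`.
#' @export
pair_records <- function(nt_map, aa_map, labels = NULL, strict = FALSE) {
  if (length(nt_map) == 0L || length(aa_map) == 0L) {
    stop("both sequence maps must be non-empty")
  }
  common <- names(nt_map)[names(nt_map) %in% names(aa_map)]
  if (length(common) == 0L) stop("no ids shared between the nt and aa files")
  only_nt <- setdiff(names(nt_map), common)
  only_aa <- setdiff(names(aa_map), common)
  if (length(only_nt) || length(only_aa)) {
    message(length(only_nt), " nt-only and ", length(only_aa),
            " aa-only id(s) dropped during pairing")
  }
  ds <- data.frame(
    id = common,
    nt = unname(nt_map[common]),
    aa = unname(aa_map[common]),
    stringsAsFactors = FALSE
  )
  len_ok <- nchar(ds$nt) == 3L * nchar(ds$aa) |
    nchar(ds$nt) == 3L * (nchar(ds$aa) + 1L)
  if (!all(len_ok)) {
    msg <- paste0(sum(!len_ok), " pair(s) violate the nt/aa length relation",
                  " (first: ", ds$id[!len_ok][1L], ")")
    if (strict) stop(msg) else warning(msg)
  }
  if (!is.null(labels)) {
    miss <- setdiff(ds$id, names(labels))
    if (length(miss)) {
      stop("labels missing for id(s): ",
           paste(utils::head(miss, 5L), collapse = ", "))
    }
    ds$label <- as.integer(labels[ds$id])
    if (!all(ds$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  }
  ds
}

#' Read a two-column id/label table
#'
#' Headerless TSV `id<TAB>label` with label in \{0, 1\}.
#'
#' @param path Path to the table.
#' @return Named integer vector of labels.
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = c("character", "integer"))
  if (ncol(tab) != 2L) stop("label table must have exactly two columns")
  if (anyDuplicated(tab[[1]])) stop("duplicate id in label table: ",
                                    tab[[1]][duplicated(tab[[1]])][1L])
  if (!all(tab[[2]] %in% c(0L, 1L))) stop("labels must be 0 or 1")
  stats::setNames(tab[[2]], tab[[1]])
}

#' Write an id/label table
#' @param labels Named integer vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(names(labels), unname(labels)), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Translate a nucleotide sequence in a fixed frame
#'
#' Standard genetic code; translation stops before the first stop codon;
#' codons containing `N` translate to `X`; a trailing partial codon is
#' dropped.
#'
#' @param nt Nucleotide string over `ACGTN`.
#' @param frame 0, 1 or 2.
#' @return Peptide string (possibly empty).
#' @export
translate_orf <- function(nt, frame = 0L) {
  stopifnot(frame %in% 0:2)
  nt <- toupper(nt)
  s <- substring(nt, frame + 1L, nchar(nt))
  n_codon <- nchar(s) %/% 3L
  if (n_codon == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(s, starts, starts + 2L)
  code <- Biostrings::GENETIC_CODE
  aa <- ifelse(grepl("N", codons, fixed = TRUE), "X",
               unname(code[codons]))
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1L] - 1L)]
  paste(aa, collapse = "")
}

# Gapless global identity between two peptides: best over all relative
# offsets of (#matching aligned positions) / max(len_a, len_b).
pair_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  denom <- max(la, lb)
  best <- 0
  for (off in seq.int(-(lb - 1L), la - 1L)) {
    ia <- max(1L, 1L + off); ib <- max(1L, 1L - off)
    n <- min(la - ia, lb - ib) + 1L
    m <- sum(ca[ia:(ia + n - 1L)] == cb[ib:(ib + n - 1L)])
    if (m / denom > best) best <- m / denom
  }
  best
}

#' Greedy redundancy filter on peptide sequences
#'
#' A lightweight stand-in for CD-HIT-style clustering: records are visited
#' longest peptide first (ties broken by input order) and a record is
#' dropped when its gapless global identity to any already-retained record
#' is at least `identity_threshold`. Identity is the best, over all
#' ungapped relative offsets, of matching positions divided by the longer
#' sequence length. Deterministic given the input; not equivalent to CD-HIT.
#'
#' @param ds Dataset data.frame with columns `id`, `nt`, `aa`.
#' @param identity_threshold Fraction in (0, 1].
#' @return The filtered dataset, in original row order.
#' @export
redundancy_filter <- function(ds, identity_threshold = 0.8) {
  if (nrow(ds) == 0L) stop("dataset is empty")
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 1) {
    stop("identity_threshold must be in (0, 1]")
  }
  ord <- order(-nchar(ds$aa), seq_len(nrow(ds)))
  kept <- integer(0)
  for (i in ord) {
    drop <- FALSE
    for (j in kept) {
      if (pair_identity(ds$aa[i], ds$aa[j]) >= identity_threshold) {
        drop <- TRUE
        break
      }
    }
    if (!drop) kept <- c(kept, i)
  }
  ds[sort(kept), , drop = FALSE]
}

#' Subsample a labeled dataset to a class ratio
#'
#' Subsamples without replacement so that positives:negatives is `ratio`
#' (a length-2 numeric, e.g. `c(1, 1)`), reproducibly under `seed`.
#'
#' @param ds Labeled dataset data.frame.
#' @param ratio Length-2 numeric `c(pos, neg)`.
#' @param seed Integer seed.
#' @return Balanced dataset, rows in original order.
#' @export
balance_dataset <- function(ds, ratio = c(1, 1), seed) {
  if (is.null(ds$label)) stop("dataset has no labels")
  pos <- which(ds$label == 1L)
  neg <- which(ds$label == 0L)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both classes must be present to balance")
  }
  stopifnot(length(ratio) == 2L, all(ratio > 0))
  m <- min(length(pos) / ratio[1], length(neg) / ratio[2])
  n_pos <- floor(m * ratio[1])
  n_neg <- floor(m * ratio[2])
  withr::with_seed(seed, {
    take <- c(sample(pos, n_pos), sample(neg, n_neg))
  })
  ds[sort(take), , drop = FALSE]
}
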