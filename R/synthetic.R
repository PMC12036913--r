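# Synthetic paired sORF/SEP generator with tunable class separation.

codon_table_by_aa <- function() {
  code <- Biostrings::GENETIC_CODE
  split(names(code), unname(code))
}

#' Generate a labeled synthetic sORF/SEP dataset
#'
#' Emulates a balanced coding/non-coding benchmark of paired nucleotide
#' and peptide records. Peptide lengths are uniform in `len_range_aa`;
#' every peptide starts with M and the nucleotide sequence is the
#' ATG-initiated codon spelling of the peptide plus one stop codon drawn
#' uniformly from TAA/TAG/TGA, so `nchar(nt) = 3 * (nchar(aa) + 1)` and
#' frame-0 translation returns the peptide exactly.
#'
#' Class separation is injected at the distribution level, not by motif
#' planting: positive residues are drawn with probability proportional to
#' `exp(delta * h / 2)` (h = standardized hydrophobicity) and positive
#' codons with a synonymous-codon bias favouring G/C third positions by a
#' factor `exp(delta / 2)`; negatives draw residues and synonymous codons
#' uniformly. `delta = 0` makes both classes identically distributed.
#'
#' @param n_pos,n_neg Class counts.
#' @param len_range_aa Peptide length range, minimum at least 10.
#' @param delta Separation strength, >= 0 (0 = null). Default 1.
#' @param seed Integer seed; output is fully reproducible.
#' @return Labeled dataset data.frame (`id`, `nt`, `aa`, `label`),
#'   positives first.
#' @export
simulate_sorf_data <- function(n_pos = 500L, n_neg = 500L,
                               len_range_aa = c(10L, 60L), delta = 1,
                               seed = 1L) {
  if (n_pos < 1L || n_neg < 1L) stop("class counts must be >= 1")
  if (length(len_range_aa) != 2L || len_range_aa[1L] > len_range_aa[2L] ||
      len_range_aa[1L] < 10L) {
    stop("len_range_aa must be an ordered pair with minimum >= 10")
  }
  if (delta < 0) stop("delta must be >= 0")
  codons <- codon_table_by_aa()
  codons <- codons[names(codons) != "*"]
  stops <- c("TAA", "TAG", "TGA")
  h <- aa_property_tables()$hydrophobicity
  res_prob_pos <- exp(delta * h / 2)
  res_prob_pos <- res_prob_pos / sum(res_prob_pos)
  gc3 <- lapply(codons, function(cs) {
    as.integer(substr(cs, 3L, 3L) %in% c("G", "C"))
  })

  draw_record <- function(positive) {
    L <- sample(len_range_aa[1L]:len_range_aa[2L], 1L)
    body <- if (positive) {
      sample(AA_ALPHABET, L - 1L, replace = TRUE, prob = res_prob_pos)
    } else {
      sample(AA_ALPHABET, L - 1L, replace = TRUE)
    }
    pep <- c("M", body)
    nt <- vapply(pep, function(a) {
      cs <- codons[[a]]
      if (positive && length(cs) > 1L) {
        sample(cs, 1L, prob = exp(delta / 2 * gc3[[a]]))
      } else {
        cs[sample.int(length(cs), 1L)]
      }
    }, character(1))
    list(aa = paste(pep, collapse = ""),
         nt = paste(c(nt, sample(stops, 1L)), collapse = ""))
  }

  withr::with_seed(seed, {
    recs <- c(lapply(seq_len(n_pos), function(i) draw_record(TRUE)),
              lapply(seq_len(n_neg), function(i) draw_record(FALSE)))
  })
  data.frame(
    id = sprintf("sorf_%05d", seq_len(n_pos + n_neg)),
    nt = vapply(recs, `[[`, character(1), "nt"),
    aa = vapply(recs, `[[`, character(1), "aa"),
    label = rep(c(1L, 0L), c(n_pos, n_neg)),
    stringsAsFactors = FALSE
  )
}

#' Write a dataset as paired FASTA files plus a label table
#'
#' @param ds Dataset data.frame.
#' @param prefix Output prefix; writes `<prefix>_nt.fasta`,
#'   `<prefix>_aa.fasta` and, when labels are present,
#'   `<prefix>_labels.tsv`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(ds, prefix) {
  paths <- c(nt = paste0(prefix, "_nt.fasta"),
             aa = paste0(prefix, "_aa.fasta"))
  write_fasta(stats::setNames(ds$nt, ds$id), paths[["nt"]])
  write_fasta(stats::setNames(ds$aa, ds$id), paths[["aa"]])
  if (!is.null(ds$label)) {
    paths <- c(paths, labels = paste0(prefix, "_labels.tsv"))
    write_labels(stats::setNames(ds$label, ds$id), paths[["labels"]])
  }
  invisible(paths)
}
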