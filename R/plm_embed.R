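# Per-peptide embeddings: a deterministic stub for offline work, TSV
# read/write, and an adapter slot for a real protein-language-model
# backend.
#
# An embedding matrix is a numeric matrix with one row per record
# (rownames = ids) and attributes `source` and `width`.

embedding_matrix <- function(m, source) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !anyDuplicated(rownames(m)))
  attr(m, "source") <- source
  attr(m, "width") <- ncol(m)
  m
}

stub_token_hash <- function(seq) {
  codes <- utf8ToInt(seq)
  L <- length(codes)
  if (L < 3L) codes <- c(codes, rep(88L, 3L - L))  # pad short input with 'X'
  L <- length(codes)
  h <- codes[1:(L - 2L)] * 961L + codes[2:(L - 1L)] * 31L + codes[3:L]
  h %% 104729L
}

#' Deterministic stub embedding of a peptide
#'
#' A fixed, seed-keyed function of the sequence standing in for a protein
#' language model: each overlapping 3-mer token is hashed and, jointly with
#' its position, projected through seed-derived sinusoidal random features;
#' token contributions are summed and the result scaled to unit norm. The
#' map is reproducible, sequence-sensitive and permutation-sensitive; it
#' encodes local composition only, none of the evolutionary structure a
#' trained language model captures.
#'
#' @param seq Peptide string.
#' @param width Embedding width (default 1280).
#' @param seed Integer seed keying the projection.
#' @return Numeric vector of length `width` with unit L2 norm.
#' @export
embed_stub <- function(seq, width = 1280L, seed = 1L) {
  stopifnot(width >= 1L)
  proj <- withr::with_seed(seed, {
    list(a = stats::runif(width, 0.01, 2), b = stats::runif(width, 0.01, 2),
         c = stats::runif(width, 0, 2 * pi))
  })
  h <- stub_token_hash(toupper(seq))
  pos <- seq_along(h)
  phase <- outer(h, proj$a) + outer(pos, proj$b)
  v <- colSums(sin(sweep(phase, 2L, proj$c, "+")))
  v / sqrt(sum(v^2))
}

#' Embed every record of a dataset
#'
#' @param ds Dataset data.frame with columns `id` and `aa`.
#' @param source `"stub"` (default), `"file"` (read a precomputed TSV) or
#'   `"esm2"` (external adapter; see [embed_esm2()]).
#' @param width Stub width.
#' @param seed Stub seed.
#' @param path TSV path for `source = "file"`.
#' @return Embedding matrix with one row per record, in dataset order.
#' @export
embed_dataset <- function(ds, source = c("stub", "file", "esm2"),
                          width = 1280L, seed = 1L, path = NULL) {
  source <- match.arg(source)
  if (source == "stub") {
    proj <- withr::with_seed(seed, {
      list(a = stats::runif(width, 0.01, 2), b = stats::runif(width, 0.01, 2),
           c = stats::runif(width, 0, 2 * pi))
    })
    m <- t(vapply(ds$aa, function(s) {
      h <- stub_token_hash(toupper(s))
      phase <- outer(h, proj$a) + outer(seq_along(h), proj$b)
      v <- colSums(sin(sweep(phase, 2L, proj$c, "+")))
      v / sqrt(sum(v^2))
    }, numeric(width), USE.NAMES = FALSE))
    rownames(m) <- ds$id
    embedding_matrix(m, "stub")
  } else if (source == "file") {
    if (is.null(path)) stop("source = 'file' needs a path")
    em <- read_embeddings(path)
    miss <- setdiff(ds$id, rownames(em))
    if (length(miss)) stop("embeddings missing for id(s): ",
                           paste(utils::head(miss, 5L), collapse = ", "))
    embedding_matrix(em[ds$id, , drop = FALSE], "file")
  } else {
    embed_esm2(ds$aa)
  }
}

#' ESM-2 adapter (not bundled)
#'
#' Placeholder for a real protein-language-model backend producing
#' mean-pooled 1280-dimensional final-layer representations. No model
#' weights or Python runtime are bundled; calling this raises an error
#' describing how to supply embeddings instead (precompute them with the
#' `esm` Python package and load with `source = "file"`). The rest of the
#' pipeline never requires it: every code path works with the stub.
#'
#' @param seqs Character vector of peptides.
#' @return Never returns.
#' @export
embed_esm2 <- function(seqs) {
  stop("No ESM-2 backend is bundled. Precompute embeddings externally ",
       "(e.g. with the 'esm' Python package, mean-pooling the final ",
       "layer to 1280 dims), write them as an id + 1280-column TSV and ",
       "load them with embed_dataset(ds, source = 'file', path = ...).")
}

#' Read / write an embedding TSV
#'
#' The format is one header-less row per record: id followed by a fixed
#' number of numeric columns, tab-separated.
#'
#' @param path File path.
#' @return `read_embeddings`: embedding matrix. `write_embeddings`:
#'   `path`, invisibly.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("embedding file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    stop("ragged embedding file at row ", which(widths != widths[1L])[1L])
  }
  if (widths[1L] < 2L) stop("embedding rows need an id plus numeric columns")
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate id in embedding file: ",
                               ids[duplicated(ids)][1L])
  m <- t(vapply(fields, function(f) as.numeric(f[-1L]),
                numeric(widths[1L] - 1L)))
  if (anyNA(m)) stop("non-numeric embedding value at row ",
                     which(apply(is.na(m), 1L, any))[1L])
  rownames(m) <- ids
  embedding_matrix(m, "file")
}

#' @rdname read_embeddings
#' @param em Embedding matrix.
#' @export
write_embeddings <- function(em, path) {
  lines <- vapply(seq_len(nrow(em)), function(i) {
    paste(c(rownames(em)[i], format(em[i, ], digits = 17, trim = TRUE,
                                    scientific = FALSE)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
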