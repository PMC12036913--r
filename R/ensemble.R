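# The stacked ensemble: fused-feature construction, the gradient-boosted
# tree branch, stratified out-of-fold stacking with a logistic-regression
# meta-learner, prediction and serialization.

# Canonical fused block order and compat-mode widths. The fused vector is
# AAC + APAAC + PAAC + QSOrder + aa k-mer + CTD + Fickett + nt k-mer =
# 20+26+23+46+841+30+1+750 = 1737.
FUSED_BLOCK_ORDER <- c("aac", "apaac", "paac", "qsorder", "kmer_aa",
                       "ctd", "fickett", "kmer_nt")
FUSED_BLOCK_WIDTHS <- c(aac = 20L, apaac = 26L, paac = 23L, qsorder = 46L,
                        kmer_aa = 841L, ctd = 30L, fickett = 1L,
                        kmer_nt = 750L)

#' Fuse amino-acid and nucleotide feature blocks
#'
#' Concatenates the eight named blocks in the canonical order
#' AAC, APAAC, PAAC, QSOrder, aa k-mer, CTD, Fickett, nt k-mer
#' (total width 1737 in compat mode). The caller's list order is
#' irrelevant; blocks are looked up by name, and a missing block or a
#' block of unexpected width is an error naming it.
#'
#' @param aa_blocks Named list with elements `aac`, `apaac`, `paac`,
#'   `qsorder`, `kmer_aa`.
#' @param nt_blocks Named list with elements `ctd`, `fickett`, `kmer_nt`.
#' @param widths Expected block widths (defaults to the compat layout).
#' @return Named numeric vector (length 1737 with default widths).
#' @export
fuse_features <- function(aa_blocks, nt_blocks, widths = FUSED_BLOCK_WIDTHS) {
  blocks <- c(aa_blocks, nt_blocks)
  miss <- setdiff(FUSED_BLOCK_ORDER, names(blocks))
  if (length(miss)) stop("missing feature block(s): ",
                         paste(miss, collapse = ", "))
  for (nm in FUSED_BLOCK_ORDER) {
    if (length(blocks[[nm]]) != widths[[nm]]) {
      stop("block '", nm, "' has width ", length(blocks[[nm]]),
           ", expected ", widths[[nm]])
    }
  }
  unlist(blocks[FUSED_BLOCK_ORDER])
}

#' Encode a paired dataset into the fused feature matrix
#'
#' Runs every nucleotide and amino-acid encoder on each record and fuses
#' the blocks; one row per record, 1737 columns in compat mode.
#'
#' @param ds Dataset data.frame with columns `id`, `nt`, `aa`.
#' @param lag,w Sequence-order parameters for PAAC/APAAC/QSOrder.
#' @param denominator_mode k-mer denominator convention.
#' @return Numeric matrix with rownames `ds$id` and named columns.
#' @export
encode_dataset <- function(ds, lag = 3L, w = 0.05,
                           denominator_mode = "windows") {
  tables <- aa_property_tables()
  matrices <- aa_distance_matrices()
  rows <- lapply(seq_len(nrow(ds)), function(i) {
    aa_seq <- ds$aa[i]; nt_seq <- ds$nt[i]
    fuse_features(
      aa_blocks = list(
        aac = aac(aa_seq),
        apaac = apaac(aa_seq, lag = lag, w = w, tables = tables),
        paac = paac(aa_seq, lag = lag, w = w, tables = tables),
        qsorder = qsorder(aa_seq, lag = lag, w = w, matrices = matrices),
        kmer_aa = kmer_aa(aa_seq, mode = "compat841",
                          denominator_mode = denominator_mode)
      ),
      nt_blocks = list(
        ctd = ctd_nt(nt_seq),
        fickett = c(fickett = fickett_score(nt_seq)),
        kmer_nt = kmer_nt(nt_seq, denominator_mode = denominator_mode)
      )
    )
  })
  m <- do.call(rbind, rows)
  rownames(m) <- ds$id
  m
}

#' Write a feature matrix as TSV plus a JSON column schema
#'
#' @param X Feature matrix with rownames (ids) and colnames.
#' @param path Output TSV path; the schema is written to `<path>.schema.json`.
#' @return `path`, invisibly.
#' @export
write_features <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  schema <- list(columns = colnames(X), n_features = ncol(X))
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Train the gradient-boosted-tree branch
#'
#' Depth-7 gradient-boosted trees minimizing binary log-loss; the branch
#' probability is the sigmoid of the additive tree score. Single-threaded
#' and seeded, so retraining on identical input reproduces identical
#' predictions.
#'
#' @param X Numeric feature matrix.
#' @param y Binary 0/1 labels.
#' @param nrounds Number of boosting rounds.
#' @param eta Learning rate.
#' @param max_depth Tree depth (default 7).
#' @param seed Integer seed.
#' @return Object of class `gbdt_branch`.
#' @export
train_gbdt <- function(X, y, nrounds = 150L, eta = 0.1, max_depth = 7L,
                       seed = 1L) {
  if (nrow(X) < 20L) stop("gbdt branch needs at least 20 records")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  fit <- withr::with_seed(seed, {
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1L, seed = seed,
                    tree_method = "hist", eval_metric = "logloss"),
      data = dtrain, nrounds = nrounds, verbose = 0
    )
  })
  structure(list(model = fit, nrounds = nrounds, eta = eta,
                 max_depth = max_depth, seed = seed,
                 feature_names = colnames(X)),
            class = "gbdt_branch")
}

#' Predict probabilities from the GBDT branch
#' @param object A `gbdt_branch`.
#' @param newdata Feature matrix with the training columns.
#' @param ... Unused.
#' @return Probabilities in (0, 1).
#' @export
predict.gbdt_branch <- function(object, newdata, ...) {
  if (!identical(colnames(newdata), object$feature_names)) {
    if (!all(object$feature_names %in% colnames(newdata))) {
      stop("feature layout mismatch: newdata lacks trained columns")
    }
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  p <- stats::predict(object$model, xgboost::xgb.DMatrix(newdata))
  pmin(pmax(p, 1e-9), 1 - 1e-9)
}

stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < k) {
        stop("a class has fewer records than folds; use fewer folds")
      }
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  fold
}

#' Fit the stacked sORF/SEP ensemble
#'
#' The central fitting function. Encodes the paired records into the
#' 1737-dimensional fused feature vector (unless a precomputed matrix is
#' supplied), obtains per-record embeddings (deterministic stub by
#' default), and fits the three-model stack: a depth-7 gradient-boosted
#' tree branch on the fused features, a self-attention network on the
#' embeddings, and a logistic-regression meta-learner on the two branch
#' probabilities. Meta-features are collected out-of-fold with stratified
#' `k_folds`-fold splitting so the meta-learner never sees in-sample
#' branch outputs; both branches are then refit on the full data.
#'
#' @param ds Labeled dataset data.frame (`id`, `nt`, `aa`, `label`).
#' @param features Optional precomputed fused feature matrix (rows
#'   matching `ds$id`).
#' @param embeddings Optional precomputed embedding matrix.
#' @param embed_source `"stub"`, `"file"` or `"esm2"` when `embeddings`
#'   is NULL.
#' @param embed_width Stub embedding width.
#' @param embed_path Embedding TSV for `embed_source = "file"`.
#' @param k_folds Stacking folds (default 5).
#' @param lag,w,denominator_mode Encoder options.
#' @param gbdt_nrounds,gbdt_eta GBDT branch options.
#' @param attention_epochs,attention_lr,d_model,d_hidden Attention branch
#'   options.
#' @param seed Master seed; all branch and fold seeds derive from it.
#' @return An object of class `sep_stack`.
#' @export
sep_stack <- function(ds, features = NULL, embeddings = NULL,
                      embed_source = "stub", embed_width = 1280L,
                      embed_path = NULL, k_folds = 5L, lag = 3L, w = 0.05,
                      denominator_mode = "windows", gbdt_nrounds = 150L,
                      gbdt_eta = 0.1, attention_epochs = 128L,
                      attention_lr = 0.001, d_model = 32L, d_hidden = 32L,
                      seed = 1L) {
  if (is.null(ds$label)) stop("training requires a labeled dataset")
  y <- as.integer(ds$label)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (k_folds < 2L) stop("k_folds must be at least 2")
  if (is.null(features)) {
    features <- encode_dataset(ds, lag = lag, w = w,
                               denominator_mode = denominator_mode)
  }
  if (is.null(embeddings)) {
    embeddings <- embed_dataset(ds, source = embed_source,
                                width = embed_width, seed = seed + 11L,
                                path = embed_path)
  }
  stopifnot(nrow(features) == nrow(ds), nrow(embeddings) == nrow(ds))

  fold <- stratified_folds(y, k_folds, seed + 23L)
  oof_ml <- numeric(length(y))
  oof_dl <- numeric(length(y))
  for (f in seq_len(k_folds)) {
    tr <- fold != f; te <- fold == f
    if (length(unique(y[tr])) < 2L) {
      stop("a training fold holds a single class; use fewer folds")
    }
    g <- train_gbdt(features[tr, , drop = FALSE], y[tr],
                    nrounds = gbdt_nrounds, eta = gbdt_eta,
                    seed = seed + 100L + f)
    a <- train_attention(embeddings[tr, , drop = FALSE], y[tr],
                         d_model = d_model, d_hidden = d_hidden,
                         lr = attention_lr, epochs = attention_epochs,
                         seed = seed + 200L + f)
    oof_ml[te] <- predict(g, features[te, , drop = FALSE])
    oof_dl[te] <- predict(a, embeddings[te, , drop = FALSE])
  }

  meta_df <- data.frame(y = y, ml = oof_ml, dl = oof_dl)
  meta <- stats::glm(y ~ ml + dl, family = stats::binomial(), data = meta_df)

  gbdt <- train_gbdt(features, y, nrounds = gbdt_nrounds, eta = gbdt_eta,
                     seed = seed + 100L)
  attn <- train_attention(embeddings, y, d_model = d_model,
                          d_hidden = d_hidden, lr = attention_lr,
                          epochs = attention_epochs, seed = seed + 200L)

  cv_eval <- evaluate_predictions(
    y, stats::plogis(stats::coef(meta)[1L] +
                       stats::coef(meta)[2L] * oof_ml +
                       stats::coef(meta)[3L] * oof_dl))

  structure(list(
    gbdt = gbdt,
    attention = attn,
    meta_coef = stats::coef(meta),
    layout = colnames(features),
    embed = list(source = attr(embeddings, "source"),
                 width = ncol(embeddings),
                 seed = seed + 11L, path = embed_path),
    encoder = list(lag = lag, w = w, denominator_mode = denominator_mode),
    k_folds = k_folds,
    seed = seed,
    oof = meta_df,
    cv_eval = cv_eval,
    n = length(y)
  ), class = "sep_stack")
}

meta_probability <- function(coefs, ml, dl) {
  stats::plogis(coefs[[1L]] + coefs[[2L]] * ml + coefs[[3L]] * dl)
}

#' Predict with a fitted stacked ensemble
#'
#' Encodes `newdata` with the stored encoder configuration and embedding
#' source, runs both branches, and combines them through the
#' logistic-regression meta-learner. A record is called a SEP
#' (`label_hat = 1`) when the ensemble probability `P` exceeds 0.5;
#' `P = 0.5` exactly is called negative.
#'
#' @param object A fitted `sep_stack`.
#' @param newdata Dataset data.frame (`id`, `nt`, `aa`); labels ignored.
#' @param features,embeddings Optional precomputed matrices.
#' @param ... Unused.
#' @return data.frame with columns `id`, `ML_Output`, `DL_Output`, `P`,
#'   `label_hat`.
#' @export
predict.sep_stack <- function(object, newdata, features = NULL,
                              embeddings = NULL, ...) {
  if (is.null(features)) {
    enc <- object$encoder
    features <- encode_dataset(newdata, lag = enc$lag, w = enc$w,
                               denominator_mode = enc$denominator_mode)
  }
  if (!identical(colnames(features), object$layout)) {
    stop("feature layout mismatch with the trained ensemble")
  }
  if (is.null(embeddings)) {
    if (object$embed$source == "esm2") {
      embeddings <- embed_esm2(newdata$aa)
    } else if (object$embed$source == "file") {
      embeddings <- embed_dataset(newdata, source = "file",
                                  path = object$embed$path)
    } else {
      embeddings <- embed_dataset(newdata, source = "stub",
                                  width = object$embed$width,
                                  seed = object$embed$seed)
    }
  }
  if (ncol(embeddings) != object$embed$width) {
    stop("embedding width mismatch with the trained ensemble")
  }
  ml <- predict(object$gbdt, features)
  dl <- predict(object$attention, embeddings)
  p <- meta_probability(object$meta_coef, ml, dl)
  data.frame(id = newdata$id, ML_Output = unname(ml), DL_Output = unname(dl),
             P = unname(p), label_hat = as.integer(unname(p) > 0.5),
             row.names = NULL)
}

#' @export
print.sep_stack <- function(x, ...) {
  cat("Stacked sORF/SEP ensemble\n")
  cat("  records: ", x$n, "   fused features: ", length(x$layout),
      "   embeddings: ", x$embed$source, " (", x$embed$width, "-dim)\n",
      sep = "")
  cat("  branches: depth-", x$gbdt$max_depth, " GBDT (",
      x$gbdt$nrounds, " rounds) + self-attention (",
      x$attention$epochs, " epochs)\n", sep = "")
  cat("  meta-learner: logit(P) = ",
      sprintf("%.3f", x$meta_coef[1L]), " + ",
      sprintf("%.3f", x$meta_coef[2L]), " * ML + ",
      sprintf("%.3f", x$meta_coef[3L]), " * DL\n", sep = "")
  invisible(x)
}

#' @export
summary.sep_stack <- function(object, ...) {
  print(object)
  cat("\nOut-of-fold (", object$k_folds, "-fold) stacking performance:\n",
      sep = "")
  print(object$cv_eval)
  invisible(object)
}

#' Meta-learner coefficients
#' @param object A `sep_stack`.
#' @param ... Unused.
#' @export
coef.sep_stack <- function(object, ...) object$meta_coef

#' ROC curve of the out-of-fold stacked predictions
#' @param x A `sep_stack`.
#' @param ... Passed to `plot`.
#' @export
plot.sep_stack <- function(x, ...) {
  roc <- x$cv_eval$roc
  plot(roc$fpr, roc$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("Out-of-fold ROC (AUC = %.3f)",
                      x$cv_eval$metrics[["AUC"]]), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Save / load a fitted ensemble bundle
#'
#' The bundle is a directory holding JSON metadata (block layout, encoder
#' and embedding configuration, seeds, meta-learner coefficients) plus the
#' two branch artifacts. A reloaded bundle reproduces predictions
#' bit-identically.
#'
#' @param object A fitted `sep_stack`.
#' @param dir Bundle directory (created if needed).
#' @return `save_sep_stack`: `dir`, invisibly. `load_sep_stack`: the
#'   restored `sep_stack`.
#' @export
save_sep_stack <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    package = "sepstack",
    meta_coef = as.list(object$meta_coef),
    layout = object$layout,
    embed = object$embed,
    encoder = object$encoder,
    k_folds = object$k_folds,
    seed = object$seed,
    n = object$n,
    gbdt = object$gbdt[c("nrounds", "eta", "max_depth", "seed")],
    attention = object$attention[c("width", "d_model", "d_hidden", "d_k",
                                   "lr", "epochs", "seed")]
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  xgboost::xgb.save(object$gbdt$model, file.path(dir, "gbdt.ubj"))
  saveRDS(object$attention, file.path(dir, "attention.rds"))
  # meta coefficients also live in the RDS artifact: the JSON copy is for
  # human inspection and cannot guarantee bit-exact doubles
  saveRDS(object[c("oof", "cv_eval", "meta_coef")],
          file.path(dir, "stacking.rds"))
  invisible(dir)
}

#' @rdname save_sep_stack
#' @export
load_sep_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  model <- xgboost::xgb.load(file.path(dir, "gbdt.ubj"))
  gbdt <- structure(list(model = model, nrounds = meta$gbdt$nrounds,
                         eta = meta$gbdt$eta,
                         max_depth = meta$gbdt$max_depth,
                         seed = meta$gbdt$seed,
                         feature_names = meta$layout),
                    class = "gbdt_branch")
  attn <- readRDS(file.path(dir, "attention.rds"))
  stacking <- readRDS(file.path(dir, "stacking.rds"))
  embed <- meta$embed
  if (is.null(embed$path)) embed["path"] <- list(NULL)
  structure(list(
    gbdt = gbdt, attention = attn,
    meta_coef = stacking$meta_coef,
    layout = meta$layout, embed = embed, encoder = meta$encoder,
    k_folds = meta$k_folds, seed = meta$seed,
    oof = stacking$oof, cv_eval = stacking$cv_eval, n = meta$n
  ), class = "sep_stack")
}
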