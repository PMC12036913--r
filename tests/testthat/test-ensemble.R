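make_blocks <- function(widths = c(aac = 20L, apaac = 26L, paac = 23L,
                                   qsorder = 46L, kmer_aa = 841L,
                                   ctd = 30L, fickett = 1L,
                                   kmer_nt = 750L)) {
  lapply(widths, function(w) seq_len(w) / w)
}

test_that("feature fusion is canonical, 1737-wide and width-checked", {
  b <- make_blocks()
  v <- fuse_features(b[c("aac", "apaac", "paac", "qsorder", "kmer_aa")],
                     b[c("ctd", "fickett", "kmer_nt")])
  expect_length(v, 1737L)
  # caller-side permutation must not change the output
  v2 <- fuse_features(b[c("kmer_aa", "paac", "aac", "qsorder", "apaac")],
                      b[c("fickett", "kmer_nt", "ctd")])
  expect_identical(v, v2)

  bad <- b
  bad$aac <- seq_len(22L)
  expect_error(fuse_features(bad[c("aac", "apaac", "paac", "qsorder",
                                   "kmer_aa")],
                             b[c("ctd", "fickett", "kmer_nt")]),
               "width 22")
  expect_error(fuse_features(b[c("aac", "apaac")],
                             b[c("ctd", "fickett", "kmer_nt")]),
               "missing feature block")
})

test_that("encoded datasets have one 1737-row per record", {
  ds <- simulate_sorf_data(5, 5, seed = 2)
  X <- encode_dataset(ds)
  expect_identical(dim(X), c(10L, 1737L))
  expect_identical(rownames(X), ds$id)
  expect_identical(X, encode_dataset(ds))
})

test_that("the GBDT branch separates blobs and is seed-deterministic", {
  set.seed(71)
  n <- 200
  y <- rep(c(1, 0), each = n / 2)
  X <- cbind(x1 = rnorm(n, mean = 3 * y), x2 = rnorm(n, mean = -3 * y))
  g <- train_gbdt(X, y, nrounds = 40L, seed = 5L)
  p <- predict(g, X)
  expect_true(all(p > 0 & p < 1))
  expect_gte(mean((p > 0.5) == y), 0.99)
  g2 <- train_gbdt(X, y, nrounds = 40L, seed = 5L)
  expect_identical(predict(g2, X), p)
  expect_error(train_gbdt(X, rep(1, n), nrounds = 5L), "both classes")
})

test_that("the attention branch learns a separable embedding fixture", {
  set.seed(73)
  n <- 400; wd <- 64
  mu <- rnorm(wd) / sqrt(wd)
  y <- rep(c(1, 0), each = n / 2)
  E <- t(sapply(y, function(yi) (2 * yi - 1) * mu + rnorm(wd, sd = 0.5)))
  tr <- sort(sample(n, 300)); te <- setdiff(seq_len(n), tr)
  a <- train_attention(E[tr, ], y[tr], seed = 3L)
  auc <- evaluate_predictions(y[te], predict(a, E[te, ]))$metrics[["AUC"]]
  expect_gte(auc, 0.95)

  w <- attention_weights(a, E[te, ])
  expect_true(all(rowSums(w) == 1))

  a2 <- train_attention(E[tr, ], y[tr], seed = 3L)
  expect_equal(a$final_loss, a2$final_loss, tolerance = 1e-6)
  expect_identical(predict(a2, E[te, ]), predict(a, E[te, ]))
  expect_error(predict(a, E[te, 1:10]), "width")
  expect_error(train_attention(E, rep(1, n)), "both classes")
})

test_that("stacking collects exactly one out-of-fold pair per record", {
  ds <- simulate_sorf_data(30, 30, seed = 11)
  fit <- sep_stack(ds, embed_width = 64L, k_folds = 3L,
                   gbdt_nrounds = 15L, attention_epochs = 16L, seed = 4L)
  expect_identical(dim(fit$oof), c(60L, 3L))
  expect_true(all(fit$oof$ml > 0 & fit$oof$ml < 1))
  expect_true(all(fit$oof$dl > 0 & fit$oof$dl < 1))
  expect_length(coef(fit), 3L)
  expect_error(sep_stack(ds, k_folds = 1L), "at least 2")
  expect_error(sep_stack(ds[ds$label == 1L, ], k_folds = 2L),
               "both classes")
})

test_that("the meta combination follows the printed sigmoid decision rule", {
  ds <- simulate_sorf_data(15, 15, seed = 13)
  fit <- sep_stack(ds, embed_width = 32L, k_folds = 3L,
                   gbdt_nrounds = 10L, attention_epochs = 8L, seed = 6L)

  # degenerate weights: P = 0.5 everywhere, tie broken to the negative class
  fit0 <- fit
  fit0$meta_coef <- c(0, 0, 0)
  pred0 <- predict(fit0, ds)
  expect_true(all(pred0$P == 0.5))
  expect_true(all(pred0$label_hat == 0L))

  # direct evaluation of the linear-combination + sigmoid formula
  expect_equal(sepstack:::meta_probability(c(-4, 4, 4), 1, 1),
               1 / (1 + exp(-4)), tolerance = 1e-12)
  pred <- predict(fit, ds)
  expect_equal(pred$P,
               plogis(coef(fit)[1] + coef(fit)[2] * pred$ML_Output +
                        coef(fit)[3] * pred$DL_Output),
               tolerance = 1e-12)
  expect_identical(pred$label_hat, as.integer(pred$P > 0.5))
})

test_that("a saved and reloaded bundle reproduces predictions exactly", {
  ds <- simulate_sorf_data(15, 15, seed = 17)
  fit <- sep_stack(ds, embed_width = 32L, k_folds = 3L,
                   gbdt_nrounds = 10L, attention_epochs = 8L, seed = 8L)
  pred <- predict(fit, ds)
  dir <- withr::local_tempdir()
  save_sep_stack(fit, dir)
  back <- load_sep_stack(dir)
  expect_identical(predict(back, ds), pred)
  expect_equal(coef(back), coef(fit), tolerance = 1e-15)
})

test_that("print, summary and plot methods run cleanly", {
  ds <- simulate_sorf_data(16, 16, seed = 19)
  fit <- sep_stack(ds, embed_width = 32L, k_folds = 3L,
                   gbdt_nrounds = 5L, attention_epochs = 4L, seed = 9L)
  expect_output(print(fit), "Stacked sORF/SEP ensemble")
  expect_output(summary(fit), "Out-of-fold")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
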