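# tiny reusable memorisation corpus: one 3-species sentence repeated
memo_setup <- function(epochs = 30) {
  sp <- c("alpha unum", "beta duo", "gamma tres")
  sents <- rep(list(sentence_of(sp, covers = c(30, 20, 10))), 50)
  vocab <- fit_vocabulary(sents, "species")
  cfg <- lm_config(layers = 2, hidden = 32, heads = 2, ffn = 64,
                   epochs = epochs, batch_size = 8, seed = 7, lr = 2e-3)
  list(sp = sp, sents = sents, vocab = vocab, cfg = cfg)
}

test_that("analytic gradients match central finite differences", {
  cfg <- lm_config(layers = 2, hidden = 8, heads = 2, ffn = 12, seed = 3,
                   max_len = 12)
  V <- 11L
  params <- with_seed(11, init_params(V, cfg, n_classes = 3))
  for (nm in names(params))
    if (is.matrix(params[[nm]]) && !nm %in% c("Wc"))
      params[[nm]] <- params[[nm]] * 12  # non-degenerate attention
  ids <- matrix(-1L, 3, 7)
  lens <- c(7L, 5L, 6L)
  ids[1, 1:7] <- c(0L, 6L, 4L, 7L, 4L, 8L, 1L)
  ids[2, 1:5] <- c(0L, 9L, 4L, 10L, 1L)
  ids[3, 1:6] <- c(0L, 5L, 4L, 2L, 4L, 1L)
  labels <- matrix(-1L, 3, 7)
  labels[1, 4] <- 7L; labels[3, 4] <- 8L; labels[2, 2] <- 9L
  classes <- c(0L, 2L, 1L)
  eps <- 1e-5
  for (mode in 0:1) {
    target <- if (mode == 0) labels else classes
    res <- cpp_loss_grads(params, ids, target, lens, cfg$layers,
                          cfg$heads, mode)
    for (nm in c("Wq_1", "Wk_2", "Wv_1", "Wo_2", "W1_1", "W2_2",
                 "ln1g_1", "ln2b_2", "tok_emb", "pos_emb", "out_b",
                 "Wp", "Wc")) {
      idx <- with_seed(derive_seed(77, nm, mode),
                       sample(length(params[[nm]]),
                              min(4, length(params[[nm]]))))
      for (i in idx) {
        p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
        num <- (cpp_loss_grads(p1, ids, target, lens, cfg$layers,
                               cfg$heads, mode)$loss -
                cpp_loss_grads(p2, ids, target, lens, cfg$layers,
                               cfg$heads, mode)$loss) / (2 * eps)
        ana <- res$grads[[nm]][i]
        expect_equal(ana, num, tolerance = 1e-4,
                     label = paste("grad", nm, "mode", mode))
      }
    }
  }
})

test_that("a tiny model memorises a degenerate corpus", {
  ms <- memo_setup()
  m <- train_mlm(ms$sents, ms$vocab, ms$cfg)
  expect_lt(tail(m$loss, 1), 0.5)
  for (i in seq_along(ms$sp)) {
    s <- ms$sp
    s[i] <- "[MASK]"
    top <- predict_topk(m, s, k = 3)[[1]]
    expect_equal(top$token[1], ms$sp[i])
  }
})

test_that("training is deterministic under the seed", {
  ms <- memo_setup(epochs = 3)
  m1 <- train_mlm(ms$sents, ms$vocab, ms$cfg)
  m2 <- train_mlm(ms$sents, ms$vocab, ms$cfg)
  expect_identical(m1$loss, m2$loss)
  expect_identical(m1$params$tok_emb, m2$params$tok_emb)
})

test_that("an untrained model outputs near-uniform distributions", {
  ms <- memo_setup(epochs = 0)
  m0 <- train_mlm(ms$sents, ms$vocab, ms$cfg)
  expect_length(m0$loss, 0)
  top <- predict_topk(m0, c("alpha unum", "[MASK]", "gamma tres"),
                      k = length(ms$vocab$tokens), renormalize = FALSE)[[1]]
  expect_equal(sum(top$prob), 1, tolerance = 1e-5)
  expect_lt(max(top$prob) / min(top$prob), 2)
})

test_that("top-k predictions renormalise to one and k=1 is certain", {
  ms <- memo_setup(epochs = 5)
  m <- train_mlm(ms$sents, ms$vocab, ms$cfg)
  top5 <- predict_topk(m, c("[MASK]", "beta duo"), k = 5)[[1]]
  expect_equal(sum(top5$prob_renorm), 1, tolerance = 1e-9)
  expect_true(all(diff(top5$prob) <= 0))
  top1 <- predict_topk(m, c("[MASK]", "beta duo"), k = 1)[[1]]
  expect_equal(top1$prob_renorm, 1)
  expect_error(predict_topk(m, c("alpha unum")), "no \\[MASK\\]")
})

test_that("perplexity obeys its closed-form laws", {
  cor <- tiny_corpus(30)
  vocab <- fit_vocabulary(cor$sentences, "species")
  u <- uniform_lm(vocab)
  pp <- perplexity(u, cor$sentences, seed = 2)
  expect_equal(pp$perplexity, vocab$n_content, tolerance = 1e-3)
  expect_equal(log(pp$perplexity), pp$cross_entropy, tolerance = 1e-6)
  expect_gte(pp$perplexity, 1)
  # near-perfect model: memorised corpus has perplexity close to 1
  ms <- memo_setup()
  m <- train_mlm(ms$sents, ms$vocab, ms$cfg)
  pm <- perplexity(m, ms$sents[1:10], seed = 2)
  expect_lt(pm$perplexity, 2)
  expect_gte(pm$perplexity, 1)
})

test_that("assemblage completion appends the missing species then stops", {
  ms <- memo_setup()
  m <- train_mlm(ms$sents, ms$vocab, ms$cfg)
  out <- complete_assemblage(m, ms$sp[1:2], max_additions = 5)
  expect_equal(out$species, ms$sp[3])
  expect_false(any(duplicated(c(ms$sp[1:2], out$species))))
  expect_equal(nrow(complete_assemblage(m, ms$sp[1:2],
                                        max_additions = 0)), 0)
  # full assemblage observed: the end-of-list token should win immediately
  full <- complete_assemblage(m, ms$sp, max_additions = 5)
  expect_equal(nrow(full), 0)
})

test_that("rank masking evaluation enforces the strict >10 species rule", {
  s11 <- sentence_of(paste("gen sp", letters[1:11]))
  s10 <- sentence_of(paste("gen sp", LETTERS[1:10]))
  # oracle that always answers with the plot's rank-1 species
  oracle <- function(context, k, ...)
    tibble::tibble(species = s11$species[1], prob = 1)
  res <- rank_masking_eval(oracle, list(s11, s10))
  expect_equal(res$n_plots, 1)          # the 10-species plot is excluded
  expect_equal(res$per_rank$accuracy, c(1, rep(0, 9)))
  expect_true(all(res$per_rank$n == 1))
  expect_equal(res$overall, 0.1)
})

test_that("model save/load round-trips parameters and predictions", {
  ms <- memo_setup(epochs = 5)
  m <- train_mlm(ms$sents, ms$vocab, ms$cfg)
  dir <- tempfile("model")
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_equal(m2$params, m$params, tolerance = 1e-12)
  q <- c("[MASK]", "beta duo")
  expect_equal(predict_topk(m2, q)[[1]]$token,
               predict_topk(m, q)[[1]]$token)
})
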