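test_that("EUNIS codes parse to their group and broad projections", {
  p <- parse_eunis(c("N14", "T13", "MA223", "R22"))
  expect_equal(p$group, c("N1", "T1", "MA22", "R2"))
  expect_equal(p$broad, c("N", "T", "MA2", "R"))
  expect_error(parse_eunis("Z12"), "unknown broad")
  expect_error(parse_eunis("N1"), "level-3")     # group, not type
  expect_error(parse_eunis("MA23"), "level-3")   # too short under MA2
  expect_error(parse_eunis(""), "empty")
})

test_that("metric laws hold and a hand-built confusion is reproduced", {
  truth <- c("N14", "N14", "T13")
  ranked <- rbind(c("N14", "T13", "R22"),
                  c("N15", "N14", "T13"),
                  c("R22", "N15", "N14"))
  m <- habitat_metrics(truth, ranked)
  expect_equal(m$top1, 1 / 3)
  expect_equal(m$top3, 2 / 3)
  expect_equal(m$group, 2 / 3)   # N15 projects into group N1
  expect_equal(m$broad, 2 / 3)
  expect_equal(sum(diag(m$confusion[, rownames(m$confusion)])) / sum(m$confusion),
               m$top1)
  expect_gte(m$top3, m$top1)
  expect_gte(m$group, m$top1)
  expect_gte(m$broad, m$group)
})

test_that("a perfect predictor scores one on every accuracy", {
  truth <- c("N14", "T13", "R22", "MA221")
  m <- habitat_metrics(truth, cbind(truth, truth, truth))
  expect_equal(unlist(m[c("top1", "top3", "group", "broad", "f1_macro")]),
               c(top1 = 1, top3 = 1, group = 1, broad = 1, f1_macro = 1))
})

test_that("fine-tuning separates habitats with disjoint species pools", {
  model <- make_model(n_habitats = 3, pool_size = 8, n_generalists = 0,
                      mean_richness = 6, seed = 31)
  dat <- suppressWarnings(sample_plots(model, 300, seed = 32))
  sents <- build_sentences(dat$observations, seed = 33)
  vocab <- fit_vocabulary(sents, "species")
  # constant rate: at this tiny step count the decaying schedule would
  # leave the late epochs with almost no learning signal
  cfg <- lm_config(layers = 1, hidden = 32, heads = 2, ffn = 64,
                   epochs = 8, seed = 34, lr = 2e-3, warmup = NA)
  test <- seq_len(60)
  clf <- fine_tune(NULL, sents[-test], dat$headers$habitat[-test],
                   config = cfg, vocab = vocab)
  met <- evaluate_classifier(clf, sents[test], dat$headers$habitat[test])
  expect_gte(met$top1, 0.95)
  expect_gte(met$top3, met$top1)
  # deterministic under the seed
  clf2 <- fine_tune(NULL, sents[-test], dat$headers$habitat[-test],
                    config = cfg, vocab = vocab)
  expect_identical(clf$loss, clf2$loss)
})

test_that("class probabilities cover the label set and sum to one", {
  model <- make_model(n_habitats = 2, pool_size = 5, n_generalists = 0,
                      mean_richness = 4, seed = 41)
  dat <- suppressWarnings(sample_plots(model, 80, seed = 42))
  sents <- build_sentences(dat$observations, seed = 43)
  cfg <- lm_config(layers = 1, hidden = 16, heads = 2, ffn = 32,
                   epochs = 2, seed = 44)
  clf <- fine_tune(NULL, sents, dat$headers$habitat, config = cfg,
                   vocab = fit_vocabulary(sents, "species"))
  pred <- predict_habitat(clf, sents[[1]], k = length(clf$classes))
  expect_equal(sum(pred$prob), 1, tolerance = 1e-6)
  expect_setequal(pred$code, clf$classes)
  expect_true(all(diff(pred$prob) <= 0))
})

test_that("degenerate label sets are rejected", {
  s <- list(sentence_of(c("aa bb", "cc dd")))
  v <- fit_vocabulary(s, "species")
  cfg <- lm_config(layers = 1, hidden = 16, heads = 2, epochs = 1)
  expect_error(fine_tune(NULL, s, "T13", config = cfg, vocab = v),
               "at least 2")
  expect_error(fine_tune(NULL, s, "T1", config = cfg, vocab = v),
               "level-3")
})

test_that("ablation with drop = none equals the plain evaluation", {
  model <- make_model(n_habitats = 2, pool_size = 5, n_generalists = 0,
                      mean_richness = 5, seed = 51)
  dat <- suppressWarnings(sample_plots(model, 60, seed = 52))
  sents <- build_sentences(dat$observations, seed = 53)
  cfg <- lm_config(layers = 1, hidden = 16, heads = 2, ffn = 32,
                   epochs = 3, seed = 54)
  clf <- fine_tune(NULL, sents, dat$headers$habitat, config = cfg,
                   vocab = fit_vocabulary(sents, "species"))
  a_none <- ablation_eval(clf, sents, dat$headers$habitat, "none")
  met <- evaluate_classifier(clf, sents, dat$headers$habitat)
  expect_equal(a_none, met$top1)
  # dropping the last species of a 2-species plot leaves one species
  two <- sentence_of(c("aa bb", "cc dd"))
  expect_silent(ablation_eval(clf, list(two), dat$headers$habitat[1],
                              "last"))
})
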