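test_that("co-occurrence counts match the hand count on a 3-plot fixture", {
  plots <- list(c("a", "b"), c("a", "b"), c("a", "c"))
  cooc <- build_cooccurrence(plots)
  expect_equal(cooc$C["a", "b"], 2)
  expect_equal(cooc$C["a", "c"], 1)
  expect_equal(cooc$C["b", "c"], 0)
  expect_equal(unname(diag(cooc$C)), c(3, 2, 1))
  expect_true(isSymmetric(cooc$C))
  expect_equal(cooc$n_plots, 3)
})

test_that("a single-species plot gives zero pair counts", {
  cooc <- build_cooccurrence(list("a"))
  expect_equal(unname(cooc$C["a", "a"]), 1)
  expect_equal(sum(cooc$C) - sum(diag(cooc$C)), 0)
})

test_that("naive Bayes ranks the frequent co-occurrer first on the fixture", {
  cooc <- build_cooccurrence(list(c("a", "b"), c("a", "b"), c("a", "c")))
  out <- nb_predict(cooc, "a")
  # hand evaluation: score(b) = log(2/6)+log((2+1)/(2+3));
  #                  score(c) = log(1/6)+log((1+1)/(1+3))
  expect_equal(out$species, c("b", "c"))
  expect_equal(out$score[out$species == "b"],
               log(2 / 6) + log(3 / 5))
  expect_equal(out$score[out$species == "c"],
               log(1 / 6) + log(2 / 4))
})

test_that("naive Bayes excludes observed species and ignores unknowns", {
  cooc <- build_cooccurrence(list(c("a", "b"), c("b", "c")))
  expect_equal(nrow(nb_predict(cooc, c("a", "b", "c"))), 0)
  expect_warning(out <- nb_predict(cooc, c("a", "zzz")), "unknown")
  expect_false("a" %in% out$species)
})

test_that("naive Bayes scores equal the brute-force oracle on random fixtures", {
  for (rep in 1:20) {
    with_seed(1000 + rep, {
      n_sp <- sample(5:30, 1)
      species <- paste0("sp", sprintf("%02d", seq_len(n_sp)))
      plots <- lapply(seq_len(sample(10:40, 1)), function(i)
        sample(species, sample(2:min(8, n_sp), 1)))
      obs <- sample(species, sample(1:3, 1))
      mine <- nb_predict(build_cooccurrence(plots), obs)
      oracle <- oracle_nb(plots, obs)
      expect_equal(mine$species, oracle$species)
      expect_equal(mine$score, oracle$score, tolerance = 1e-12)
    })
  }
})

test_that("naive Bayes ranking is invariant to observed-set order", {
  cor <- tiny_corpus(60)
  plots <- split(tolower(cor$dat$observations$taxon),
                 cor$dat$observations$plot_id)
  cooc <- build_cooccurrence(plots)
  obs <- plots[[1]][1:3]
  expect_equal(nb_predict(cooc, obs), nb_predict(cooc, rev(obs)))
})

test_that("the masked MLP recovers disjoint species pairs", {
  plots <- rep(list(c("aa bb", "cc dd"), c("ee ff", "gg hh")), 40)
  mlp <- mlp_fillmask_train(plots, hidden = 16, epochs = 30, seed = 2)
  expect_equal(mlp_fillmask_predict(mlp, "aa bb", k = 1)$species, "cc dd")
  expect_equal(mlp_fillmask_predict(mlp, "gg hh", k = 1)$species, "ee ff")
  # determinism
  mlp2 <- mlp_fillmask_train(plots, hidden = 16, epochs = 30, seed = 2)
  expect_identical(mlp$params, mlp2$params)
})

test_that("an untrained MLP is near uniform; 1-species plots are skipped", {
  plots <- c(rep(list(c("aa bb", "cc dd", "ee ff")), 10), list("aa bb"))
  mlp0 <- mlp_fillmask_train(plots, hidden = 8, epochs = 0, seed = 3)
  p <- mlp_fillmask_predict(mlp0, "aa bb")
  expect_lt(max(p$prob) / min(p$prob), 1.6)
  expect_false("aa bb" %in% p$species)
})

test_that("both baselines satisfy the shared fill-blank contract", {
  cor <- tiny_corpus(80, mean_richness = 8)
  plots <- split(tolower(cor$dat$observations$taxon),
                 cor$dat$observations$plot_id)
  nb <- nb_predictor(build_cooccurrence(plots))
  mlp <- mlp_fillmask_train(plots, hidden = 16, epochs = 3, seed = 4)
  ctx <- c(plots[[1]][1], NA, plots[[1]][3])
  for (pred in list(nb, mlp)) {
    out <- fill_blank(pred, ctx, k = 3)
    expect_equal(nrow(out), 3)
    expect_false(any(out$species %in% ctx[!is.na(ctx)]))
  }
})

test_that("on independent-species data the NB ranking tracks marginal frequency", {
  # frequency-only world: species occur independently with fixed rates
  rates <- c(a = 0.8, b = 0.6, c = 0.4, d = 0.3, e = 0.2, f = 0.1)
  plots <- with_seed(7, lapply(1:400, function(i) {
    s <- names(rates)[runif(6) < rates]
    if (length(s) < 2) c("a", "b") else s
  }))
  cooc <- build_cooccurrence(plots)
  out <- nb_predict(cooc, "f")
  freq <- sort(cooc$n_species[setdiff(names(rates), "f")],
               decreasing = TRUE)
  expect_equal(out$species[1], names(freq)[1])
})
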