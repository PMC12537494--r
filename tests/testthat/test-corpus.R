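test_that("sentences list species in descending cover order, lowercased", {
  obs <- tibble::tibble(plot_id = "p1",
                        taxon = c("Pancratium maritimum",
                                  "Thinopyrum junceum", "Salsola kali"),
                        cover = c(10, 60, 5))
  s <- build_sentence(obs)
  expect_equal(s$species, c("thinopyrum junceum", "pancratium maritimum",
                            "salsola kali"))
  expect_equal(format(s), paste("thinopyrum junceum, pancratium maritimum,",
                                "salsola kali"))
  expect_true(all(diff(s$covers) <= 0))
})

test_that("tied covers permute with the seed but keep the species multiset", {
  obs <- tibble::tibble(plot_id = "p1", taxon = paste("Sp", letters[1:6]),
                        cover = rep(7, 6))
  s1 <- build_sentence(obs, seed = 1)
  s2 <- build_sentence(obs, seed = 2)
  expect_setequal(s1$species, s2$species)
  expect_false(identical(s1$species, s2$species))
  expect_identical(build_sentence(obs, seed = 1)$species, s1$species)
})

test_that("random order mode shuffles but keeps the multiset", {
  obs <- tibble::tibble(plot_id = "p9", taxon = paste("Sp", letters[1:8]),
                        cover = 8:1)
  r <- build_sentence(obs, order_mode = "random", seed = 3)
  expect_setequal(r$species, tolower(obs$taxon))
  expect_false(identical(r$species, tolower(obs$taxon)))
  expect_error(build_sentence(obs[0, ]), "empty plot")
})

test_that("vocabulary schemes count tokens as expected and are deterministic", {
  sents <- list(sentence_of(c("hedera helix", "hedera hibernica")))
  vs <- fit_vocabulary(sents, "species")
  vt <- fit_vocabulary(sents, "term")
  expect_equal(vs$n_content, 2)
  expect_equal(vt$n_content, 3)      # hedera, helix, hibernica
  expect_identical(fit_vocabulary(sents, "species"), vs)
  expect_error(fit_vocabulary(list(), "species"), "empty")
})

test_that("vocabulary recovers the generator's species count exactly", {
  cor <- tiny_corpus(60)
  v <- fit_vocabulary(cor$sentences, "species")
  n_model <- 2 * 6 + 4
  seen <- length(unique(tolower(cor$dat$observations$taxon)))
  expect_equal(v$n_content, seen)
  expect_lte(v$n_content, n_model)
})

test_that("encode/decode round-trip and term-scheme structure hold", {
  sents <- list(sentence_of(c("aa bb", "cc dd")))
  vt <- fit_vocabulary(sents, "term")
  tk <- encode(c("aa bb", "cc dd"), vt)
  # [CLS] aa bb , cc dd [SEP]
  expect_length(tk$ids, 7)
  expect_equal(tk$ids[1], 0L)
  expect_equal(tk$ids[length(tk$ids)], 1L)
  expect_equal(sum(tk$ids == 4L), 1)   # exactly one comma
  expect_equal(decode(tk, vt), "aa bb, cc dd")

  vs <- fit_vocabulary(sents, "species")
  tks <- encode(c("aa bb", "cc dd"), vs)
  expect_equal(decode(tks, vs), "aa bb, cc dd")
  expect_error(decode(tks$ids[-length(tks$ids)], vs), "SEP")
})

test_that("out-of-vocabulary species map to [UNK] with categories intact", {
  vs <- fit_vocabulary(list(sentence_of(c("aa bb"))), "species")
  tk <- encode(c("aa bb", "zz yy"), vs)
  expect_equal(tk$ids[4], 3L)          # [UNK]
  expect_equal(decode(tk, vs), "aa bb, [UNK]")
  expect_equal(tk$cats[4], 6L)         # unknown category
})

test_that("[MASK] encodes from sentences and renders literally", {
  vs <- fit_vocabulary(list(sentence_of(c("aa bb", "cc dd"))), "species")
  tk <- encode(c("aa bb", "[MASK]"), vs)
  expect_equal(sum(tk$ids == 2L), 1)
  expect_match(decode(tk, vs), "\\[MASK\\]")
  vt <- fit_vocabulary(list(sentence_of(c("aa bb", "cc dd"))), "term")
  tkt <- encode(c("aa bb", "[MASK]"), vt)
  expect_equal(sum(tkt$ids == 2L), 2)  # genus and epithet masks
})

test_that("the collator never touches special tokens and labels selections", {
  sents <- lapply(1:50, function(i)
    sentence_of(paste("gen", letters[1:8], "sp", i %% 5)))
  v <- fit_vocabulary(sents, "species")
  corp <- encode_corpus(sents, v)
  b <- mask_collate(corp, v, seed = 9)
  specials <- corp$ids %in% 0:4 & corp$ids >= 0
  expect_true(all(b$ids[specials] == corp$ids[specials]))
  expect_true(all(b$labels[specials] == -1L))
  sel <- b$labels >= 0
  expect_true(all(b$labels[sel] == corp$ids[sel]))
})

test_that("degenerate collator rates behave as specified", {
  v <- fit_vocabulary(list(sentence_of(c("aa bb", "cc dd", "ee ff"))),
                      "species")
  tk <- encode(c("aa bb", "cc dd", "ee ff"), v)
  all_mask <- mask_collate(tk, v, seed = 1, select_rate = 1, mask_frac = 1,
                           random_frac = 0)
  content <- tk$cats >= 3
  expect_true(all(all_mask$ids[content] == 2L))
  none <- mask_collate(tk, v, seed = 1, select_rate = 0)
  expect_identical(none$ids, tk$ids)
  expect_true(all(none$labels == -1L))
})

test_that("term-scheme random replacement is category matched", {
  sents <- lapply(1:30, function(i) sentence_of(
    paste(c("alpha", "beta", "gamma")[1 + (i %% 3)],
          c("unum", "duo", "tres", "quattuor"))))
  v <- fit_vocabulary(sents, "term")
  corp <- encode_corpus(sents, v)
  b <- mask_collate(corp, v, seed = 4, select_rate = 1, mask_frac = 0,
                    random_frac = 1)
  genus_pos <- corp$cats == 4L
  epi_pos <- corp$cats == 5L
  expect_true(all(b$ids[genus_pos] %in% v$genus_ids))
  expect_true(all(b$ids[epi_pos] %in% v$epithet_ids))
})

test_that("vocabulary JSON and corpus text serialisation round-trip", {
  cor <- tiny_corpus(10)
  v <- fit_vocabulary(cor$sentences, "term")
  path <- tempfile(fileext = ".json")
  save_vocabulary(v, path)
  expect_equal(load_vocabulary(path), v)
  cpath <- tempfile(fileext = ".txt")
  write_corpus(cor$sentences, cpath)
  expect_equal(readLines(cpath)[1], format(cor$sentences[[1]]))
})
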