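test_that("zero-cover removal is a strict zero test", {
  tab <- plot_table(rep("p1", 5), paste("Sp", 1:5),
                    c(10, 0, 0.0001, 0, 5))
  out <- drop_zero_cover(tab)
  expect_equal(nrow(out), 3)
  expect_true(all(out$cover > 0))
  expect_identical(drop_zero_cover(out), out)
})

test_that("layer merging sums covers and conserves total cover mass", {
  tab <- plot_table(rep("p1", 3), c("Quercus robur", "Quercus robur",
                                    "Poa annua"),
                    c(60, 50, 10), layer = c("tree", "herb", NA))
  out <- merge_duplicate_layers(tab)
  expect_equal(nrow(out), 2)
  expect_equal(out$cover[out$taxon == "Quercus robur"], 110)
  expect_equal(sum(out$cover), sum(tab$cover))

  distinct <- plot_table(rep("p2", 3), paste("Sp", 1:3), c(5, 4, 3))
  expect_equal(merge_duplicate_layers(distinct)$cover, c(5, 4, 3))
})

test_that("standardisation lumps subspecies, drops genus and unmatched", {
  fx <- curation_fixture()
  merged <- merge_duplicate_layers(drop_zero_cover(fx$table))
  res <- standardize_taxa(merged, fx$names)
  p01 <- res$table[res$table$plot_id == "p01", ]
  expect_equal(sum(p01$taxon == "hedera helix"), 1)
  expect_equal(p01$cover[p01$taxon == "hedera helix"], 8)  # 5 + 3
  expect_false(any(res$table$taxon %in% c("hedera", "carex cuprina")))
  expect_setequal(unique(res$dropped$reason), c("genus", "unmatched"))
  expect_true(all(res$table$taxon == tolower(res$table$taxon)))
})

test_that("rare-species boundary is strict: 9 plots out, 10 plots kept", {
  mk <- function(n_plots, taxon) plot_table(sprintf("q%02d", seq_len(n_plots)),
                                            rep(taxon, n_plots),
                                            rep(10, n_plots))
  tab <- dplyr::bind_rows(mk(9, "rare species"), mk(10, "common species"))
  tab$rank <- "species"
  out <- drop_hybrids_and_rare(as_plot_table(tab), curation_config())
  expect_false("rare species" %in% out$taxon)
  expect_equal(sum(out$taxon == "common species"), 10)
})

test_that("hybrids are retained when the flag is off", {
  tab <- plot_table(sprintf("q%02d", 1:12), rep("salix rubens", 12),
                    rep(10, 12))
  tab$rank <- "hybrid"
  cfg_on <- curation_config()
  cfg_off <- curation_config(drop_hybrids = FALSE)
  expect_equal(nrow(drop_hybrids_and_rare(as_plot_table(tab), cfg_on)), 0)
  expect_equal(nrow(drop_hybrids_and_rare(as_plot_table(tab), cfg_off)), 12)
})

test_that("degraded-plot rule: 25% loss kept, >25% or lost dominant removed", {
  fx <- curation_fixture()
  merged <- merge_duplicate_layers(drop_zero_cover(fx$table))
  snap <- take_snapshot(merged, seed = 1)
  std <- standardize_taxa(merged, fx$names)$table
  kept <- drop_hybrids_and_rare(std, curation_config())
  out <- drop_degraded_plots(kept, snap, fx$names, curation_config())
  ids <- unique(out$plot_id)
  expect_true("p05" %in% ids)    # exactly 1/4 lost
  expect_false("p02" %in% ids)   # 3/5 lost
  expect_false("p06" %in% ids)   # dominant hybrid lost
  expect_true("p01" %in% ids)    # subspecies lumping is not a loss
})

test_that("rare habitat types are demoted to unlabelled", {
  h <- structure(tibble::tibble(
    plot_id = sprintf("p%02d", 1:25),
    lon = 0, lat = 0,
    habitat = c(rep("T13", 10), rep("R22", 9), rep(NA, 6))),
    class = c("veg_headers", class(tibble::tibble())))
  out <- demote_rare_habitats(h, curation_config())
  expect_equal(sum(out$habitat == "T13", na.rm = TRUE), 10)
  expect_equal(sum(out$habitat == "R22", na.rm = TRUE), 0)
  expect_identical(demote_rare_habitats(out, curation_config()), out)
})

test_that("the 12-plot fixture yields the hand-enumerated per-step counts", {
  fx <- curation_fixture()
  res <- curate(fx$table, fx$headers, fx$names)
  rep <- res$report
  expect_equal(rep$step,
               c("zero_cover", "layer_merge", "standardize", "hybrid_rare",
                 "degraded_plots", "rare_habitats"))
  expect_equal(rep$observations, c(52, 51, 46, 43, 37, 37))
  expect_equal(rep$plots, c(12, 12, 12, 12, 10, 10))
  expect_equal(rep$dropped, c(1, 1, 5, 3, 6, 2))
  expect_equal(nrow(res$classification), 37)
  expect_equal(length(unique(res$classification$plot_id)), 10)
  expect_equal(nrow(res$fill_mask), 0)
  # observation counts never increase along the chain
  expect_true(all(diff(rep$observations) <= 0))
})

test_that("curation is idempotent when no species is near the rarity bound", {
  cor <- tiny_corpus(200)
  names_tab <- synth_name_table(cor$model)
  res <- curate(cor$dat$observations, cor$dat$headers, names_tab)
  curated <- dplyr::bind_rows(res$classification, res$fill_mask)
  again <- curate(curated, res$headers, names_tab)
  expect_true(all(again$report$dropped == 0))
  expect_equal(nrow(again$classification) + nrow(again$fill_mask),
               nrow(curated))
})

test_that("re-curation changes nothing upstream of the rare-species filter", {
  fx <- curation_fixture()
  res <- curate(fx$table, fx$headers, fx$names)
  again <- curate(res$classification, res$headers, fx$names)
  pre_rare <- c("zero_cover", "layer_merge", "standardize")
  expect_true(all(again$report$dropped[again$report$step %in% pre_rare] == 0))
  # the rare filter may only shrink counts on a second pass (12 plots sit
  # right at the 10-plot threshold, so its cascade is the only change)
  expect_lte(nrow(again$classification) + nrow(again$fill_mask),
             nrow(res$classification))
})

test_that("labelled and unlabelled plots partition the curated table", {
  cor <- tiny_corpus(30)
  h <- cor$dat$headers
  h$habitat[1:10] <- NA
  sets <- split_datasets(cor$dat$observations, h)
  all_ids <- unique(cor$dat$observations$plot_id)
  expect_setequal(c(unique(sets$fill_mask$plot_id),
                    unique(sets$classification$plot_id)), all_ids)
  expect_length(intersect(unique(sets$fill_mask$plot_id),
                          unique(sets$classification$plot_id)), 0)
})
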