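# Shared fixture builders. Everything is constructed in code; expected
# values quoted in tests were enumerated by hand from these definitions.

# internal helpers used across tests, resolved explicitly so the tests run
# identically under any testthat loading strategy
with_seed <- vegsyntax:::with_seed
derive_seed <- vegsyntax:::derive_seed
as_plot_table <- vegsyntax:::as_plot_table
init_params <- vegsyntax:::init_params
cpp_loss_grads <- vegsyntax:::cpp_loss_grads
default_habitat_codes <- vegsyntax:::default_habitat_codes

sentence_of <- function(species, covers = rev(seq_along(species)),
                        plot_id = "p") {
  structure(list(plot_id = plot_id, species = tolower(species),
                 covers = covers), class = "veg_sentence")
}

# A 12-plot observation table exercising every curation rule. Hand
# bookkeeping (see test-curation.R for the per-step count table):
#  - "Zea mays" recorded with cover 0 in p07;
#  - "Poa annua" recorded in two layers of p08 (60 + 50 -> 110);
#  - two Hedera helix subspecies in p01 lump to "hedera helix";
#  - "Hedera" (genus) in p02/p04 and "Carex cuprina" (unmatched) in
#    p02/p05 are dropped by standardisation;
#  - "Salix x rubens" (hybrid, top cover of p06) and "Rara avis"
#    (2 plots < 10) are dropped next;
#  - p02 loses 3/5 of its taxa (removed), p05 exactly 1/4 (kept), p06
#    loses its most abundant taxon (removed).
curation_fixture <- function() {
  rows <- list(
    # plot,  taxon,                          layer, cover
    c("p01", "Quercus robur",                NA, 80),
    c("p01", "Fagus sylvatica",              NA, 30),
    c("p01", "Poa annua",                    NA, 10),
    c("p01", "Rara avis",                    NA, 5),
    c("p01", "Hedera helix subsp. helix",    NA, 5),
    c("p01", "Hedera helix subsp. poetarum", NA, 3),
    c("p02", "Quercus robur",                NA, 50),
    c("p02", "Poa annua",                    NA, 20),
    c("p02", "Hedera",                       NA, 10),
    c("p02", "Carex cuprina",                NA, 10),
    c("p02", "Rara avis",                    NA, 5),
    c("p03", "Quercus robur",                NA, 60),
    c("p03", "Fagus sylvatica",              NA, 30),
    c("p03", "Poa annua",                    NA, 10),
    c("p03", "Hedera helix",                 NA, 5),
    c("p04", "Quercus robur",                NA, 40),
    c("p04", "Poa annua",                    NA, 30),
    c("p04", "Hedera",                       NA, 20),
    c("p04", "Fagus sylvatica",              NA, 10),
    c("p04", "Hedera helix",                 NA, 8),
    c("p05", "Quercus robur",                NA, 45),
    c("p05", "Fagus sylvatica",              NA, 25),
    c("p05", "Carex cuprina",                NA, 5),
    c("p05", "Hedera helix",                 NA, 5),
    c("p06", "Salix x rubens",               NA, 70),
    c("p06", "Quercus robur",                NA, 40),
    c("p06", "Fagus sylvatica",              NA, 30),
    c("p06", "Poa annua",                    NA, 10),
    c("p06", "Hedera helix",                 NA, 5),
    c("p07", "Quercus robur",                NA, 50),
    c("p07", "Fagus sylvatica",              NA, 20),
    c("p07", "Poa annua",                    NA, 10),
    c("p07", "Hedera helix",                 NA, 5),
    c("p07", "Zea mays",                     NA, 0),
    c("p08", "Quercus robur",                NA, 55),
    c("p08", "Fagus sylvatica",              NA, 25),
    c("p08", "Poa annua",                    "tree", 60),
    c("p08", "Poa annua",                    "herb", 50),
    c("p08", "Hedera helix",                 NA, 5),
    c("p09", "Quercus robur",                NA, 35),
    c("p09", "Fagus sylvatica",              NA, 20),
    c("p09", "Poa annua",                    NA, 10),
    c("p09", "Hedera helix",                 NA, 5),
    c("p10", "Quercus robur",                NA, 30),
    c("p10", "Fagus sylvatica",              NA, 15),
    c("p10", "Poa annua",                    NA, 5),
    c("p10", "Hedera helix",                 NA, 5),
    c("p11", "Quercus robur",                NA, 25),
    c("p11", "Poa annua",                    NA, 10),
    c("p11", "Hedera helix",                 NA, 5),
    c("p12", "Poa annua",                    NA, 20),
    c("p12", "Hedera helix",                 NA, 10),
    c("p12", "Fagus sylvatica",              NA, 5))
  m <- do.call(rbind, rows)
  table <- plot_table(plot_id = m[, 1], taxon = m[, 2],
                      cover = as.numeric(m[, 4]), layer = m[, 3])
  names_tab <- structure(tibble::tibble(
    input_name = c("Quercus robur", "Fagus sylvatica", "Poa annua",
                   "Rara avis", "Hedera helix",
                   "Hedera helix subsp. helix",
                   "Hedera helix subsp. poetarum",
                   "Hedera", "Carex cuprina", "Salix x rubens",
                   "Zea mays"),
    accepted_binomial = c("quercus robur", "fagus sylvatica", "poa annua",
                          "rara avis", "hedera helix", "hedera helix",
                          "hedera helix", NA, NA, "salix rubens",
                          "zea mays"),
    rank = c("species", "species", "species", "species", "species",
             "subspecies", "subspecies", "genus", "unmatched", "hybrid",
             "species")), class = c("veg_names", class(tibble::tibble())))
  headers <- structure(tibble::tibble(
    plot_id = sprintf("p%02d", 1:12),
    lon = seq(4, 15, length.out = 12),
    lat = seq(43, 54, length.out = 12),
    habitat = c("T13", "R22", "T13", "T13", "T13", "V15", "T13", "T13",
                "T13", "T13", "T13", "T13")),
    class = c("veg_headers", class(tibble::tibble())))
  list(table = table, names = names_tab, headers = headers)
}

# Independent naive Bayes oracle: per-candidate loop straight over the plot
# lists (no matrix algebra shared with the implementation).
oracle_nb <- function(plots, observed, alpha = 1) {
  plots <- lapply(plots, unique)
  species <- sort(unique(unlist(plots)), method = "radix")
  observed <- intersect(observed, species)
  N <- vapply(species, function(s)
    sum(vapply(plots, function(p) s %in% p, logical(1))), numeric(1))
  V <- length(species)
  cands <- setdiff(species, observed)
  scores <- vapply(cands, function(s) {
    sc <- log(N[[s]]) - log(sum(N))
    for (o in observed) {
      co <- sum(vapply(plots, function(p) s %in% p && o %in% p,
                       logical(1)))
      sc <- sc + log((co + alpha) / (N[[s]] + alpha * V))
    }
    sc
  }, numeric(1))
  ord <- order(-round(scores, 9), cands, method = "radix")
  tibble::tibble(species = cands[ord], score = unname(scores[ord]))
}

# small deterministic corpus of sentences drawn from a community model
tiny_corpus <- function(n_plots = 40, seed = 5, mean_richness = 6, ...) {
  model <- make_model(n_habitats = 2, pool_size = 6, n_generalists = 4,
                      mean_richness = mean_richness, seed = seed, ...)
  dat <- suppressWarnings(sample_plots(model, n_plots, seed = seed + 1))
  list(model = model, dat = dat,
       sentences = build_sentences(dat$observations, seed = seed + 2))
}
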