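# Syllable inventory for invented-but-plausible Latin binomials; purely
# synthetic names, never real taxa.
GENUS_SYL <- c("ac", "bel", "cal", "dor", "er", "fla", "gal", "hel", "is",
               "jun", "kar", "lim", "mon", "nar", "or", "pel", "quer",
               "ros", "sil", "thy", "ul", "ver", "xan", "yso", "zel")
GENUS_END <- c("ia", "us", "um", "ella", "aria", "ium", "ora", "ix")
EPI_SYL <- c("al", "bor", "cam", "den", "el", "fol", "gra", "hir", "in",
             "lat", "mar", "nig", "ob", "pal", "ru", "sax", "ten", "vel")
EPI_END <- c("a", "um", "us", "ens", "icum", "alis", "osa", "ata")

make_binomials <- function(n, seed = 1L, n_genera = max(3L, n %/% 4L)) {
  with_seed(derive_seed(seed, "names"), {
    genera <- character(0)
    while (length(genera) < n_genera) {
      g <- paste0(paste(sample(GENUS_SYL, sample(2:3, 1), replace = TRUE),
                        collapse = ""), sample(GENUS_END, 1))
      genera <- unique(c(genera, g))
    }
    species <- character(0)
    while (length(species) < n) {
      e <- paste0(paste(sample(EPI_SYL, sample(2:3, 1), replace = TRUE),
                        collapse = ""), sample(EPI_END, 1))
      s <- paste(sample(genera, 1), e)
      species <- unique(c(species, s))
    }
    # report capitalised (field style); the corpus lowercases downstream
    vapply(species, function(s) {
      paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
    }, character(1), USE.NAMES = FALSE)
  })
}

default_habitat_codes <- function(n) {
  i <- seq_len(n) - 1L
  broad <- EUNIS_BROAD[(i %% length(EUNIS_BROAD)) + 1L]
  paste0(broad, (i %/% length(EUNIS_BROAD)) + 1L, (i %% 8L) + 1L)
}

#' Describe a synthetic multi-habitat plant community
#'
#' Builds the generative model the sampler draws from: each habitat has a
#' species pool with geometric rank-abundance weights, a spatial centre
#' (habitats cluster in space, so spatial-block cross-validation is
#' meaningfully different from random splitting) and a valid level-3
#' habitat code; a shared generalist pool with Zipf weights produces the
#' long-tailed species frequency distribution typical of large plot
#' archives. Habitat-pool species carry a boosted abundance weight, so the
#' dominant (top-cover) species of a plot tends to be habitat-diagnostic —
#' mirroring how the habitat typology is anchored on dominant species.
#'
#' @param n_habitats Number of habitat types.
#' @param pool_size Species per habitat pool (pools are disjoint).
#' @param n_generalists Species in the shared generalist pool (0 = fully
#'   disjoint habitats, for which the optimal classifier is perfect).
#' @param geometric_ratio Rank-abundance decay within each habitat pool.
#' @param generalist_mix Expected fraction of a plot's species drawn from
#'   the generalist pool (when one exists).
#' @param mean_richness,richness_size Negative-binomial richness (mean
#'   species per plot and size/overdispersion parameter). Default mean 20.
#' @param specialist_abund Multiplier on habitat-pool abundance weights
#'   (controls how reliably specialists take the top cover ranks).
#' @param cover_grid Ordinal-style cover percentages that sampled covers
#'   are snapped to (creates frequent ties, as in field data).
#' @param dispersion_deg Spatial spread (degrees) of plots around their
#'   habitat centre.
#' @param habitat_codes Optional level-3 codes (defaults generated).
#' @param seed Seed; the model is fully deterministic given it.
#' @return A `veg_community` model.
#' @export
make_model <- function(n_habitats = 4, pool_size = 50, n_generalists = 50,
                       geometric_ratio = 0.85, generalist_mix = 0.5,
                       mean_richness = 20, richness_size = 10,
                       specialist_abund = 3,
                       cover_grid = c(0.5, 1, 2, 3, 5, 8, 13, 20, 30, 45,
                                      60, 80),
                       dispersion_deg = 0.4, habitat_codes = NULL,
                       seed = 1L) {
  assert_that(n_habitats >= 1 && pool_size >= 1, "positive sizes required")
  assert_that(geometric_ratio > 0 && geometric_ratio < 1,
              "geometric_ratio in (0,1)")
  n_sp <- n_habitats * pool_size + n_generalists
  species <- make_binomials(n_sp, seed)
  codes <- habitat_codes %||% default_habitat_codes(n_habitats)
  centres <- with_seed(derive_seed(seed, "centres"), {
    tibble(lon = runif(n_habitats, -8, 28),
           lat = runif(n_habitats, 37, 62))
  })
  habitats <- lapply(seq_len(n_habitats), function(h) {
    pool_sp <- species[((h - 1) * pool_size + 1):(h * pool_size)]
    w <- geometric_ratio^(seq_len(pool_size) - 1)
    list(code = codes[h],
         centre = c(lon = centres$lon[h], lat = centres$lat[h]),
         pool = tibble(species = pool_sp,
                       weight = w / sum(w),
                       abund = specialist_abund * w))
  })
  names(habitats) <- codes
  generalists <- if (n_generalists > 0) {
    gsp <- species[(n_habitats * pool_size + 1):n_sp]
    w <- 1 / seq_len(n_generalists)
    tibble(species = gsp, weight = w / sum(w), abund = w)
  } else tibble(species = character(0), weight = numeric(0),
                abund = numeric(0))
  structure(list(habitats = habitats, generalists = generalists,
                 generalist_mix = if (n_generalists > 0) generalist_mix
                                  else 0,
                 mean_richness = mean_richness,
                 richness_size = richness_size,
                 cover_grid = sort(cover_grid, decreasing = TRUE),
                 dispersion_deg = dispersion_deg,
                 motif = NULL, seed = as.integer(seed)),
            class = "veg_community")
}

#' @export
print.veg_community <- function(x, ...) {
  cat(sprintf(paste0("<veg_community: %d habitats x %d pool species, ",
                     "%d generalists%s>\n"),
              length(x$habitats), nrow(x$habitats[[1]]$pool),
              nrow(x$generalists),
              if (is.null(x$motif)) "" else ", motif injected"))
  invisible(x)
}

#' Inject an obligate-companion motif into a community model
#'
#' Enforces the pattern "species A and species C never occur together
#' without species B": during sampling, any plot that drew both A and C
#' and not B gets B added. The selection weights of A and C can be boosted
#' so the three-species joint count is large enough (target of order 100+
#' joint occurrences at typical corpus sizes). By default the motif triple
#' is taken from the generalist pool at frequency ranks 2 (A), 4 (B) and
#' 6 (C), so A typically outranks B, which outranks C, in cover order —
#' while the globally most frequent species stays a non-motif generalist.
#'
#' @param model A [make_model()] community.
#' @param species Optional character triple `c(A, B, C)`; defaults to the
#'   generalists at frequency ranks `ranks`.
#' @param ranks Generalist frequency ranks used for A, B and C when
#'   `species` is not given. Mid-tail ranks keep the motif species well
#'   below the most frequent generalists, which is what makes the
#'   frequency-driven baseline fail on this pattern.
#' @param boost Multiplier applied to the selection weights of A and C
#'   (raises the A-and-C joint count that carries the signal).
#' @param abund_ranks Generalist abundance ranks whose ordering weights are
#'   copied onto A, B and C, so cover order tends to run A > B > C.
#' @return The model with `motif` set.
#' @export
inject_motif <- function(model, species = NULL, ranks = c(8, 5, 12),
                         boost = 2, abund_ranks = c(3, 6, 10)) {
  if (is.null(species)) {
    assert_that(nrow(model$generalists) >= max(ranks),
                "default motif triple needs a larger generalist pool")
    species <- model$generalists$species[ranks]
  }
  assert_that(length(species) == 3 && !anyDuplicated(species),
              "motif needs three distinct species")
  all_sp <- c(unlist(lapply(model$habitats, function(h) h$pool$species)),
              model$generalists$species)
  assert_that(all(species %in% all_sp),
              "motif species must belong to the model's pools")
  gi <- match(species, model$generalists$species)
  if (!anyNA(gi)) {
    model$generalists$weight[gi[c(1, 3)]] <-
      model$generalists$weight[gi[c(1, 3)]] * boost
    model$generalists$abund[gi] <- model$generalists$abund[abund_ranks]
  }
  model$motif <- list(a = species[1], b = species[2], c = species[3],
                      boost = boost)
  model
}

#' Remove an injected motif
#' @param model A `veg_community`.
#' @return The model without the motif constraint (selection weights keep
#'   any boost applied at injection unless the model is rebuilt).
#' @export
remove_motif <- function(model) {
  model$motif <- NULL
  model
}

#' Sample vegetation plots from a community model
#'
#' Per plot: a habitat is drawn uniformly; a richness is drawn from the
#' negative-binomial; species are drawn without replacement, mixing the
#' habitat pool and the generalist pool; covers follow geometric decay over
#' the abundance ranks and are snapped to the ordinal cover grid (creating
#' ties); coordinates scatter around the habitat centre. The motif
#' constraint, when present, is enforced exactly. Fully reproducible given
#' the seed.
#'
#' @param model A [make_model()] community.
#' @param n_plots Number of plots.
#' @param seed Seed.
#' @param cover_ratio Geometric decay of cover with abundance rank.
#' @return A list: `observations` (`veg_plot_table`), `headers`
#'   (`veg_headers` with true habitat codes), `truth` (tibble plot_id,
#'   habitat) and `model`.
#' @export
sample_plots <- function(model, n_plots, seed = 1L, cover_ratio = 0.7) {
  if (n_plots == 0) {
    return(list(observations = plot_table(character(0), character(0),
                                          numeric(0)),
                headers = structure(tibble(plot_id = character(0),
                                           lon = numeric(0),
                                           lat = numeric(0),
                                           habitat = character(0)),
                                    class = c("veg_headers",
                                              class(tibble()))),
                truth = tibble(plot_id = character(0),
                               habitat = character(0)),
                model = model))
  }
  H <- length(model$habitats)
  grid <- model$cover_grid
  n_truncated <- 0L
  res <- with_seed(derive_seed(seed, "plots"), {
    obs_plot <- vector("list", n_plots)
    hab <- character(n_plots)
    lon <- numeric(n_plots)
    lat <- numeric(n_plots)
    for (i in seq_len(n_plots)) {
      h <- model$habitats[[sample.int(H, 1)]]
      pool <- h$pool
      gen <- model$generalists
      mix <- model$generalist_mix
      cand <- rbind(pool, gen)
      w <- c(pool$weight * (1 - mix),
             if (nrow(gen) > 0) gen$weight * mix else numeric(0))
      r <- 2L + stats::rnbinom(1, mu = max(model$mean_richness - 2, 0.1),
                               size = model$richness_size)
      if (r > nrow(cand)) {
        n_truncated <- n_truncated + 1L
        r <- nrow(cand)
      }
      pick <- sample.int(nrow(cand), r, prob = w)
      sel <- cand[pick, , drop = FALSE]
      if (!is.null(model$motif)) {
        m <- model$motif
        if (m$a %in% sel$species && m$c %in% sel$species &&
            !(m$b %in% sel$species)) {
          bi <- which(cand$species == m$b)
          sel <- rbind(sel, cand[bi, , drop = FALSE])
        }
      }
      a <- sel$abund * exp(rnorm(nrow(sel), sd = 0.8))
      ord <- order(-a)
      ideal <- 100 * cover_ratio^(seq_len(nrow(sel)) - 1)
      cover <- vapply(ideal, function(x) grid[which.min(abs(grid - x))],
                      numeric(1))
      obs_plot[[i]] <- tibble(taxon = sel$species[ord], cover = cover)
      hab[i] <- h$code
      lon[i] <- min(180, max(-180,
                             h$centre["lon"] +
                               rnorm(1, sd = model$dispersion_deg)))
      lat[i] <- min(90, max(-90,
                            h$centre["lat"] +
                              rnorm(1, sd = model$dispersion_deg)))
    }
    list(obs_plot = obs_plot, hab = hab, lon = lon, lat = lat)
  })
  if (n_truncated > 0)
    warn(paste0("richness exceeded the candidate pool in ", n_truncated,
                " plot(s); truncated"))
  plot_ids <- sprintf("p%06d", seq_len(n_plots))
  n_per <- vapply(res$obs_plot, nrow, integer(1))
  obs <- plot_table(plot_id = rep(plot_ids, n_per),
                    taxon = unlist(lapply(res$obs_plot, `[[`, "taxon")),
                    cover = unlist(lapply(res$obs_plot, `[[`, "cover")))
  headers <- structure(tibble(plot_id = plot_ids, lon = res$lon,
                              lat = res$lat, habitat = res$hab),
                       class = c("veg_headers", class(tibble())))
  list(observations = obs, headers = headers,
       truth = tibble(plot_id = plot_ids, habitat = res$hab),
       model = model)
}

#' Identity name table for a synthetic community
#'
#' Synthetic species names are already accepted binomials, so the name
#' table maps each name to its lowercase self at species rank — letting the
#' full curation chain run on generated data.
#'
#' @param model A `veg_community`.
#' @return A `veg_names` tibble.
#' @export
synth_name_table <- function(model) {
  sp <- c(unlist(lapply(model$habitats, function(h) h$pool$species)),
          model$generalists$species)
  structure(tibble(input_name = sp,
                   accepted_binomial = tolower(sp),
                   rank = "species"),
            class = c("veg_names", class(tibble())))
}
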