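#' Curation settings
#'
#' Thresholds for the pre-processing filter chain. Boundary semantics are
#' strict as worded in the protocol: a species kept in exactly
#' `min_species_occurrences` plots survives ("less than ten" removes 9,
#' keeps 10); a plot losing exactly `plot_loss_threshold` of its taxa
#' survives ("more than 25%" removes only strictly larger losses).
#'
#' @param min_species_occurrences Species present (after layer merging) in
#'   fewer than this many plots are removed. Default 10.
#' @param plot_loss_threshold Plots losing strictly more than this fraction
#'   of their distinct taxa during name standardisation (or their most
#'   abundant taxon) are removed. Default 0.25.
#' @param min_habitat_plots Habitat types labelling fewer than this many
#'   curated plots are demoted to unlabelled. Default 10.
#' @param drop_hybrids Remove hybrid taxa. Default `TRUE`.
#' @param rare_fixed_point If `TRUE`, iterate the rare-species filter to a
#'   fixed point instead of the default single pass with counts frozen
#'   before any removal.
#' @param seed Seed for the (rare) cover tie-break when recording each
#'   plot's most abundant taxon.
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(min_species_occurrences = 10,
                            plot_loss_threshold = 0.25,
                            min_habitat_plots = 10,
                            drop_hybrids = TRUE,
                            rare_fixed_point = FALSE,
                            seed = 1L) {
  assert_that(is_count(min_species_occurrences), "min_species_occurrences must be a positive integer")
  assert_that(is_count(min_habitat_plots), "min_habitat_plots must be a positive integer")
  assert_that(is.numeric(plot_loss_threshold) &&
                plot_loss_threshold > 0 && plot_loss_threshold < 1,
              "plot_loss_threshold must lie in (0, 1)")
  structure(list(min_species_occurrences = as.integer(min_species_occurrences),
                 plot_loss_threshold = plot_loss_threshold,
                 min_habitat_plots = as.integer(min_habitat_plots),
                 drop_hybrids = isTRUE(drop_hybrids),
                 rare_fixed_point = isTRUE(rare_fixed_point),
                 seed = as.integer(seed)),
            class = "curation_config")
}

as_plot_table <- function(tab) {
  if (!inherits(tab, "veg_plot_table"))
    class(tab) <- c("veg_plot_table", class(tab))
  tab
}

#' Remove observations recorded with zero percent cover
#'
#' Zero-cover rows are treated as recording errors or deliberate absence
#' records; everything else is left untouched. The test is a strict zero
#' test, so arbitrarily small positive covers survive.
#'
#' @param table A `veg_plot_table`.
#' @return The filtered table.
#' @export
drop_zero_cover <- function(table) {
  as_plot_table(table[table$cover > 0, , drop = FALSE])
}

#' Merge duplicated taxa recorded in several layers of one plot
#'
#' A taxon appearing more than once in a plot (typically once per vegetation
#' layer) is collapsed to a single record whose cover is the sum of the
#' merged covers; sums above 100% are legitimate because layers overlap.
#' The merged record keeps the position of the taxon's first occurrence
#' within the plot and its `layer` is cleared when records actually merged.
#'
#' @param table A `veg_plot_table` with no zero covers.
#' @return A table in which (plot_id, taxon) pairs are unique.
#' @export
merge_duplicate_layers <- function(table) {
  key <- paste(table$plot_id, table$taxon, sep = "\r")
  first <- !duplicated(key)
  summed <- rowsum(table$cover, key, reorder = FALSE)
  n_per <- rowsum(rep(1L, nrow(table)), key, reorder = FALSE)
  out <- table[first, , drop = FALSE]
  # rowsum(reorder = FALSE) groups in order of first appearance, matching
  # the rows selected by !duplicated()
  out$cover <- as.numeric(summed)
  out$layer[as.integer(n_per) > 1L] <- NA_character_
  as_plot_table(out)
}

#' Snapshot per-plot composition before name standardisation
#'
#' Records, for every plot, its distinct taxa and its most abundant taxon
#' (maximum summed cover; ties broken by a seeded random draw). The snapshot
#' is consumed by [drop_degraded_plots()].
#'
#' @param table A layer-merged `veg_plot_table`.
#' @param seed Tie-break seed.
#' @return A tibble with columns `plot_id`, `taxa` (list of character) and
#'   `top_taxon`.
#' @export
take_snapshot <- function(table, seed = 1L) {
  split_idx <- split(seq_len(nrow(table)), table$plot_id)
  plot_ids <- names(split_idx)
  taxa <- lapply(split_idx, function(i) unique(table$taxon[i]))
  top <- vapply(plot_ids, function(p) {
    i <- split_idx[[p]]
    cov <- table$cover[i]
    best <- i[cov == max(cov)]
    if (length(best) > 1)
      best <- with_seed(derive_seed(seed, "snapshot", p),
                        best[sample.int(length(best), 1)])
    table$taxon[best]
  }, character(1))
  tibble(plot_id = plot_ids, taxa = unname(taxa), top_taxon = unname(top))
}

std_lookup <- function(names) {
  acc <- unique(names$accepted_binomial[!is.na(names$accepted_binomial)])
  # accepted binomials standardise to themselves (already-curated input)
  c(stats::setNames(names$accepted_binomial, names$input_name),
    stats::setNames(acc, acc)[!acc %in% names$input_name])
}

#' Standardise taxon names against an accepted backbone
#'
#' Applies a [read_name_records()] table: unmatched names and names resolved
#' only to genus are dropped; subspecies are lumped into their parent
#' binomial (covers re-merged by summation, as for layers); every surviving
#' taxon becomes a lowercase accepted binomial. Taxa absent from the name
#' table are treated as unmatched.
#'
#' @param table A layer-merged `veg_plot_table`.
#' @param names A `veg_names` table.
#' @return A list with `table` (standardised) and `dropped`, a tibble of
#'   removed observations with the reason (`unmatched` or `genus`).
#' @export
standardize_taxa <- function(table, names) {
  idx <- match(table$taxon, names$input_name)
  rank <- ifelse(is.na(idx), "unmatched", names$rank[idx])
  accepted <- ifelse(is.na(idx), NA_character_, names$accepted_binomial[idx])
  # names that are already accepted binomials (e.g. re-running curation on
  # curated output) pass through under their own accepted rank
  self <- is.na(idx) & tolower(table$taxon) %in% names$accepted_binomial
  if (any(self)) {
    acc_rank <- vapply(tolower(table$taxon[self]), function(a) {
      r <- names$rank[names$accepted_binomial %in% a]
      if ("hybrid" %in% r) "hybrid" else "species"
    }, character(1))
    accepted[self] <- tolower(table$taxon[self])
    rank[self] <- acc_rank
  }
  drop <- rank %in% c("unmatched", "genus") | is.na(accepted)
  dropped <- tibble(plot_id = table$plot_id[drop],
                    taxon = table$taxon[drop],
                    reason = ifelse(rank[drop] == "genus", "genus",
                                    "unmatched"))
  out <- table[!drop, , drop = FALSE]
  out$taxon <- tolower(accepted[!drop])
  out$rank <- ifelse(rank[!drop] == "hybrid", "hybrid", "species")
  # subspecies lumped to the parent binomial may now duplicate within a plot
  out <- merge_with_rank(out)
  list(table = as_plot_table(out), dropped = dropped)
}

merge_with_rank <- function(table) {
  key <- paste(table$plot_id, table$taxon, sep = "\r")
  first <- !duplicated(key)
  summed <- rowsum(table$cover, key, reorder = FALSE)
  out <- table[first, , drop = FALSE]
  out$cover <- as.numeric(summed)
  out
}

#' Remove hybrid taxa and dataset-wide rare species
#'
#' Species presence is counted at plot level (one count per plot in which
#' the species occurs) over the whole dataset, once, before any removal in
#' this step; species below `min_species_occurrences` are then removed in a
#' single pass. With `rare_fixed_point = TRUE` the count-and-remove cycle is
#' iterated until stable.
#'
#' @param table A standardised `veg_plot_table` (a `rank` column marks
#'   hybrids; absent means no hybrids present).
#' @param config A [curation_config()].
#' @return The filtered table.
#' @export
drop_hybrids_and_rare <- function(table, config = curation_config()) {
  if (config$drop_hybrids && "rank" %in% names(table))
    table <- table[table$rank != "hybrid", , drop = FALSE]
  repeat {
    counts <- table(table$taxon)
    keep <- names(counts)[counts >= config$min_species_occurrences]
    changed <- length(keep) < length(counts)
    table <- table[table$taxon %in% keep, , drop = FALSE]
    if (!changed || !config$rare_fixed_point) break
  }
  as_plot_table(table)
}

#' Remove plots degraded by name standardisation
#'
#' A plot is kept only if (a) the fraction of its pre-standardisation
#' distinct taxa that are no longer represented is at most
#' `plot_loss_threshold` (strictly more is removed) and (b) the
#' standardised form of its pre-standardisation most abundant taxon is
#' still present. Lumping two subspecies into one binomial does not count
#' as a loss: a snapshot taxon is lost only when its standardised form is
#' absent from the plot.
#'
#' @param table The current `veg_plot_table`.
#' @param snapshot A [take_snapshot()] tibble taken before
#'   [standardize_taxa()].
#' @param names The `veg_names` table used for standardisation.
#' @param config A [curation_config()].
#' @return The filtered table.
#' @export
drop_degraded_plots <- function(table, snapshot, names,
                                config = curation_config()) {
  missing <- setdiff(unique(table$plot_id), snapshot$plot_id)
  assert_that(length(missing) == 0,
              paste0("plot(s) absent from snapshot: ",
                     paste(missing, collapse = ", ")))
  lut <- std_lookup(names)
  current <- split(table$taxon, table$plot_id)
  keep_plot <- vapply(seq_len(nrow(snapshot)), function(i) {
    p <- snapshot$plot_id[i]
    now <- current[[p]]
    if (is.null(now)) return(FALSE)          # plot vanished entirely
    std <- tolower(unname(lut[snapshot$taxa[[i]]]))
    lost <- is.na(std) | !(std %in% now)
    frac <- sum(lost) / length(std)
    top_std <- tolower(unname(lut[snapshot$top_taxon[i]]))
    frac <= config$plot_loss_threshold &&
      !is.na(top_std) && top_std %in% now
  }, logical(1))
  kept_ids <- snapshot$plot_id[keep_plot]
  as_plot_table(table[table$plot_id %in% kept_ids, , drop = FALSE])
}

#' Demote very rare habitat types to unlabelled
#'
#' Habitat types labelling fewer than `min_habitat_plots` curated plots are
#' cleared, so those plots join the unlabelled (fill-mask) pool.
#'
#' @param headers A `veg_headers` tibble.
#' @param config A [curation_config()].
#' @param plot_ids Optional vector restricting the habitat counts to
#'   curated plots (headers outside it are ignored for counting).
#' @return The headers with rare habitat codes set to `NA`.
#' @export
demote_rare_habitats <- function(headers, config = curation_config(),
                                 plot_ids = NULL) {
  in_scope <- if (is.null(plot_ids)) rep(TRUE, nrow(headers))
              else headers$plot_id %in% plot_ids
  all_hab <- unique(headers$habitat[!is.na(headers$habitat)])
  counts <- table(factor(headers$habitat[in_scope & !is.na(headers$habitat)],
                         levels = all_hab))
  rare <- names(counts)[counts < config$min_habitat_plots]
  headers$habitat[headers$habitat %in% rare] <- NA_character_
  headers
}

#' Partition curated plots into fill-mask and classification datasets
#'
#' @param table The curated `veg_plot_table`.
#' @param headers The (demoted) `veg_headers`.
#' @return A list with `fill_mask` and `classification` tables: every
#'   curated plot appears in exactly one of the two, according to whether
#'   its header carries a habitat label.
#' @export
split_datasets <- function(table, headers) {
  labelled <- headers$plot_id[!is.na(headers$habitat)]
  lab <- table$plot_id %in% labelled
  list(fill_mask = as_plot_table(table[!lab, , drop = FALSE]),
       classification = as_plot_table(table[lab, , drop = FALSE]))
}

report_row <- function(step, table, dropped) {
  tibble(step = step,
         observations = nrow(table),
         plots = length(unique(table$plot_id)),
         dropped = dropped)
}

#' Run the full curation chain
#'
#' Applies, in fixed order: zero-cover removal, layer merging, composition
#' snapshot, name standardisation, hybrid/rare-species removal,
#' degraded-plot removal, rare-habitat demotion and the labelled/unlabelled
#' split. Produces a per-step count report.
#'
#' @param table Raw `veg_plot_table`.
#' @param headers Raw `veg_headers`.
#' @param names A `veg_names` table.
#' @param config A [curation_config()].
#' @return A list: `fill_mask`, `classification` (tables), `headers`
#'   (with demotions applied), `report` (tibble: step, observations, plots,
#'   dropped).
#' @export
curate <- function(table, headers, names, config = curation_config()) {
  steps <- list()
  n0 <- nrow(table)
  t1 <- drop_zero_cover(table)
  steps[[1]] <- report_row("zero_cover", t1, n0 - nrow(t1))
  t2 <- merge_duplicate_layers(t1)
  steps[[2]] <- report_row("layer_merge", t2, nrow(t1) - nrow(t2))
  snap <- take_snapshot(t2, seed = config$seed)
  s3 <- standardize_taxa(t2, names)
  t3 <- s3$table
  steps[[3]] <- report_row("standardize", t3, nrow(t2) - nrow(t3))
  t4 <- drop_hybrids_and_rare(t3, config)
  steps[[4]] <- report_row("hybrid_rare", t4, nrow(t3) - nrow(t4))
  t5 <- drop_degraded_plots(t4, snap, names, config)
  steps[[5]] <- report_row("degraded_plots", t5, nrow(t4) - nrow(t5))
  h6 <- demote_rare_habitats(headers, config,
                             plot_ids = unique(t5$plot_id))
  demoted <- sum(!is.na(headers$habitat)) - sum(!is.na(h6$habitat))
  steps[[6]] <- report_row("rare_habitats", t5, demoted)
  sets <- split_datasets(t5, h6)
  report <- dplyr::bind_rows(steps)
  t5$rank <- NULL
  sets$fill_mask$rank <- NULL
  sets$classification$rank <- NULL
  list(fill_mask = sets$fill_mask,
       classification = sets$classification,
       headers = h6,
       report = report)
}
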