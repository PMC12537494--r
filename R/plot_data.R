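#' Column dialect for observation and header tables
#'
#' Vegetation-plot archives export long tables under varying column names.
#' A dialect maps the exporter's column names onto the canonical internal
#' names used throughout the package (`plot_id`, `taxon`, `layer`, `cover`
#' for observations; `plot_id`, `lon`, `lat`, `habitat` for headers). The
#' default mirrors a typical European archive export.
#'
#' @param plot_id,taxon,layer,cover,lon,lat,habitat Column names in the file.
#' @return A named list of class `veg_dialect`.
#' @export
#' @examples
#' eva_dialect(taxon = "Species name")
eva_dialect <- function(plot_id = "PlotObservationID",
                        taxon = "Matched concept",
                        layer = "Layer",
                        cover = "Cover %",
                        lon = "Longitude",
                        lat = "Latitude",
                        habitat = "Expert System") {
  structure(list(plot_id = plot_id, taxon = taxon, layer = layer,
                 cover = cover, lon = lon, lat = lat, habitat = habitat),
            class = "veg_dialect")
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE, encoding = "UTF-8")
  if (length(first) == 0) return("\t")
  counts <- c(`\t` = lengths(regmatches(first, gregexpr("\t", first))),
              `,`  = lengths(regmatches(first, gregexpr(",", first))),
              `;`  = lengths(regmatches(first, gregexpr(";", first))))
  names(counts)[which.max(counts)]
}

read_delim_utf8 <- function(path, delimiter) {
  if (is.null(delimiter)) delimiter <- detect_delim(path)
  readr::read_delim(path, delim = delimiter, col_types = readr::cols(
    .default = readr::col_character()),
    locale = readr::locale(encoding = "UTF-8"),
    progress = FALSE, show_col_types = FALSE)
}

require_columns <- function(raw, dialect, needed, path) {
  missing <- setdiff(unlist(dialect[needed]), names(raw))
  assert_that(length(missing) == 0,
              paste0("file '", path, "' lacks mapped column(s): ",
                     paste(missing, collapse = ", ")))
}

#' Read a long-format plot observation table
#'
#' One row per (plot, taxon, layer) observation with a percent cover value.
#' Rows whose cover fails numeric coercion are not loaded silently: they are
#' collected in the `problems` attribute (a tibble with the row number and
#' offending value) and a warning summarises the count.
#'
#' @param path Path to a delimited text file with a header row (UTF-8).
#' @param dialect A [eva_dialect()] column mapping.
#' @param delimiter Field delimiter; `NULL` (default) auto-detects among
#'   tab, comma and semicolon from the header line.
#' @return A tibble with columns `plot_id`, `taxon`, `layer`, `cover`
#'   (class `veg_plot_table`); row order is preserved from the file.
#' @export
read_observations <- function(path, dialect = eva_dialect(),
                              delimiter = NULL) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  raw <- read_delim_utf8(path, delimiter)
  require_columns(raw, dialect, c("plot_id", "taxon", "cover"), path)
  has_layer <- dialect$layer %in% names(raw)
  tab <- tibble(
    plot_id = as.character(raw[[dialect$plot_id]]),
    taxon   = as.character(raw[[dialect$taxon]]),
    layer   = if (has_layer) as.character(raw[[dialect$layer]])
              else NA_character_,
    cover   = suppressWarnings(as.numeric(raw[[dialect$cover]])))
  bad <- which(is.na(tab$cover) | is.na(tab$taxon) | tab$taxon == "")
  problems <- tibble(row = bad,
                     taxon = tab$taxon[bad],
                     cover = as.character(raw[[dialect$cover]])[bad])
  if (length(bad) > 0) {
    warn(paste0(length(bad), " row(s) failed coercion and were reported, ",
                "not loaded (see attr(., 'problems'))"))
    tab <- tab[-bad, , drop = FALSE]
  }
  structure(tab, problems = problems,
            class = c("veg_plot_table", class(tab)))
}

#' Read a plot header table (coordinates and optional habitat label)
#'
#' @inheritParams read_observations
#' @return A tibble with columns `plot_id`, `lon`, `lat`, `habitat`
#'   (`NA` when the plot is unlabelled). Rows with out-of-range coordinates
#'   are reported in the `problems` attribute and dropped with a warning;
#'   duplicated `plot_id` is an error.
#' @export
read_headers <- function(path, dialect = eva_dialect(), delimiter = NULL) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  raw <- read_delim_utf8(path, delimiter)
  require_columns(raw, dialect, c("plot_id", "lon", "lat"), path)
  has_hab <- dialect$habitat %in% names(raw)
  tab <- tibble(
    plot_id = as.character(raw[[dialect$plot_id]]),
    lon = suppressWarnings(as.numeric(raw[[dialect$lon]])),
    lat = suppressWarnings(as.numeric(raw[[dialect$lat]])),
    habitat = if (has_hab) as.character(raw[[dialect$habitat]])
              else NA_character_)
  tab$habitat[!is.na(tab$habitat) & tab$habitat == ""] <- NA_character_
  if (anyDuplicated(tab$plot_id))
    abort(paste0("duplicated plot_id in headers: ",
                 paste(unique(tab$plot_id[duplicated(tab$plot_id)]),
                       collapse = ", ")))
  bad <- which(is.na(tab$lon) | is.na(tab$lat) |
                 tab$lon < -180 | tab$lon > 180 |
                 tab$lat < -90 | tab$lat > 90)
  problems <- tibble(row = bad, lon = tab$lon[bad], lat = tab$lat[bad])
  if (length(bad) > 0) {
    warn(paste0(length(bad), " header row(s) with invalid coordinates ",
                "reported, not loaded"))
    tab <- tab[-bad, , drop = FALSE]
  }
  structure(tab, problems = problems,
            class = c("veg_headers", class(tab)))
}

#' Write an observation or header table back to delimited text
#'
#' The inverse of [read_observations()] / [read_headers()]: writing then
#' re-reading with the same dialect reproduces the table (round trip).
#'
#' @param x A table from [read_observations()] or [read_headers()].
#' @param path Output path.
#' @param dialect Column mapping used for the output header row.
#' @param delimiter Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, dialect = eva_dialect(), delimiter = "\t") {
  is_headers <- all(c("lon", "lat") %in% names(x))
  if (is_headers) {
    out <- tibble(x$plot_id, x$lon, x$lat, x$habitat)
    names(out) <- unlist(dialect[c("plot_id", "lon", "lat", "habitat")])
  } else {
    out <- tibble(x$plot_id, x$taxon, x$layer, x$cover)
    names(out) <- unlist(dialect[c("plot_id", "taxon", "layer", "cover")])
  }
  readr::write_delim(out, path, delim = delimiter, na = "")
  invisible(path)
}

#' Read a taxon name-standardisation table
#'
#' A user-supplied synonym/backbone table replacing live name-matching
#' services. Columns: `input_name`, `accepted_binomial` (lowercase
#' "genus epithet", empty when unmatched) and `rank` (one of `species`,
#' `subspecies`, `genus`, `hybrid`, `unmatched`). Subspecies records must
#' already point at their parent binomial.
#'
#' @inheritParams read_observations
#' @return A tibble of class `veg_names`.
#' @export
read_name_records <- function(path, delimiter = NULL) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  raw <- read_delim_utf8(path, delimiter)
  assert_that(all(c("input_name", "accepted_binomial", "rank") %in%
                    names(raw)),
              "name table needs columns input_name, accepted_binomial, rank")
  out <- tibble(input_name = raw$input_name,
                accepted_binomial = tolower(raw$accepted_binomial),
                rank = raw$rank)
  out$accepted_binomial[is.na(out$accepted_binomial) |
                          out$accepted_binomial == ""] <- NA_character_
  out$rank[is.na(out$accepted_binomial)] <- "unmatched"
  bad <- !out$rank %in% c("species", "subspecies", "genus", "hybrid",
                          "unmatched")
  assert_that(!any(bad), paste0("unknown rank value(s): ",
                                paste(unique(out$rank[bad]), collapse = ", ")))
  structure(out, class = c("veg_names", class(out)))
}

#' Construct an observation table in code
#'
#' Convenience constructor used by the generator and by tests.
#'
#' @param plot_id,taxon,cover Equal-length vectors; `layer` optional.
#' @return A `veg_plot_table` tibble.
#' @export
plot_table <- function(plot_id, taxon, cover, layer = NA_character_) {
  tab <- tibble(plot_id = as.character(plot_id),
                taxon = as.character(taxon),
                layer = as.character(layer),
                cover = as.numeric(cover))
  structure(tab, class = c("veg_plot_table", class(tab)))
}
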