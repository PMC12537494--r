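# Special tokens occupy the first five ids of every vocabulary, in this
# order; content tokens follow, lexicographically, so identical corpora
# always produce identical vocabularies.
SPECIALS <- c("[CLS]", "[SEP]", "[MASK]", "[UNK]", ",")
CLS_ID <- 0L; SEP_ID <- 1L; MASK_ID <- 2L; UNK_ID <- 3L; COMMA_ID <- 4L

# Position categories, as integer codes used in encoded matrices.
CAT_LEVELS <- c("classify", "separator", "comma", "species", "genus",
                "epithet", "unknown")
CAT_CLS <- 0L; CAT_SEP <- 1L; CAT_COMMA <- 2L; CAT_SPECIES <- 3L
CAT_GENUS <- 4L; CAT_EPITHET <- 5L; CAT_UNK <- 6L

#' Serialise one plot as an abundance-ordered species sentence
#'
#' Species are listed in descending cover order, lowercased. Tied covers
#' (ubiquitous when covers come from ordinal scales) are ordered randomly
#' within the tied group under the given seed; `order_mode = "random"`
#' shuffles the whole list instead, discarding the abundance signal.
#'
#' @param obs Observations of a single plot: a data frame with `taxon` and
#'   `cover` columns (a one-plot slice of a `veg_plot_table`).
#' @param order_mode `"abundance"` (default) or `"random"`.
#' @param seed Seed for tie-breaking / shuffling.
#' @return A `veg_sentence`: list with `plot_id`, `species` (ordered
#'   lowercase binomials) and `covers` (in the same order).
#' @export
build_sentence <- function(obs, order_mode = c("abundance", "random"),
                           seed = 1L) {
  order_mode <- match.arg(order_mode)
  assert_that(nrow(obs) >= 1, "cannot build a sentence from an empty plot")
  plot_id <- if ("plot_id" %in% names(obs)) obs$plot_id[1] else NA_character_
  n <- nrow(obs)
  ord <- with_seed(derive_seed(seed, "order", plot_id), {
    if (order_mode == "abundance") order(-obs$cover, sample.int(n))
    else sample.int(n)
  })
  structure(list(plot_id = plot_id,
                 species = tolower(obs$taxon[ord]),
                 covers = obs$cover[ord]),
            class = "veg_sentence")
}

#' @export
format.veg_sentence <- function(x, ...) paste(x$species, collapse = ", ")

#' @export
print.veg_sentence <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Build sentences for every plot of a table
#'
#' Each plot gets its own tie-break stream derived from `(seed, plot_id)`,
#' so sentences are reproducible plot by plot and a fresh `seed` (e.g. per
#' epoch) redraws the permutations within tied cover groups.
#'
#' @param table A curated `veg_plot_table`.
#' @inheritParams build_sentence
#' @return A named list of `veg_sentence` (names = plot ids, in first-
#'   appearance order).
#' @export
build_sentences <- function(table, order_mode = "abundance", seed = 1L) {
  idx <- split(seq_len(nrow(table)), factor(table$plot_id,
                                            levels = unique(table$plot_id)))
  lapply(idx, function(i)
    build_sentence(table[i, , drop = FALSE], order_mode, seed))
}

split_binomial <- function(sp) strsplit(sp, " ", fixed = TRUE)

#' Fit a tokenizer vocabulary on a sentence corpus
#'
#' Two schemes: `"species"` treats each whole binomial as one token;
#' `"term"` splits each binomial into a genus token and an epithet token.
#' Content tokens are ordered lexicographically after the five special
#' tokens (`[CLS]`, `[SEP]`, `[MASK]`, `[UNK]`, the comma), so the mapping
#' is deterministic. Ids are dense and 0-based.
#'
#' @param sentences A list of `veg_sentence` (or character vectors of
#'   binomials).
#' @param scheme `"species"` or `"term"`.
#' @return A `veg_vocab`: list with `scheme`, `tokens` (id `i` is
#'   `tokens[i + 1]`), and for the term scheme the genus/epithet token id
#'   sets used for category-matched random replacement.
#' @export
fit_vocabulary <- function(sentences, scheme = c("species", "term")) {
  scheme <- match.arg(scheme)
  assert_that(length(sentences) > 0, "empty corpus")
  sp <- unlist(lapply(sentences, function(s)
    if (inherits(s, "veg_sentence")) s$species else s))
  sp <- unique(tolower(sp))
  if (scheme == "species") {
    content <- sort(sp, method = "radix")
    genus_ids <- epithet_ids <- integer(0)
  } else {
    parts <- split_binomial(sp)
    genus <- unique(vapply(parts, `[`, character(1), 1))
    epithet <- unique(unlist(lapply(parts, function(p) p[-1])))
    content <- sort(unique(c(genus, epithet)), method = "radix")
    genus_ids <- match(sort(genus, method = "radix"), content) - 1L +
      length(SPECIALS)
    epithet_ids <- match(sort(epithet, method = "radix"), content) - 1L +
      length(SPECIALS)
  }
  tokens <- c(SPECIALS, content)
  structure(list(scheme = scheme, tokens = tokens,
                 n_content = length(content),
                 content_ids = seq_along(content) - 1L + length(SPECIALS),
                 genus_ids = genus_ids, epithet_ids = epithet_ids),
            class = "veg_vocab")
}

#' @export
print.veg_vocab <- function(x, ...) {
  cat(sprintf("<veg_vocab scheme=%s, %d content tokens + %d specials>\n",
              x$scheme, x$n_content, length(SPECIALS)))
  invisible(x)
}

token_id <- function(vocab, token) {
  id <- match(token, vocab$tokens) - 1L
  id[is.na(id)] <- UNK_ID
  id
}

#' Encode a sentence as a token-id sequence
#'
#' Produces `[CLS]`, the content tokens with exactly one comma token between
#' species, and a final `[SEP]`. Unseen binomials (species scheme) or terms
#' (term scheme) map to `[UNK]`. The literal species entry `"[MASK]"` (or a
#' masked term such as `"[MASK] maritima"`) encodes as mask tokens, so
#' fill-mask queries can be written as plain sentences.
#'
#' @param sentence A `veg_sentence` or character vector of binomials.
#' @param vocab A fitted [fit_vocabulary()].
#' @return A `veg_tokens`: list with integer `ids` (0-based) and `cats`
#'   (position categories, integer-coded; see `CAT_LEVELS` in the source).
#' @export
encode <- function(sentence, vocab) {
  species <- if (inherits(sentence, "veg_sentence")) sentence$species
             else tolower(as.character(sentence))
  assert_that(length(species) >= 1, "cannot encode an empty species list")
  ids <- CLS_ID
  cats <- CAT_CLS
  for (i in seq_along(species)) {
    if (i > 1) { ids <- c(ids, COMMA_ID); cats <- c(cats, CAT_COMMA) }
    if (vocab$scheme == "species") {
      if (species[i] == "[mask]") {
        ids <- c(ids, MASK_ID); cats <- c(cats, CAT_SPECIES)
      } else {
        id <- token_id(vocab, species[i])
        ids <- c(ids, id)
        cats <- c(cats, if (id == UNK_ID) CAT_UNK else CAT_SPECIES)
      }
    } else {
      parts <- split_binomial(species[i])[[1]]
      if (identical(parts, "[mask]")) parts <- c("[mask]", "[mask]")
      for (j in seq_along(parts)) {
        cat_j <- if (j == 1) CAT_GENUS else CAT_EPITHET
        if (parts[j] == "[mask]") {
          ids <- c(ids, MASK_ID); cats <- c(cats, cat_j)
        } else {
          id <- token_id(vocab, parts[j])
          ids <- c(ids, id)
          cats <- c(cats, if (id == UNK_ID) CAT_UNK else cat_j)
        }
      }
    }
  }
  ids <- c(ids, SEP_ID); cats <- c(cats, CAT_SEP)
  structure(list(ids = as.integer(ids), cats = as.integer(cats)),
            class = "veg_tokens")
}

#' Decode a token sequence back to a sentence string
#'
#' Inverse of [encode()] on in-vocabulary input; `[MASK]` and `[UNK]`
#' render literally. A sequence without a final `[SEP]` is malformed.
#'
#' @param tokens A `veg_tokens` (or integer id vector).
#' @param vocab The vocabulary used for encoding.
#' @return A single string, e.g. `"hedera helix, quercus robur"`.
#' @export
decode <- function(tokens, vocab) {
  ids <- if (inherits(tokens, "veg_tokens")) tokens$ids else as.integer(tokens)
  assert_that(length(ids) >= 2 && ids[length(ids)] == SEP_ID,
              "malformed sequence: no terminal [SEP]")
  body <- ids[-c(1, length(ids))]
  if (length(body) == 0) return("")
  words <- vocab$tokens[body + 1L]
  out <- character(0)
  group <- character(0)
  for (w in words) {
    if (w == ",") { out <- c(out, paste(group, collapse = " ")); group <- character(0) }
    else group <- c(group, w)
  }
  out <- c(out, paste(group, collapse = " "))
  paste(out, collapse = ", ")
}

#' Encode a whole corpus into padded id/category matrices
#'
#' Sequences longer than `max_len` are truncated from the tail of the
#' species list (least abundant species dropped) so the terminal `[SEP]`
#' is always present.
#'
#' @param sentences List of `veg_sentence` / character vectors.
#' @param vocab A `veg_vocab`.
#' @param max_len Maximum sequence length in tokens.
#' @return List: `ids` and `cats` integer matrices (n x max observed
#'   length, padded with `-1`), `lengths`, and `plot_ids`.
#' @export
encode_corpus <- function(sentences, vocab, max_len = 128L) {
  enc <- lapply(sentences, function(s) {
    tk <- encode(s, vocab)
    if (length(tk$ids) > max_len) {
      keep <- max_len - 1L
      # cut back to the last comma before the limit, then close with [SEP]
      while (keep > 1L && tk$cats[keep] != CAT_COMMA) keep <- keep - 1L
      tk$ids <- c(tk$ids[seq_len(keep - 1L)], SEP_ID)
      tk$cats <- c(tk$cats[seq_len(keep - 1L)], CAT_SEP)
    }
    tk
  })
  lens <- vapply(enc, function(t) length(t$ids), integer(1))
  L <- max(lens)
  n <- length(enc)
  ids <- matrix(-1L, n, L)
  cats <- matrix(-1L, n, L)
  for (i in seq_len(n)) {
    ids[i, seq_len(lens[i])] <- enc[[i]]$ids
    cats[i, seq_len(lens[i])] <- enc[[i]]$cats
  }
  list(ids = ids, cats = cats, lengths = lens,
       plot_ids = names(sentences) %||% as.character(seq_len(n)))
}

#' Corrupt token sequences for the masked-species objective
#'
#' Every content token (species, genus, epithet or `[UNK]` position) is
#' independently selected with probability `select_rate`; special tokens
#' and commas are never touched. Each selected token is replaced by
#' `[MASK]` with probability `mask_frac`, by a random content token with
#' probability `random_frac` (drawn category-matched under the term scheme:
#' genus slots draw genus tokens, epithet slots epithet tokens), and kept
#' unchanged otherwise. Labels carry the original id at selected positions
#' and `-1` elsewhere.
#'
#' @param tokens A `veg_tokens`, a list of them, or an [encode_corpus()]
#'   result.
#' @param vocab The `veg_vocab` (needed for the random-replacement pool).
#' @param seed Seed; a fresh seed gives a fresh corruption of the same
#'   corpus, as redrawn every training epoch.
#' @param select_rate,mask_frac,random_frac The selection and corruption
#'   rates (defaults 0.15, 0.8, 0.1; the remaining 0.1 keeps the token).
#' @return A list with `ids` (corrupted), `labels` (same shape, `-1` =
#'   ignore) and `seed`; matrices when the input was a corpus, single
#'   vectors otherwise.
#' @export
mask_collate <- function(tokens, vocab, seed = 1L, select_rate = 0.15,
                         mask_frac = 0.8, random_frac = 0.1) {
  assert_that(select_rate >= 0 && select_rate <= 1, "select_rate in [0,1]")
  assert_that(mask_frac + random_frac <= 1 + 1e-12,
              "mask_frac + random_frac must be at most 1")
  single <- inherits(tokens, "veg_tokens")
  if (single) {
    ids <- matrix(tokens$ids, 1); cats <- matrix(tokens$cats, 1)
  } else if (is.list(tokens) && !is.null(tokens$ids) &&
             is.matrix(tokens$ids)) {
    ids <- tokens$ids; cats <- tokens$cats
  } else {
    corp <- encode_corpus(tokens, vocab)
    ids <- corp$ids; cats <- corp$cats
  }
  labels <- matrix(-1L, nrow(ids), ncol(ids))
  content <- which(cats >= CAT_SPECIES)        # species/genus/epithet/unknown
  out <- ids
  with_seed(derive_seed(seed, "collate"), {
    sel <- content[runif(length(content)) < select_rate]
    if (length(sel) > 0) {
      labels[sel] <- ids[sel]
      u <- runif(length(sel))
      to_mask <- sel[u < mask_frac]
      to_rand <- sel[u >= mask_frac & u < mask_frac + random_frac]
      out[to_mask] <- MASK_ID
      if (length(to_rand) > 0) {
        pool_for <- function(cat) {
          if (vocab$scheme == "term" && cat == CAT_GENUS) vocab$genus_ids
          else if (vocab$scheme == "term" && cat == CAT_EPITHET)
            vocab$epithet_ids
          else vocab$content_ids
        }
        out[to_rand] <- vapply(to_rand, function(p) {
          pool <- pool_for(cats[p])
          pool[sample.int(length(pool), 1)]
        }, integer(1))
      }
    }
  })
  if (single)
    list(ids = as.integer(out[1, ]), labels = as.integer(labels[1, ]),
         seed = seed)
  else list(ids = out, labels = labels, seed = seed)
}

#' Save / load a vocabulary as JSON
#' @param vocab A `veg_vocab`.
#' @param path File path.
#' @return `path` (save) or the vocabulary (load).
#' @export
save_vocabulary <- function(vocab, path) {
  jsonlite::write_json(unclass(vocab), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_vocabulary
#' @export
load_vocabulary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$tokens <- as.character(x$tokens)
  x$content_ids <- as.integer(x$content_ids)
  x$genus_ids <- as.integer(x$genus_ids)
  x$epithet_ids <- as.integer(x$epithet_ids)
  x$n_content <- as.integer(x$n_content)
  structure(x, class = "veg_vocab")
}

#' Write a sentence corpus as plain text, one sentence per line
#' @param sentences List of `veg_sentence`.
#' @param path File path.
#' @export
write_corpus <- function(sentences, path) {
  writeLines(vapply(sentences, format, character(1)), path, useBytes = TRUE)
  invisible(path)
}
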