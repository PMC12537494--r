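#' Encoder / training configuration
#'
#' Desk-scale defaults: a 2-layer, 128-wide, 4-head encoder trained for five
#' epochs. The feed-forward width defaults to twice the hidden width. Larger
#' presets in the style of the base/large encoder families can be obtained
#' by raising `layers`/`hidden`/`heads`.
#'
#' @param layers Number of transformer blocks.
#' @param hidden Hidden width (must be divisible by `heads`).
#' @param heads Attention heads.
#' @param ffn Feed-forward inner width (default `2 * hidden`).
#' @param dropout Dropout rate on the residual branches during training.
#' @param epochs Full passes over the corpus (default 5).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param seed Master seed: controls initialisation, per-epoch masking,
#'   shuffling and dropout.
#' @param max_len Maximum tokenised sequence length; longer sentences are
#'   truncated from the least abundant end.
#' @param select_rate,mask_frac,random_frac Masking-collator rates.
#' @param clip Global gradient-norm clip (0 disables).
#' @param warmup Fraction of the total training steps spent linearly
#'   warming the learning rate up from zero; the rate then decays linearly
#'   to zero over the remaining steps (the standard encoder fine-tuning
#'   schedule). Set to `NA` for a constant learning rate.
#' @return A list of class `lm_config`.
#' @export
lm_config <- function(layers = 2, hidden = 128, heads = 4,
                      ffn = 2 * hidden, dropout = 0, epochs = 5,
                      lr = 1e-3, batch_size = 32, seed = 1L,
                      max_len = 128, select_rate = 0.15, mask_frac = 0.8,
                      random_frac = 0.1, clip = 1.0, warmup = 0.1) {
  assert_that(hidden %% heads == 0, "hidden must be divisible by heads")
  assert_that(layers >= 1 && epochs >= 0, "layers >= 1, epochs >= 0")
  structure(list(layers = as.integer(layers), hidden = as.integer(hidden),
                 heads = as.integer(heads), ffn = as.integer(ffn),
                 dropout = dropout, epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 max_len = as.integer(max_len), select_rate = select_rate,
                 mask_frac = mask_frac, random_frac = random_frac,
                 clip = clip, warmup = warmup),
            class = "lm_config")
}

schedule_steps <- function(config, n) {
  warmup <- config$warmup %||% NA_real_
  if (is.null(warmup) || is.na(warmup))
    return(c(total = 0, warmup = 0))
  total <- config$epochs * ceiling(n / config$batch_size)
  c(total = total, warmup = ceiling(warmup * total))
}

init_params <- function(vocab_size, config, n_classes = 2L,
                        init_sd = 0.02) {
  H <- config$hidden; F <- config$ffn; L <- config$layers
  P <- config$max_len
  rm_ <- function(r, c) matrix(rnorm(r * c, sd = init_sd), r, c)
  params <- list(tok_emb = rm_(vocab_size, H), pos_emb = rm_(P, H))
  for (l in seq_len(L)) {
    params[[paste0("Wq_", l)]] <- rm_(H, H)
    params[[paste0("bq_", l)]] <- numeric(H)
    params[[paste0("Wk_", l)]] <- rm_(H, H)
    params[[paste0("bk_", l)]] <- numeric(H)
    params[[paste0("Wv_", l)]] <- rm_(H, H)
    params[[paste0("bv_", l)]] <- numeric(H)
    params[[paste0("Wo_", l)]] <- rm_(H, H)
    params[[paste0("bo_", l)]] <- numeric(H)
    params[[paste0("W1_", l)]] <- rm_(H, F)
    params[[paste0("b1_", l)]] <- numeric(F)
    params[[paste0("W2_", l)]] <- rm_(F, H)
    params[[paste0("b2_", l)]] <- numeric(H)
    params[[paste0("ln1g_", l)]] <- rep(1, H)
    params[[paste0("ln1b_", l)]] <- numeric(H)
    params[[paste0("ln2g_", l)]] <- rep(1, H)
    params[[paste0("ln2b_", l)]] <- numeric(H)
  }
  params$out_b <- numeric(vocab_size)
  params$Wp <- rm_(H, H)
  params$bp <- numeric(H)
  params$Wc <- rm_(H, n_classes)
  params$bc <- numeric(n_classes)
  params
}

zero_like <- function(params) lapply(params, function(p) {
  if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
})

#' Train a masked-species encoder on a sentence corpus
#'
#' Self-supervised masked-token objective: each epoch the corpus is freshly
#' corrupted by [mask_collate()] (selection and corruption redrawn under
#' `(seed, epoch)`), shuffled, and passed through the encoder; the model
#' learns to recover the hidden species (or genus/epithet term) from its
#' bidirectional context. Training is deterministic given the seed when BLAS
#' runs single-threaded. With `epochs = 0` the randomly initialised model is
#' returned untrained (its output distributions are near uniform).
#'
#' @param sentences A list of `veg_sentence` (see [build_sentences()]).
#' @param vocab A fitted [fit_vocabulary()].
#' @param config An [lm_config()].
#' @param params Optional pre-initialised parameter list (e.g. a saved
#'   checkpoint) to continue training from.
#' @return A `veg_mlm` model: parameters, vocabulary, config and the
#'   per-epoch training loss.
#' @export
train_mlm <- function(sentences, vocab, config = lm_config(),
                      params = NULL) {
  assert_that(length(sentences) > 0, "empty corpus")
  corp <- encode_corpus(sentences, vocab, config$max_len)
  V <- length(vocab$tokens)
  if (is.null(params))
    params <- with_seed(derive_seed(config$seed, "init"),
                        init_params(V, config))
  adam_m <- zero_like(params)
  adam_v <- zero_like(params)
  adam_t <- 0
  sched <- schedule_steps(config, length(sentences))
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    batch <- mask_collate(corp, vocab, seed = derive_seed(config$seed, ep),
                          select_rate = config$select_rate,
                          mask_frac = config$mask_frac,
                          random_frac = config$random_frac)
    res <- cpp_train_epoch(params, adam_m, adam_v, batch$ids, batch$labels,
                           corp$lengths, config$layers, config$heads,
                           config$batch_size, config$lr, config$dropout,
                           0L, derive_seed(config$seed, "shuffle", ep),
                           adam_t, config$clip,
                           sched[["total"]], sched[["warmup"]])
    adam_t <- res$adam_t
    losses[ep] <- res$loss
  }
  structure(list(params = params, vocab = vocab, config = config,
                 loss = losses),
            class = "veg_mlm")
}

#' @export
print.veg_mlm <- function(x, ...) {
  cat(sprintf(paste0("<veg_mlm: %d layers x %d hidden (%d heads), ",
                     "%s scheme, %d tokens>\n"),
              x$config$layers, x$config$hidden, x$config$heads,
              x$vocab$scheme, length(x$vocab$tokens)))
  if (length(x$loss)) cat("  final training loss:",
                          round(tail(x$loss, 1), 4), "\n")
  invisible(x)
}

# logits at requested positions for any language model; rows follow the
# sequence-major scan of the corpus matrices
model_logits <- function(model, ids, lengths, want) {
  UseMethod("model_logits")
}

#' @export
model_logits.veg_mlm <- function(model, ids, lengths, want) {
  cpp_forward(model$params, ids, lengths, model$config$layers,
              model$config$heads, 0L, want)
}

#' A uniform-output reference language model
#'
#' Assigns probability `1 / n_content` to every content token and
#' (numerically) zero to special tokens, at every position. Serves as the
#' uninformed floor in perplexity comparisons: its perplexity equals the
#' content vocabulary size.
#'
#' @param vocab A `veg_vocab`.
#' @return A `veg_uniform_lm` model.
#' @export
uniform_lm <- function(vocab) {
  structure(list(vocab = vocab), class = "veg_uniform_lm")
}

#' @export
model_logits.veg_uniform_lm <- function(model, ids, lengths, want) {
  V <- length(model$vocab$tokens)
  n <- sum(want != 0)
  row <- rep(-1e9, V)
  row[model$vocab$content_ids + 1L] <- 0
  matrix(row, n, V, byrow = TRUE)
}

softmax_rows <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Top-k predictions at each masked position of a sentence
#'
#' @param model A trained `veg_mlm`.
#' @param sentence Species list containing at least one `"[MASK]"` entry
#'   (whole species masked) or, under the term scheme, a masked term such
#'   as `"[MASK] maritima"`.
#' @param k Number of candidates per mask.
#' @param renormalize If `TRUE` (default) also report probabilities
#'   renormalised so the top k sum to 1.
#' @return A list, one tibble per mask position, with columns `token`,
#'   `prob` and (optionally) `prob_renorm`, best first.
#' @export
predict_topk <- function(model, sentence, k = 5, renormalize = TRUE) {
  tk <- encode(sentence, model$vocab)
  mask_pos <- which(tk$ids == MASK_ID)
  assert_that(length(mask_pos) > 0, "sentence contains no [MASK]")
  ids <- matrix(tk$ids, 1)
  want <- matrix(0L, 1, length(tk$ids))
  want[1, mask_pos] <- 1L
  logits <- model_logits(model, ids, as.integer(length(tk$ids)), want)
  probs <- softmax_rows(logits)
  lapply(seq_along(mask_pos), function(i) {
    p <- probs[i, ]
    ord <- order(-p, model$vocab$tokens, method = "radix")[seq_len(k)]
    out <- tibble(token = model$vocab$tokens[ord], prob = p[ord])
    if (renormalize) out$prob_renorm <- out$prob / sum(out$prob)
    out
  })
}

#' Perplexity of a language model on a held-out corpus
#'
#' The exponential of the mean cross-entropy over masked positions, using
#' the standard masking collator to pick the evaluated positions. 1 is a
#' perfect model; the content-vocabulary size is the uninformed ceiling.
#'
#' @param model A `veg_mlm` (or [uniform_lm()]).
#' @param sentences Held-out sentences.
#' @param seed Collator seed.
#' @param mask_frac Fraction of selected tokens replaced by `[MASK]`
#'   (default 1 at evaluation: every evaluated position is fully hidden).
#' @return A list: `perplexity`, `cross_entropy`, `n_positions`.
#' @export
perplexity <- function(model, sentences, seed = 1L, mask_frac = 1) {
  vocab <- model$vocab
  corp <- encode_corpus(sentences, vocab,
                        model$config$max_len %||% 128L)
  batch <- mask_collate(corp, vocab, seed = seed, mask_frac = mask_frac,
                        random_frac = 0)
  want <- matrix(0L, nrow(batch$labels), ncol(batch$labels))
  want[batch$labels >= 0] <- 1L
  if (sum(want) == 0)
    return(list(perplexity = NA_real_, cross_entropy = NA_real_,
                n_positions = 0L))
  logits <- model_logits(model, batch$ids, corp$lengths, want)
  probs <- softmax_rows(logits)
  # labels in sequence-major scan order, matching the logit rows
  lab <- unlist(lapply(seq_len(nrow(batch$labels)), function(i) {
    l <- batch$labels[i, seq_len(corp$lengths[i])]
    l[l >= 0]
  }))
  ce <- -mean(log(probs[cbind(seq_along(lab), lab + 1L)] + 1e-300))
  list(perplexity = exp(ce), cross_entropy = ce,
       n_positions = length(lab))
}

#' Suggest species to complete a partial assemblage
#'
#' Appends a `[MASK]` slot after the observed species and takes the model's
#' best candidate among species not already listed; the special end-of-list
#' token competes with the species, so when it wins the model considers the
#' assemblage complete and the procedure stops. Repeats up to
#' `max_additions` times. Species-scheme models only.
#'
#' @param model A trained `veg_mlm` (species scheme).
#' @param species Observed species, most abundant first.
#' @param max_additions Upper bound on appended species.
#' @return A tibble `species`, `prob` (model probability when appended),
#'   `sep_prob` (end-of-list probability at that step); zero rows when the
#'   model immediately considers the list complete.
#' @export
complete_assemblage <- function(model, species, max_additions = 10) {
  assert_that(model$vocab$scheme == "species",
              "assemblage completion requires a species-scheme model")
  assert_that(length(species) >= 1, "partial species list must be non-empty")
  current <- tolower(species)
  out <- tibble(species = character(0), prob = numeric(0),
                sep_prob = numeric(0))
  if (max_additions < 1) return(out)
  for (step in seq_len(max_additions)) {
    res <- predict_topk(model, c(current, "[MASK]"),
                        k = length(model$vocab$tokens),
                        renormalize = FALSE)[[1]]
    sep_prob <- res$prob[res$token == "[SEP]"]
    cand <- res[!res$token %in% c(current, SPECIALS), , drop = FALSE]
    if (nrow(cand) == 0 || sep_prob >= cand$prob[1]) break
    out <- dplyr::bind_rows(out, tibble(species = cand$token[1],
                                        prob = cand$prob[1],
                                        sep_prob = sep_prob))
    current <- c(current, cand$token[1])
  }
  out
}

#' @export
fill_blank.veg_mlm <- function(predictor, context, k = 1, ...) {
  vocab <- predictor$vocab
  slot <- which(is.na(context))
  sentence <- context
  sentence[slot] <- "[MASK]"
  res <- predict_topk(predictor, sentence,
                      k = length(vocab$tokens), renormalize = FALSE)
  if (vocab$scheme == "species") {
    r <- res[[1]]
    r <- r[!r$token %in% SPECIALS, , drop = FALSE]
    out <- tibble(species = r$token, prob = r$prob)
  } else {
    # one mask for the genus, one for the epithet; the binomial must be
    # reassembled and both halves scored (independence approximation)
    g <- res[[1]][res[[1]]$token %in% vocab$tokens[vocab$genus_ids + 1L], ]
    e <- res[[2]][res[[2]]$token %in% vocab$tokens[vocab$epithet_ids + 1L], ]
    g <- head(g, 10); e <- head(e, 10)
    combo <- expand.grid(gi = seq_len(nrow(g)), ei = seq_len(nrow(e)))
    sp <- paste(g$token[combo$gi], e$token[combo$ei])
    pr <- g$prob[combo$gi] * e$prob[combo$ei]
    ord <- order(-pr, sp, method = "radix")
    out <- tibble(species = sp[ord], prob = pr[ord])
  }
  head(out, k)
}

#' Rank-wise fill-mask accuracy over labelled plots
#'
#' For each plot recording strictly more than ten species, the ten most
#' abundant species are masked one at a time; the predictor's top
#' candidate is scored by exact species match (under the term scheme both
#' the genus and the epithet must be right). Reports accuracy per
#' abundance rank and the micro average over all (plot, rank) trials.
#'
#' @param predictor A `veg_mlm`, `veg_nb` or `veg_mlp` (see
#'   [fill_blank()]).
#' @param sentences Cover-ordered plot sentences.
#' @param ranks Abundance ranks evaluated (default 1:10).
#' @return A list: `per_rank` tibble (`rank`, `n`, `accuracy`) and
#'   `overall` micro accuracy.
#' @export
rank_masking_eval <- function(predictor, sentences, ranks = 1:10) {
  keep <- vapply(sentences, function(s) length(s$species) >
                   max(ranks), logical(1))
  sentences <- sentences[keep]
  hits <- matrix(NA, length(sentences), length(ranks))
  for (i in seq_along(sentences)) {
    sp <- sentences[[i]]$species
    for (j in seq_along(ranks)) {
      r <- ranks[j]
      context <- sp
      context[r] <- NA
      top <- fill_blank(predictor, context, k = 1)
      hits[i, j] <- nrow(top) > 0 && top$species[1] == sp[r]
    }
  }
  per_rank <- tibble(rank = ranks,
                     n = colSums(!is.na(hits)),
                     accuracy = colMeans(hits, na.rm = TRUE))
  list(per_rank = per_rank, overall = mean(hits, na.rm = TRUE),
       n_plots = length(sentences))
}

#' Save / load an encoder model as plain text
#'
#' Parameters are written one matrix per TSV file plus a JSON manifest
#' (config, vocabulary, classes if any), so a model directory is fully
#' text-based and portable.
#'
#' @param model A `veg_mlm` or `veg_habitat_clf`.
#' @param dir Directory (created if needed).
#' @return `dir` (save); the model (load).
#' @export
save_model <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(class = class(model)[1], config = unclass(model$config),
                   vocab = unclass(model$vocab), loss = model$loss,
                   classes = model$classes,
                   param_names = names(model$params))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (nmp in names(model$params)) {
    p <- model$params[[nmp]]
    if (!is.matrix(p)) p <- matrix(p, nrow = 1)
    utils::write.table(p, file.path(dir, paste0(nmp, ".tsv")),
                       row.names = FALSE, col.names = FALSE, sep = "\t")
  }
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  params <- lapply(manifest$param_names, function(nmp) {
    p <- as.matrix(utils::read.table(file.path(dir, paste0(nmp, ".tsv")),
                                     sep = "\t"))
    dimnames(p) <- NULL
    if (nrow(p) == 1 && !nmp %in% c("tok_emb", "pos_emb")) as.numeric(p)
    else p
  })
  names(params) <- manifest$param_names
  vocab <- manifest$vocab
  vocab$tokens <- as.character(vocab$tokens)
  vocab$content_ids <- as.integer(vocab$content_ids)
  vocab$genus_ids <- as.integer(vocab$genus_ids)
  vocab$epithet_ids <- as.integer(vocab$epithet_ids)
  vocab$n_content <- as.integer(vocab$n_content)
  class(vocab) <- "veg_vocab"
  config <- manifest$config
  class(config) <- "lm_config"
  out <- list(params = params, vocab = vocab, config = config,
              loss = manifest$loss)
  if (!is.null(manifest$classes)) out$classes <- manifest$classes
  class(out) <- manifest$class
  out
}
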