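EUNIS_BROAD <- c("MA2", "N", "Q", "R", "S", "T", "U", "V")

#' Parse hierarchical EUNIS habitat codes
#'
#' EUNIS habitat codes are hierarchical: a broad habitat group (level 1) is
#' one letter — except the littoral biogenic group, coded `MA2` — and each
#' deeper level appends one alphanumeric character. So `N14` is a level-3
#' habitat type in group `N1` within broad group `N`, and a level-3 code
#' under `MA2` has five characters. Level-3 codes are required here since
#' coarser accuracies are derived by projecting level-3 predictions.
#'
#' @param codes Character vector of level-3 codes.
#' @return A tibble with `code`, `group` (level 2) and `broad` (level 1).
#'   Unknown broad prefixes or wrong code lengths are errors.
#' @export
parse_eunis <- function(codes) {
  codes <- as.character(codes)
  assert_that(all(!is.na(codes) & nzchar(codes)), "empty habitat code")
  broad <- ifelse(startsWith(codes, "MA"), "MA2",
                  substr(codes, 1, 1))
  bad <- !broad %in% EUNIS_BROAD |
    (broad == "MA2" & !startsWith(codes, "MA2"))
  assert_that(!any(bad),
              paste0("unknown broad habitat group for code(s): ",
                     paste(unique(codes[bad]), collapse = ", ")))
  blen <- nchar(broad)
  wrong <- nchar(codes) != blen + 2L
  assert_that(!any(wrong),
              paste0("not a level-3 habitat code: ",
                     paste(unique(codes[wrong]), collapse = ", ")))
  tibble(code = codes, group = substr(codes, 1, blen + 1L), broad = broad)
}

#' Fine-tune an encoder into a habitat-type classifier
#'
#' Replaces the masked-token decoder's role with a classification head (a
#' tanh pooling layer over the sequence-level position plus a linear output
#' layer sized to the label set) and trains the whole network for
#' `config$epochs` passes on labelled sentences. The label set is closed:
#' predictions are always one of the training labels.
#'
#' @param model A trained `veg_mlm` whose vocabulary matches the corpus
#'   (or `NULL` to train from random initialisation).
#' @param sentences Labelled plot sentences.
#' @param labels Character vector of level-3 habitat codes, parallel to
#'   `sentences`.
#' @param config Optional [lm_config()] override; defaults to the encoder
#'   model's config.
#' @param vocab Required when `model` is `NULL`.
#' @return A `veg_habitat_clf`: parameters, vocabulary, config, `classes`
#'   and the training loss curve.
#' @export
fine_tune <- function(model, sentences, labels, config = NULL,
                      vocab = NULL) {
  assert_that(length(sentences) == length(labels),
              "sentences and labels must be parallel")
  parse_eunis(labels)          # validates level-3 codes
  classes <- sort(unique(labels), method = "radix")
  assert_that(length(classes) >= 2, "need at least 2 habitat classes")
  if (!is.null(model)) {
    vocab <- model$vocab
    config <- config %||% model$config
  }
  assert_that(!is.null(vocab) && !is.null(config),
              "vocab and config are required when model is NULL")
  V <- length(vocab$tokens)
  params <- with_seed(derive_seed(config$seed, "clf-init"), {
    p <- init_params(V, config, n_classes = length(classes))
    if (!is.null(model)) {
      keep <- setdiff(names(model$params), c("Wc", "bc"))
      p[keep] <- model$params[keep]
    }
    p
  })
  corp <- encode_corpus(sentences, vocab, config$max_len)
  y <- match(labels, classes) - 1L
  adam_m <- zero_like(params)
  adam_v <- zero_like(params)
  adam_t <- 0
  sched <- schedule_steps(config, length(sentences))
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    res <- cpp_train_epoch(params, adam_m, adam_v, corp$ids, y,
                           corp$lengths, config$layers, config$heads,
                           config$batch_size, config$lr, config$dropout,
                           1L, derive_seed(config$seed, "clf-shuffle", ep),
                           adam_t, config$clip,
                           sched[["total"]], sched[["warmup"]])
    adam_t <- res$adam_t
    losses[ep] <- res$loss
  }
  structure(list(params = params, vocab = vocab, config = config,
                 classes = classes, loss = losses),
            class = "veg_habitat_clf")
}

#' @export
print.veg_habitat_clf <- function(x, ...) {
  cat(sprintf("<veg_habitat_clf: %d habitat types, %d layers x %d hidden>\n",
              length(x$classes), x$config$layers, x$config$hidden))
  invisible(x)
}

clf_probs <- function(clf, sentences) {
  corp <- encode_corpus(sentences, clf$vocab, clf$config$max_len)
  logits <- cpp_forward(clf$params, corp$ids, corp$lengths,
                        clf$config$layers, clf$config$heads, 1L,
                        matrix(0L, 1, 1))
  probs <- softmax_rows(logits)
  colnames(probs) <- clf$classes
  probs
}

#' Predict habitat types for sentences
#'
#' @param clf A [fine_tune()] classifier.
#' @param sentences One `veg_sentence` / species vector, or a list of them.
#' @param k Number of ranked candidates per plot.
#' @return For a single sentence, a tibble `code`, `prob` (descending); for
#'   a list, a list of such tibbles. Probabilities sum to 1 over the full
#'   label set before truncation to `k`.
#' @export
predict_habitat <- function(clf, sentences, k = 3) {
  single <- inherits(sentences, "veg_sentence") ||
    is.character(sentences)
  if (single) sentences <- list(sentences)
  probs <- clf_probs(clf, sentences)
  out <- lapply(seq_len(nrow(probs)), function(i) {
    p <- probs[i, ]
    ord <- order(-p, clf$classes, method = "radix")[seq_len(min(k, length(p)))]
    tibble(code = clf$classes[ord], prob = unname(p[ord]))
  })
  if (single) out[[1]] else out
}

#' Classification metrics over ranked habitat predictions
#'
#' Top-1 accuracy scores the first candidate against the true level-3
#' code; top-3 admits any of the first three candidates; group and broad
#' accuracy project the top candidate and the truth to levels 2 and 1.
#' Precision, recall and F1 are computed micro (over plots) and macro
#' (averaged over classes present in the truth).
#'
#' @param truth Character vector of true level-3 codes.
#' @param ranked Character matrix (n x >= 1) of predicted codes, best
#'   first; extra columns beyond the third are ignored for top-3.
#' @return A `veg_metrics` list: `top1`, `top3`, `group`, `broad`,
#'   `precision_micro`, `recall_micro`, `f1_micro`, `precision_macro`,
#'   `recall_macro`, `f1_macro`, `per_class` tibble and `confusion` table.
#' @export
habitat_metrics <- function(truth, ranked) {
  if (is.vector(ranked)) ranked <- matrix(ranked, ncol = 1)
  assert_that(nrow(ranked) == length(truth),
              "prediction/truth size mismatch")
  pt <- parse_eunis(truth)
  p1 <- parse_eunis(ranked[, 1])
  top1 <- mean(ranked[, 1] == truth)
  kk <- min(3, ncol(ranked))
  top3 <- mean(vapply(seq_along(truth), function(i)
    truth[i] %in% ranked[i, seq_len(kk)], logical(1)))
  group <- mean(p1$group == pt$group)
  broad <- mean(p1$broad == pt$broad)
  classes <- sort(unique(truth), method = "radix")
  confusion <- table(truth = factor(truth, levels = classes),
                     pred = factor(ranked[, 1],
                                   levels = sort(unique(c(classes,
                                                          ranked[, 1])))))
  per_class <- dplyr::bind_rows(lapply(classes, function(cl) {
    tp <- sum(truth == cl & ranked[, 1] == cl)
    fp <- sum(truth != cl & ranked[, 1] == cl)
    fn <- sum(truth == cl & ranked[, 1] != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- tp / (tp + fn)
    f1 <- if (!is.na(prec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else 0
    tibble(code = cl, n = tp + fn, precision = prec, recall = rec, f1 = f1)
  }))
  micro <- top1  # single-label: micro precision = recall = accuracy
  structure(list(top1 = top1, top3 = top3, group = group, broad = broad,
                 precision_micro = micro, recall_micro = micro,
                 f1_micro = micro,
                 precision_macro = mean(per_class$precision, na.rm = TRUE),
                 recall_macro = mean(per_class$recall),
                 f1_macro = mean(per_class$f1),
                 per_class = per_class, confusion = confusion,
                 n = length(truth)),
            class = "veg_metrics")
}

#' @export
print.veg_metrics <- function(x, ...) {
  cat(sprintf(paste0("habitat classification over %d plots:\n",
                     "  top-1 %.4f | top-3 %.4f | group %.4f | broad %.4f\n",
                     "  macro F1 %.4f\n"),
              x$n, x$top1, x$top3, x$group, x$broad, x$f1_macro))
  invisible(x)
}

#' Evaluate a classifier on labelled test plots
#'
#' @param clf A [fine_tune()] classifier.
#' @param sentences Test sentences.
#' @param truth True level-3 codes, parallel to `sentences`.
#' @return A [habitat_metrics()] object.
#' @export
evaluate_classifier <- function(clf, sentences, truth) {
  preds <- predict_habitat(clf, sentences, k = 3)
  ranked <- t(vapply(preds, function(p) {
    c(p$code, rep(p$code[1], 3))[1:3]
  }, character(3)))
  habitat_metrics(truth, ranked)
}

#' Classification accuracy after removing one species per plot
#'
#' Quantifies how much each abundance position carries: removes the first
#' (most abundant), the last (least abundant) or a random species from
#' every plot before prediction, and reports top-1 accuracy. `drop =
#' "none"` is the unablated reference.
#'
#' @param clf A [fine_tune()] classifier.
#' @param sentences Test sentences (each with at least 2 species).
#' @param truth True level-3 codes.
#' @param drop One of `"none"`, `"first"`, `"last"`, `"random"`.
#' @param seed Seed for `drop = "random"`.
#' @return Top-1 accuracy after ablation.
#' @export
ablation_eval <- function(clf, sentences, truth,
                          drop = c("none", "first", "last", "random"),
                          seed = 1L) {
  drop <- match.arg(drop)
  ablate <- function(s, i) {
    sp <- if (inherits(s, "veg_sentence")) s$species else s
    if (drop == "none" || length(sp) < 2) return(sp)
    cut <- switch(drop,
                  first = 1L,
                  last = length(sp),
                  random = with_seed(derive_seed(seed, "ablate", i),
                                     sample.int(length(sp), 1)))
    sp[-cut]
  }
  red <- lapply(seq_along(sentences), function(i) ablate(sentences[[i]], i))
  preds <- predict_habitat(clf, red, k = 1)
  mean(vapply(preds, function(p) p$code[1], character(1)) == truth)
}
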