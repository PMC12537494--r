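#' Build a species co-occurrence matrix from training plots
#'
#' Presence-absence semantics: `C[a, b]` counts the plots in which species
#' `a` and `b` were both recorded, regardless of cover; the diagonal holds
#' each species' plot count.
#'
#' @param plots A list of character vectors (species per plot), a list of
#'   `veg_sentence`, or a `veg_plot_table`.
#' @return A `veg_cooccurrence`: list with `C` (symmetric dense matrix with
#'   species dimnames), `n_species` counts (= `diag(C)`) and `n_plots`.
#' @export
build_cooccurrence <- function(plots) {
  plots <- as_species_lists(plots)
  species <- sort(unique(unlist(plots)), method = "radix")
  i <- rep(seq_along(plots), lengths(plots))
  j <- match(unlist(plots), species)
  X <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(plots), length(species)))
  X@x[] <- 1  # guard against duplicated species within a plot
  C <- as.matrix(Matrix::crossprod(X))
  dimnames(C) <- list(species, species)
  structure(list(C = C, n_species = diag(C), n_plots = length(plots)),
            class = "veg_cooccurrence")
}

as_species_lists <- function(plots) {
  if (inherits(plots, "veg_plot_table") || is.data.frame(plots)) {
    idx <- split(seq_len(nrow(plots)),
                 factor(plots$plot_id, levels = unique(plots$plot_id)))
    lapply(idx, function(ii) unique(tolower(plots$taxon[ii])))
  } else {
    lapply(plots, function(p)
      unique(tolower(if (inherits(p, "veg_sentence")) p$species else p)))
  }
}

#' Naive Bayes settings for co-occurrence completion
#'
#' @param alpha Additive smoothing constant (> 0, default 1) applied to the
#'   conditional co-occurrence probabilities.
#' @return A list of class `nb_config`.
#' @export
nb_config <- function(alpha = 1) {
  assert_that(is.numeric(alpha) && alpha > 0, "alpha must be positive")
  structure(list(alpha = alpha), class = "nb_config")
}

#' Rank candidate species for an observed assemblage (naive Bayes)
#'
#' Scores every candidate species `s` not in the observed set by the naive
#' Bayes decomposition over the co-occurrence matrix:
#' `score(s) = log P(s) + sum over observed o of log P(o | s)`, with
#' `P(s) = N_s / sum_t N_t` and
#' `P(o | s) = (C[o, s] + alpha) / (N_s + alpha * V)` where `V` is the
#' number of species in the matrix. Candidates are returned in descending
#' score order with a lexicographic tie-break. Observed species unknown to
#' the matrix are ignored with a warning.
#'
#' @param cooc A [build_cooccurrence()] matrix.
#' @param observed Character vector of observed species.
#' @param config A [nb_config()].
#' @param k Number of candidates to return (default all).
#' @return A tibble `species`, `score` (log scale), best first.
#' @export
nb_predict <- function(cooc, observed, config = nb_config(), k = Inf) {
  observed <- unique(tolower(observed))
  assert_that(length(observed) > 0, "observed set must be non-empty")
  species <- rownames(cooc$C)
  unknown <- setdiff(observed, species)
  if (length(unknown) > 0) {
    warn(paste0("ignoring species unknown to the matrix: ",
                paste(unknown, collapse = ", ")))
    observed <- setdiff(observed, unknown)
  }
  candidates <- setdiff(species, observed)
  if (length(candidates) == 0 || length(observed) == 0)
    return(tibble(species = character(0), score = numeric(0)))
  V <- length(species)
  N <- cooc$n_species
  prior <- log(N[candidates]) - log(sum(N))
  cond <- cooc$C[observed, candidates, drop = FALSE]
  denom <- N[candidates] + config$alpha * V
  loglik <- colSums(log(sweep(cond + config$alpha, 2, denom, "/")))
  score <- prior + loglik
  # scores within 1e-9 count as tied and fall back to the lexicographic
  # tie-break, so the ranking is stable against float association noise
  ord <- order(-round(score, 9), candidates, method = "radix")
  out <- tibble(species = candidates[ord], score = unname(score[ord]))
  head(out, n = if (is.finite(k)) k else nrow(out))
}

#' Train the masked multilayer-perceptron baseline
#'
#' A feedforward network over presence-absence vectors, trained by
#' stochastic gradient descent on the log-loss: each epoch, every training
#' plot with at least two species has one species masked at random; the
#' input is the presence indicator of the remaining species and the target
#' is the masked species. Plots with a single species are skipped.
#'
#' @param plots Training plots (as in [build_cooccurrence()]).
#' @param hidden Hidden layer width (default 64; one hidden layer).
#' @param lr Learning rate for plain SGD.
#' @param epochs Passes over the training plots.
#' @param batch_size Minibatch size.
#' @param seed Seed controlling initialisation and the per-epoch masks.
#' @return A `veg_mlp` predictor.
#' @export
mlp_fillmask_train <- function(plots, hidden = 64, lr = 0.5, epochs = 5,
                               batch_size = 32, seed = 1L) {
  plots <- as_species_lists(plots)
  plots <- plots[lengths(plots) >= 2]
  assert_that(length(plots) > 0, "no trainable plots (need >= 2 species)")
  species <- sort(unique(unlist(plots)), method = "radix")
  V <- length(species)
  idx_lists <- lapply(plots, match, species)
  params <- with_seed(derive_seed(seed, "mlp-init"), list(
    W1 = matrix(rnorm(V * hidden, sd = 0.05), V, hidden),
    b1 = numeric(hidden),
    W2 = matrix(rnorm(hidden * V, sd = 0.05), hidden, V),
    b2 = numeric(V)))
  n <- length(idx_lists)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ep_loss <- 0; n_seen <- 0
    with_seed(derive_seed(seed, "mlp-epoch", ep), {
      ord <- sample.int(n)
      masked_pos <- vapply(idx_lists, function(ii)
        ii[sample.int(length(ii), 1)], integer(1))
      for (start in seq(1, n, by = batch_size)) {
        rows <- ord[start:min(start + batch_size - 1, n)]
        B <- length(rows)
        X <- matrix(0, B, V)
        for (b in seq_len(B)) {
          ii <- idx_lists[[rows[b]]]
          X[b, setdiff(ii, masked_pos[rows[b]])] <- 1
        }
        y <- masked_pos[rows]
        H <- pmax(X %*% params$W1 +
                    matrix(params$b1, B, hidden, byrow = TRUE), 0)
        logits <- H %*% params$W2 +
          matrix(params$b2, B, V, byrow = TRUE)
        logits <- logits - apply(logits, 1, max)
        P <- exp(logits) / rowSums(exp(logits))
        ep_loss <- ep_loss - sum(log(P[cbind(seq_len(B), y)] + 1e-12))
        n_seen <- n_seen + B
        dL <- P
        dL[cbind(seq_len(B), y)] <- dL[cbind(seq_len(B), y)] - 1
        dL <- dL / B
        dW2 <- crossprod(H, dL)
        db2 <- colSums(dL)
        dH <- dL %*% t(params$W2) * (H > 0)
        dW1 <- crossprod(X, dH)
        db1 <- colSums(dH)
        params$W1 <- params$W1 - lr * dW1
        params$b1 <- params$b1 - lr * db1
        params$W2 <- params$W2 - lr * dW2
        params$b2 <- params$b2 - lr * db2
      }
    })
    losses[ep] <- ep_loss / n_seen
  }
  structure(list(species = species, params = params, loss = losses,
                 hidden = hidden, seed = seed),
            class = "veg_mlp")
}

#' Rank candidate species with the trained MLP baseline
#'
#' @param predictor A [mlp_fillmask_train()] model.
#' @param observed Character vector of observed species.
#' @param k Number of candidates (default all).
#' @return A tibble `species`, `prob`, best first; observed species are
#'   excluded from the candidates.
#' @export
mlp_fillmask_predict <- function(predictor, observed, k = Inf) {
  observed <- unique(tolower(observed))
  x <- numeric(length(predictor$species))
  x[match(intersect(observed, predictor$species), predictor$species)] <- 1
  p <- predictor$params
  h <- pmax(drop(x %*% p$W1) + p$b1, 0)
  logits <- drop(h %*% p$W2) + p$b2
  logits <- logits - max(logits)
  prob <- exp(logits) / sum(exp(logits))
  names(prob) <- predictor$species
  keep <- setdiff(predictor$species, observed)
  prob <- prob[keep]
  ord <- order(-prob, keep, method = "radix")
  out <- tibble(species = keep[ord], prob = unname(prob[ord]))
  head(out, n = if (is.finite(k)) k else nrow(out))
}

#' Wrap a co-occurrence matrix as a fill-mask predictor
#' @param cooc A [build_cooccurrence()] matrix.
#' @param config A [nb_config()].
#' @return A `veg_nb` predictor usable with [fill_blank()] and
#'   [rank_masking_eval()].
#' @export
nb_predictor <- function(cooc, config = nb_config()) {
  structure(list(cooc = cooc, config = config), class = "veg_nb")
}

#' Predict the species hidden at a masked slot
#'
#' Shared predictor contract for the fill-mask evaluation: `context` is the
#' abundance-ordered species list with `NA` at the masked position(s). The
#' encoder model uses the full ordered context; the co-occurrence and MLP
#' baselines use the observed species set only.
#'
#' @param predictor A `veg_mlm`, `veg_nb` or `veg_mlp` object.
#' @param context Character vector with `NA` at the masked slot.
#' @param k Number of ranked candidates to return.
#' @param ... Passed to methods.
#' @return A tibble with a `species` column (best first) and a score or
#'   probability column.
#' @export
fill_blank <- function(predictor, context, k = 1, ...) {
  UseMethod("fill_blank")
}

#' @export
fill_blank.function <- function(predictor, context, k = 1, ...) {
  predictor(context, k, ...)
}

#' @export
fill_blank.veg_nb <- function(predictor, context, k = 1, ...) {
  obs <- context[!is.na(context)]
  out <- nb_predict(predictor$cooc, obs, predictor$config, k = k)
  out
}

#' @export
fill_blank.veg_mlp <- function(predictor, context, k = 1, ...) {
  obs <- context[!is.na(context)]
  mlp_fillmask_predict(predictor, obs, k = k)
}
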