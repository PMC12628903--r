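#' Training configuration
#'
#' Optimization protocol defaults: minibatch size 64, 10 epochs, Adam at
#' learning rate 0.001, binary cross-entropy loss, early stopping on
#' validation loss with patience 3.
#'
#' @param batch_size Minibatch size (>= 1).
#' @param epochs Maximum epochs (>= 1).
#' @param learning_rate Adam step size (> 0; 0 is allowed for no-op
#'   training in diagnostics).
#' @param patience Early-stopping epochs without validation improvement.
#' @param threshold Decision threshold for thresholded metrics.
#' @param seed Integer seed driving shuffling and dropout.
#' @return A `train_config` object.
#' @export
train_config <- function(batch_size = 64L, epochs = 10L, learning_rate = 0.001,
                         patience = 3L, threshold = 0.5, seed = 42L) {
  if (batch_size < 1L || epochs < 1L || patience < 1L) {
    stop_ppifusion("batch_size, epochs and patience must be >= 1",
                   "ppifusion_config_error")
  }
  if (learning_rate < 0) {
    stop_ppifusion("learning_rate must be >= 0", "ppifusion_config_error")
  }
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 optimizer = "adam", loss = "bce",
                 patience = as.integer(patience),
                 threshold = threshold,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Binary cross-entropy loss
#'
#' Mean over samples of `-(y log p + (1-y) log(1-p))` with probabilities
#' clipped to `[1e-7, 1 - 1e-7]`.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary labels (0/1) of equal length.
#' @export
bce_loss <- function(probs, labels) {
  if (length(probs) != length(labels)) {
    stop_ppifusion("probs and labels must have equal length",
                   "ppifusion_validation_error")
  }
  eps <- 1e-7
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# ---- Adam -------------------------------------------------------------------

# The optimizer state (and the trained parameter set) is deep-copied at
# adam_init so the C++ kernel may update all three tensors in place.
deep_copy <- function(x) {
  if (is.list(x)) lapply(x, deep_copy) else x + 0
}

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

# Updates params/state in place (both must be uniquely referenced).
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  tt <- state$t
  walk <- function(p, g, m, v) {
    keys <- if (is.null(names(p))) seq_along(p) else names(p)
    for (i in seq_along(p)) {
      k <- keys[[i]]
      gi <- if (is.character(k) && !is.null(names(g))) g[[k]] else g[[i]]
      if (is.null(gi)) next
      if (is.list(p[[i]])) {
        walk(p[[i]], gi, m[[i]], v[[i]])
      } else {
        .adam_update_inplace(p[[i]], gi, m[[i]], v[[i]], lr, beta1, beta2,
                             eps, tt)
      }
    }
  }
  walk(params, grads, state$m, state$v)
  list(params = params, state = state)
}

# ---- dataset plumbing -------------------------------------------------------

# Build aligned feature matrices for a pair table from a named feature list.
pair_feature_matrices <- function(pairs, features) {
  missing <- setdiff(unique(c(pairs$protein_a, pairs$protein_b)), names(features))
  if (length(missing) > 0L) {
    stop_ppifusion(sprintf("missing embeddings for: %s",
                           paste(missing, collapse = ", ")),
                   "ppifusion_missing_embedding_error")
  }
  X1 <- do.call(rbind, features[pairs$protein_a])
  X2 <- do.call(rbind, features[pairs$protein_b])
  list(X1 = X1, X2 = X2, y = as.numeric(pairs$label))
}

# Restrict feature vectors to the embedding-profile slice of the fused
# layout [ankh (1536) ; esm (1280)]. Toy input dims pass through unchanged.
slice_features <- function(features, embeddings, input_dim) {
  full <- length(features[[1L]])
  if (embeddings == "fused" || full == input_dim) return(features)
  if (full != FUSED_DIM) {
    stop_ppifusion(sprintf(
      "cannot take the %s slice: feature length %d is not the fused %d",
      embeddings, full, FUSED_DIM), "ppifusion_validation_error")
  }
  idx <- if (embeddings == "ankh") seq_len(ANKH_DIM) else ANKH_DIM + seq_len(ESM2_DIM)
  lapply(features, function(v) v[idx])
}

# ---- training loop ----------------------------------------------------------

#' Train the pair classifier
#'
#' Minibatch gradient descent with Adam (beta1 0.9, beta2 0.999, eps
#' 1e-8) on binary cross-entropy. Shuffling and dropout are driven by
#' `cfg$seed`; training stops when `cfg$patience` epochs pass without
#' validation-loss improvement or the epoch budget is exhausted, and the
#' weights from the best epoch are returned.
#'
#' @param model An initialized `mpidnn_model`.
#' @param dataset List with `pairs` (labeled-pair data.frame) and
#'   `features` (named list of per-protein vectors), e.g. from
#'   [make_planted_embeddings()].
#' @param split List with `train` and `validation` pair data.frames
#'   (see [make_splits()]).
#' @param cfg A [train_config()].
#' @return List with `model` (best weights), `history` (per-epoch
#'   data.frame: train_loss, val_loss, val_auc), `best_epoch`,
#'   `stopped_early`.
#' @export
train_model <- function(model, dataset, split, cfg = train_config()) {
  features <- slice_features(dataset$features, model$config$embeddings,
                             model$config$input_dim)
  tr <- pair_feature_matrices(split$train, features)
  va <- pair_feature_matrices(split$validation, features)
  if (any(!is.finite(tr$X1)) || any(!is.finite(tr$X2))) {
    stop_ppifusion("non-finite training features", "ppifusion_validation_error")
  }
  n <- nrow(tr$X1)
  params <- deep_copy(model$params)  # adam_step mutates in place
  state <- adam_init(params)
  h_train <- numeric(0); h_val <- numeric(0); h_auc <- numeric(0)
  best_loss <- Inf; best_params <- deep_copy(params); best_epoch <- 0L
  bad_epochs <- 0L; stopped_early <- FALSE
  with_local_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
        m <- structure(list(config = model$config, params = params),
                       class = "mpidnn_model")
        fw <- model_forward(m, tr$X1[idx, , drop = FALSE],
                            tr$X2[idx, , drop = FALSE],
                            training = TRUE, want_cache = TRUE)
        loss <- bce_loss(fw$prob, tr$y[idx])
        if (!is.finite(loss)) {
          stop_ppifusion(sprintf(
            "NaN loss at epoch %d, batch starting %d (lr %g)", epoch, s,
            cfg$learning_rate), "ppifusion_numerical_error")
        }
        epoch_loss <- epoch_loss + loss * length(idx)
        dlogit <- (fw$prob - tr$y[idx]) / length(idx)
        grads <- model_backward(m, fw$cache, dlogit)
        st <- adam_step(params, grads, state, cfg$learning_rate)
        params <- st$params; state <- st$state
      }
      m <- structure(list(config = model$config, params = params),
                     class = "mpidnn_model")
      val_prob <- model_forward(m, va$X1, va$X2, training = FALSE)$prob
      val_loss <- bce_loss(val_prob, va$y)
      val_auc <- if (length(unique(va$y)) < 2L) NA_real_ else auroc(val_prob, va$y)
      h_train <- c(h_train, epoch_loss / n)
      h_val <- c(h_val, val_loss)
      h_auc <- c(h_auc, val_auc)
      if (val_loss < best_loss) {
        best_loss <- val_loss; best_params <- deep_copy(params); best_epoch <- epoch
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= cfg$patience) {
          stopped_early <- TRUE
          break
        }
      }
    }
  })
  history <- data.frame(epoch = seq_along(h_train), train_loss = h_train,
                        val_loss = h_val, val_auc = h_auc)
  list(model = structure(list(config = model$config, params = best_params),
                         class = "mpidnn_model"),
       history = history, best_epoch = best_epoch,
       stopped_early = stopped_early)
}

#' k-fold cross-validation
#'
#' Pairs are shuffled by `cfg$seed` and partitioned into `k` folds; each
#' fold in turn is the held-out test set while a fresh model (seed
#' `model_cfg$seed + fold`) is trained on the rest. Early stopping uses
#' an internal 90:10 split of the training folds, never the test fold.
#' Per-fold metrics and mean/sd aggregates are returned in the
#' value-plus-spread style used for cross-validated reporting.
#'
#' @param dataset List with `pairs` and `features`.
#' @param k Number of folds (>= 2), default 5.
#' @param cfg A [train_config()].
#' @param model_cfg A [model_config()].
#' @return List with `reports` (per fold), `summary` (data.frame of
#'   metric, mean, sd), `folds`.
#' @export
cross_validate <- function(dataset, k = 5L, cfg = train_config(),
                           model_cfg = model_config()) {
  pairs <- dataset$pairs
  n <- nrow(pairs)
  if (k < 2L || n < k) {
    stop_ppifusion("need k >= 2 and at least k pairs", "ppifusion_config_error")
  }
  perm <- with_local_seed(cfg$seed, sample.int(n))
  folds <- lapply(assign_folds(n, k), function(ix) perm[ix])
  reports <- vector("list", k)
  for (i in seq_len(k)) {
    test_pairs <- pairs[folds[[i]], , drop = FALSE]
    pool <- pairs[unlist(folds[-i]), , drop = FALSE]
    inner <- make_splits(pool, val_fraction = 0.1, k = 2L,
                         seed = cfg$seed + i)
    fold_model_cfg <- model_cfg
    fold_model_cfg$seed <- model_cfg$seed + i
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + i
    fit <- train_model(init_model(fold_model_cfg), dataset,
                       inner[c("train", "validation")], fold_cfg)
    features <- slice_features(dataset$features, model_cfg$embeddings,
                               model_cfg$input_dim)
    te <- pair_feature_matrices(test_pairs, features)
    prob <- model_forward(fit$model, te$X1, te$X2, training = FALSE)$prob
    reports[[i]] <- metrics_report(prob, te$y, threshold = cfg$threshold)
  }
  metric_names <- c("sensitivity", "precision", "f1", "mcc", "aupr", "auc")
  vals <- sapply(metric_names, function(mn)
    vapply(reports, function(r) r[[mn]], numeric(1)))
  summary <- data.frame(metric = metric_names,
                        mean = apply(vals, 2L, mean, na.rm = TRUE),
                        sd = apply(vals, 2L, stats::sd, na.rm = TRUE),
                        row.names = NULL)
  list(reports = reports, summary = summary, folds = folds)
}
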