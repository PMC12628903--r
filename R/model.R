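#' Model configuration
#'
#' Architecture switches and sizes for the pair classifier. The input
#' dimension follows the embedding profile: 2816 for the fused
#' (Ankh+ESM-2) vectors, 1536 for Ankh only, 1280 for ESM-2 only, unless
#' overridden (toy tests use small dims).
#'
#' Defaults: extractor width 512, prediction head widths 512/256/64/1,
#' dropout 0.1, 4 attention heads. With the default extractor the fused
#' pair representation `F = [F1 (2x512); F2 (512)]` is 1536-wide.
#'
#' @param embeddings `"fused"`, `"ankh"` or `"esm2"`; sets `input_dim`.
#' @param input_dim Optional explicit input dimension.
#' @param extractor_dim Width of the shared-weight extraction layer.
#' @param head_layers Widths of the prediction head; last must be 1.
#' @param n_heads Heads of the multi-head attention block (MDNN profile).
#' @param dropout_rate Dropout probability in \[0, 1).
#' @param use_multihead `TRUE` for the MDNN profile (multi-head attention
#'   block over the pair-feature tokens before the first hidden layer),
#'   `FALSE` for the plain DNN profile.
#' @param seed Integer seed for weight initialization.
#' @return A `model_config` object.
#' @export
model_config <- function(embeddings = c("fused", "ankh", "esm2"),
                         input_dim = NULL,
                         extractor_dim = 512L,
                         head_layers = c(512L, 256L, 64L, 1L),
                         n_heads = 4L,
                         dropout_rate = 0.1,
                         use_multihead = TRUE,
                         seed = 42L) {
  embeddings <- match.arg(embeddings)
  if (is.null(input_dim)) {
    input_dim <- switch(embeddings, fused = FUSED_DIM, ankh = ANKH_DIM,
                        esm2 = ESM2_DIM)
  }
  if (length(head_layers) < 1L || head_layers[length(head_layers)] != 1L) {
    stop_ppifusion("head_layers must end in a single output unit",
                   "ppifusion_config_error")
  }
  if (!(dropout_rate >= 0 && dropout_rate < 1)) {
    stop_ppifusion("dropout_rate must be in [0, 1)", "ppifusion_config_error")
  }
  if (use_multihead && extractor_dim %% n_heads != 0L) {
    stop_ppifusion(sprintf("n_heads = %d must divide extractor_dim = %d",
                           n_heads, extractor_dim), "ppifusion_config_error")
  }
  structure(list(embeddings = embeddings, input_dim = as.integer(input_dim),
                 extractor_dim = as.integer(extractor_dim),
                 head_layers = as.integer(head_layers),
                 n_heads = as.integer(n_heads),
                 dropout_rate = dropout_rate,
                 use_multihead = isTRUE(use_multihead),
                 seed = as.integer(seed)),
            class = "model_config")
}

init_matrix <- function(nr, nc) {
  s <- 1 / sqrt(nr)
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

#' Initialize model weights
#'
#' Uniform initialization scaled by `1/sqrt(fan_in)`, driven entirely by
#' `config$seed`; biases start at zero.
#'
#' @param config A [model_config()].
#' @return An `mpidnn_model`: list with `config` and `params`.
#' @export
init_model <- function(config) {
  d <- config$extractor_dim
  params <- with_local_seed(config$seed, {
    p <- list(ex_W = init_matrix(config$input_dim, d), ex_b = numeric(d),
              fus_Wq = init_matrix(d, d), fus_Wk = init_matrix(d, d),
              fus_Wv = init_matrix(d, d))
    if (config$use_multihead) {
      p$ha_Wq <- init_matrix(d, d); p$ha_Wk <- init_matrix(d, d)
      p$ha_Wv <- init_matrix(d, d); p$ha_Wo <- init_matrix(d, d)
      p$ha_bo <- numeric(d)
    }
    widths <- c(3L * d, config$head_layers)
    p$mlp_W <- vector("list", length(config$head_layers))
    p$mlp_b <- vector("list", length(config$head_layers))
    for (l in seq_along(config$head_layers)) {
      p$mlp_W[[l]] <- init_matrix(widths[l], widths[l + 1L])
      p$mlp_b[[l]] <- numeric(widths[l + 1L])
    }
    p
  })
  structure(list(config = config, params = params), class = "mpidnn_model")
}

# ---- batched multi-head attention (internal) --------------------------------

add_bias <- function(A, b) A + rep(b, each = nrow(A))

# tokens: list of T matrices (B x d_model). Wq/Wk/Wv: d_model x d_attn with
# columns partitioned among heads; optional output projection Wo (d_attn x d).
bmha_forward <- function(tokens, Wq, Wk, Wv, n_heads, Wo = NULL, bo = NULL) {
  Tn <- length(tokens)
  B <- nrow(tokens[[1L]])
  d_attn <- ncol(Wq)
  dk <- d_attn / n_heads
  # one dgemm per projection over all tokens, then split by token
  XX <- do.call(rbind, tokens)
  rows <- lapply(seq_len(Tn), function(t) (t - 1L) * B + seq_len(B))
  split_rows <- function(M) lapply(rows, function(r) M[r, , drop = FALSE])
  Q <- split_rows(XX %*% Wq)
  K <- split_rows(XX %*% Wk)
  V <- split_rows(XX %*% Wv)
  A <- vector("list", n_heads)   # per head: list over t of B x T weight rows
  O <- lapply(seq_len(Tn), function(t) matrix(0, B, d_attn))
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    A[[h]] <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      S <- vapply(seq_len(Tn), function(u)
        rowSums(Q[[t]][, idx, drop = FALSE] * K[[u]][, idx, drop = FALSE]),
        numeric(B)) / sqrt(dk)
      if (B == 1L) S <- matrix(S, nrow = 1L)
      At <- softmax_rows(S)
      A[[h]][[t]] <- At
      acc <- matrix(0, B, dk)
      for (u in seq_len(Tn)) {
        acc <- acc + At[, u] * V[[u]][, idx, drop = FALSE]
      }
      O[[t]][, idx] <- acc
    }
  }
  out <- if (is.null(Wo)) O else lapply(O, function(Ot) add_bias(Ot %*% Wo, bo))
  list(out = out, cache = list(tokens = tokens, Q = Q, K = K, V = V, A = A,
                               O = O, Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo,
                               n_heads = n_heads, dk = dk))
}

bmha_backward <- function(cache, dout) {
  tokens <- cache$tokens; Q <- cache$Q; K <- cache$K; V <- cache$V
  A <- cache$A; O <- cache$O
  Tn <- length(tokens); B <- nrow(tokens[[1L]])
  dk <- cache$dk; n_heads <- cache$n_heads
  d_attn <- ncol(cache$Wq)
  if (!is.null(cache$Wo)) {
    dWo <- matrix(0, nrow(cache$Wo), ncol(cache$Wo))
    dbo <- numeric(ncol(cache$Wo))
    dO <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      dWo <- dWo + crossprod(O[[t]], dout[[t]])
      dbo <- dbo + colSums(dout[[t]])
      dO[[t]] <- tcrossprod(dout[[t]], cache$Wo)
    }
  } else {
    dWo <- NULL; dbo <- NULL; dO <- dout
  }
  dQ <- lapply(seq_len(Tn), function(t) matrix(0, B, d_attn))
  dK <- lapply(seq_len(Tn), function(t) matrix(0, B, d_attn))
  dV <- lapply(seq_len(Tn), function(t) matrix(0, B, d_attn))
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    for (t in seq_len(Tn)) {
      dOh <- dO[[t]][, idx, drop = FALSE]
      At <- A[[h]][[t]]
      dA <- vapply(seq_len(Tn), function(u)
        rowSums(dOh * V[[u]][, idx, drop = FALSE]), numeric(B))
      if (B == 1L) dA <- matrix(dA, nrow = 1L)
      for (u in seq_len(Tn)) {
        dV[[u]][, idx] <- dV[[u]][, idx, drop = FALSE] + At[, u] * dOh
      }
      dS <- At * (dA - rowSums(At * dA))
      for (u in seq_len(Tn)) {
        su <- dS[, u] / sqrt(dk)
        dQ[[t]][, idx] <- dQ[[t]][, idx, drop = FALSE] +
          su * K[[u]][, idx, drop = FALSE]
        dK[[u]][, idx] <- dK[[u]][, idx, drop = FALSE] +
          su * Q[[t]][, idx, drop = FALSE]
      }
    }
  }
  XX <- do.call(rbind, tokens)
  dQa <- do.call(rbind, dQ); dKa <- do.call(rbind, dK); dVa <- do.call(rbind, dV)
  dWq <- crossprod(XX, dQa)
  dWk <- crossprod(XX, dKa)
  dWv <- crossprod(XX, dVa)
  dtok_all <- tcrossprod(dQa, cache$Wq) + tcrossprod(dKa, cache$Wk) +
    tcrossprod(dVa, cache$Wv)
  dtokens <- lapply(seq_len(Tn), function(t)
    dtok_all[(t - 1L) * B + seq_len(B), , drop = FALSE])
  list(dtokens = dtokens, dWq = dWq, dWk = dWk, dWv = dWv,
       dWo = dWo, dbo = dbo)
}

# ---- full forward / backward ------------------------------------------------

dropout_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

apply_mask <- function(X, M) if (is.null(M)) X else X * M

# X1, X2: B x input_dim matrices of pair features. Dropout masks are drawn
# from the current RNG stream when training = TRUE; callers own seeding.
model_forward <- function(model, X1, X2, training = FALSE, want_cache = FALSE) {
  p <- model$params; cfg <- model$config
  B <- nrow(X1)
  rate <- if (training) cfg$dropout_rate else 0
  AA <- add_bias(rbind(X1, X2) %*% p$ex_W, p$ex_b)
  A1 <- AA[seq_len(B), , drop = FALSE]
  A2 <- AA[B + seq_len(B), , drop = FALSE]
  R1 <- pmax(A1, 0); R2 <- pmax(A2, 0)
  M1 <- dropout_mask(B, ncol(R1), rate); M2 <- dropout_mask(B, ncol(R2), rate)
  H1 <- apply_mask(R1, M1); H2 <- apply_mask(R2, M2)
  fus <- bmha_forward(list(H1, H2), p$fus_Wq, p$fus_Wk, p$fus_Wv, n_heads = 1L)
  O1 <- fus$out[[1L]]; O2 <- fus$out[[2L]]
  F2 <- (H1 + H2) / 2
  if (cfg$use_multihead) {
    ha <- bmha_forward(list(O1, O2, F2), p$ha_Wq, p$ha_Wk, p$ha_Wv,
                       n_heads = cfg$n_heads, Wo = p$ha_Wo, bo = p$ha_bo)
    Z1 <- O1 + ha$out[[1L]]; Z2 <- O2 + ha$out[[2L]]; Z3 <- F2 + ha$out[[3L]]
    Z <- cbind(Z1, Z2, Z3)
  } else {
    ha <- NULL
    Z <- cbind(O1, O2, F2)
  }
  L <- length(p$mlp_W)
  acts <- vector("list", L); masks <- vector("list", L); pre <- vector("list", L)
  cur <- Z
  for (l in seq_len(L)) {
    acts[[l]] <- cur
    zl <- add_bias(cur %*% p$mlp_W[[l]], p$mlp_b[[l]])
    if (l < L) {
      pre[[l]] <- zl
      rl <- pmax(zl, 0)
      masks[l] <- list(dropout_mask(B, ncol(rl), rate))
      cur <- apply_mask(rl, masks[[l]])
    } else {
      cur <- zl
    }
  }
  logit <- as.vector(cur)
  prob <- stats::plogis(logit)
  res <- list(prob = prob, logit = logit)
  if (want_cache) {
    res$cache <- list(X1 = X1, X2 = X2, A1 = A1, A2 = A2, M1 = M1, M2 = M2,
                      H1 = H1, H2 = H2, fus = fus$cache, ha = ha$cache,
                      O1 = O1, O2 = O2, F2 = F2, acts = acts, pre = pre,
                      masks = masks, B = B)
  }
  res
}

# dlogit: numeric vector of length B (dLoss/dlogit). Returns gradient list
# mirroring model$params.
model_backward <- function(model, cache, dlogit) {
  p <- model$params; cfg <- model$config
  L <- length(p$mlp_W)
  d <- cfg$extractor_dim
  g <- list(mlp_W = vector("list", L), mlp_b = vector("list", L))
  dcur <- matrix(dlogit, ncol = 1L)
  for (l in rev(seq_len(L))) {
    g$mlp_W[[l]] <- crossprod(cache$acts[[l]], dcur)
    g$mlp_b[[l]] <- colSums(dcur)
    dprev <- tcrossprod(dcur, p$mlp_W[[l]])
    if (l > 1L) {
      lm <- l - 1L
      dprev <- apply_mask(dprev, cache$masks[[lm]]) * (cache$pre[[lm]] > 0)
    }
    dcur <- dprev
  }
  dZ <- dcur
  dZ1 <- dZ[, 1:d, drop = FALSE]
  dZ2 <- dZ[, (d + 1L):(2L * d), drop = FALSE]
  dZ3 <- dZ[, (2L * d + 1L):(3L * d), drop = FALSE]
  if (cfg$use_multihead) {
    hab <- bmha_backward(cache$ha, list(dZ1, dZ2, dZ3))
    dO1 <- dZ1 + hab$dtokens[[1L]]
    dO2 <- dZ2 + hab$dtokens[[2L]]
    dF2 <- dZ3 + hab$dtokens[[3L]]
    g$ha_Wq <- hab$dWq; g$ha_Wk <- hab$dWk; g$ha_Wv <- hab$dWv
    g$ha_Wo <- hab$dWo; g$ha_bo <- hab$dbo
  } else {
    dO1 <- dZ1; dO2 <- dZ2; dF2 <- dZ3
  }
  fub <- bmha_backward(cache$fus, list(dO1, dO2))
  g$fus_Wq <- fub$dWq; g$fus_Wk <- fub$dWk; g$fus_Wv <- fub$dWv
  dH1 <- fub$dtokens[[1L]] + dF2 / 2
  dH2 <- fub$dtokens[[2L]] + dF2 / 2
  dA1 <- apply_mask(dH1, cache$M1) * (cache$A1 > 0)
  dA2 <- apply_mask(dH2, cache$M2) * (cache$A2 > 0)
  g$ex_W <- crossprod(cache$X1, dA1) + crossprod(cache$X2, dA2)
  g$ex_b <- colSums(dA1) + colSums(dA2)
  g
}

#' Predict interaction probabilities for feature-vector pairs
#'
#' Deterministic (evaluation-mode) forward pass of the trained model.
#'
#' @param model An `mpidnn_model`.
#' @param X1,X2 Matrices (pairs x input_dim) of per-protein feature
#'   vectors, rows aligned.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
model_predict <- function(model, X1, X2) {
  if (!is.matrix(X1)) X1 <- matrix(X1, nrow = 1L)
  if (!is.matrix(X2)) X2 <- matrix(X2, nrow = 1L)
  if (ncol(X1) != model$config$input_dim || ncol(X2) != model$config$input_dim) {
    stop_ppifusion(sprintf("feature dim %d does not match model input_dim %d",
                           ncol(X1), model$config$input_dim),
                   "ppifusion_validation_error")
  }
  model_forward(model, X1, X2, training = FALSE)$prob
}

# ---- functional single-pair operations --------------------------------------

#' Shared-weight feature extraction for one vector
#'
#' `dropout(relu(W v + b))`; with dropout inactive the dropout step is the
#' identity. The same parameter set serves both proteins of a pair.
#'
#' @param v Numeric input vector.
#' @param params List with `W` (input_dim x output_dim) and `b`.
#' @param dropout_active Draw an inverted-dropout mask from the current
#'   RNG stream (training behaviour).
#' @param dropout_rate Dropout probability.
#' @return Numeric extracted feature vector.
#' @export
feature_extract <- function(v, params, dropout_active = FALSE, dropout_rate = 0.3) {
  if (length(v) != nrow(params$W)) {
    stop_ppifusion(sprintf("input length %d does not match W rows %d",
                           length(v), nrow(params$W)),
                   "ppifusion_validation_error")
  }
  out <- pmax(as.vector(v %*% params$W) + params$b, 0)
  if (dropout_active && dropout_rate > 0) {
    out <- out * ((stats::runif(length(out)) >= dropout_rate) / (1 - dropout_rate))
  }
  out
}

#' Fuse the extracted features of a protein pair
#'
#' The two extracted vectors are stacked as a 2-token sequence and passed
#' through scaled dot-product self-attention; the flattened attention
#' output is the fusion vector `F1`. The element-wise mean of the two
#' vectors is `F2` (order-invariant). The overall representation is the
#' concatenation `F = [F1; F2]`.
#'
#' @param f1,f2 Extracted feature vectors of equal length.
#' @param params An [attention_params()] for the fusion attention.
#' @return A `fusion_output`: list with `f1_vec`, `f2_vec`, `F1`, `F2`, `F`.
#' @export
fuse_pair <- function(f1, f2, params) {
  if (length(f1) != length(f2)) {
    stop_ppifusion("f1 and f2 must have equal length", "ppifusion_validation_error")
  }
  sa <- self_attention(rbind(f1, f2), params)
  F1 <- c(sa$output[1L, ], sa$output[2L, ])
  F2 <- (f1 + f2) / 2
  structure(list(f1_vec = f1, f2_vec = f2, F1 = F1, F2 = F2, F = c(F1, F2),
                 weights = sa$weights),
            class = "fusion_output")
}

#' Deep prediction head on a fused pair representation
#'
#' Fully connected layers with ReLU and dropout, ending in a single
#' sigmoid unit that returns the interaction probability.
#'
#' @param f Fused feature vector.
#' @param head List with `layers` (each a list `W`, `b`; last layer is the
#'   single logit unit) and optional `dropout_rate` (default 0.3).
#' @param dropout_active Training-mode dropout flag.
#' @return Probability strictly in (0, 1).
#' @export
predict_pair <- function(f, head, dropout_active = FALSE) {
  rate <- if (is.null(head$dropout_rate)) 0.3 else head$dropout_rate
  layers <- head$layers
  cur <- f
  for (l in seq_along(layers)) {
    if (length(cur) != nrow(layers[[l]]$W)) {
      stop_ppifusion(sprintf("layer %d: input length %d does not match W rows %d",
                             l, length(cur), nrow(layers[[l]]$W)),
                     "ppifusion_validation_error")
    }
    cur <- as.vector(cur %*% layers[[l]]$W) + layers[[l]]$b
    if (any(!is.finite(cur))) {
      stop_ppifusion(sprintf("non-finite intermediate at layer %d", l),
                     "ppifusion_numerical_error")
    }
    if (l < length(layers)) {
      cur <- pmax(cur, 0)
      if (dropout_active && rate > 0) {
        cur <- cur * ((stats::runif(length(cur)) >= rate) / (1 - rate))
      }
    }
  }
  stats::plogis(cur)
}
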