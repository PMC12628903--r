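# Independent reference implementations used as oracles. These are
# deliberately written in a different style (explicit loops, recursive
# DP) from the package code paths they check.

# Global alignment identity: recursive Needleman-Wunsch with memoisation,
# match +1 / mismatch 0 / linear gap -1, counting matches along the
# optimal path with the same tie preference (diagonal, then gap in s2).
nw_ref <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(NA_real_, n + 1, m + 1)
  H[1, ] <- -(0:m)
  H[, 1] <- -(0:n)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      H[i + 1, j + 1] <- max(H[i, j] + (a[i] == b[j]),
                             H[i, j + 1] - 1,
                             H[i + 1, j] - 1)
    }
  }
  i <- n; j <- m; matches <- 0
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && H[i + 1, j + 1] == H[i, j] + (a[i] == b[j])) {
      matches <- matches + (a[i] == b[j])
      i <- i - 1; j <- j - 1
    } else if (i > 0 && H[i + 1, j + 1] == H[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  list(score = H[n + 1, m + 1], identity = matches / min(n, m))
}

# Scaled dot-product attention evaluated with explicit scalar loops.
attention_ref <- function(x, wq, wk, wv) {
  dk <- ncol(wq)
  Tn <- nrow(x)
  q <- matrix(0, Tn, dk); k <- matrix(0, Tn, dk); v <- matrix(0, Tn, dk)
  for (t in 1:Tn) for (j in 1:dk) {
    q[t, j] <- sum(x[t, ] * wq[, j])
    k[t, j] <- sum(x[t, ] * wk[, j])
    v[t, j] <- sum(x[t, ] * wv[, j])
  }
  w <- matrix(0, Tn, Tn)
  for (t in 1:Tn) {
    s <- numeric(Tn)
    for (u in 1:Tn) s[u] <- sum(q[t, ] * k[u, ]) / sqrt(dk)
    e <- exp(s - max(s))
    w[t, ] <- e / sum(e)
  }
  out <- matrix(0, Tn, dk)
  for (t in 1:Tn) for (j in 1:dk) out[t, j] <- sum(w[t, ] * v[, j])
  list(output = out, weights = w)
}

confusion_ref <- function(probs, labels, threshold = 0.5) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(probs)) {
    pred <- probs[i] >= threshold
    if (pred && labels[i] == 1) tp <- tp + 1L
    else if (pred && labels[i] == 0) fp <- fp + 1L
    else if (!pred && labels[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# AUC by exhaustive pair enumeration (concordant + half ties).
auroc_ref <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Average precision by an explicit rank walk (stable descending order).
aupr_ref <- function(probs, labels) {
  ord <- order(-probs)
  y <- labels[ord]
  tp <- 0; s <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1) {
      tp <- tp + 1
      s <- s + tp / i
    }
  }
  s / sum(labels == 1)
}

bce_ref <- function(probs, labels) {
  eps <- 1e-7
  total <- 0
  for (i in seq_along(probs)) {
    p <- min(max(probs[i], eps), 1 - eps)
    total <- total + -(labels[i] * log(p) + (1 - labels[i]) * log(1 - p))
  }
  total / length(probs)
}

protein <- function(id, seq) {
  list(protein_id = id, sequence = seq, length = nchar(seq))
}

protein_df <- function(...) {
  ps <- list(...)
  data.frame(protein_id = vapply(ps, `[[`, "", "protein_id"),
             sequence = vapply(ps, `[[`, "", "sequence"),
             length = vapply(ps, function(p) nchar(p$sequence), 1L),
             stringsAsFactors = FALSE)
}

random_seq <- function(n, alphabet = c("A","C","D","E","F","G","H","I","K","L",
                                       "M","N","P","Q","R","S","T","V","W","Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

pair_df <- function(a, b, label = NULL, score = NULL) {
  d <- data.frame(protein_a = a, protein_b = b, stringsAsFactors = FALSE)
  if (!is.null(label)) d$label <- as.integer(label)
  if (!is.null(score)) d$score <- score
  d
}

# small planted dataset + model configuration used by several training tests
small_planted <- function(seed = 42L, noise_sd = 0.25) {
  make_planted_embeddings(n_proteins = 60L, latent_dim = 4L, n_pos = 60L,
                          n_neg = 300L, noise_sd = noise_sd,
                          feature_dim = 64L, seed = seed)
}

small_model_cfg <- function(seed = 42L, use_multihead = TRUE) {
  model_config(input_dim = 64L, extractor_dim = 32L,
               head_layers = c(32L, 16L, 1L), n_heads = 4L,
               use_multihead = use_multihead, seed = seed)
}
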