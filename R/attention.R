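#' Attention projection parameters
#'
#' Bundles the query/key/value projection matrices of one scaled
#' dot-product attention head. All three map the model dimension (rows)
#' to the key dimension `d_k` (columns).
#'
#' @param w_q,w_k,w_v Numeric projection matrices with equal dimensions.
#' @return An `attention_params` object.
#' @export
attention_params <- function(w_q, w_k, w_v) {
  dims <- rbind(dim(w_q), dim(w_k), dim(w_v))
  if (nrow(unique(dims)) != 1L) {
    stop_ppifusion("w_q, w_k, w_v must share dimensions", "ppifusion_validation_error")
  }
  if (ncol(w_q) < 1L) {
    stop_ppifusion("d_k must be >= 1", "ppifusion_config_error")
  }
  structure(list(w_q = w_q, w_k = w_k, w_v = w_v, d_k = ncol(w_q)),
            class = "attention_params")
}

# Numerically stable row-wise softmax (column loop beats apply() for the
# few-token matrices this package sees).
softmax_rows <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  z <- exp(m - mx)
  z / rowSums(z)
}

#' Scaled dot-product self-attention
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V` with `Q = x w_q`, `K = x w_k`,
#' `V = x w_v` over the token rows of `x`. Each output row is a convex
#' combination of value projections; the returned weight matrix has rows
#' summing to one.
#'
#' @param x Numeric matrix, tokens in rows.
#' @param params An [attention_params()] object.
#' @return An `attention_result`: list with `output` (tokens x d_k) and
#'   `weights` (tokens x tokens).
#' @export
self_attention <- function(x, params) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != nrow(params$w_q)) {
    stop_ppifusion(sprintf("token dim %d does not match projection rows %d",
                           ncol(x), nrow(params$w_q)),
                   "ppifusion_validation_error")
  }
  q <- x %*% params$w_q
  k <- x %*% params$w_k
  v <- x %*% params$w_v
  w <- softmax_rows(q %*% t(k) / sqrt(params$d_k))
  structure(list(output = w %*% v, weights = w), class = "attention_result")
}

#' Multi-head scaled dot-product attention
#'
#' Runs one [self_attention()] per head, concatenates head outputs along
#' features and applies the output projection `w_out`. With per-head key
#' dimension `model_dim / n_heads` and a square `w_out` the output shape
#' equals the input shape.
#'
#' @param x Numeric matrix, tokens in rows.
#' @param heads List of [attention_params()], one per head.
#' @param w_out Output projection matrix (`sum(d_k) x output_dim`).
#' @return Numeric matrix of attended tokens.
#' @export
multi_head_attention <- function(x, heads, w_out) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  n_heads <- length(heads)
  if (n_heads < 1L) stop_ppifusion("need at least one head", "ppifusion_config_error")
  if (ncol(x) %% n_heads != 0L) {
    stop_ppifusion(sprintf("n_heads = %d does not divide model dim %d",
                           n_heads, ncol(x)), "ppifusion_config_error")
  }
  outs <- lapply(heads, function(h) self_attention(x, h)$output)
  concat <- do.call(cbind, outs)
  if (nrow(w_out) != ncol(concat)) {
    stop_ppifusion("w_out rows must equal concatenated head dimension",
                   "ppifusion_validation_error")
  }
  concat %*% w_out
}
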