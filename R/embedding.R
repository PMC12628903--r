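AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

ANKH_DIM <- 1536L
ESM2_DIM <- 1280L
FUSED_DIM <- ANKH_DIM + ESM2_DIM

embedding_matrix <- function(protein_id, values, source) {
  structure(list(protein_id = protein_id, values = values, source = source),
            class = "embedding_matrix")
}

pooled_vector <- function(protein_id, values, source) {
  structure(list(protein_id = protein_id, values = values, source = source),
            class = "pooled_vector")
}

#' Deterministic synthetic per-residue embedder
#'
#' Stand-in for a protein language model: column `j` of the returned
#' `dim x L` matrix is a unit-variance pseudo-random vector keyed by a
#' stable integer hash of (residue letter at `j`, `j` mod 8, `seed`).
#' Identical inputs give bitwise-identical matrices on any platform. The
#' position phase cycles mod 8 so downstream attention has exploitable
#' positional structure with a bounded key vocabulary.
#'
#' @param protein One row of [read_protein_fasta()] output (or a list with
#'   `protein_id` and `sequence`).
#' @param dim Feature dimension (rows), e.g. 1536 or 1280.
#' @param seed Integer seed.
#' @return An `embedding_matrix` (fields `protein_id`, `values`, `source`).
#' @export
synthetic_embed <- function(protein, dim, seed = 42L) {
  if (dim < 1L) stop_ppifusion("dim must be >= 1", "ppifusion_config_error")
  seq <- protein$sequence
  if (is.null(seq) || nchar(seq) == 0L) {
    stop_ppifusion("sequence must be non-empty", "ppifusion_validation_error")
  }
  letters_ <- strsplit(seq, "")[[1L]]
  a_idx <- match(letters_, AA_ALPHABET)
  if (anyNA(a_idx)) {
    stop_ppifusion(sprintf("invalid residue '%s' in %s",
                           letters_[which(is.na(a_idx))[1L]], protein$protein_id),
                   "ppifusion_validation_error")
  }
  L <- length(letters_)
  phase <- (seq_len(L) - 1L) %% 8L
  # 21 letters x 8 phases -> at most 168 distinct columns per seed
  base_key <- (abs(as.integer(seed)) %% 100000L) * 16384L
  lut <- matrix(NA_real_, nrow = dim, ncol = 21L * 8L)
  col_of <- function(a, p) (a - 1L) * 8L + p + 1L
  needed <- unique(col_of(a_idx, phase))
  for (k in needed) {
    lut[, k] <- with_local_seed(base_key + k, stats::rnorm(dim))
  }
  values <- lut[, col_of(a_idx, phase), drop = FALSE]
  src <- if (dim == ANKH_DIM) "synthetic-a" else if (dim == ESM2_DIM) "synthetic-e" else "synthetic"
  embedding_matrix(protein$protein_id, values, src)
}

#' Mean-pool a per-residue embedding matrix over residues
#'
#' Each feature row of the `D x L` matrix is averaged over the `L`
#' residue positions, giving one fixed-length vector per protein.
#'
#' @param matrix An `embedding_matrix`.
#' @return A `pooled_vector` of length `D`.
#' @export
mean_pool <- function(matrix) {
  v <- matrix$values
  if (is.null(dim(v)) || ncol(v) < 1L) {
    stop_ppifusion("empty embedding matrix", "ppifusion_validation_error")
  }
  pooled_vector(matrix$protein_id, rowMeans(v), matrix$source)
}

#' Concatenate pooled embeddings of the two language models
#'
#' Fuses the 1536-dimensional (Ankh-type) and 1280-dimensional
#' (ESM-2-type) pooled vectors of one protein into a single
#' 2816-dimensional vector, Ankh first.
#'
#' @param v_a `pooled_vector` with source `ankh`/`synthetic-a`, length 1536.
#' @param v_e `pooled_vector` with source `esm2`/`synthetic-e`, length 1280.
#' @return Numeric vector of length 2816.
#' @export
concat_pair_vector <- function(v_a, v_e) {
  if (!identical(v_a$protein_id, v_e$protein_id)) {
    stop_ppifusion(sprintf("pooled vectors belong to different proteins: %s vs %s",
                           v_a$protein_id, v_e$protein_id),
                   "ppifusion_pairing_error")
  }
  if (!(v_a$source %in% c("ankh", "synthetic-a")) ||
      !(v_e$source %in% c("esm2", "synthetic-e"))) {
    stop_ppifusion("sources must be ankh-type then esm-type", "ppifusion_validation_error")
  }
  if (length(v_a$values) != ANKH_DIM || length(v_e$values) != ESM2_DIM) {
    stop_ppifusion(sprintf("expected lengths %d and %d, got %d and %d",
                           ANKH_DIM, ESM2_DIM,
                           length(v_a$values), length(v_e$values)),
                   "ppifusion_validation_error")
  }
  c(v_a$values, v_e$values)
}

#' Construct a synthetic embedder satisfying the embedder contract
#'
#' An embedder is a function of one protein record returning the named
#' list of per-residue `embedding_matrix` objects it produces (`ankh`
#' and/or `esm`). The synthetic embedder emulates the matrix shapes of
#' the two real language models deterministically from (sequence, seed).
#'
#' @param seed Integer seed.
#' @param mode `"fused"` (both matrices), `"ankh"` or `"esm2"`.
#' @return A function `protein -> list(ankh = ..., esm = ...)`.
#' @export
make_synthetic_embedder <- function(seed = 42L, mode = c("fused", "ankh", "esm2")) {
  mode <- match.arg(mode)
  function(protein) {
    out <- list()
    if (mode %in% c("fused", "ankh")) {
      out$ankh <- synthetic_embed(protein, ANKH_DIM, seed = seed)
    }
    if (mode %in% c("fused", "esm2")) {
      out$esm <- synthetic_embed(protein, ESM2_DIM, seed = seed + 1L)
    }
    out
  }
}

#' Embed a protein set into per-protein feature vectors, with caching
#'
#' Applies an embedder to every protein, mean-pools, and (in fused mode)
#' concatenates Ankh-then-ESM into 2816-dimensional vectors. Results are
#' persisted to `cache_path` (an RDS container keyed by protein id);
#' a rerun with the identical protein set and dimension loads the cache
#' bit-identically, while a changed protein set triggers a rebuild.
#'
#' @param proteins data.frame from [read_protein_fasta()].
#' @param embedder Function from [make_synthetic_embedder()] or a real
#'   language-model adapter with the same contract.
#' @param cache_path Optional RDS path; `NULL` disables caching.
#' @return Named list mapping protein_id to numeric feature vector.
#' @export
embed_dataset <- function(proteins, embedder, cache_path = NULL) {
  one <- function(p) {
    mats <- embedder(p)
    pooled <- lapply(mats, mean_pool)
    if (!is.null(pooled$ankh) && !is.null(pooled$esm)) {
      concat_pair_vector(pooled$ankh, pooled$esm)
    } else if (!is.null(pooled$ankh)) {
      pooled$ankh$values
    } else if (!is.null(pooled$esm)) {
      pooled$esm$values
    } else {
      stop_ppifusion("embedder returned no matrices", "ppifusion_validation_error")
    }
  }
  # probe one protein to learn the output dimension for cache validation
  first <- list(protein_id = proteins$protein_id[1L],
                sequence = proteins$sequence[1L])
  probe <- one(first)
  want_dim <- length(probe)
  if (!is.null(cache_path) && file.exists(cache_path)) {
    cache <- readRDS(cache_path)
    if (!identical(cache$dim, want_dim)) {
      stop_ppifusion(sprintf(
        "stale embedding cache %s: dimension %d but %d requested; delete and rebuild",
        cache_path, cache$dim, want_dim), "ppifusion_stale_cache_error")
    }
    if (identical(sort(names(cache$vectors)), sort(proteins$protein_id))) {
      return(cache$vectors)
    }
  }
  vectors <- vector("list", nrow(proteins))
  names(vectors) <- proteins$protein_id
  vectors[[1L]] <- probe
  for (i in seq_len(nrow(proteins))[-1L]) {
    vectors[[i]] <- one(list(protein_id = proteins$protein_id[i],
                             sequence = proteins$sequence[i]))
  }
  if (!is.null(cache_path)) {
    saveRDS(list(dim = want_dim, vectors = vectors), cache_path)
  }
  vectors
}
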