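AA20 <- setdiff(AA_ALPHABET, "X")

random_aa <- function(n, letters_pool = AA20) {
  paste(sample(letters_pool, n, replace = TRUE), collapse = "")
}

repeat_motif <- function(motif, len) {
  substr(strrep(motif, ceiling(len / nchar(motif))), 1L, len)
}

#' Generate a toy STRING-format fixture with a known stage-by-stage audit
#'
#' Writes a links file, a FASTA file and a YAML manifest into `out_dir`.
#' The construction plants every boundary the dataset pipeline must
#' respect: raw scores 390/400/800/850 (strict labeling bounds at
#' 0.4/0.8), sequence lengths 49/50/800/801 (inclusive length bounds),
#' one duplicated-order links row (canonical dedup) and one exact
#' duplicate sequence (the single intended cluster merge). Remaining bulk
#' pairs connect proteins whose sequences are rejection-sampled so all
#' pairwise identities stay below 0.35, keeping them singleton clusters;
#' the boundary-length proteins use low-complexity repeat motifs over
#' disjoint letter sets for the same reason.
#'
#' The manifest's `expected` block is computed by enumerating the
#' constructed records through each rule (scores, lengths, greedy
#' clustering, subsample arithmetic) independently of the pipeline
#' functions, and is the oracle for the pipeline audit.
#'
#' @param n_proteins Number of proteins (>= 10); default 30.
#' @param seed Integer seed; regeneration with the same seed is
#'   byte-identical.
#' @param out_dir Output directory (created if needed).
#' @param ratio Negative:positive subsampling ratio recorded for the
#'   audit; default 5 (toy scale).
#' @return Invisible list with `links`, `fasta`, `manifest` paths and the
#'   `expected` counts.
#' @export
make_toy_string <- function(n_proteins = 30L, seed = 42L, out_dir, ratio = 5L) {
  if (n_proteins < 10L) {
    stop_ppifusion("n_proteins must be >= 10", "ppifusion_config_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("TP%03d", seq_len(n_proteins))
  res <- with_local_seed(seed, {
    lens <- integer(n_proteins)
    seqs <- character(n_proteins)
    # boundary proteins: repeat motifs over disjoint letter pairs so they
    # never cluster with anything
    lens[1L] <- 49L;  seqs[1L] <- repeat_motif("EL", 49L)   # below min_len
    lens[2L] <- 50L;  seqs[2L] <- repeat_motif("HY", 50L)   # at min_len
    lens[3L] <- 800L; seqs[3L] <- repeat_motif("WM", 800L)  # at max_len
    lens[4L] <- 801L; seqs[4L] <- repeat_motif("KD", 801L)  # above max_len
    # duplicate sequence pair (5 is the lexicographically earlier rep)
    lens[5L] <- 120L; seqs[5L] <- random_aa(120L)
    lens[6L] <- 120L; seqs[6L] <- seqs[5L]
    # bulk: narrow length band, rejection-sampled for mutual dissimilarity
    cluster_pool <- c(2L, 3L, 5L)
    for (i in 7L:n_proteins) {
      lens[i] <- sample(110:130, 1L)
      repeat {
        cand <- random_aa(lens[i])
        ok <- all(vapply(cluster_pool, function(j)
          sequence_identity(cand, seqs[j]) < 0.35, logical(1)))
        if (ok) break
      }
      seqs[i] <- cand
      cluster_pool <- c(cluster_pool, i)
    }
    bulk <- 7L:n_proteins
    n_bulk <- length(bulk)
    bulk_pairs <- t(combn(bulk, 2L))
    bw <- function(i) bulk[(i - 1L) %% n_bulk + 1L]
    # planted pairs: (a index, b index, raw score); mixed pairs reuse bulk
    # partners cyclically, bulk-bulk pairs take the first combn rows
    planted <- rbind(
      c(1L, bw(1L), 850L),     # positive, dies at length filter (len 49)
      c(4L, bw(2L), 200L),     # negative, dies at length filter (len 801)
      c(2L, 3L, 850L),         # positive, boundary lengths 50/800 retained
      c(bulk_pairs[1L, ], 390L),  # negative, 0.39 strictly below 0.4
      c(bulk_pairs[2L, ], 400L),  # ambiguous, 0.40 excluded
      c(bulk_pairs[3L, ], 800L),  # ambiguous, 0.80 excluded
      c(bulk_pairs[4L, ], 850L),  # positive, survives everything
      c(5L, bw(3L), 980L),     # positive; written in both orders below
      c(6L, bw(4L), 850L))     # positive, dies at clustering (dup of 5)
    # remaining bulk pairs, distinct from the planted ones
    planted_key <- paste(pmin(planted[, 1L], planted[, 2L]),
                         pmax(planted[, 1L], planted[, 2L]))
    all_bulk <- bulk_pairs[!(paste(bulk_pairs[, 1L], bulk_pairs[, 2L]) %in%
                               planted_key), , drop = FALSE]
    m_target <- min(3L * n_bulk, nrow(all_bulk))
    pick <- all_bulk[sample.int(nrow(all_bulk), m_target), , drop = FALSE]
    n_bpos <- ceiling(0.08 * m_target)
    n_bgap <- ceiling(0.08 * m_target)
    n_bneg <- m_target - n_bpos - n_bgap
    bscore <- c(sample(801:1000, n_bpos, replace = TRUE),
                sample(400:800, n_bgap, replace = TRUE),
                sample(0:399, n_bneg, replace = TRUE))
    records <- rbind(planted, cbind(pick, bscore))
    list(lens = lens, seqs = seqs, records = records)
  })
  lens <- res$lens; seqs <- res$seqs; records <- res$records

  # ---- independent enumeration of expected survivor counts ----
  a <- ids[records[, 1L]]; b <- ids[records[, 2L]]
  raw <- records[, 3L]
  # canonical order; the extra duplicated-order row is only in the file
  swap <- a > b
  pa <- ifelse(swap, b, a); pb <- ifelse(swap, a, b)
  stopifnot(!anyDuplicated(paste(pa, pb)))
  n_parsed <- nrow(records)
  score <- raw / 1000
  lab <- ifelse(score < 0.4, 0L, ifelse(score > 0.8, 1L, NA_integer_))
  keep_lab <- !is.na(lab)
  len_of <- stats::setNames(lens, ids)
  keep_len <- keep_lab & len_of[pa] >= 50L & len_of[pa] <= 800L &
    len_of[pb] >= 50L & len_of[pb] <= 800L
  # greedy clustering of proteins present in surviving pairs, re-stated
  member <- unique(c(pa[keep_len], pb[keep_len]))
  ordm <- member[order(-len_of[member], member)]
  reps <- character(0)
  rep_of <- character(0)
  for (id in ordm) {
    hit <- NA_character_
    for (r in reps) {
      if (sequence_identity(seqs[match(id, ids)], seqs[match(r, ids)]) >= 0.40) {
        hit <- r; break
      }
    }
    if (is.na(hit)) reps <- c(reps, id)
    rep_of[id] <- if (is.na(hit)) id else hit
  }
  keep_cl <- keep_len & rep_of[pa] == pa & rep_of[pb] == pb
  n_pos <- sum(lab[keep_cl] == 1L)
  n_neg <- sum(lab[keep_cl] == 0L)
  if (n_neg < ratio * n_pos) {
    stop_ppifusion(sprintf(
      "toy construction infeasible: %d negatives < ratio %d x %d positives; lower ratio",
      n_neg, ratio, n_pos), "ppifusion_config_error")
  }
  expected <- list(parsed = n_parsed, labeled = sum(keep_lab),
                   length_filtered = sum(keep_len), clustered = sum(keep_cl),
                   positives = n_pos, negatives = n_neg,
                   subsampled = n_pos + ratio * n_pos)

  # ---- write files (LF, fixed formatting, byte-stable) ----
  links_path <- file.path(out_dir, "links.txt")
  fasta_path <- file.path(out_dir, "proteins.fasta")
  manifest_path <- file.path(out_dir, "manifest.yaml")
  lines <- c("protein1 protein2 combined_score",
             paste(a, b, raw))
  # duplicated-order row for the 980 pair exercises canonical dedup
  dup_row <- which(raw == 980L)[1L]
  lines <- append(lines, paste(b[dup_row], a[dup_row], raw[dup_row]),
                  after = dup_row + 1L)
  writeLines(lines, links_path, sep = "\n")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), fasta_path, sep = "\n")
  yaml::write_yaml(list(kind = "toy-string", seed = as.integer(seed),
                        n_proteins = as.integer(n_proteins),
                        ratio = as.integer(ratio),
                        params = list(low = 0.4, high = 0.8, min_len = 50L,
                                      max_len = 800L, identity = 0.40),
                        expected = expected),
                   manifest_path)
  invisible(list(links = links_path, fasta = fasta_path,
                 manifest = manifest_path, expected = expected))
}

#' Planted-structure embedding dataset
#'
#' Every protein receives a latent vector `u = latent_mean + eps`,
#' `eps ~ N(0, I)`, in `latent_dim` dimensions; the pairs with the
#' `n_pos` largest latent dot products `u_i . u_j` are labeled
#' interactions and `n_neg` non-interactions are sampled uniformly from
#' the rest. The shared mean component models a hub-like interaction
#' propensity and makes the dominant term of `u_i . u_j` additive across
#' the pair, so the planted signal is linearly recoverable from
#' concatenated pair features (a logistic probe succeeds) while the
#' residual bilinear term rewards pair-interaction modeling.
#'
#' Observed per-protein features are a fixed random linear lift of `u`
#' into `feature_dim` dimensions plus isotropic Gaussian noise. The lift
#' is block-structured like the fused embedding layout: the Ankh-sized
#' block (first `1536/2816` of the rows) encodes only the leading 75% of
#' latent coordinates and the ESM-sized block only the trailing 75%, so
#' the two views are partially overlapping and complementary — as the
#' two language models are — and the fused profile sees strictly more
#' signal than either single block. A competent classifier attains high
#' AUC; at extreme noise the signal is destroyed and AUC collapses to
#' chance.
#'
#' @param n_proteins Number of proteins; default 300.
#' @param latent_dim Latent dimension; default 8.
#' @param n_pos,n_neg Positive / negative pair counts; defaults 200 and
#'   2000 (the 1:10 regime).
#' @param noise_sd Feature noise standard deviation; default 0.25
#'   (signal entries have approximately unit variance around their mean).
#' @param latent_mean Per-coordinate mean of the latent vectors
#'   (interaction-propensity component); default 2.
#' @param feature_dim Observed feature dimension; default 2816 (the
#'   fused embedding layout).
#' @param seed Integer seed; identical specs give identical datasets.
#' @return List with `pairs` (protein_a, protein_b, label), `features`
#'   (named list of feature vectors), `latent` (matrix of u vectors) and
#'   the spec fields.
#' @export
make_planted_embeddings <- function(n_proteins = 300L, latent_dim = 8L,
                                    n_pos = 200L, n_neg = 2000L,
                                    noise_sd = 0.25, feature_dim = 2816L,
                                    latent_mean = 2, seed = 42L) {
  if (n_pos < 1L || n_neg < 1L) {
    stop_ppifusion("n_pos and n_neg must be >= 1", "ppifusion_config_error")
  }
  total <- choose(n_proteins, 2L)
  if (n_pos + n_neg > total) {
    stop_ppifusion(sprintf("n_pos + n_neg = %d exceeds %d possible pairs",
                           n_pos + n_neg, total), "ppifusion_config_error")
  }
  ids <- sprintf("SP%04d", seq_len(n_proteins))
  with_local_seed(seed, {
    U <- latent_mean +
      matrix(stats::rnorm(n_proteins * latent_dim), n_proteins, latent_dim)
    D <- tcrossprod(U)
    iu <- which(upper.tri(D), arr.ind = TRUE)
    dots <- D[upper.tri(D)]
    ord <- order(-dots)
    pos_idx <- ord[seq_len(n_pos)]
    neg_idx <- sample(ord[-seq_len(n_pos)], n_neg)
    sel <- c(pos_idx, neg_idx)
    pairs <- data.frame(
      protein_a = ids[pmin(iu[sel, 1L], iu[sel, 2L])],
      protein_b = ids[pmax(iu[sel, 1L], iu[sel, 2L])],
      label = rep(c(1L, 0L), c(n_pos, n_neg)),
      stringsAsFactors = FALSE)
    # block-structured lift: ankh-sized block sees the leading latent
    # coords, esm-sized block the trailing ones (75% each, overlapping)
    n_view <- max(1L, ceiling(0.75 * latent_dim))
    view_a <- seq_len(n_view)
    view_e <- (latent_dim - n_view + 1L):latent_dim
    rows_a <- seq_len(round(feature_dim * ANKH_DIM / FUSED_DIM))
    rows_e <- setdiff(seq_len(feature_dim), rows_a)
    M <- matrix(0, feature_dim, latent_dim)
    M[rows_a, view_a] <- stats::rnorm(length(rows_a) * n_view) / sqrt(n_view)
    M[rows_e, view_e] <- stats::rnorm(length(rows_e) * n_view) / sqrt(n_view)
    X <- U %*% t(M) +
      noise_sd * matrix(stats::rnorm(n_proteins * feature_dim),
                        n_proteins, feature_dim)
    features <- lapply(seq_len(n_proteins), function(i) X[i, ])
    names(features) <- ids
    list(pairs = pairs, features = features, latent = U,
         n_proteins = n_proteins, latent_dim = latent_dim,
         n_pos = n_pos, n_neg = n_neg, noise_sd = noise_sd,
         latent_mean = latent_mean, seed = seed)
  })
}
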