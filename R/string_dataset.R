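#' Read protein sequences from a FASTA file
#'
#' Sequence identifiers are the first whitespace-delimited token of each
#' FASTA header. Identifiers must be unique and sequences non-empty.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A data.frame with columns `protein_id`, `sequence`, `length`.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) {
    stop_ppifusion(sprintf("FASTA file not found: %s", path), "ppifusion_io_error")
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop_ppifusion(
      sprintf("duplicate protein ids in FASTA: %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", ")),
      "ppifusion_validation_error")
  }
  seqs <- as.character(aa)
  lens <- nchar(seqs)
  if (any(lens < 1L)) {
    stop_ppifusion("empty sequence in FASTA", "ppifusion_validation_error")
  }
  data.frame(protein_id = ids, sequence = unname(seqs), length = unname(lens),
             stringsAsFactors = FALSE)
}

#' Parse a STRING physical-links file into scored pairs
#'
#' Reads a whitespace-delimited file with at least three columns
#' (`protein1`, `protein2`, `combined_score`), skipping an optional header
#' whose first token is `"protein1"`. Raw integer scores in \[0, 1000\] are
#' normalized to \[0, 1\]. Pairs are put in canonical order (lexicographically
#' smaller id first) so that (a,b) and (b,a) collapse to a single record;
#' self-pairs are dropped. On duplicate canonical pairs the first occurrence
#' wins.
#'
#' @param path Path to the links file.
#' @param min_records Minimum number of scored pairs required after
#'   deduplication; fewer is an error.
#' @return A data.frame with columns `protein_a`, `protein_b`, `score`.
#' @export
parse_links <- function(path, min_records = 0L) {
  if (!file.exists(path)) {
    stop_ppifusion(sprintf("links file not found: %s", path), "ppifusion_io_error")
  }
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) > 0L) {
    first_tok <- sub("\\s.*$", "", trimws(lines[1L]))
    if (identical(first_tok, "protein1")) {
      lines <- lines[-1L]
      lineno <- lineno[-1L]
    }
  }
  if (length(lines) == 0L) {
    out <- data.frame(protein_a = character(0), protein_b = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
    if (min_records > 0L) {
      stop_ppifusion(sprintf("links file has 0 records, %d required", min_records),
                     "ppifusion_validation_error")
    }
    return(out)
  }
  toks <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(toks)
  if (any(nf < 3L)) {
    bad <- lineno[which(nf < 3L)[1L]]
    stop_ppifusion(sprintf("malformed links line %d: fewer than 3 fields", bad),
                   "ppifusion_parse_error")
  }
  a <- vapply(toks, `[[`, character(1), 1L)
  b <- vapply(toks, `[[`, character(1), 2L)
  raw <- suppressWarnings(as.numeric(vapply(toks, `[[`, character(1), 3L)))
  if (anyNA(raw) || any(raw != round(raw))) {
    bad <- lineno[which(is.na(raw) | raw != round(raw))[1L]]
    stop_ppifusion(sprintf("malformed links line %d: score is not an integer", bad),
                   "ppifusion_parse_error")
  }
  if (any(raw < 0 | raw > 1000)) {
    bad <- lineno[which(raw < 0 | raw > 1000)[1L]]
    stop_ppifusion(sprintf("links line %d: raw score outside [0, 1000]", bad),
                   "ppifusion_validation_error")
  }
  swap <- a > b
  pa <- ifelse(swap, b, a)
  pb <- ifelse(swap, a, b)
  keep <- pa != pb
  pa <- pa[keep]; pb <- pb[keep]; raw <- raw[keep]
  key <- paste(pa, pb, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(protein_a = pa[first], protein_b = pb[first],
                    score = raw[first] / 1000, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (nrow(out) < min_records) {
    stop_ppifusion(sprintf("links file has %d records, %d required",
                           nrow(out), min_records),
                   "ppifusion_validation_error")
  }
  out
}

#' Label scored pairs as interactions / non-interactions
#'
#' Pairs with normalized score strictly below `low` are non-interactions
#' (label 0); strictly above `high`, interactions (label 1). Scores in the
#' closed interval `[low, high]` are ambiguous and excluded.
#'
#' @param pairs data.frame from [parse_links()].
#' @param low,high Score thresholds, defaults 0.4 and 0.8.
#' @return data.frame with columns `protein_a`, `protein_b`, `label`.
#' @export
label_pairs <- function(pairs, low = 0.4, high = 0.8) {
  if (!(low >= 0 && low < high && high <= 1)) {
    stop_ppifusion("need 0 <= low < high <= 1", "ppifusion_config_error")
  }
  lab <- ifelse(pairs$score < low, 0L, ifelse(pairs$score > high, 1L, NA_integer_))
  out <- data.frame(protein_a = pairs$protein_a[!is.na(lab)],
                    protein_b = pairs$protein_b[!is.na(lab)],
                    label = lab[!is.na(lab)], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter labeled pairs by sequence length
#'
#' A pair survives only if both member sequences have length within
#' `[min_len, max_len]` (inclusive bounds).
#'
#' @param pairs data.frame of labeled pairs.
#' @param proteins data.frame from [read_protein_fasta()].
#' @param min_len,max_len Length bounds, defaults 50 and 800.
#' @export
filter_by_length <- function(pairs, proteins, min_len = 50L, max_len = 800L) {
  lens <- stats::setNames(proteins$length, proteins$protein_id)
  missing <- setdiff(unique(c(pairs$protein_a, pairs$protein_b)), names(lens))
  if (length(missing) > 0L) {
    stop_ppifusion(sprintf("missing sequences for: %s",
                           paste(missing, collapse = ", ")),
                   "ppifusion_missing_sequence_error")
  }
  la <- lens[pairs$protein_a]; lb <- lens[pairs$protein_b]
  ok <- la >= min_len & la <= max_len & lb >= min_len & lb <= max_len
  out <- pairs[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and linear
#' gap penalty -1; identity is the number of identical aligned positions
#' divided by the length of the shorter sequence (the convention of
#' greedy redundancy-removal tools). Traceback tie-breaks are fixed
#' (diagonal, then gap in the second sequence) so the value is
#' deterministic.
#'
#' @param s1,s2 Amino-acid strings.
#' @return Identity fraction in \[0, 1\].
#' @export
sequence_identity <- function(s1, s2) {
  if (nchar(s1) == 0L || nchar(s2) == 0L) {
    stop_ppifusion("empty sequence", "ppifusion_validation_error")
  }
  cnt <- .nw_align_counts(s1, s2)
  cnt[["matches"]] / min(nchar(s1), nchar(s2))
}

#' Greedy sequence-identity clustering (redundancy removal)
#'
#' Proteins are sorted by decreasing length (ties broken by lexicographic
#' id) and scanned once: each protein joins the first earlier
#' representative with pairwise identity at or above `threshold`,
#' otherwise it founds its own cluster. This mirrors the greedy
#' incremental strategy of CD-HIT-style tools with exact global-alignment
#' identity in place of word-filter heuristics.
#'
#' @param proteins data.frame from [read_protein_fasta()].
#' @param threshold Identity threshold in (0, 1); default 0.40.
#' @return Named character vector mapping protein_id to representative id.
#' @export
greedy_identity_cluster <- function(proteins, threshold = 0.40) {
  if (!(threshold > 0 && threshold < 1)) {
    stop_ppifusion("threshold must be in (0, 1)", "ppifusion_config_error")
  }
  n <- nrow(proteins)
  if (n == 0L) return(stats::setNames(character(0), character(0)))
  ord <- order(-proteins$length, proteins$protein_id)
  ids <- proteins$protein_id[ord]
  seqs <- proteins$sequence[ord]
  rep_of <- character(n)
  names(rep_of) <- ids
  rep_idx <- integer(0)  # indices (into sorted order) of representatives
  for (i in seq_len(n)) {
    assigned <- NA_character_
    for (r in rep_idx) {
      if (sequence_identity(seqs[i], seqs[r]) >= threshold) {
        assigned <- ids[r]
        break
      }
    }
    if (is.na(assigned)) {
      rep_idx <- c(rep_idx, i)
      rep_of[i] <- ids[i]
    } else {
      rep_of[i] <- assigned
    }
  }
  rep_of
}

#' Drop pairs touching non-representative proteins
#'
#' After clustering, only pairs whose both members are cluster
#' representatives are retained; member pairs are not remapped onto
#' representatives (remapping can create duplicate or self pairs).
#'
#' @param pairs data.frame of labeled pairs.
#' @param clusters Named vector from [greedy_identity_cluster()].
#' @export
deduplicate_by_cluster <- function(pairs, clusters) {
  missing <- setdiff(unique(c(pairs$protein_a, pairs$protein_b)), names(clusters))
  if (length(missing) > 0L) {
    stop_ppifusion(sprintf("cluster map does not cover: %s",
                           paste(missing, collapse = ", ")),
                   "ppifusion_validation_error")
  }
  is_rep_a <- clusters[pairs$protein_a] == pairs$protein_a
  is_rep_b <- clusters[pairs$protein_b] == pairs$protein_b
  out <- pairs[is_rep_a & is_rep_b, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subsample negatives to a fixed negative:positive ratio
#'
#' Keeps every positive pair and draws exactly `ratio` times as many
#' negatives, uniformly without replacement, using `seed`. Output order is
#' positives (input order) followed by sampled negatives (draw order).
#'
#' @param pairs data.frame of labeled pairs.
#' @param ratio Integer negative:positive ratio; default 10.
#' @param seed Integer RNG seed.
#' @export
subsample_negatives <- function(pairs, ratio = 10L, seed = 42L) {
  if (ratio < 1L) stop_ppifusion("ratio must be >= 1", "ppifusion_config_error")
  pos <- which(pairs$label == 1L)
  neg <- which(pairs$label == 0L)
  need <- as.numeric(ratio) * length(pos)
  if (length(neg) < need) {
    stop_ppifusion(sprintf(
      "insufficient negatives: %d available, %d required (ratio %d x %d positives)",
      length(neg), as.integer(need), as.integer(ratio), length(pos)),
      "ppifusion_validation_error")
  }
  chosen <- with_local_seed(seed, sample(neg, size = need, replace = FALSE))
  out <- pairs[c(pos, chosen), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Train/validation split with k disjoint folds of the training pool
#'
#' Shuffles pairs with `seed`, holds out `val_fraction` as validation, and
#' partitions the remaining training pool into `k` folds whose sizes
#' differ by at most one.
#'
#' @param pairs data.frame of labeled pairs.
#' @param val_fraction Fraction held out for validation; default 0.2.
#' @param k Number of folds over the training pool; default 5.
#' @param seed Integer RNG seed.
#' @return List with `train`, `validation` (data.frames), `folds` (list of
#'   integer row indices into `train`) and `seed`.
#' @export
make_splits <- function(pairs, val_fraction = 0.2, k = 5L, seed = 42L) {
  n <- nrow(pairs)
  if (!(val_fraction > 0 && val_fraction < 1)) {
    stop_ppifusion("val_fraction must be in (0, 1)", "ppifusion_config_error")
  }
  if (k < 2L) stop_ppifusion("k must be >= 2", "ppifusion_config_error")
  if (n < k) {
    stop_ppifusion(sprintf("k = %d exceeds number of pairs (%d)", k, n),
                   "ppifusion_config_error")
  }
  perm <- with_local_seed(seed, sample.int(n))
  n_val <- round(val_fraction * n)
  val_idx <- perm[seq_len(n_val)]
  train_idx <- perm[setdiff(seq_len(n), seq_len(n_val))]
  train <- pairs[train_idx, , drop = FALSE]
  rownames(train) <- NULL
  validation <- pairs[val_idx, , drop = FALSE]
  rownames(validation) <- NULL
  folds <- assign_folds(length(train_idx), k)
  list(train = train, validation = validation, folds = folds, seed = seed)
}

# Partition 1..n into k folds (round robin over an already-shuffled
# sequence) with sizes differing by at most one.
assign_folds <- function(n, k) {
  f <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(i) which(f == i))
}

#' Run the full dataset-construction pipeline
#'
#' parse -> label -> length-filter -> cluster-dedupe -> negative
#' subsampling -> splits, recording the number of surviving pairs after
#' every stage. Clustering may optionally run before labeling.
#'
#' @param links_path,fasta_path Input files.
#' @param low,high Score thresholds for labeling.
#' @param min_len,max_len Sequence length bounds.
#' @param identity Clustering identity threshold.
#' @param ratio Negative:positive subsampling ratio.
#' @param val_fraction,folds Split parameters.
#' @param seed Integer seed driving all randomness.
#' @param cluster_stage `"after_labeling"` (default) or `"before_labeling"`.
#' @return List with `pairs`, `splits`, `proteins`, `clusters`,
#'   `stage_log` (named integer vector of survivor counts).
#' @export
build_ppi_dataset <- function(links_path, fasta_path,
                              low = 0.4, high = 0.8,
                              min_len = 50L, max_len = 800L,
                              identity = 0.40, ratio = 10L,
                              val_fraction = 0.2, folds = 5L, seed = 42L,
                              cluster_stage = c("after_labeling", "before_labeling")) {
  cluster_stage <- match.arg(cluster_stage)
  proteins <- read_protein_fasta(fasta_path)
  scored <- parse_links(links_path)
  log <- c(parsed = nrow(scored))

  cluster_pairs <- function(pairs) {
    ids <- unique(c(pairs$protein_a, pairs$protein_b))
    cl <- greedy_identity_cluster(proteins[proteins$protein_id %in% ids, ,
                                           drop = FALSE], identity)
    list(pairs = deduplicate_by_cluster(pairs, cl), clusters = cl)
  }

  clusters <- NULL
  if (cluster_stage == "before_labeling") {
    labeled0 <- data.frame(protein_a = scored$protein_a,
                           protein_b = scored$protein_b,
                           label = NA_integer_, score = scored$score,
                           stringsAsFactors = FALSE)
    cc <- cluster_pairs(labeled0)
    clusters <- cc$clusters
    scored <- cc$pairs[, c("protein_a", "protein_b", "score")]
    log <- c(log, clustered = nrow(scored))
  }
  labeled <- label_pairs(scored, low = low, high = high)
  log <- c(log, labeled = nrow(labeled))
  lenok <- filter_by_length(labeled, proteins, min_len = min_len, max_len = max_len)
  log <- c(log, length_filtered = nrow(lenok))
  if (cluster_stage == "after_labeling") {
    cc <- cluster_pairs(lenok)
    clusters <- cc$clusters
    lenok <- cc$pairs
    log <- c(log, clustered = nrow(lenok))
  }
  sub <- subsample_negatives(lenok, ratio = ratio, seed = seed)
  log <- c(log, subsampled = nrow(sub))
  splits <- make_splits(sub, val_fraction = val_fraction, k = folds, seed = seed)
  list(pairs = sub, splits = splits, proteins = proteins,
       clusters = clusters, stage_log = log)
}

#' Write labeled pairs as TSV
#' @param pairs data.frame with `protein_a`, `protein_b`, `label`.
#' @param path Output path.
#' @export
write_labeled_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("protein_a", "protein_b", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read labeled pairs from TSV
#' @param path Path written by [write_labeled_pairs()].
#' @export
read_labeled_pairs <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "integer"))
}
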