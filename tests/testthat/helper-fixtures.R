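# Shared fixtures, generated once per test run (seeded; cheap to rebuild).

.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixture_cache$fix)) {
    .fixture_cache$fix <- generate_genome(fixture_config())
  }
  .fixture_cache$fix
}

default_mining <- function() {
  if (is.null(.fixture_cache$members)) {
    fix <- default_fixture()
    .fixture_cache$members <- mine_family(fix$transcripts, fix$genome,
                                          fix$seed_alignment)
  }
  .fixture_cache$members
}

default_sites <- function() {
  if (is.null(.fixture_cache$sites)) {
    fix <- default_fixture()
    .fixture_cache$sites <- scan_transcripts(fix$transcripts, fix$genome)
  }
  .fixture_cache$sites
}

random_protein_str <- function(n) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A","C","G","T"), n, replace = TRUE), collapse = "")
}

# Naive per-window Hamming scan: the independent oracle for
# find_target_sites (character-by-character, no vectorized tricks).
naive_site_scan <- function(seq, mirna, max_mm = 2, allowed = c(1, 7, 9)) {
  sig <- strsplit(binding_signature(mirna), "")[[1]]
  ch <- strsplit(seq, "")[[1]]
  L <- length(sig)
  hits <- list()
  for (s in seq_len(length(ch) - L + 1)) {
    win <- ch[s:(s + L - 1)]
    if (any(win == "N")) next
    mm_cols <- which(win != sig)
    mm_pos <- L - mm_cols + 1  # miRNA 5'-based numbering
    if (length(mm_pos) <= max_mm && all(mm_pos %in% allowed)) {
      hits[[length(hits) + 1]] <- list(start = s - 1L, n = length(mm_pos),
                                       pos = sort(mm_pos))
    }
  }
  hits
}

# Exhaustive global-alignment enumeration oracle for short sequences:
# scores every monotone alignment path with affine gap runs.
enumerate_global_score <- function(a, b, submat, gap_open = -10, gap_extend = -1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1, j + 1, score + submat[ca[i], cb[j]], "m")
    }
    if (i <= length(ca)) {
      pen <- gap_extend + if (state == "x") 0 else gap_open
      rec(i + 1, j, score + pen, "x")
    }
    if (j <= length(cb)) {
      pen <- gap_extend + if (state == "y") 0 else gap_open
      rec(i, j + 1, score + pen, "y")
    }
  }
  rec(1, 1, 0, "m")
  best
}

# Planted-deletion protein family with known homology (ancestor-column
# coordinates), for MSA benchmarking.
planted_msa_family <- function(n = 6, len = 60, sub_rate = 0.08) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  anc <- sample(aa, len, replace = TRUE)
  seqs <- character(n); keep <- list()
  for (s in seq_len(n)) {
    ch <- anc
    subs <- which(stats::runif(len) < sub_rate)
    ch[subs] <- vapply(ch[subs], function(x) sample(setdiff(aa, x), 1), character(1))
    kept <- rep(TRUE, len)
    if (s > 1) {
      d0 <- sample(5:(len - 10), 1)
      kept[d0:(d0 + sample(2:5, 1))] <- FALSE
    }
    keep[[s]] <- kept
    seqs[s] <- paste(ch[kept], collapse = "")
  }
  names(seqs) <- paste0("seq", seq_len(n))
  list(seqs = seqs, keep = keep, len = len)
}

# Fraction of true homologous residue pairs recovered by an alignment.
msa_pair_recall <- function(alignment, fam) {
  rows <- do.call(rbind, strsplit(unname(alignment[names(fam$seqs)]), ""))
  n <- nrow(rows)
  # residue index per column per sequence
  idx <- t(apply(rows, 1, function(r) {
    out <- cumsum(r != "-"); out[r == "-"] <- NA; out
  }))
  true_pairs <- 0; found <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      pos_i <- cumsum(fam$keep[[i]])
      pos_j <- cumsum(fam$keep[[j]])
      shared <- which(fam$keep[[i]] & fam$keep[[j]])
      tp <- cbind(pos_i[shared], pos_j[shared])
      true_pairs <- true_pairs + nrow(tp)
      ali <- stats::na.omit(cbind(idx[i, ], idx[j, ]))
      key <- paste(ali[, 1], ali[, 2])
      found <- found + sum(paste(tp[, 1], tp[, 2]) %in% key)
    }
  }
  found / true_pairs
}

# Independently coded step-by-step TMM oracle (sorting-based, written
# separately from the package's rank-based implementation).
oracle_tmm <- function(counts, ref_col, logratio_trim = 0.30, sum_trim = 0.05) {
  lib <- colSums(counts)
  f <- numeric(ncol(counts))
  for (k in seq_len(ncol(counts))) {
    if (k == ref_col) { f[k] <- 1; next }
    y <- counts[, k]; r <- counts[, ref_col]
    use <- y > 0 & r > 0
    y <- y[use]; r <- r[use]
    M <- log2(y) - log2(r)
    A <- 0.5 * (log2(y / lib[k]) + log2(r / lib[ref_col]))
    w <- (lib[k] - y) / (lib[k] * y) + (lib[ref_col] - r) / (lib[ref_col] * r)
    n <- length(M)
    ordM <- order(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    keepM <- ordM[seq(loM, hiM)]
    ordA <- order(A)
    loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
    keepA <- ordA[seq(loA, hiA)]
    keep <- intersect(keepM, keepA)
    f[k] <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f / exp(mean(log(f)))
}
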