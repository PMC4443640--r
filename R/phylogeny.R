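# SBP-domain phylogeny from scratch: progressive multiple alignment on a
# UPGMA guide tree, corrected protein distances, and neighbor-joining.
#
# Tree inference is deliberately distance-based (NJ on Kimura-corrected
# distances) rather than full maximum likelihood; downstream checks are
# phrased in terms of clade memberships, which are robust to that choice.

# ---- progressive multiple alignment ---------------------------------

as_char_matrix <- function(rows) {
  do.call(rbind, strsplit(rows, "", fixed = TRUE))
}

# Align two profiles (character matrices) with affine-gap NW; column
# score = mean pairwise substitution score, gap-residue pairs scoring 0.
align_profiles <- function(A, B, submat, gap_open, gap_extend) {
  n <- ncol(A); m <- ncol(B)
  aa <- rownames(submat)
  colsc <- matrix(0, n, m)
  for (i in seq_len(n)) {
    ra <- A[, i]; ra <- ra[ra != "-"]
    if (length(ra) == 0) { colsc[i, ] <- 0; next }
    for (j in seq_len(m)) {
      rb <- B[, j]; rb <- rb[rb != "-"]
      if (length(rb) == 0) next
      colsc[i, j] <- sum(submat[ra, rb, drop = FALSE]) /
        (nrow(A) * nrow(B))
    }
  }
  M <- matrix(NEG_INF, n + 1, m + 1)
  X <- matrix(NEG_INF, n + 1, m + 1)
  Y <- matrix(NEG_INF, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- gap_open + (i - 1) * gap_extend
  for (j in 2:(m + 1)) Y[1, j] <- gap_open + (j - 1) * gap_extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
        colsc[i - 1, j - 1]
      X[i, j] <- max(max(M[i - 1, j], Y[i - 1, j]) + gap_open + gap_extend,
                     X[i - 1, j] + gap_extend)
      Y[i, j] <- max(max(M[i, j - 1], X[i, j - 1]) + gap_open + gap_extend,
                     Y[i, j - 1] + gap_extend)
    }
  }
  # traceback (diagonal > up > left)
  eps <- 1e-9
  i <- n + 1; j <- m + 1
  sc <- c(M[i, j], X[i, j], Y[i, j])
  state <- which(sc >= max(sc) - eps)[1]
  takeA <- logical(0); takeB <- logical(0)
  while (i > 1 || j > 1) {
    if (i == 1) state <- 3L
    if (j == 1) state <- 2L
    if (state == 1L) {
      takeA <- c(TRUE, takeA); takeB <- c(TRUE, takeB)
      tgt <- M[i, j] - colsc[i - 1, j - 1]
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which(abs(prev - tgt) < eps)[1]
      i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      takeA <- c(TRUE, takeA); takeB <- c(FALSE, takeB)
      if (abs(X[i, j] - (X[i - 1, j] + gap_extend)) < eps && i > 2) state <- 2L
      else state <- if (M[i - 1, j] >= Y[i - 1, j] - eps) 1L else 3L
      i <- i - 1
    } else {
      takeA <- c(FALSE, takeA); takeB <- c(TRUE, takeB)
      if (abs(Y[i, j] - (Y[i, j - 1] + gap_extend)) < eps && j > 2) state <- 3L
      else state <- if (M[i, j - 1] >= X[i, j - 1] - eps) 1L else 2L
      j <- j - 1
    }
  }
  L <- length(takeA)
  outA <- matrix("-", nrow(A), L)
  outB <- matrix("-", nrow(B), L)
  outA[, takeA] <- A
  outB[, takeB] <- B
  rbind(outA, outB)
}

#' Progressive multiple sequence alignment
#'
#' Aligns protein sequences progressively: pairwise global alignments
#' give percent-identity distances, a UPGMA guide tree (average-linkage
#' clustering) orders the merges, and profiles are merged leaf-to-root
#' with affine-gap profile-profile alignment.
#'
#' @param seqs Named character vector of protein sequences (>= 1).
#' @param submat Substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend Gap penalties (defaults -10, -1).
#' @return Named character vector of aligned rows (equal length, gap
#'   `-`), in input order.
#' @export
progressive_msa <- function(seqs, submat = blosum62(),
                            gap_open = -10, gap_extend = -1) {
  n <- length(seqs)
  if (n == 0) stop("no sequences")
  if (n == 1) return(seqs)
  if (n == 2) {
    al <- align_global(seqs[[1]], seqs[[2]], submat, gap_open, gap_extend)
    return(stats::setNames(c(al$a_aligned, al$b_aligned), names(seqs)))
  }
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      al <- align_global(seqs[[i]], seqs[[j]], submat, gap_open, gap_extend)
      D[i, j] <- D[j, i] <- 1 - alignment_identity(al$a_aligned, al$b_aligned) / 100
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")  # UPGMA
  profiles <- vector("list", n - 1)  # per merge step
  prof_names <- vector("list", n - 1)
  get_node <- function(k) {
    if (k < 0) {
      list(mat = as_char_matrix(seqs[[-k]]), names = names(seqs)[-k])
    } else {
      list(mat = profiles[[k]], names = prof_names[[k]])
    }
  }
  for (s in seq_len(n - 1)) {
    a <- get_node(hc$merge[s, 1]); b <- get_node(hc$merge[s, 2])
    profiles[[s]] <- align_profiles(a$mat, b$mat, submat, gap_open, gap_extend)
    prof_names[[s]] <- c(a$names, b$names)
  }
  final <- profiles[[n - 1]]
  rows <- apply(final, 1, paste, collapse = "")
  stats::setNames(rows, prof_names[[n - 1]])[names(seqs)]
}

# ---- corrected distances --------------------------------------------

#' Corrected pairwise protein distances from an alignment
#'
#' For each pair of rows, `p` = mismatches over co-ungapped columns
#' (columns where neither row has a gap), corrected to substitutions per
#' site: `kimura` uses `d = -ln(1 - p - p^2/5)`, `poisson` uses
#' `d = -ln(1 - p)`, `p` returns the raw proportion. A `p` outside the
#' correction's domain is capped at `d_max` and flagged in the
#' `"saturated"` attribute. A pair with zero co-ungapped columns is a
#' hard error.
#'
#' @param alignment Named character vector of aligned rows.
#' @param correction `"kimura"` (default), `"poisson"`, or `"p"`.
#' @param d_max Cap for saturated distances (default 10).
#' @return Symmetric numeric matrix (zero diagonal) with row/column
#'   names; attribute `saturated` is a logical matrix marking capped
#'   entries.
#' @export
protein_distance <- function(alignment, correction = c("kimura", "poisson", "p"),
                             d_max = 10) {
  correction <- match.arg(correction)
  if (length(unique(nchar(alignment))) > 1) stop("ragged alignment")
  n <- length(alignment)
  chars <- as_char_matrix(alignment)
  D <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      co <- chars[i, ] != "-" & chars[j, ] != "-"
      if (!any(co)) {
        stop("no co-ungapped columns for pair ", names(alignment)[i],
             " / ", names(alignment)[j])
      }
      p <- sum(chars[i, co] != chars[j, co]) / sum(co)
      arg <- switch(correction,
                    kimura = 1 - p - p^2 / 5,
                    poisson = 1 - p,
                    p = NA)
      if (correction == "p") {
        d <- p
      } else if (arg <= 0) {
        d <- d_max; sat[i, j] <- sat[j, i] <- TRUE
      } else {
        d <- -log(arg)
        if (d > d_max) { d <- d_max; sat[i, j] <- sat[j, i] <- TRUE }
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  attr(D, "saturated") <- sat
  D
}

# ---- neighbor joining -----------------------------------------------

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing
#' the Q criterion is joined (ties broken by the smallest row index,
#' then column index), branch lengths follow the usual three-point
#' formulas, and negative branch lengths are clamped to zero with the
#' deficit transferred to the sister branch. Requires n >= 3; the result
#' is unrooted (trifurcating root node).
#'
#' @param D Symmetric distance matrix with row/column names.
#' @return An [ape::read.tree()] `phylo` object with branch lengths.
#' @export
neighbor_joining <- function(D) {
  n <- nrow(D)
  if (n < 3) stop("neighbor joining requires at least 3 taxa")
  stopifnot(!is.null(rownames(D)), isTRUE(all.equal(D, t(D), check.attributes = FALSE)))
  labels <- rownames(D)
  # active node newick fragments
  frag <- labels
  d <- D
  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  fmt <- function(x) formatC(x, digits = 12, format = "g")
  while (nrow(d) > 3) {
    m <- nrow(d)
    rs <- rowSums(d)
    Q <- (m - 2) * d - outer(rs, rs, "+")
    diag(Q) <- Inf
    # tie-break: smallest (i, j) with i < j in current index order
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        if (Q[i, j] < bestq - 1e-12) { bestq <- Q[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    ll <- clamp_pair(li, lj)
    newfrag <- paste0("(", frag[i], ":", fmt(ll[1]), ",",
                      frag[j], ":", fmt(ll[2]), ")")
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    d <- d2
  }
  # final three-point attachment
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ls <- pmax(c(l1, l2, l3), 0)
  nwk <- paste0("(", frag[1], ":", fmt(ls[1]), ",", frag[2], ":", fmt(ls[2]),
                ",", frag[3], ":", fmt(ls[3]), ");")
  ape::read.tree(text = nwk)
}

#' Is a taxon set monophyletic on an unrooted tree?
#'
#' Tests whether some edge bipartition of the (unrooted) tree separates
#' exactly `taxa` from the rest; by bipartition symmetry the complement
#' of a clade is also monophyletic.
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of tip labels.
#' @return `TRUE` or `FALSE`.
#' @export
clade_check <- function(tree, taxa) {
  tips <- tree$tip.label
  unknown <- setdiff(taxa, tips)
  if (length(unknown) > 0) {
    stop("unknown taxon/taxa: ", paste(unknown, collapse = ", "))
  }
  target <- sort(unique(taxa))
  if (length(target) %in% c(0L, length(tips))) return(TRUE)
  n <- length(tips)
  # descendant tip sets of every internal node
  desc <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    out <- character(0)
    for (k in kids) {
      out <- c(out, if (k <= n) tips[k] else desc(k))
    }
    out
  }
  internal <- unique(tree$edge[, 1])
  for (node in internal) {
    s <- sort(desc(node))
    if (identical(s, target) || identical(sort(setdiff(tips, s)), target)) {
      return(TRUE)
    }
  }
  # single-tip bipartitions
  length(target) == 1 || length(target) == n - 1
}

#' Build an SBP-domain phylogeny for family members
#'
#' Extracts each member's domain sequence, aligns all domains with
#' [progressive_msa()], computes corrected distances and returns the
#' neighbor-joining tree plus intermediates.
#'
#' @param members Family-member tibble (needs `gene_id`,
#'   `transcript_id`, `domain_start`, `domain_end`).
#' @param transcripts,genome Annotation context.
#' @param correction Distance correction (see [protein_distance()]).
#' @return List with `alignment` (named rows), `distances` (matrix) and
#'   `tree` (`phylo`).
#' @export
domain_phylogeny <- function(members, transcripts, genome,
                             correction = "kimura") {
  doms <- vapply(seq_len(nrow(members)), function(i) {
    tx <- transcripts[transcripts$transcript_id == members$transcript_id[i], ]
    prot <- translate_cds(cds_sequence(tx, genome))
    substring(prot, members$domain_start[i] + 1L, members$domain_end[i])
  }, character(1))
  names(doms) <- members$gene_id
  aln <- progressive_msa(doms)
  D <- protein_distance(aln, correction = correction)
  list(alignment = aln, distances = D, tree = neighbor_joining(D))
}
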