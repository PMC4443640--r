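# Affine-gap pairwise alignment (Gotoh three-state DP).
#
# Gap scoring: a gap of length k scores gap_open + k * gap_extend
# (defaults -10, -1 in half-bit units, matching the BLOSUM62 scale).
# Traceback ties are resolved deterministically: diagonal > up > left.

#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 scores (half-bits) as shipped with Biostrings.
#'
#' @return A numeric matrix with amino-acid row/column names.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

check_protein <- function(x, submat) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- setdiff(ch, rownames(submat))
  if (length(bad) > 0) {
    stop("character(s) not in substitution matrix: ", paste(bad, collapse = ", "))
  }
  ch
}

NEG_INF <- -1e12

affine_dp <- function(a, b, submat, gap_open, gap_extend, local = FALSE) {
  ca <- check_protein(a, submat)
  cb <- check_protein(b, submat)
  n <- length(ca); m <- length(cb)
  S <- submat[ca, cb, drop = FALSE]

  M <- matrix(NEG_INF, n + 1, m + 1)  # a[i] aligned to b[j]
  X <- matrix(NEG_INF, n + 1, m + 1)  # gap in b (vertical, consume a)
  Y <- matrix(NEG_INF, n + 1, m + 1)  # gap in a (horizontal, consume b)
  M[1, 1] <- 0
  if (!local) {
    for (i in 2:(n + 1)) X[i, 1] <- gap_open + (i - 1) * gap_extend
    for (j in 2:(m + 1)) Y[1, j] <- gap_open + (j - 1) * gap_extend
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }

  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      best_prev <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      M[i, j] <- best_prev + S[i - 1, j - 1]
      if (local && M[i, j] < 0) M[i, j] <- 0
      X[i, j] <- max(max(M[i - 1, j], Y[i - 1, j]) + gap_open + gap_extend,
                     X[i - 1, j] + gap_extend)
      Y[i, j] <- max(max(M[i, j - 1], X[i, j - 1]) + gap_open + gap_extend,
                     Y[i, j - 1] + gap_extend)
    }
  }
  list(M = M, X = X, Y = Y, ca = ca, cb = cb, S = S)
}

traceback_global <- function(dp, gap_open, gap_extend) {
  M <- dp$M; X <- dp$X; Y <- dp$Y; S <- dp$S
  eps <- 1e-9
  i <- nrow(M); j <- ncol(M)
  a_al <- character(0); b_al <- character(0)
  sc <- c(M[i, j], X[i, j], Y[i, j])
  state <- which(sc >= max(sc) - eps)[1]  # tie order: diagonal > up > left
  while (i > 1 || j > 1) {
    if (i == 1) state <- 3L
    if (j == 1) state <- 2L
    if (state == 1L) {
      a_al <- c(dp$ca[i - 1], a_al); b_al <- c(dp$cb[j - 1], b_al)
      tgt <- M[i, j] - S[i - 1, j - 1]
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which(abs(prev - tgt) < eps)[1]
      i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      a_al <- c(dp$ca[i - 1], a_al); b_al <- c("-", b_al)
      if (abs(X[i, j] - (X[i - 1, j] + gap_extend)) < eps &&
          !(i - 1 == 1 && j == 1)) {
        state <- 2L
      } else {
        state <- if (M[i - 1, j] >= Y[i - 1, j] - eps) 1L else 3L
      }
      i <- i - 1
    } else {
      a_al <- c("-", a_al); b_al <- c(dp$cb[j - 1], b_al)
      if (abs(Y[i, j] - (Y[i, j - 1] + gap_extend)) < eps &&
          !(i == 1 && j - 1 == 1)) {
        state <- 3L
      } else {
        state <- if (M[i, j - 1] >= X[i, j - 1] - eps) 1L else 2L
      }
      j <- j - 1
    }
  }
  list(a = paste(a_al, collapse = ""), b = paste(b_al, collapse = ""))
}

#' Global pairwise protein alignment (Needleman-Wunsch, affine gaps)
#'
#' @param a,b Protein strings.
#' @param submat Substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend Gap penalties; a gap of length k scores
#'   `gap_open + k * gap_extend`.
#' @return A list with `a_aligned`, `b_aligned`, `score`.
#' @export
align_global <- function(a, b, submat = blosum62(),
                         gap_open = -10, gap_extend = -1) {
  dp <- affine_dp(a, b, submat, gap_open, gap_extend, local = FALSE)
  n <- nchar(a) + 1L; m <- nchar(b) + 1L
  score <- max(dp$M[n, m], dp$X[n, m], dp$Y[n, m])
  tb <- traceback_global(dp, gap_open, gap_extend)
  list(a_aligned = tb$a, b_aligned = tb$b, score = score)
}

#' Local pairwise protein alignment (Smith-Waterman, affine gaps)
#'
#' @inheritParams align_global
#' @return A list with `a_aligned`, `b_aligned`, `score`, `identity`
#'   (percent identical over alignment columns) and `length` (alignment
#'   columns).
#' @export
align_local <- function(a, b, submat = blosum62(),
                        gap_open = -10, gap_extend = -1) {
  dp <- affine_dp(a, b, submat, gap_open, gap_extend, local = TRUE)
  best <- which(dp$M == max(dp$M), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  score <- dp$M[best[1], best[2]]
  if (score <= 0) {
    return(list(a_aligned = "", b_aligned = "", score = 0,
                identity = 0, length = 0L))
  }
  tb <- traceback_local(dp, best[1], best[2], gap_open, gap_extend)
  ident <- alignment_identity(tb$a, tb$b)
  list(a_aligned = tb$a, b_aligned = tb$b, score = score,
       identity = ident, length = nchar(tb$a))
}

# Dedicated local traceback: follow best-scoring states back until an M
# cell with value 0 is reached.
traceback_local <- function(dp, i, j, gap_open, gap_extend) {
  M <- dp$M; X <- dp$X; Y <- dp$Y; S <- dp$S
  eps <- 1e-9
  a_al <- character(0); b_al <- character(0)
  state <- 1L
  repeat {
    if (state == 1L) {
      if (M[i, j] < eps) break
      a_al <- c(dp$ca[i - 1], a_al); b_al <- c(dp$cb[j - 1], b_al)
      tgt <- M[i, j] - S[i - 1, j - 1]
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      i <- i - 1; j <- j - 1
      if (abs(prev[1] - tgt) < eps) state <- 1L
      else if (abs(prev[2] - tgt) < eps) state <- 2L
      else if (abs(prev[3] - tgt) < eps) state <- 3L
      else break  # started from an implicit 0 (local start)
    } else if (state == 2L) {
      a_al <- c(dp$ca[i - 1], a_al); b_al <- c("-", b_al)
      open_val <- max(M[i - 1, j], Y[i - 1, j]) + gap_open + gap_extend
      if (abs(X[i, j] - open_val) < eps &&
          abs(M[i - 1, j] - max(M[i - 1, j], Y[i - 1, j])) < eps) state <- 1L
      else if (abs(X[i, j] - (X[i - 1, j] + gap_extend)) < eps) state <- 2L
      else state <- 3L
      i <- i - 1
    } else {
      a_al <- c("-", a_al); b_al <- c(dp$cb[j - 1], b_al)
      open_val <- max(M[i, j - 1], X[i, j - 1]) + gap_open + gap_extend
      if (abs(Y[i, j] - open_val) < eps &&
          abs(M[i, j - 1] - max(M[i, j - 1], X[i, j - 1])) < eps) state <- 1L
      else if (abs(Y[i, j] - (Y[i, j - 1] + gap_extend)) < eps) state <- 3L
      else state <- 2L
      j <- j - 1
    }
  }
  list(a = paste(a_al, collapse = ""), b = paste(b_al, collapse = ""))
}

#' Percent identity of an aligned pair
#'
#' Identical residues divided by total alignment columns (gaps count as
#' columns), times 100.
#'
#' @param a,b Aligned strings of equal length.
#' @return Percent identity in `[0, 100]`.
#' @export
alignment_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0) return(0)
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  100 * sum(ca == cb & ca != "-") / length(ca)
}
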