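# miR156 binding-site scanning under a positional mismatch rule.
#
# A transcript window is an accepted binding site when its mismatches to
# the binding signature (the reverse complement of the mature miRNA)
# number at most `max_mismatches` AND every mismatch falls at an allowed
# position. Positions are counted 1-based along the mature miRNA from its
# 5' end by default, which corresponds to the 3' end of the
# transcript-sense site; the convention is configurable because figure
# legends rarely state it.

#' Mismatch rule for binding-site acceptance
#'
#' @param max_mismatches Maximum number of mismatches (default 2).
#' @param allowed_positions Positions (1-based) where mismatches are
#'   tolerated; default `c(1, 7, 9)`.
#' @param wobble_counts_as_match Should G:U wobble pairs count as matches
#'   (default `FALSE`: a wobble is a mismatch)?
#' @param position_origin `"mirna5p"` (count along the mature miRNA from
#'   its 5' end; default) or `"site5p"` (count along the transcript-sense
#'   site from its 5' end).
#' @return A list of class `mismatch_rule`.
#' @export
mismatch_rule <- function(max_mismatches = 2L,
                          allowed_positions = c(1L, 7L, 9L),
                          wobble_counts_as_match = FALSE,
                          position_origin = c("mirna5p", "site5p")) {
  position_origin <- match.arg(position_origin)
  stopifnot(max_mismatches >= 0, all(allowed_positions >= 1))
  if (max_mismatches > length(allowed_positions)) {
    stop("max_mismatches exceeds the number of allowed positions")
  }
  structure(list(max_mismatches = as.integer(max_mismatches),
                 allowed_positions = sort(as.integer(allowed_positions)),
                 wobble_counts_as_match = wobble_counts_as_match,
                 position_origin = position_origin),
            class = "mismatch_rule")
}

#' Transcript-sense binding signature of a mature miRNA
#'
#' The reverse complement of the (U-to-T normalized) mature sequence:
#' the transcript subsequence a perfect miRNA:mRNA duplex would occupy.
#'
#' @param mirna Mature miRNA sequence (RNA or DNA alphabet).
#' @return DNA string of the same length.
#' @export
binding_signature <- function(mirna) {
  s <- normalize_nucleotides(mirna)
  if (grepl("N", s, fixed = TRUE)) stop("miRNA sequence contains N")
  reverse_complement(s)
}

#' The canonical mature miR156 sequence
#'
#' The 20-nt mature miR156 conserved across plants (and validated in
#' Citrus), U-to-T normalized.
#'
#' @return A 20-character DNA string.
#' @export
mir156_sequence <- function() "TGACAGAAGAGAGTGAGCAC"

# Mismatch profile of every window of width L against the signature.
# Returns a list with per-window mismatch counts restricted by rule.
window_mismatches <- function(seq_chars, sig_chars, wobble_ok) {
  L <- length(sig_chars)
  n <- length(seq_chars)
  n_win <- n - L + 1L
  if (n_win < 1) return(NULL)
  mm <- matrix(FALSE, nrow = n_win, ncol = L)
  has_n <- logical(n_win)
  for (j in seq_len(L)) {
    w <- seq_chars[j:(j + n_win - 1L)]
    ne <- w != sig_chars[j]
    if (wobble_ok) {
      # miRNA G : site T  <=> signature C vs window T
      # miRNA U : site G  <=> signature A vs window G
      wob <- (sig_chars[j] == "C" & w == "T") | (sig_chars[j] == "A" & w == "G")
      ne <- ne & !wob
    }
    mm[, j] <- ne
    has_n <- has_n | w == "N"
  }
  list(mm = mm, has_n = has_n)
}

#' Find miRNA binding sites on spliced transcripts
#'
#' Reports every window (length = miRNA length) of each transcript whose
#' mismatches to the binding signature number at most
#' `rule$max_mismatches` and all fall at `rule$allowed_positions`.
#' Windows containing `N` never match. Sites are sorted by transcript
#' and start coordinate.
#'
#' @param transcript_seqs Named character vector of spliced transcript
#'   sequences (mRNA sense).
#' @param mirna Mature miRNA sequence.
#' @param rule A [mismatch_rule()].
#' @return Tibble with columns `transcript_id`, `start`, `end` (0-based
#'   half-open transcript coordinates), `n_mismatch`,
#'   `mismatch_positions` (comma-joined, in the rule's numbering; empty
#'   string for a perfect site).
#' @export
find_target_sites <- function(transcript_seqs, mirna,
                              rule = mismatch_rule()) {
  stopifnot(inherits(rule, "mismatch_rule"))
  sig <- binding_signature(mirna)
  L <- nchar(sig)
  if (any(rule$allowed_positions > L)) {
    stop("allowed position beyond miRNA length")
  }
  sig_chars <- strsplit(sig, "", fixed = TRUE)[[1]]
  # column j of the window corresponds to miRNA position L - j + 1
  pos_of_col <- if (rule$position_origin == "mirna5p") rev(seq_len(L)) else seq_len(L)
  allowed_cols <- which(pos_of_col %in% rule$allowed_positions)

  rows <- purrr::imap(transcript_seqs, function(s, tid) {
    s <- normalize_nucleotides(s)
    wm <- window_mismatches(strsplit(s, "", fixed = TRUE)[[1]], sig_chars,
                            rule$wobble_counts_as_match)
    if (is.null(wm)) return(NULL)
    n_mm <- rowSums(wm$mm)
    n_allowed <- rowSums(wm$mm[, allowed_cols, drop = FALSE])
    ok <- !wm$has_n & n_mm <= rule$max_mismatches & n_mm == n_allowed
    if (!any(ok)) return(NULL)
    starts <- which(ok) - 1L
    mmpos <- vapply(which(ok), function(i) {
      p <- sort(pos_of_col[which(wm$mm[i, ])])
      paste(p, collapse = ",")
    }, character(1))
    tibble::tibble(transcript_id = tid, start = starts, end = starts + L,
                   n_mismatch = as.integer(n_mm[ok]),
                   mismatch_positions = mmpos)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(transcript_id = character(), start = integer(),
                          end = integer(), n_mismatch = integer(),
                          mismatch_positions = character()))
  }
  dplyr::arrange(out, .data$transcript_id, .data$start)
}

#' Locate sites in the transcript's region partition
#'
#' Labels each site with the unique region (`FIVE_UTR`, `CDS`,
#' `THREE_UTR`, `NONCODING`) containing it entirely; a site crossing a
#' region boundary is labelled `SPANNING` and the region containing the
#' site midpoint is recorded in `secondary_region`.
#'
#' @param sites Tibble from [find_target_sites()].
#' @param partitions Tibble from [region_partition()].
#' @return `sites` with added columns `region` and `secondary_region`.
#' @export
locate_site <- function(sites, partitions) {
  if (nrow(sites) == 0) {
    return(dplyr::mutate(sites, region = character(0),
                         secondary_region = character(0)))
  }
  region_of <- function(tid, s, e) {
    part <- partitions[partitions$transcript_id == tid, , drop = FALSE]
    if (nrow(part) == 0) stop("no partition for transcript ", tid)
    L <- max(part$end)
    if (s < 0 || e > L) {
      stop("site [", s, ",", e, ") out of bounds for transcript ", tid)
    }
    whole <- part$region[part$start <= s & part$end >= e]
    if (length(whole) >= 1) return(c(whole[1], NA_character_))
    mid <- s + (e - s) %/% 2L
    mid_reg <- part$region[part$start <= mid & part$end > mid][1]
    c("SPANNING", mid_reg)
  }
  labs <- t(mapply(region_of, sites$transcript_id, sites$start, sites$end))
  sites$region <- unname(labs[, 1])
  sites$secondary_region <- unname(labs[, 2])
  sites
}

#' Scan annotated transcripts and locate sites
#'
#' Convenience wrapper: extracts spliced sequences, scans them with
#' [find_target_sites()], and annotates regions with [locate_site()].
#'
#' @param transcripts Transcript-model tibble.
#' @param genome Named character vector of chromosomes.
#' @param mirna Mature miRNA sequence (default [mir156_sequence()]).
#' @param rule A [mismatch_rule()].
#' @return Sites tibble with region labels.
#' @export
scan_transcripts <- function(transcripts, genome,
                             mirna = mir156_sequence(),
                             rule = mismatch_rule()) {
  seqs <- spliced_sequence(transcripts, genome)
  seqs <- seqs[nchar(seqs) >= nchar(mirna)]
  sites <- find_target_sites(seqs, mirna, rule)
  locate_site(sites, region_partition(
    transcripts[transcripts$transcript_id %in% names(seqs), , drop = FALSE]))
}

#' Project transcript-coordinate sites to genome coordinates (BED6)
#'
#' Each site becomes one BED line per contiguous genomic block (a site
#' crossing an intron yields several lines sharing a name). Scores hold
#' the mismatch count.
#'
#' @param sites Sites tibble.
#' @param transcripts Transcript-model tibble.
#' @param name Feature name prefix (default "miR156_site").
#' @return Tibble with BED6 columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
sites_to_bed <- function(sites, transcripts, name = "miR156_site") {
  rows <- purrr::map(seq_len(nrow(sites)), function(i) {
    tx <- transcripts[transcripts$transcript_id == sites$transcript_id[i], ]
    if (nrow(tx) == 0) stop("transcript not in annotation: ", sites$transcript_id[i])
    ex <- tx$exons[[1]]
    strand <- tx$strand[1]
    ex_len <- ex$end - ex$start
    tx_len <- sum(ex_len)
    s <- sites$start[i]; e <- sites$end[i]
    if (strand == "-") { tmp <- tx_len - e; e <- tx_len - s; s <- tmp }
    cum <- cumsum(c(0L, ex_len))
    blocks <- list()
    for (k in seq_len(nrow(ex))) {
      bs <- max(s, cum[k]); be <- min(e, cum[k + 1])
      if (bs < be) {
        blocks[[length(blocks) + 1]] <- c(ex$start[k] + (bs - cum[k]),
                                          ex$start[k] + (be - cum[k]))
      }
    }
    m <- do.call(rbind, blocks)
    tibble::tibble(chrom = tx$seqid[1], start = m[, 1], end = m[, 2],
                   name = paste0(name, "_", sites$transcript_id[i], "_", sites$start[i]),
                   score = sites$n_mismatch[i], strand = strand)
  })
  dplyr::bind_rows(rows)
}

#' Enumerate all distinct site variants accepted by a rule
#'
#' Exhaustively counts the 20-mers (or L-mers) within Hamming reach of a
#' signature that the rule accepts: mismatch subsets of the allowed
#' positions up to `max_mismatches`, three alternative bases each.
#' Useful for rule sanity checks; with the defaults (2 mismatches at
#' positions 1, 7, 9) the count is 37.
#'
#' @param mirna Mature miRNA sequence.
#' @param rule A [mismatch_rule()].
#' @return Character vector of accepted site sequences (including the
#'   perfect match).
#' @export
enumerate_accepted_sites <- function(mirna, rule = mismatch_rule()) {
  sig <- binding_signature(mirna)
  L <- nchar(sig)
  sig_chars <- strsplit(sig, "", fixed = TRUE)[[1]]
  pos_of_col <- if (rule$position_origin == "mirna5p") rev(seq_len(L)) else seq_len(L)
  cols_allowed <- which(pos_of_col %in% rule$allowed_positions)
  bases <- c("A", "C", "G", "T")
  out <- paste(sig_chars, collapse = "")
  for (k in seq_len(rule$max_mismatches)) {
    combs <- utils::combn(cols_allowed, k, simplify = FALSE)
    for (cc in combs) {
      alt <- lapply(cc, function(j) setdiff(bases, sig_chars[j]))
      grid <- expand.grid(alt, stringsAsFactors = FALSE)
      for (g in seq_len(nrow(grid))) {
        v <- sig_chars
        v[cc] <- unlist(grid[g, ])
        out <- c(out, paste(v, collapse = ""))
      }
    }
  }
  variants <- unique(out)
  if (rule$wobble_counts_as_match) {
    # wobble variants at non-allowed positions are also accepted; fold in
    stop("enumeration with wobble_counts_as_match not supported")
  }
  variants
}
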