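# Profile-based mining of SBP-domain proteins.
#
# The family search is a position-specific scoring matrix built from a
# seed alignment of reference SBP domains, scanned over every annotated
# protein, with candidate hits confirmed by Smith-Waterman identity to
# the unaligned reference domains and collapsed to one representative
# transcript per locus.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

#' Read an aligned protein FASTA
#'
#' @param path Path to an aligned FASTA (gap character `-`).
#' @return Named character vector of equal-length aligned rows.
#' @export
read_alignment_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  rows <- stats::setNames(toupper(as.character(set)), sub("\\s.*$", "", names(set)))
  if (length(unique(nchar(rows))) > 1) {
    stop("ragged alignment: rows have unequal lengths")
  }
  rows
}

#' Build a log-odds profile from a seed alignment
#'
#' Converts an aligned set of domain sequences into a position-specific
#' scoring matrix. Per column, residue frequencies get a Laplace
#' pseudocount (`pseudocount` added per residue) and are scored as
#' log-odds against the background in half-bits
#' (`2 * log2(freq / background)`). Columns with more than 50% gaps are
#' dropped, so the profile width can be smaller than the alignment width.
#'
#' @param seed Named character vector of aligned rows (from
#'   [read_alignment_fasta()]), at least 2 sequences.
#' @param pseudocount Pseudocount weight added per residue per column
#'   (default 1).
#' @param background Named numeric vector of residue background
#'   frequencies over the 20 amino acids; default uniform (1/20).
#' @return An object of class `spl_profile`: list with `scores`
#'   (20 x width matrix, half-bits), `width`, `max_score`, `consensus`,
#'   `background`, `pseudocount`.
#' @export
build_profile <- function(seed, pseudocount = 1, background = NULL) {
  if (length(seed) < 2) stop("need at least 2 seed sequences")
  if (length(unique(nchar(seed))) > 1) stop("ragged alignment: rows have unequal lengths")
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA20)
  }
  chars <- do.call(rbind, strsplit(seed, "", fixed = TRUE))
  gap_frac <- colMeans(chars == "-")
  keep <- which(gap_frac <= 0.5)
  if (length(keep) == 0) stop("all columns are majority-gap")
  scores <- vapply(keep, function(j) {
    col <- chars[, j]
    col <- col[col != "-"]
    counts <- table(factor(col, levels = AA20))
    freq <- (as.numeric(counts) + pseudocount / 1) /
      (length(col) + 20 * pseudocount)
    2 * log2(freq / background[AA20])
  }, numeric(20))
  rownames(scores) <- AA20
  consensus <- paste(AA20[apply(scores, 2, which.max)], collapse = "")
  structure(list(scores = scores, width = length(keep),
                 max_score = sum(apply(scores, 2, max)),
                 consensus = consensus,
                 background = background, pseudocount = pseudocount),
            class = "spl_profile")
}

#' @export
print.spl_profile <- function(x, ...) {
  cat("<spl_profile> width", x$width, "max score",
      round(x$max_score, 1), "half-bits\n")
  invisible(x)
}

score_windows <- function(profile, protein) {
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  w <- profile$width
  n <- length(ch)
  if (n < w) return(numeric(0))
  idx <- match(ch, AA20)  # non-standard residues contribute 0 (background odds)
  contrib <- matrix(0, nrow = n, ncol = w)
  for (j in seq_len(w)) {
    known <- !is.na(idx)
    contrib[known, j] <- profile$scores[idx[known], j]
  }
  vapply(seq_len(n - w + 1L), function(s) {
    sum(contrib[cbind(s:(s + w - 1L), seq_len(w))])
  }, numeric(1))
}

#' Scan a protein for domain hits
#'
#' Slides the profile over the protein and reports the best-scoring
#' window plus any further non-overlapping windows, keeping only windows
#' whose `fraction_of_max` (score divided by the profile's maximum
#' attainable score) reaches `min_fraction`. A protein shorter than the
#' profile yields an empty result (with a message), not an error.
#'
#' @param profile An `spl_profile`.
#' @param proteins Named character vector of protein sequences.
#' @param min_fraction Minimum score as a fraction of the maximum
#'   attainable profile score (default 0.6).
#' @return Tibble with columns `protein_id`, `start`, `end` (0-based
#'   half-open protein coordinates), `score`, `fraction_of_max`.
#' @export
scan_protein <- function(profile, proteins, min_fraction = 0.6) {
  stopifnot(inherits(profile, "spl_profile"))
  rows <- purrr::imap(proteins, function(p, id) {
    sc <- score_windows(profile, p)
    if (length(sc) == 0) {
      message("protein ", id, " shorter than profile width; skipped")
      return(NULL)
    }
    frac <- sc / profile$max_score
    cand <- order(sc, decreasing = TRUE)
    cand <- cand[frac[cand] >= min_fraction]
    taken <- logical(length(sc))
    keep <- integer(0)
    for (s in cand) {
      span <- s:(s + profile$width - 1L)
      span <- span[span <= length(taken)]
      if (!any(taken[span])) {
        keep <- c(keep, s)
        taken[span] <- TRUE
      }
    }
    if (length(keep) == 0) return(NULL)
    keep <- sort(keep)
    tibble::tibble(protein_id = id, start = keep - 1L,
                   end = keep - 1L + profile$width,
                   score = sc[keep], fraction_of_max = frac[keep])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(protein_id = character(), start = integer(),
                          end = integer(), score = numeric(),
                          fraction_of_max = numeric())
  }
  out
}

#' Confirm candidate hits against reference domains
#'
#' Keeps a hit iff its best Smith-Waterman local-alignment identity to
#' any reference domain reaches `min_identity` percent over at least
#' `min_columns` alignment columns.
#'
#' @param hits Tibble from [scan_protein()].
#' @param proteins Named character vector the hits refer to.
#' @param references Named character vector of unaligned reference domain
#'   sequences.
#' @param min_identity Identity cutoff in percent (default 40).
#' @param min_columns Minimum alignment columns (default 60).
#' @return `hits` filtered, with added columns `best_reference`,
#'   `best_identity`.
#' @export
confirm_candidates <- function(hits, proteins, references,
                               min_identity = 40, min_columns = 60) {
  if (length(references) == 0) stop("empty reference domain set")
  if (nrow(hits) == 0) {
    return(dplyr::mutate(hits, best_reference = character(0),
                         best_identity = numeric(0)))
  }
  res <- purrr::map(seq_len(nrow(hits)), function(i) {
    sub <- substring(proteins[[hits$protein_id[i]]],
                     hits$start[i] + 1L, hits$end[i])
    best_id <- -Inf; best_ref <- NA_character_
    for (r in names(references)) {
      al <- align_local(sub, references[[r]])
      if (al$length >= min_columns && al$identity > best_id) {
        best_id <- al$identity; best_ref <- r
      }
    }
    list(ref = best_ref, id = best_id)
  })
  hits$best_reference <- vapply(res, `[[`, character(1), "ref")
  hits$best_identity <- vapply(res, `[[`, numeric(1), "id")
  dplyr::filter(hits, is.finite(.data$best_identity),
                .data$best_identity >= min_identity)
}

#' Collapse hits to one family member per locus
#'
#' Maps each confirmed hit to its gene through the annotation and keeps
#' exactly one representative transcript per gene: longest CDS, ties
#' broken by longest spliced transcript, then by lexicographically
#' smallest transcript id. Hits on transcripts absent from the
#' annotation are dropped with a warning.
#'
#' @param hits Confirmed hits tibble (protein ids = transcript ids).
#' @param transcripts Transcript-model tibble.
#' @return Tibble of family members: `gene_id`, `transcript_id`,
#'   `protein_length`, `domain_start`, `domain_end`, `score`,
#'   `fraction_of_max`, `best_identity`.
#' @export
collapse_loci <- function(hits, transcripts) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(gene_id = character(), transcript_id = character(),
                          protein_length = integer(), domain_start = integer(),
                          domain_end = integer(), score = numeric(),
                          fraction_of_max = numeric(), best_identity = numeric()))
  }
  tx_info <- transcripts |>
    dplyr::mutate(
      cds_len = purrr::map_int(.data$cds, ~ sum(.x$end - .x$start)),
      spliced_len = purrr::map_int(.data$exons, ~ sum(.x$end - .x$start))
    ) |>
    dplyr::select("transcript_id", "gene_id", "cds_len", "spliced_len")

  unknown <- setdiff(hits$protein_id, tx_info$transcript_id)
  if (length(unknown) > 0) {
    warning("hit(s) on transcript(s) missing from annotation excluded: ",
            paste(unknown, collapse = ", "))
  }
  # strongest hit per transcript, then representative transcript per gene
  per_tx <- hits |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::inner_join(tx_info, by = c(protein_id = "transcript_id"))

  per_tx |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(dplyr::desc(.data$cds_len), dplyr::desc(.data$spliced_len),
                   .data$protein_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      gene_id = .data$gene_id,
      transcript_id = .data$protein_id,
      protein_length = .data$cds_len %/% 3L - 1L,
      domain_start = .data$start,
      domain_end = .data$end,
      score = .data$score,
      fraction_of_max = .data$fraction_of_max,
      best_identity = .data$best_identity
    ) |>
    dplyr::arrange(.data$gene_id)
}

#' Mine a genome for SBP-domain family members
#'
#' End-to-end family mining: conceptual translation of every annotated
#' CDS, profile scan, local-alignment confirmation, and locus collapse.
#'
#' @param transcripts Transcript-model tibble.
#' @param genome Named character vector of chromosome sequences.
#' @param seed Aligned seed rows (see [build_profile()]).
#' @param min_fraction,min_identity,min_columns,pseudocount Thresholds
#'   passed to the stages.
#' @return Family-member tibble (see [collapse_loci()]).
#' @export
mine_family <- function(transcripts, genome, seed,
                        min_fraction = 0.6, min_identity = 40,
                        min_columns = 60, pseudocount = 1) {
  profile <- build_profile(seed, pseudocount = pseudocount)
  cds <- cds_sequence(transcripts, genome)
  cds <- cds[nchar(cds) > 0]
  proteins <- vapply(cds, translate_cds, character(1))
  hits <- scan_protein(profile, proteins, min_fraction = min_fraction)
  refs <- stats::setNames(gsub("-", "", seed, fixed = TRUE), names(seed))
  confirmed <- confirm_candidates(hits, proteins, refs,
                                  min_identity = min_identity,
                                  min_columns = min_columns)
  collapse_loci(confirmed, transcripts)
}
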