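# Three-way subgroup classification, antisense overlap detection and
# ortholog evidence scoring.
#
# The family splits into: short proteins (< 200 aa) with a binding site
# in the 3'UTR; long proteins (> 300 aa) with the site inside the ORF;
# and members without a site. Boundary lengths (exactly 200 or 300 aa)
# and any other length/region combination are deliberately UNCLASSIFIED:
# the clades are defined by strict inequalities and nothing in between
# is invented.

#' Assign a family subgroup
#'
#' @param protein_length Protein length(s) in amino acids.
#' @param site_region Region label(s) of the member's 5'-most binding
#'   site (`THREE_UTR`, `CDS`, ...), or `NA` for no site.
#' @return Character vector of labels: `SHORT_3UTR`, `LONG_ORF`,
#'   `NO_SITE`, `UNCLASSIFIED`.
#' @export
assign_subgroup <- function(protein_length, site_region) {
  stopifnot(all(protein_length > 0))
  n <- max(length(protein_length), length(site_region))
  protein_length <- rep_len(protein_length, n)
  site_region <- rep_len(as.character(site_region), n)
  dplyr::case_when(
    is.na(site_region) ~ "NO_SITE",
    protein_length < 200 & site_region == "THREE_UTR" ~ "SHORT_3UTR",
    protein_length > 300 & site_region == "CDS" ~ "LONG_ORF",
    TRUE ~ "UNCLASSIFIED"
  )
}

#' Classify family members from mining and scanning output
#'
#' Joins family members with their binding sites (a member's summary
#' site is the 5'-most site on its representative transcript) and
#' assigns subgroups.
#'
#' @param members Family-member tibble from [mine_family()].
#' @param sites Located sites tibble from [scan_transcripts()].
#' @return Tibble with `gene_id`, `transcript_id`, `protein_length`,
#'   `site_region` (`NA` if none), `site_start`, `n_mismatch`,
#'   `mismatch_positions`, `subgroup`.
#' @export
classify_members <- function(members, sites) {
  first_site <- sites |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::slice_min(.data$start, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("transcript_id", site_start = "start",
                  "n_mismatch", "mismatch_positions", site_region = "region")
  members |>
    dplyr::left_join(first_site, by = "transcript_id") |>
    dplyr::mutate(subgroup = assign_subgroup(.data$protein_length,
                                             .data$site_region)) |>
    dplyr::select("gene_id", "transcript_id", "protein_length",
                  "site_region", "site_start", "n_mismatch",
                  "mismatch_positions", "subgroup")
}

transcript_spans <- function(transcripts) {
  tibble::tibble(
    transcript_id = transcripts$transcript_id,
    gene_id = transcripts$gene_id,
    seqid = transcripts$seqid,
    strand = transcripts$strand,
    start = purrr::map_int(transcripts$exons, ~ min(.x$start)),
    end = purrr::map_int(transcripts$exons, ~ max(.x$end))
  )
}

#' Detect antisense-overlapping transcript pairs
#'
#' Reports every pair of transcripts on the same chromosome and opposite
#' strands whose unspliced genomic spans overlap by at least
#' `min_overlap` bp. `encompasses` is `TRUE` when the span of
#' `transcript_a` fully contains that of `transcript_b` (the containing
#' transcript is always reported as `transcript_a`).
#'
#' @param transcripts Transcript-model tibble.
#' @param min_overlap Minimum genomic overlap in bp (default 1).
#' @return Tibble with `transcript_a`, `transcript_b`, `overlap`,
#'   `encompasses`.
#' @export
detect_antisense_overlaps <- function(transcripts, min_overlap = 1L) {
  sp <- transcript_spans(transcripts)
  gr <- GenomicRanges::GRanges(
    seqnames = sp$seqid,
    ranges = IRanges::IRanges(start = sp$start + 1L, end = sp$end),
    strand = sp$strand
  )
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE,
                                      minoverlap = as.integer(min_overlap))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  keep <- q < s & sp$strand[q] != sp$strand[s]
  q <- q[keep]; s <- s[keep]
  if (length(q) == 0) {
    return(tibble::tibble(transcript_a = character(), transcript_b = character(),
                          overlap = integer(), encompasses = logical()))
  }
  ov <- pmin(sp$end[q], sp$end[s]) - pmax(sp$start[q], sp$start[s])
  a_contains <- sp$start[q] <= sp$start[s] & sp$end[q] >= sp$end[s]
  b_contains <- sp$start[s] <= sp$start[q] & sp$end[s] >= sp$end[q]
  swap <- b_contains & !a_contains
  a <- ifelse(swap, s, q); b <- ifelse(swap, q, s)
  tibble::tibble(
    transcript_a = sp$transcript_id[a],
    transcript_b = sp$transcript_id[b],
    overlap = as.integer(ov),
    encompasses = a_contains | b_contains
  ) |>
    dplyr::arrange(.data$transcript_a, .data$transcript_b)
}

length_class <- function(len) {
  dplyr::case_when(len < 200 ~ "short", len > 300 ~ "long", TRUE ~ "mid")
}

# Protein of the antisense/adjacent neighbor (within `window` bp) of a
# gene, or NA if none exists.
neighbor_protein <- function(gene_id, transcripts, genome, window = 5000L) {
  sp <- transcript_spans(transcripts)
  own <- sp[sp$gene_id == gene_id, , drop = FALSE]
  if (nrow(own) == 0) return(NA_character_)
  g_start <- min(own$start); g_end <- max(own$end)
  cand <- sp[sp$gene_id != gene_id & sp$seqid == own$seqid[1] &
               sp$start < g_end + window & sp$end > g_start - window, , drop = FALSE]
  if (nrow(cand) == 0) return(NA_character_)
  # prefer antisense-overlapping, then nearest
  ov <- pmin(cand$end, g_end) - pmax(cand$start, g_start)
  anti <- cand$strand != own$strand[1]
  ord <- order(-(ov > 0 & anti), -ov)
  for (i in ord) {
    tx <- transcripts[transcripts$transcript_id == cand$transcript_id[i], ]
    cds <- cds_sequence(tx, genome)
    if (nchar(cds) > 0) return(translate_cds(cds))
  }
  NA_character_
}

#' Score ortholog evidence between a query and a reference member
#'
#' Combines four lines of evidence into a composite score in `[0, 1]`:
#' SBP-domain local-alignment identity (as identity/100), protein
#' length-class agreement, binding-site region agreement, and neighbor
#' coupling (both genomes carry an antisense/adjacent neighbor gene
#' within `window` bp whose proteins align at `neighbor_identity`
#' percent or better). The composite is the weighted mean of the
#' available components; if neighbor context is missing in either
#' genome, that component is excluded and the remaining weights
#' renormalized.
#'
#' @param query,ref One-row classified member tibbles (with
#'   `transcript_id`, `protein_length`, `site_region`, `domain_start`,
#'   `domain_end` columns; see [classify_members()] joined back to
#'   [mine_family()] output).
#' @param query_ctx,ref_ctx Lists with elements `transcripts` and
#'   `genome` giving each member's annotation context.
#' @param weights Numeric(4): weights for identity, length class, site
#'   region, neighbor coupling (default equal).
#' @param window Neighbor search window in bp (default 5000).
#' @param neighbor_identity Neighbor protein identity cutoff in percent
#'   (default 50).
#' @return One-row tibble: `query`, `reference`, `domain_identity`,
#'   `length_class_match`, `site_position_match`, `neighbor_coupling`,
#'   `composite`.
#' @export
ortholog_evidence <- function(query, ref, query_ctx, ref_ctx,
                              weights = rep(1, 4), window = 5000L,
                              neighbor_identity = 50) {
  stopifnot(nrow(query) == 1, nrow(ref) == 1, length(weights) == 4)
  dom_seq <- function(m, ctx) {
    prot <- translate_cds(cds_sequence(
      ctx$transcripts[ctx$transcripts$transcript_id == m$transcript_id, ],
      ctx$genome))
    substring(prot, m$domain_start + 1L, m$domain_end)
  }
  dq <- dom_seq(query, query_ctx); dr <- dom_seq(ref, ref_ctx)
  identity <- align_local(dq, dr)$identity
  len_match <- length_class(query$protein_length) == length_class(ref$protein_length)
  site_match <- isTRUE(query$site_region == ref$site_region) ||
    (is.na(query$site_region) && is.na(ref$site_region))

  nq <- neighbor_protein(query$gene_id, query_ctx$transcripts,
                         query_ctx$genome, window)
  nr <- neighbor_protein(ref$gene_id, ref_ctx$transcripts,
                         ref_ctx$genome, window)
  if (is.na(nq) || is.na(nr)) {
    coupling <- NA
    comp_vals <- c(identity / 100, len_match, site_match)
    comp_w <- weights[1:3]
  } else {
    coupling <- align_local(nq, nr)$identity >= neighbor_identity
    comp_vals <- c(identity / 100, len_match, site_match, coupling)
    comp_w <- weights
  }
  tibble::tibble(
    query = query$gene_id, reference = ref$gene_id,
    domain_identity = identity,
    length_class_match = len_match,
    site_position_match = site_match,
    neighbor_coupling = coupling,
    composite = sum(comp_vals * comp_w) / sum(comp_w)
  )
}
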