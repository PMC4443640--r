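#' Read a genome (or transcript set) from FASTA
#'
#' Reads a multi-record FASTA file into a named character vector of
#' nucleotide sequences. Sequences are normalized at the boundary:
#' lowercase is raised to uppercase and `U` becomes `T`, so RNA and DNA
#' inputs flow through the same downstream scanners. Only `A`, `C`, `G`,
#' `T` and `N` survive normalization; any other character is an error.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped records).
#' @return A named character vector, one element per record, in file order.
#' @export
read_genome_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate sequence id(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  seqs <- normalize_nucleotides(as.character(set))
  empty <- ids[nchar(seqs) == 0]
  if (length(empty) > 0) {
    stop("empty sequence for record(s): ", paste(empty, collapse = ", "))
  }
  stats::setNames(seqs, ids)
}

#' Normalize a nucleotide string
#'
#' Uppercases and maps U to T. Errors on characters outside \{A,C,G,T,N\}.
#'
#' @param x Character vector of nucleotide strings.
#' @return Normalized character vector.
#' @export
normalize_nucleotides <- function(x) {
  out <- chartr("acgtunU", "ACGTTNT", x)
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    stop("non-nucleotide character(s) in sequence(s): ",
         paste(which(bad), collapse = ", "))
  }
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read transcript models from a GFF3 annotation
#'
#' Parses gene/mRNA/exon/CDS features (Parent-linked) into a tibble of
#' transcript models, one row per transcript. GFF3 coordinates are 1-based
#' inclusive; internally every interval is 0-based half-open, converted at
#' this boundary. Minus-strand models keep genomic coordinates; spliced
#' order (5' to 3') is derived on demand.
#'
#' Any feature type with exon children is accepted as a transcript.
#' Orphan exons (no Parent) raise a warning and are skipped; a CDS segment
#' falling outside its transcript's exons is a hard error.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `transcript_id`, `gene_id`, `seqid`,
#'   `strand`, and list-columns `exons` and `cds` of two-column data frames
#'   (`start`, `end`; 0-based half-open, sorted by genomic start).
#' @export
read_transcript_models <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble::tibble(
    seqid  = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end    = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type   = as.character(gr$type),
    id     = as.character(gr$ID),
    parent = vapply(as.list(gr$Parent), function(p) {
      if (length(p) == 0) NA_character_ else as.character(p[[1]])
    }, character(1))
  )

  feats <- dplyr::filter(df, .data$type %in% c("exon", "CDS"))
  orphans <- feats$type == "exon" & is.na(feats$parent)
  if (any(orphans)) {
    warning(sum(orphans), " orphan exon(s) without Parent skipped")
    feats <- feats[!orphans, , drop = FALSE]
  }

  parents <- dplyr::filter(df, !.data$type %in% c("exon", "CDS"), !is.na(.data$id))
  gene_of <- stats::setNames(parents$parent, parents$id)
  tx_ids <- unique(feats$parent[feats$type == "exon"])

  rows <- purrr::map(tx_ids, function(tid) {
    ex <- dplyr::filter(feats, .data$parent == tid, .data$type == "exon") |>
      dplyr::arrange(.data$start)
    cd <- dplyr::filter(feats, .data$parent == tid, .data$type == "CDS") |>
      dplyr::arrange(.data$start)
    for (i in seq_len(nrow(cd))) {
      inside <- any(cd$start[i] >= ex$start & cd$end[i] <= ex$end)
      if (!inside) {
        stop("CDS segment [", cd$start[i], ",", cd$end[i],
             ") of transcript ", tid, " lies outside its exons")
      }
    }
    gid <- gene_of[[tid]]
    if (is.null(gid) || is.na(gid)) gid <- tid
    tibble::tibble(
      transcript_id = tid,
      gene_id = gid,
      seqid = ex$seqid[1],
      strand = ex$strand[1],
      exons = list(data.frame(start = ex$start, end = ex$end)),
      cds = list(data.frame(start = cd$start, end = cd$end))
    )
  })
  dplyr::bind_rows(rows)
}

#' Write transcript models to GFF3
#'
#' Inverse of [read_transcript_models()]: emits gene, mRNA, exon and CDS
#' features with Parent attributes, converting back to 1-based inclusive
#' coordinates.
#'
#' @param transcripts Transcript-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(transcripts, path) {
  lines <- c("##gff-version 3")
  genes <- split(transcripts, transcripts$gene_id)
  for (gid in unique(transcripts$gene_id)) {
    g <- genes[[gid]]
    span <- range(unlist(lapply(g$exons, function(e) c(e$start, e$end))))
    lines <- c(lines, sprintf("%s\tsplfam\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$seqid[1], span[1] + 1L, span[2], g$strand[1], gid))
    for (i in seq_len(nrow(g))) {
      tid <- g$transcript_id[i]
      ex <- g$exons[[i]]; cd <- g$cds[[i]]
      lines <- c(lines, sprintf("%s\tsplfam\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                                g$seqid[i], min(ex$start) + 1L, max(ex$end),
                                g$strand[i], tid, gid))
      lines <- c(lines,
        sprintf("%s\tsplfam\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                g$seqid[i], ex$start + 1L, ex$end, g$strand[i], tid))
      if (nrow(cd) > 0) {
        lines <- c(lines,
          sprintf("%s\tsplfam\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                  g$seqid[i], cd$start + 1L, cd$end, g$strand[i], tid))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

reverse_complement <- function(x) {
  vapply(x, function(s) {
    rc <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(rc, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

extract_intervals <- function(chrom_seq, intervals) {
  if (nrow(intervals) == 0) return("")
  paste(substring(chrom_seq, intervals$start + 1L, intervals$end), collapse = "")
}

#' Spliced transcript sequence
#'
#' Concatenates exon sequences in genomic order and, for minus-strand
#' transcripts, reverse-complements so the result always reads 5' to 3'
#' in mRNA sense.
#'
#' @param transcripts Transcript-model tibble (one or more rows).
#' @param genome Named character vector from [read_genome_fasta()].
#' @return Named character vector of spliced sequences (names are
#'   transcript ids).
#' @export
spliced_sequence <- function(transcripts, genome) {
  out <- vapply(seq_len(nrow(transcripts)), function(i) {
    chrom <- genome[[transcripts$seqid[i]]]
    if (is.null(chrom)) stop("chromosome not in genome: ", transcripts$seqid[i])
    ex <- transcripts$exons[[i]]
    if (any(ex$start < 0) || any(ex$end > nchar(chrom))) {
      stop("exon out of chromosome bounds for transcript ",
           transcripts$transcript_id[i])
    }
    s <- extract_intervals(chrom, ex)
    if (transcripts$strand[i] == "-") s <- reverse_complement(s) else s
  }, character(1))
  stats::setNames(out, transcripts$transcript_id)
}

# Map a genomic position set (list of intervals) into spliced transcript
# coordinates. Returns a single [start, end) interval per contiguous block
# in transcript space.
genomic_to_transcript <- function(intervals, exons, strand) {
  ex_len <- exons$end - exons$start
  cum <- cumsum(c(0L, ex_len))
  tx_len <- sum(ex_len)
  blocks <- lapply(seq_len(nrow(intervals)), function(i) {
    s <- intervals$start[i]; e <- intervals$end[i]
    hit <- which(s >= exons$start & e <= exons$end)
    if (length(hit) == 0) stop("interval not contained in a single exon")
    k <- hit[1]
    c(cum[k] + (s - exons$start[k]), cum[k] + (e - exons$start[k]))
  })
  m <- do.call(rbind, blocks)
  if (strand == "-") m <- cbind(tx_len - m[, 2], tx_len - m[, 1])
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(start = m[, 1], end = m[, 2])
}

#' Partition a transcript into 5'UTR / CDS / 3'UTR
#'
#' Computes the region partition of each spliced transcript in transcript
#' coordinates (0-based half-open on the 5'-to-3' mRNA). On the minus
#' strand the 5'UTR is the genomically rightmost non-coding part. A
#' transcript without CDS yields a single `NONCODING` region. A CDS whose
#' length is not a multiple of 3 is flagged (`frame_warning = TRUE`), not
#' an error.
#'
#' @param transcripts Transcript-model tibble.
#' @return Tibble with columns `transcript_id`, `region` (`FIVE_UTR`,
#'   `CDS`, `THREE_UTR`, `NONCODING`), `start`, `end`, `frame_warning`.
#' @export
region_partition <- function(transcripts) {
  rows <- purrr::map(seq_len(nrow(transcripts)), function(i) {
    ex <- transcripts$exons[[i]]
    cd <- transcripts$cds[[i]]
    tid <- transcripts$transcript_id[i]
    L <- sum(ex$end - ex$start)
    if (is.null(cd) || nrow(cd) == 0) {
      return(tibble::tibble(transcript_id = tid, region = "NONCODING",
                            start = 0L, end = L, frame_warning = FALSE))
    }
    tx_cds <- genomic_to_transcript(cd, ex, transcripts$strand[i])
    cds_start <- min(tx_cds$start); cds_end <- max(tx_cds$end)
    cds_len <- sum(tx_cds$end - tx_cds$start)
    warn <- (cds_len %% 3L) != 0L
    regions <- tibble::tibble(
      transcript_id = tid,
      region = c("FIVE_UTR", "CDS", "THREE_UTR"),
      start = c(0L, cds_start, cds_end),
      end = c(cds_start, cds_end, L),
      frame_warning = warn
    )
    regions[regions$end > regions$start, , drop = FALSE]
  })
  dplyr::bind_rows(rows)
}

#' CDS sequence of each transcript
#'
#' Concatenates CDS segments in spliced order (mRNA sense).
#'
#' @param transcripts Transcript-model tibble.
#' @param genome Named character vector of chromosome sequences.
#' @return Named character vector (empty string where a transcript has no
#'   CDS).
#' @export
cds_sequence <- function(transcripts, genome) {
  out <- vapply(seq_len(nrow(transcripts)), function(i) {
    cd <- transcripts$cds[[i]]
    if (is.null(cd) || nrow(cd) == 0) return("")
    chrom <- genome[[transcripts$seqid[i]]]
    s <- extract_intervals(chrom, cd)
    if (transcripts$strand[i] == "-") reverse_complement(s) else s
  }, character(1))
  stats::setNames(out, transcripts$transcript_id)
}

#' Translate a CDS nucleotide string
#'
#' Standard genetic code; the terminal stop (if present) is dropped. An
#' internal stop codon is a hard error reporting its codon position. A CDS
#' length that is not a multiple of 3 is an error.
#'
#' @param cds Nucleotide string (ACGTN; N-containing codons translate to X).
#' @return Protein string.
#' @export
translate_cds <- function(cds) {
  cds <- normalize_nucleotides(cds)
  if (nchar(cds) %% 3L != 0L) stop("CDS length not a multiple of 3: ", nchar(cds))
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  if (length(aa) > 0 && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  internal <- which(aa == "*")
  if (length(internal) > 0) {
    stop("internal stop codon(s) at codon position(s): ",
         paste(internal, collapse = ", "))
  }
  paste(aa, collapse = "")
}

#' Longest open reading frame on the mRNA-sense strand
#'
#' Scans the three forward frames for ATG..stop ORFs (no internal stop;
#' the stop codon must be present). Ties on length are broken by the
#' 5'-most start. Codons containing N never match ATG or a stop.
#'
#' @param seq Nucleotide string (mRNA sense).
#' @return A list with `start`, `end` (0-based half-open, including the
#'   stop codon) and `protein`, or `NULL` if no ORF exists.
#' @export
longest_orf <- function(seq) {
  seq <- normalize_nucleotides(seq)
  n <- nchar(seq)
  best <- NULL
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    starts <- seq(frame + 1L, n - 2L, by = 3L)
    if (length(starts) == 0 || starts[1] > n - 2L) next
    codons <- substring(seq, starts, starts + 2L)
    open_at <- NA_integer_
    for (k in seq_along(codons)) {
      if (is.na(open_at) && codons[k] == "ATG") open_at <- k
      if (!is.na(open_at) && codons[k] %in% stops) {
        len <- (k - open_at + 1L) * 3L
        s0 <- starts[open_at] - 1L
        if (is.null(best) || len > best$len ||
            (len == best$len && s0 < best$start)) {
          best <- list(start = s0, end = s0 + len, len = len)
        }
        open_at <- NA_integer_
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(start = best$start, end = best$end,
       protein = translate_cds(substring(seq, best$start + 1L, best$end)))
}
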