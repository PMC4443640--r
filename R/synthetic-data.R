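# Seeded synthetic fixtures: a small genome with planted SBP-domain
# genes, miR156 binding sites with controlled mismatch patterns, an
# antisense PP2C-style neighbor, decoy genes, count matrices with known
# scaling factors and Ct tables with known fold changes. All randomness
# flows from the config seed; re-running with the same config is
# byte-identical.

# Fixed synthetic consensus sequences. The SBP-like domain mimics the
# real domain's length (76 aa) and Cys/His clusters; it is NOT the real
# SBP domain (no database access at build time), which is irrelevant for
# planted-truth validation.
SBP_CONSENSUS <- "RKFCHYCPIFVCVTHREPVNWNVCLCCANCSGSFARSHPPKLCNAHNGIQTPTISIVQAHHFEHIWNICSCSHTEA"
PP2C_PROTEIN <- "MMGKDLIDEEGNQFIQGHNLFVFTSPMDGCHGHMTASISIDSYCVFCAMGMMHSFPPMSKVSYLKEELANMSTAEVHKEVFNPMNLQGEMLSCPMSYFKPITHGVFISVKRTCHDMGMVAVRMIMRDAYEEWKVKMQNWGDHDFNKGPLTLGEPDLDDDHYWHKEVGDTFCFSMREKASAFKTVSQACPGIMSVGHPTTYSHDDFRTHFY"

AA_STANDARD <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")
DNA4 <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(DNA4, n, replace = TRUE), collapse = "")
random_protein <- function(n) paste(sample(AA_STANDARD, n, replace = TRUE), collapse = "")

mutate_protein <- function(seq, identity) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- round((1 - identity) * length(ch))
  if (k > 0) {
    pos <- sample(length(ch), k)
    ch[pos] <- vapply(ch[pos], function(a) sample(setdiff(AA_STANDARD, a), 1),
                      character(1))
  }
  paste(ch, collapse = "")
}

# Reverse-translate a protein with uniformly random synonymous codons;
# appends a random stop codon.
reverse_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(ch, function(a) {
    cands <- by_aa[[a]]
    cands[sample.int(length(cands), 1)]
  }, character(1))
  paste0(paste(codons, collapse = ""), sample(c("TAA", "TAG", "TGA"), 1))
}

# Site sequence: binding signature mutated at the given miRNA positions
# (1-based from the miRNA 5' end; transcript-sense column L - p + 1).
planted_site <- function(mirna, mismatch_positions) {
  sig <- strsplit(binding_signature(mirna), "", fixed = TRUE)[[1]]
  L <- length(sig)
  for (p in mismatch_positions) {
    j <- L - p + 1L
    sig[j] <- sample(setdiff(DNA4, sig[j]), 1)
  }
  paste(sig, collapse = "")
}

#' Default synthetic-fixture configuration
#'
#' Study conditions for the default fixture: 12 family genes (subgroup
#' mix 3 short/3'UTR-site, 5 long/ORF-site, 4 no-site) and 8 decoys on 2
#' chromosomes; planted mismatch-position sets covering the legal space
#' plus two deliberately illegal sites (a mismatch at position 5; three
#' mismatches) on no-site genes; one antisense PP2C-style pair
#' encompassing the first short gene; per-gene domain identity drawn
#' from 70-95%; a 200 x 4 count matrix with known scaling factors
#' (negative-binomial dispersion 0.1) and 10% asymmetrically spiked
#' features; a Ct table (baseline Ct 24, sigma 0.15, 3 replicates) with
#' a planted 3-fold change.
#'
#' @param seed Integer seed driving all randomness (default 42).
#' @param n_family,n_decoys Family and decoy gene counts.
#' @param subgroup_mix Named counts for `SHORT_3UTR`, `LONG_ORF`,
#'   `NO_SITE` (must sum to `n_family`).
#' @param site_plan List of mismatch-position vectors, one per
#'   site-bearing family gene (recycled as needed).
#' @param illegal_plan List of illegal mismatch-position vectors planted
#'   in no-site genes (truth-marked illegal; never reported by the
#'   scanner).
#' @param mirna Mature miRNA (default [mir156_sequence()]).
#' @param n_chromosomes Chromosome count.
#' @param domain_identity_range Range of per-gene domain identity to the
#'   consensus.
#' @param counts_spec List: `n_features`, `n_samples`, `true_factors`,
#'   `spike_fraction`, `spike_multiplier`, `dispersion`, `base_meanlog`,
#'   `base_sdlog`.
#' @param ct_spec List: `genes` (named list of per-group fold changes),
#'   `groups`, `reference_gene`, `baseline_ct`, `sigma_ct`,
#'   `replicates`.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(
    seed = 42L,
    n_family = 12L, n_decoys = 8L,
    subgroup_mix = c(SHORT_3UTR = 3L, LONG_ORF = 5L, NO_SITE = 4L),
    site_plan = list(integer(0), 9L, c(1L, 7L),
                     7L, 1L, c(1L, 9L), c(7L, 9L), integer(0)),
    illegal_plan = list(5L, c(1L, 7L, 9L)),
    mirna = mir156_sequence(),
    n_chromosomes = 2L,
    domain_identity_range = c(0.70, 0.95),
    counts_spec = list(n_features = 200L, n_samples = 4L,
                       true_factors = c(1.0, 1.8, 0.7, 1.2),
                       spike_fraction = 0.10, spike_multiplier = 8,
                       dispersion = 0.1, base_meanlog = 4, base_sdlog = 1),
    ct_spec = list(genes = list(SPL_A = c(ON = 1, OFF = 3, DEF = 2),
                                SPL_B = c(ON = 1, OFF = 1, DEF = 1)),
                   reference_gene = "actin", baseline_ct = 24,
                   sigma_ct = 0.15, replicates = 3L)) {
  if (sum(subgroup_mix) != n_family) {
    stop("subgroup_mix must sum to n_family")
  }
  n_sites <- subgroup_mix[["SHORT_3UTR"]] + subgroup_mix[["LONG_ORF"]]
  site_plan <- rep_len(site_plan, n_sites)
  structure(list(seed = as.integer(seed), n_family = as.integer(n_family),
                 n_decoys = as.integer(n_decoys), subgroup_mix = subgroup_mix,
                 site_plan = site_plan, illegal_plan = illegal_plan,
                 mirna = normalize_nucleotides(mirna),
                 n_chromosomes = as.integer(n_chromosomes),
                 domain_identity_range = domain_identity_range,
                 counts_spec = counts_spec, ct_spec = ct_spec),
            class = "fixture_config")
}

# Realize a transcript genomically: given the spliced sequence, exon
# lengths (transcript order), intron sequences and strand, return the
# genomic block plus exon/CDS intervals in block coordinates (0-based
# half-open).
realize_gene <- function(spliced, exon_lengths, introns, cds_interval, strand) {
  stopifnot(sum(exon_lengths) == nchar(spliced),
            length(introns) == length(exon_lengths) - 1)
  k <- length(exon_lengths)
  tx_off <- cumsum(c(0L, exon_lengths))
  pieces <- character(0)
  pre_off <- integer(k)  # exon start offsets in pre-mRNA coords
  off <- 0L
  for (i in seq_len(k)) {
    pre_off[i] <- off
    pieces <- c(pieces, substring(spliced, tx_off[i] + 1L, tx_off[i + 1]))
    off <- off + exon_lengths[i]
    if (i < k) { pieces <- c(pieces, introns[i]); off <- off + nchar(introns[i]) }
  }
  pre <- paste(pieces, collapse = "")
  B <- nchar(pre)
  to_block <- function(tx_s, tx_e) {
    # map a transcript interval to genomic block segments
    segs <- list()
    for (i in seq_len(k)) {
      s <- max(tx_s, tx_off[i]); e <- min(tx_e, tx_off[i + 1])
      if (s < e) {
        ps <- pre_off[i] + (s - tx_off[i]); pe <- pre_off[i] + (e - tx_off[i])
        segs[[length(segs) + 1]] <-
          if (strand == "+") c(ps, pe) else c(B - pe, B - ps)
      }
    }
    m <- do.call(rbind, segs)
    m <- m[order(m[, 1]), , drop = FALSE]
    data.frame(start = m[, 1], end = m[, 2])
  }
  exons <- to_block(0L, sum(exon_lengths))
  cds <- if (is.null(cds_interval)) data.frame(start = integer(0), end = integer(0))
         else to_block(cds_interval[1], cds_interval[2])
  block <- if (strand == "+") pre else reverse_complement(pre)
  list(block = block, exons = exons, cds = cds)
}

# Insert a 20-nt site into a CDS at a codon boundary without creating a
# stop codon; returns the modified CDS and the site's CDS-relative
# start, or NULL if no placement works.
insert_site_in_cds <- function(cds, site, avoid_aa) {
  n_codons <- nchar(cds) %/% 3L - 1L  # exclude stop codon
  L <- nchar(site)
  stops <- c("TAA", "TAG", "TGA")
  cand_codons <- setdiff(seq(2L, n_codons - 8L), avoid_aa)
  for (c0 in sample(cand_codons)) {
    for (offset in sample(0:2)) {
      start <- (c0 - 1L) * 3L + offset      # 0-based site start in CDS
      span_start <- ((start) %/% 3L) * 3L   # codon-aligned region covering site
      span_end <- ((start + L + 2L) %/% 3L) * 3L
      if (span_end > n_codons * 3L) next
      region <- strsplit(substring(cds, span_start + 1L, span_end),
                         "", fixed = TRUE)[[1]]
      region[(start - span_start + 1L):(start - span_start + L)] <-
        strsplit(site, "", fixed = TRUE)[[1]]
      codons <- substring(paste(region, collapse = ""),
                          seq(1, length(region), 3), seq(3, length(region), 3))
      if (any(codons %in% stops)) next
      new_cds <- paste0(substring(cds, 1, span_start),
                        paste(region, collapse = ""),
                        substring(cds, span_end + 1L, nchar(cds)))
      return(list(cds = new_cds, site_start = start))
    }
  }
  NULL
}

build_transcript_seq <- function(protein, utr5_len, utr3_len, site = NULL,
                                 site_in = c("none", "cds", "utr3"),
                                 domain_aa = NULL) {
  site_in <- match.arg(site_in)
  cds <- reverse_translate(protein)
  site_tx_start <- NA_integer_
  if (site_in == "cds") {
    avoid <- if (is.null(domain_aa)) integer(0) else
      seq(domain_aa[1] - 7L, domain_aa[2] + 7L)
    ins <- insert_site_in_cds(cds, site, avoid)
    if (is.null(ins)) stop("could not place site in CDS without a stop codon")
    cds <- ins$cds
    site_tx_start <- utr5_len + ins$site_start
  }
  utr5 <- random_dna(utr5_len)
  utr3 <- random_dna(utr3_len)
  if (site_in == "utr3") {
    if (utr3_len < nchar(site) + 2L) stop("3'UTR too short for planted site")
    pos <- sample(seq_len(utr3_len - nchar(site) - 1L), 1)  # 1-based in UTR
    substring(utr3, pos, pos + nchar(site) - 1L) <- site
    site_tx_start <- utr5_len + nchar(cds) + pos - 1L
  }
  list(spliced = paste0(utr5, cds, utr3),
       cds_interval = c(utr5_len, utr5_len + nchar(cds)),
       site_tx_start = site_tx_start)
}

split_exons <- function(total_len, n_exons) {
  if (n_exons == 1) return(total_len)
  cuts <- sort(sample(seq(40L, total_len - 40L), n_exons - 1))
  diff(c(0L, cuts, total_len))
}

#' Generate a synthetic genome with planted truth
#'
#' Emits an in-memory genome (named chromosome sequences), a
#' transcript-model tibble, and truth tables describing every planted
#' feature. Family genes carry a mutated copy of the consensus SBP-like
#' domain; site-bearing genes carry one miR156 binding site built from
#' the configured mismatch plan; two no-site genes carry deliberately
#' illegal sites (disallowed position or too many mismatches); decoys
#' carry neither; one PP2C-style antisense transcript encompasses the
#' first short-subgroup gene. A self-check verifies that the emitted
#' sequences agree with the truth tables (planted sites recovered
#' exactly by the scanner, domains present in the conceptual
#' translations) and fails loudly otherwise.
#'
#' @param cfg A [fixture_config()].
#' @return List with `genome`, `transcripts`, `truth` (per-gene tibble),
#'   `antisense_truth`, `seed_alignment` (the packaged synthetic seed
#'   rows), `config`.
#' @export
generate_genome <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  withr::with_seed(cfg$seed, generate_genome_impl(cfg))
}

generate_genome_impl <- function(cfg) {
  mix <- cfg$subgroup_mix
  subgroups <- rep(names(mix), mix)
  n_fam <- cfg$n_family
  ids <- sprintf("SPL%02d", seq_len(n_fam))

  short_lengths <- c(130L, 143L, 189L)  # short-clade protein sizes
  plan_i <- 0L
  illegal_i <- 0L
  gene_specs <- list()
  for (g in seq_len(n_fam)) {
    sg <- subgroups[g]
    plen <- switch(sg,
      SHORT_3UTR = short_lengths[((g - 1L) %% 3L) + 1L],
      LONG_ORF = sample(310:450, 1),
      NO_SITE = sample(305:420, 1))
    identity <- stats::runif(1, cfg$domain_identity_range[1],
                             cfg$domain_identity_range[2])
    domain <- mutate_protein(SBP_CONSENSUS, identity)
    dlen <- nchar(domain)
    dstart <- sample(seq(5L, plen - dlen - 4L), 1)  # 0-based aa offset
    prot <- paste0("M", random_protein(dstart - 1L), domain,
                   random_protein(plen - dstart - dlen))
    site_mm <- NULL; legal <- NA
    if (sg %in% c("SHORT_3UTR", "LONG_ORF")) {
      plan_i <- plan_i + 1L
      site_mm <- cfg$site_plan[[plan_i]]
      legal <- TRUE
    } else if (illegal_i < length(cfg$illegal_plan)) {
      illegal_i <- illegal_i + 1L
      site_mm <- cfg$illegal_plan[[illegal_i]]
      legal <- FALSE
    }
    gene_specs[[g]] <- list(id = ids[g], subgroup = sg, protein = prot,
                            protein_length = plen,
                            domain_start = dstart, domain_end = dstart + dlen,
                            domain_identity = identity,
                            site_mm = site_mm, legal = legal)
  }
  decoy_specs <- lapply(seq_len(cfg$n_decoys), function(d) {
    plen <- sample(180:400, 1)
    list(id = sprintf("DEC%02d", d), subgroup = NA_character_,
         protein = paste0("M", random_protein(plen - 1L)),
         protein_length = plen, domain_start = NA_integer_,
         domain_end = NA_integer_, domain_identity = NA_real_,
         site_mm = NULL, legal = NA)
  })

  rule <- mismatch_rule()
  build_block <- function(spec) {
    # returns realized gene block(s) + truth row; retries on accidental sites
    for (attempt in 1:25) {
      site_seq <- if (!is.null(spec$site_mm)) planted_site(cfg$mirna, spec$site_mm)
      site_in <- if (is.null(spec$site_mm)) "none"
        else if (identical(spec$subgroup, "LONG_ORF")) "cds"
        else "utr3"  # SHORT_3UTR sites and illegal sites live in the 3'UTR
      bt <- build_transcript_seq(
        spec$protein, utr5_len = sample(60:120, 1),
        utr3_len = sample(170:320, 1), site = site_seq, site_in = site_in,
        domain_aa = c(spec$domain_start, spec$domain_end))
      # self-check: exactly the planted legal site, nothing else
      found <- find_target_sites(stats::setNames(bt$spliced, "x"), cfg$mirna, rule)
      want_legal <- isTRUE(spec$legal)
      ok <- if (want_legal) {
        nrow(found) == 1 && found$start == bt$site_tx_start &&
          identical(found$mismatch_positions,
                    paste(sort(spec$site_mm), collapse = ","))
      } else nrow(found) == 0
      if (ok) return(c(bt, list(site_seq = site_seq)))
    }
    stop("could not realize gene ", spec$id, " without accidental sites")
  }

  chrom_seqs <- stats::setNames(rep("", cfg$n_chromosomes),
                                sprintf("chr%d", seq_len(cfg$n_chromosomes)))
  tx_rows <- list(); truth_rows <- list(); anti_rows <- list()
  place_block <- function(chrom, realized, gene_id, tx_id) {
    # append gap + block to chromosome; register transcript row
    gap <- random_dna(sample(400:900, 1))
    offset <- nchar(chrom_seqs[[chrom]]) + nchar(gap)
    chrom_seqs[[chrom]] <<- paste0(chrom_seqs[[chrom]], gap, realized$block)
    tx_rows[[length(tx_rows) + 1]] <<- tibble::tibble(
      transcript_id = tx_id, gene_id = gene_id, seqid = chrom,
      strand = realized$strand,
      exons = list(data.frame(start = realized$exons$start + offset,
                              end = realized$exons$end + offset)),
      cds = list(data.frame(start = realized$cds$start + offset,
                            end = realized$cds$end + offset)))
    offset
  }

  all_specs <- c(gene_specs, decoy_specs)
  anti_target_tx <- NULL
  for (k in seq_along(all_specs)) {
    spec <- all_specs[[k]]
    bt <- build_block(spec)
    strand <- sample(c("+", "-"), 1)
    L <- nchar(bt$spliced)
    n_ex <- sample(2:4, 1)
    exl <- split_exons(L, n_ex)
    introns <- vapply(seq_len(n_ex - 1),
                      function(i) paste0("GT", random_dna(sample(76:396, 1)), "AG"),
                      character(1))
    realized <- realize_gene(bt$spliced, exl, introns, bt$cds_interval, strand)
    realized$strand <- strand
    chrom <- sprintf("chr%d", ((k - 1L) %% cfg$n_chromosomes) + 1L)
    tx_id <- paste0(spec$id, ".1")
    is_anti_target <- identical(spec$subgroup, "SHORT_3UTR") &&
      length(anti_rows) == 0 && k == 1L

    if (is_anti_target) {
      # embed this gene inside the intron of a PP2C antisense transcript
      pp_prot <- mutate_protein(PP2C_PROTEIN, 0.92)
      pp_cds <- reverse_translate(pp_prot)
      pp_utr5 <- 120L; pp_utr3 <- 180L
      pp_spliced <- paste0(random_dna(pp_utr5), pp_cds, random_dna(pp_utr3))
      ppL <- nchar(pp_spliced)
      exA <- ppL %/% 2L
      pp_strand <- if (strand == "+") "-" else "+"
      margin1 <- random_dna(120L); margin2 <- random_dna(120L)
      big_intron <- paste0("GT", margin1,
                           if (pp_strand == "+") realized$block
                           else reverse_complement(realized$block),
                           margin2, "AG")
      pp_real <- realize_gene(pp_spliced, c(exA, ppL - exA), big_intron,
                              c(pp_utr5, pp_utr5 + nchar(pp_cds)), pp_strand)
      pp_real$strand <- pp_strand
      pp_off <- place_block(chrom, pp_real, "PP2C01", "PP2C01.1")
      # inner gene offset inside the combined block
      inner_off <- pp_off +
        (if (pp_strand == "+") exA + 2L + 120L
         else nchar(pp_real$block) - (exA + 2L + 120L) - nchar(realized$block))
      tx_rows[[length(tx_rows) + 1]] <- tibble::tibble(
        transcript_id = tx_id, gene_id = spec$id, seqid = chrom,
        strand = strand,
        exons = list(data.frame(start = realized$exons$start + inner_off,
                                end = realized$exons$end + inner_off)),
        cds = list(data.frame(start = realized$cds$start + inner_off,
                              end = realized$cds$end + inner_off)))
      anti_rows[[1]] <- tibble::tibble(
        transcript_a = "PP2C01.1", transcript_b = tx_id, encompasses = TRUE)
      anti_target_tx <- tx_id
    } else {
      place_block(chrom, realized, spec$id, tx_id)
    }

    truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
      gene_id = spec$id, transcript_id = tx_id,
      is_family = !startsWith(spec$id, "DEC"),
      subgroup = spec$subgroup,
      protein_length = spec$protein_length,
      domain_start = spec$domain_start, domain_end = spec$domain_end,
      domain_identity = spec$domain_identity,
      site_start = bt$site_tx_start,
      site_region = if (is.null(spec$site_mm) || !isTRUE(spec$legal)) NA_character_
        else if (identical(spec$subgroup, "LONG_ORF")) "CDS" else "THREE_UTR",
      mismatch_positions = if (is.null(spec$site_mm)) NA_character_
        else paste(sort(spec$site_mm), collapse = ","),
      site_legal = spec$legal)
  }

  # alternative isoforms on two family genes, exercising the
  # representative-transcript rules (longest CDS, then longest spliced)
  add_isoform <- function(gene_id, mode) {
    base <- NULL
    for (r in tx_rows) if (r$gene_id == gene_id) base <- r
    cd <- base$cds[[1]]; ex <- base$exons[[1]]
    if (mode == "short_cds") {
      # trim 30 nt (10 codons) off the CDS 5' end, walking segments;
      # the genomic 5' side is the left end on "+", the right end on "-"
      cd2 <- cd
      left <- 30L
      if (base$strand == "+") {
        i <- 1L
        while (left > 0L) {
          take <- min(left, cd2$end[i] - cd2$start[i] - 3L)
          if (take > 0L) { cd2$start[i] <- cd2$start[i] + take; left <- left - take }
          if (left > 0L) i <- i + 1L
        }
      } else {
        i <- nrow(cd2)
        while (left > 0L) {
          take <- min(left, cd2$end[i] - cd2$start[i] - 3L)
          if (take > 0L) { cd2$end[i] <- cd2$end[i] - take; left <- left - take }
          if (left > 0L) i <- i - 1L
        }
      }
      ex2 <- ex
    } else {
      # shorten the terminal (3'UTR) exon, staying clear of the CDS
      ex2 <- ex
      if (base$strand == "+") {
        k <- nrow(ex2)
        trim <- min(40L, ex2$end[k] - max(ex2$start[k], max(cd$end)) - 5L)
        ex2$end[k] <- ex2$end[k] - max(trim, 0L)
      } else {
        trim <- min(40L, min(ex2$end[1], min(cd$start)) - ex2$start[1] - 5L)
        ex2$start[1] <- ex2$start[1] + max(trim, 0L)
      }
      cd2 <- cd
    }
    tx_rows[[length(tx_rows) + 1]] <<- tibble::tibble(
      transcript_id = paste0(gene_id, ".2"), gene_id = gene_id,
      seqid = base$seqid, strand = base$strand,
      exons = list(ex2), cds = list(cd2))
  }
  iso_genes <- ids[c(2L, min(6L, n_fam))]
  add_isoform(iso_genes[1], "short_cds")
  add_isoform(iso_genes[2], "short_utr")

  transcripts <- dplyr::bind_rows(tx_rows)
  truth <- dplyr::bind_rows(truth_rows)
  fix <- list(genome = chrom_seqs, transcripts = transcripts,
              truth = truth,
              antisense_truth = dplyr::bind_rows(anti_rows),
              seed_alignment = sbp_seed_alignment(),
              config = cfg)
  fixture_self_check(fix)
  fix
}

# Consistency pass: emitted sequences must agree with the truth table.
fixture_self_check <- function(fix) {
  tr <- fix$truth
  reps <- fix$transcripts[match(tr$transcript_id, fix$transcripts$transcript_id), ]
  spliced <- spliced_sequence(reps, fix$genome)
  prot <- vapply(cds_sequence(reps, fix$genome), translate_cds, character(1))
  for (i in seq_len(nrow(tr))) {
    if (tr$is_family[i]) {
      dom <- substring(prot[[i]], tr$domain_start[i] + 1L, tr$domain_end[i])
      if (nchar(dom) != nchar(SBP_CONSENSUS)) {
        stop("self-check: domain length mismatch for ", tr$gene_id[i])
      }
    }
    if (nchar(prot[[i]]) != tr$protein_length[i]) {
      stop("self-check: protein length mismatch for ", tr$gene_id[i])
    }
    if (!is.na(tr$site_start[i]) && isTRUE(tr$site_legal[i])) {
      found <- find_target_sites(spliced[i], fix$config$mirna, mismatch_rule())
      if (nrow(found) != 1 || found$start != tr$site_start[i]) {
        stop("self-check: planted site not recovered for ", tr$gene_id[i])
      }
    }
  }
  part <- region_partition(reps)
  lens <- tapply(part$end - part$start, part$transcript_id, sum)
  if (!all(lens[tr$transcript_id] == nchar(spliced))) {
    stop("self-check: region partition does not tile the transcript")
  }
  invisible(TRUE)
}

#' Packaged synthetic seed alignment of SBP-like domains
#'
#' Reads the 16-sequence, 76-column synthetic seed alignment shipped
#' with the package (a fixed consensus with per-sequence mutations and
#' sparse gaps; a synthetic stand-in for curated reference domains).
#'
#' @return Named character vector of aligned rows.
#' @export
sbp_seed_alignment <- function() {
  read_alignment_fasta(system.file("extdata", "sbp_seed_synthetic.afa",
                                   package = "splfam", mustWork = TRUE))
}

#' Generate a count matrix with known scaling factors
#'
#' Counts are negative binomial with per-sample scaling by the true
#' factors (`mu_ij = base_i * factor_j`); a `spike_fraction` of features
#' is additionally multiplied by `spike_multiplier` in the second sample
#' only (asymmetric composition noise that trimming must resist).
#'
#' @param cfg A [fixture_config()]; uses `cfg$counts_spec` and
#'   `cfg$seed`.
#' @return List with `counts` (matrix, features x samples), `lengths`
#'   (feature lengths, nt) and `true_factors` (recentred to geometric
#'   mean 1).
#' @export
generate_counts <- function(cfg = fixture_config()) {
  sp <- cfg$counts_spec
  withr::with_seed(cfg$seed + 1L, {
    f <- rep_len(sp$true_factors, sp$n_samples)
    stopifnot(all(f > 0))
    base <- stats::rlnorm(sp$n_features, sp$base_meanlog, sp$base_sdlog)
    mu <- outer(base, f)
    n_spike <- round(sp$spike_fraction * sp$n_features)
    spiked <- if (n_spike > 0) sample(sp$n_features, n_spike) else integer(0)
    if (length(spiked) > 0 && sp$n_samples >= 2) {
      mu[spiked, 2] <- mu[spiked, 2] * sp$spike_multiplier
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / sp$dispersion),
                     nrow = sp$n_features,
                     dimnames = list(sprintf("feat%04d", seq_len(sp$n_features)),
                                     sprintf("S%d", seq_len(sp$n_samples))))
    lengths <- sample(500:3000, sp$n_features, replace = TRUE)
    list(counts = counts, lengths = lengths,
         true_factors = f / exp(mean(log(f))),
         spiked_features = rownames(counts)[sort(spiked)])
  })
}

#' Generate a qPCR Ct table with known fold changes
#'
#' Per gene and group, `Ct = baseline - log2(fold) + noise`; the
#' reference gene is flat across groups (fold 1 everywhere) and shares
#' the same noise level.
#'
#' @param cfg A [fixture_config()]; uses `cfg$ct_spec` and `cfg$seed`.
#' @return List with `ct` (tibble: gene, sample, group, replicate, ct)
#'   and `true_fold` (tibble: gene, group, fold).
#' @export
generate_ct <- function(cfg = fixture_config()) {
  sp <- cfg$ct_spec
  withr::with_seed(cfg$seed + 2L, {
    groups <- names(sp$genes[[1]])
    grid <- expand.grid(group = groups, replicate = seq_len(sp$replicates),
                        stringsAsFactors = FALSE)
    grid$sample <- paste0(grid$group, "_r", grid$replicate)
    rows <- list()
    for (g in c(names(sp$genes), sp$reference_gene)) {
      folds <- if (g == sp$reference_gene) {
        stats::setNames(rep(1, length(groups)), groups)
      } else sp$genes[[g]]
      base <- if (g == sp$reference_gene) sp$baseline_ct - 4 else sp$baseline_ct
      rows[[g]] <- tibble::tibble(
        gene = g, sample = grid$sample, group = grid$group,
        replicate = grid$replicate,
        ct = base - log2(folds[grid$group]) +
          stats::rnorm(nrow(grid), 0, sp$sigma_ct))
    }
    true_fold <- purrr::imap(sp$genes, function(f, g) {
      tibble::tibble(gene = g, group = names(f), fold = unname(f))
    }) |> dplyr::bind_rows()
    list(ct = dplyr::bind_rows(rows), true_fold = true_fold)
  })
}

#' Write a fixture to disk
#'
#' Emits `genome.fa`, `annotation.gff3`, `seed_alignment.afa`,
#' `truth_genes.tsv`, `truth_antisense.tsv`, `counts.tsv`,
#' `feature_lengths.tsv`, `truth_factors.tsv`, `ct.tsv`,
#' `truth_folds.tsv` and `mirna.txt` into `dir`.
#'
#' @param fix Output of [generate_genome()].
#' @param dir Output directory (created if needed).
#' @param counts Optional output of [generate_counts()].
#' @param ct Optional output of [generate_ct()].
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fix, dir, counts = NULL, ct = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(fix$genome, file.path(dir, "genome.fa"))
  write_gff3(fix$transcripts, file.path(dir, "annotation.gff3"))
  write_fasta(fix$seed_alignment, file.path(dir, "seed_alignment.afa"))
  readr::write_tsv(fix$truth, file.path(dir, "truth_genes.tsv"))
  readr::write_tsv(fix$antisense_truth, file.path(dir, "truth_antisense.tsv"))
  writeLines(fix$config$mirna, file.path(dir, "mirna.txt"))
  if (!is.null(counts)) {
    cdf <- tibble::as_tibble(counts$counts, rownames = "feature")
    readr::write_tsv(cdf, file.path(dir, "counts.tsv"))
    readr::write_tsv(tibble::tibble(feature = rownames(counts$counts),
                                    length = counts$lengths),
                     file.path(dir, "feature_lengths.tsv"))
    readr::write_tsv(tibble::tibble(sample = colnames(counts$counts),
                                    factor = counts$true_factors),
                     file.path(dir, "truth_factors.tsv"))
  }
  if (!is.null(ct)) {
    readr::write_tsv(ct$ct, file.path(dir, "ct.tsv"))
    readr::write_tsv(ct$true_fold, file.path(dir, "truth_folds.tsv"))
  }
  invisible(dir)
}
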