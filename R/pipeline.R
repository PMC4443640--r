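# End-to-end orchestration: mine -> scan -> classify -> tree ->
# normalize -> qpcr, with TSV outputs and a JSON run manifest.

#' Assemble and validate a pipeline run configuration
#'
#' @param genome Path to genome FASTA.
#' @param gff3 Path to GFF3 annotation.
#' @param seed_alignment Path to aligned seed FASTA (default: packaged
#'   synthetic SBP seed alignment).
#' @param mirna Mature miRNA sequence (default [mir156_sequence()]).
#' @param counts,lengths,ct Optional paths: counts TSV (feature column +
#'   one column per sample), feature-length TSV (`feature`, `length`),
#'   Ct TSV (`gene`, `sample`, `group`, `replicate`, `ct`).
#' @param out_dir Output directory.
#' @param max_mismatches,allowed_positions,wobble Mismatch-rule
#'   parameters.
#' @param min_fraction,min_identity,min_columns Mining thresholds.
#' @param short_max,long_min Classification length thresholds (strict
#'   inequalities at 200 / 300 aa).
#' @param correction Distance correction for the phylogeny.
#' @param reference_gene,calibrator qPCR options.
#' @param seed Seed recorded in the manifest.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(genome, gff3,
                       seed_alignment = system.file("extdata", "sbp_seed_synthetic.afa",
                                                    package = "splfam"),
                       mirna = mir156_sequence(),
                       counts = NULL, lengths = NULL, ct = NULL,
                       out_dir = "splfam_out",
                       max_mismatches = 2L, allowed_positions = c(1L, 7L, 9L),
                       wobble = FALSE,
                       min_fraction = 0.6, min_identity = 40, min_columns = 60,
                       short_max = 200, long_min = 300,
                       correction = "kimura",
                       reference_gene = "actin", calibrator = NULL,
                       seed = 1L) {
  for (p in c(genome, gff3, seed_alignment, counts, lengths, ct)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  stopifnot(min_fraction > 0, min_identity > 0, short_max > 0, long_min > 0)
  structure(as.list(environment()), class = "run_config")
}

stage_log <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the full SPL-family pipeline
#'
#' Executes mining, site scanning, classification, antisense detection,
#' phylogeny and (when inputs are configured) TMM normalization and
#' qPCR statistics, writing `members.tsv`, `sites.tsv`,
#' `classification.tsv`, `overlaps.tsv`, `alignment.afa`, `tree.nwk`,
#' `distances.tsv`, `factors.tsv`, `ru_letters.tsv` and `manifest.json`
#' into the configured output directory. The run is a pure function of
#' (inputs, config, seed).
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with all in-memory results plus the
#'   manifest.
#' @export
run_spl_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t_tsv <- function(x, f) readr::write_tsv(x, file.path(cfg$out_dir, f))

  stage_log("load", "reading genome and annotation")
  genome <- read_genome_fasta(cfg$genome)
  transcripts <- read_transcript_models(cfg$gff3)
  seed <- read_alignment_fasta(cfg$seed_alignment)
  rule <- mismatch_rule(cfg$max_mismatches, cfg$allowed_positions,
                        wobble_counts_as_match = cfg$wobble)

  stage_log("mine", "profile scan over ", nrow(transcripts), " transcripts")
  members <- mine_family(transcripts, genome, seed,
                         min_fraction = cfg$min_fraction,
                         min_identity = cfg$min_identity,
                         min_columns = cfg$min_columns)
  t_tsv(members, "members.tsv")

  stage_log("scan", "miR156 site scan")
  sites <- scan_transcripts(transcripts, genome, cfg$mirna, rule)
  t_tsv(sites, "sites.tsv")

  stage_log("classify", "subgroups and antisense overlaps")
  classification <- classify_members(members, sites)
  t_tsv(classification, "classification.tsv")
  overlaps <- detect_antisense_overlaps(transcripts)
  t_tsv(overlaps, "overlaps.tsv")

  tree <- NULL; aln <- NULL
  if (nrow(members) >= 3) {
    stage_log("tree", "SBP-domain phylogeny over ", nrow(members), " members")
    phylo <- domain_phylogeny(members, transcripts, genome,
                              correction = cfg$correction)
    aln <- phylo$alignment
    tree <- phylo$tree
    write_fasta(aln, file.path(cfg$out_dir, "alignment.afa"))
    ape::write.tree(tree, file.path(cfg$out_dir, "tree.nwk"))
    dmat <- tibble::as_tibble(phylo$distances, rownames = "gene")
    t_tsv(dmat, "distances.tsv")
  }

  factors <- NULL
  if (!is.null(cfg$counts)) {
    stage_log("normalize", "TMM factors")
    cdf <- readr::read_tsv(cfg$counts, show_col_types = FALSE)
    cm <- as.matrix(cdf[, -1]); rownames(cm) <- cdf[[1]]
    factors <- tmm_factors(cm)
    t_tsv(factors, "factors.tsv")
  }

  ru <- NULL; anova_fits <- NULL
  if (!is.null(cfg$ct)) {
    stage_log("qpcr", "relative expression and Tukey-Kramer letters")
    ctab <- readr::read_tsv(cfg$ct, show_col_types = FALSE)
    ru <- relative_expression(ctab, cfg$reference_gene, cfg$calibrator)
    reps <- attr(ru, "replicates")
    anova_fits <- reps |>
      dplyr::group_by(.data$gene) |>
      dplyr::group_map(~ anova_tukey(.x, value = "ru_rep", group = "group"))
    names(anova_fits) <- sort(unique(reps$gene))
    letters_tbl <- purrr::imap(anova_fits, function(fit, g) {
      dplyr::mutate(fit$letters, gene = g, .before = 1)
    }) |> dplyr::bind_rows()
    ru_out <- dplyr::left_join(ru, letters_tbl,
                               by = c("gene", "group")) |>
      dplyr::select("gene", "group", "ru", "letter")
    t_tsv(ru_out, "ru_letters.tsv")
  }

  manifest <- list(
    config = lapply(unclass(cfg), function(x) if (is.null(x)) NA else x),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("splfam")),
    n_transcripts = nrow(transcripts),
    n_members = nrow(members),
    n_sites = nrow(sites),
    n_transcripts_with_site = length(unique(sites$transcript_id)),
    subgroup_counts = as.list(table(classification$subgroup)),
    n_overlaps = nrow(overlaps)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(members = members, sites = sites,
                 classification = classification, overlaps = overlaps,
                 alignment = aln, tree = tree, factors = factors,
                 relative_expression = ru, anova = anova_fits,
                 manifest = manifest))
}
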