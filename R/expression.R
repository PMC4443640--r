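# Expression arithmetic: FPKM, TMM normalization factors, qPCR relative
# expression (2^-ddCt against a reference gene), and one-way ANOVA with
# Tukey-Kramer letter displays.

#' Fragments per kilobase per million mapped reads
#'
#' `fpkm = count * 1e9 / (length * library_size)`.
#'
#' @param counts Numeric matrix (features x samples) of non-negative
#'   counts.
#' @param lengths Feature effective lengths in nt (recycled along rows).
#' @param library_sizes Per-sample library sizes; default `colSums(counts)`.
#' @return Numeric matrix of FPKM values, same shape as `counts`.
#' @export
fpkm <- function(counts, lengths, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), all(lengths > 0))
  if (any(library_sizes <= 0)) stop("library size must be positive")
  sweep(counts / lengths, 2, library_sizes, "/") * 1e9
}

# Robinson-Oshlack TMM factor for one sample against the reference.
tmm_pair_factor <- function(obs, ref, lib_obs, lib_ref,
                            logratio_trim = 0.30, sum_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) stop("no co-expressed features between sample pair")
  obs <- obs[keep]; ref <- ref[keep]
  # M on raw counts: the factor captures the full between-sample scaling
  # (depth x composition); dividing by library size would shift every M
  # by a constant and yield the composition-only factor instead.
  M <- log2(obs / ref)
  A <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  w <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors for a count matrix,
#' re-implemented from the published algorithm: M and A values on
#' features expressed in both members of a pair, two-sided trimming of
#' the most extreme M values (`logratio_trim` per tail, default 0.30)
#' and A values (`sum_trim` per tail, default 0.05), inverse
#' asymptotic-variance weights, factor `2^weighted mean M`, then
#' recentring so the factors have geometric mean 1.
#'
#' M values are taken on raw counts, so the factors capture the full
#' between-sample scaling (sequencing depth times library composition):
#' a sample counted exactly twice as deep gets twice the factor. The
#' composition-only factor of the edgeR convention equals this factor
#' divided by relative library size.
#'
#' The reference sample defaults to the one whose upper quartile (of
#' scaled counts) is closest to the mean upper quartile.
#'
#' @param counts Feature x sample count matrix (non-negative).
#' @param lengths Ignored here; present so a count-matrix list can be
#'   spliced in. Default `NULL`.
#' @param ref Reference sample name, or `NULL` for automatic choice.
#' @param logratio_trim Per-tail trim fraction on M values (default 0.30).
#' @param sum_trim Per-tail trim fraction on A values (default 0.05).
#' @return Tibble with columns `sample`, `factor`; attributes
#'   `reference` (chosen reference sample) and `trims`.
#' @export
tmm_factors <- function(counts, lengths = NULL, ref = NULL,
                        logratio_trim = 0.30, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("library size must be positive")
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  }
  if (is.null(ref)) {
    uq <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
    ref <- colnames(counts)[which.min(abs(uq - mean(uq)))]
  }
  stopifnot(ref %in% colnames(counts))
  f <- vapply(colnames(counts), function(s) {
    if (s == ref) return(1)
    tmm_pair_factor(counts[, s], counts[, ref], lib[s], lib[ref],
                    logratio_trim, sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))  # geometric mean 1
  out <- tibble::tibble(sample = colnames(counts), factor = unname(f))
  attr(out, "reference") <- ref
  attr(out, "trims") <- c(logratio_trim = logratio_trim, sum_trim = sum_trim)
  out
}

#' qPCR relative expression (2^-ddCt)
#'
#' Normalizes each target gene's Ct against the reference gene in the
#' same sample (`dCt = Ct_gene - Ct_ref`), then expresses each group
#' relative to the calibrator group
#' (`ddCt = mean dCt(group) - mean dCt(calibrator)`;
#' `RU = 2^-ddCt`). Samples lacking a reference-gene Ct are excluded
#' with a warning. Per-replicate RUs (each replicate's dCt against the
#' calibrator mean) are returned for downstream statistics.
#'
#' @param ct Tibble/data frame with columns `gene`, `sample`, `group`,
#'   `replicate`, `ct`.
#' @param reference_gene Name of the normalizer gene (e.g. beta-actin).
#' @param calibrator Calibrator group; default the first group level in
#'   order of appearance.
#' @return Tibble with `gene`, `group`, `ru` (group-level), and
#'   attribute `replicates`: tibble `gene`, `group`, `replicate`,
#'   `ru_rep`.
#' @export
relative_expression <- function(ct, reference_gene, calibrator = NULL) {
  ct <- tibble::as_tibble(ct)
  stopifnot(all(c("gene", "sample", "group", "replicate", "ct") %in% names(ct)))
  refs <- ct |>
    dplyr::filter(.data$gene == reference_gene) |>
    dplyr::select("sample", ref_ct = "ct")
  if (nrow(refs) == 0) stop("reference gene not found: ", reference_gene)
  targets <- dplyr::filter(ct, .data$gene != reference_gene)
  missing_ref <- setdiff(unique(targets$sample), refs$sample)
  if (length(missing_ref) > 0) {
    warning("sample(s) without reference Ct excluded: ",
            paste(missing_ref, collapse = ", "))
    targets <- dplyr::filter(targets, !.data$sample %in% missing_ref)
  }
  d <- targets |>
    dplyr::inner_join(refs, by = "sample") |>
    dplyr::mutate(dct = .data$ct - .data$ref_ct)
  if (is.null(calibrator)) calibrator <- d$group[1]
  if (!calibrator %in% d$group) stop("calibrator group absent: ", calibrator)
  cal <- d |>
    dplyr::filter(.data$group == calibrator) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(cal_dct = mean(.data$dct), .groups = "drop")
  d <- dplyr::inner_join(d, cal, by = "gene")
  reps <- d |>
    dplyr::transmute(.data$gene, .data$group, .data$replicate,
                     ru_rep = 2^(-(.data$dct - .data$cal_dct)))
  out <- d |>
    dplyr::group_by(.data$gene, .data$group) |>
    dplyr::summarise(ru = 2^(-(mean(.data$dct) - .data$cal_dct[1])),
                     .groups = "drop")
  attr(out, "replicates") <- reps
  attr(out, "calibrator") <- calibrator
  out
}

# Greedy letter display from Tukey-Kramer significance flags: groups are
# swept from the largest mean; each letter covers the maximal run of
# groups not significantly different from the letter's anchor.
assign_letters <- function(group_names, means, sig) {
  ord <- order(-means)
  k <- length(ord)
  letters_out <- stats::setNames(rep("", k), group_names)
  lab <- 0L
  covered <- rep(FALSE, k)
  for (a in seq_len(k)) {
    ga <- ord[a]
    block <- ga
    for (b in seq_len(k)) {
      gb <- ord[b]
      if (gb == ga) next
      if (!sig[ga, gb] && all(!sig[block, gb])) block <- c(block, gb)
    }
    # skip if this block is a subset of an existing letter's block
    new_block <- sort(block)
    dup <- FALSE
    if (lab > 0) {
      for (l in seq_len(lab)) {
        prev <- which(grepl(letters[l], letters_out[group_names], fixed = TRUE))
        if (all(new_block %in% prev)) { dup <- TRUE; break }
      }
    }
    if (dup) next
    lab <- lab + 1L
    letters_out[new_block] <- paste0(letters_out[new_block], letters[lab])
  }
  letters_out
}

#' One-way ANOVA with Tukey-Kramer comparisons and letter display
#'
#' Fits a one-way ANOVA (via [stats::aov()]), performs all pairwise
#' Tukey-Kramer comparisons using the studentized-range distribution
#' with the unequal-n correction
#' (`q = |mi - mj| / sqrt(MSE/2 * (1/ni + 1/nj))` against
#' `qtukey(1 - alpha, k, df)`), and assigns compact letters greedily
#' from the largest group mean (groups sharing a letter are not
#' significantly different). If every observation is identical the
#' p-value is 1 by convention and no pair is flagged.
#'
#' @param data Data frame with columns `value` and `group` (or supply
#'   `value`/`group` column names).
#' @param value,group Column names (default `"value"`, `"group"`).
#' @param alpha Family-wise significance level (default 0.05).
#' @return Object of class `spl_anova`: list with `f`, `p`, `df`
#'   (c(between, within)), `means`, `pairwise` tibble (`group_a`,
#'   `group_b`, `diff`, `q`, `p_adj`, `significant`), `letters` tibble
#'   (`group`, `mean`, `n`, `letter`), `alpha`.
#' @export
anova_tukey <- function(data, value = "value", group = "group", alpha = 0.05) {
  df <- data.frame(value = data[[value]], group = factor(data[[group]]))
  stopifnot(nlevels(df$group) >= 2)
  ns <- table(df$group)
  if (any(ns < 2)) stop("every group needs at least 2 replicates")
  k <- nlevels(df$group)
  N <- nrow(df)
  means <- tapply(df$value, df$group, mean)

  degenerate <- stats::var(df$value) == 0
  if (degenerate) {
    f <- 0; p <- 1; mse <- 0
  } else {
    fit <- stats::aov(value ~ group, data = df)
    tab <- summary(fit)[[1]]
    f <- tab$`F value`[1]; p <- tab$`Pr(>F)`[1]
    mse <- tab$`Mean Sq`[2]
  }
  dfw <- N - k
  pairs <- utils::combn(levels(df$group), 2)
  sig <- matrix(FALSE, k, k, dimnames = list(levels(df$group), levels(df$group)))
  pw <- purrr::map(seq_len(ncol(pairs)), function(c0) {
    a <- pairs[1, c0]; b <- pairs[2, c0]
    dmean <- means[[a]] - means[[b]]
    if (mse == 0) {
      qv <- if (dmean == 0) 0 else Inf
    } else {
      se <- sqrt(mse / 2 * (1 / ns[[a]] + 1 / ns[[b]]))
      qv <- abs(dmean) / se
    }
    padj <- if (is.infinite(qv)) 0 else
      stats::ptukey(qv, nmeans = k, df = dfw, lower.tail = FALSE)
    tibble::tibble(group_a = a, group_b = b, diff = dmean, q = unname(qv),
                   p_adj = unname(padj), significant = padj < alpha)
  }) |> dplyr::bind_rows()
  for (i in seq_len(nrow(pw))) {
    sig[pw$group_a[i], pw$group_b[i]] <- pw$significant[i]
    sig[pw$group_b[i], pw$group_a[i]] <- pw$significant[i]
  }
  letts <- assign_letters(levels(df$group), as.numeric(means), sig)
  structure(list(
    f = f, p = p, df = c(between = k - 1, within = dfw),
    means = means, pairwise = pw,
    letters = tibble::tibble(group = levels(df$group),
                             mean = as.numeric(means),
                             n = as.integer(ns),
                             letter = unname(letts)),
    alpha = alpha
  ), class = "spl_anova")
}

#' @export
print.spl_anova <- function(x, ...) {
  cat("One-way ANOVA with Tukey-Kramer comparisons\n")
  cat(sprintf("F(%d, %d) = %.4g, p = %.4g\n", x$df[1], x$df[2], x$f, x$p))
  print(as.data.frame(x$letters), row.names = FALSE)
  invisible(x)
}

#' Tidy the pairwise comparisons of an `spl_anova` fit
#'
#' @param x An `spl_anova` object.
#' @param ... Unused.
#' @return The pairwise-comparison tibble.
#' @export
#' @method tidy spl_anova
tidy.spl_anova <- function(x, ...) x$pairwise

#' One-row model summary of an `spl_anova` fit
#'
#' @param x An `spl_anova` object.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `p.value`, `df`, `df.residual`,
#'   `n.groups`.
#' @export
#' @method glance spl_anova
glance.spl_anova <- function(x, ...) {
  tibble::tibble(statistic = x$f, p.value = x$p,
                 df = x$df[["between"]], df.residual = x$df[["within"]],
                 n.groups = nrow(x$letters))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
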