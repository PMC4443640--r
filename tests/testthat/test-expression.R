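# FPKM, TMM factors, relative expression, ANOVA with Tukey-Kramer.

test_that("FPKM follows its closed form and is scale invariant", {
  expect_equal(fpkm(matrix(10), lengths = 1000, library_sizes = 1e6)[1, 1], 10)
  withr::with_seed(4, {
    counts <- matrix(rpois(200, 50), 50, 4)
    lens <- sample(200:5000, 50)
  })
  libs <- colSums(counts)
  f <- fpkm(counts, lens)
  # element-wise oracle recomputation
  for (k in sample(length(counts), 25)) {
    i <- (k - 1) %% 50 + 1; j <- (k - 1) %/% 50 + 1
    expect_equal(f[i, j], counts[i, j] * 1e9 / (lens[i] * libs[j]))
  }
  # doubling every count and the library size leaves FPKM unchanged
  expect_equal(fpkm(2 * counts, lens, 2 * libs), f)
  expect_error(fpkm(matrix(1), 100, 0), "positive")
})

test_that("TMM factors: identical columns give unit factors; a doubled column doubles its factor", {
  withr::with_seed(10, x <- rpois(300, 60))
  two <- cbind(A = x, B = x)
  f <- tmm_factors(two)
  expect_equal(f$factor, c(1, 1))
  doubled <- cbind(A = x, B = 2L * x)
  fd <- tmm_factors(doubled, ref = "A")
  expect_equal(fd$factor[2] / fd$factor[1], 2, tolerance = 1e-6)
  expect_equal(exp(mean(log(fd$factor))), 1, tolerance = 1e-9)
  expect_error(tmm_factors(cbind(c(1, 0), c(0, 1))), "no co-expressed")
})

test_that("TMM equals an independently coded step-by-step oracle to 1e-9", {
  cfg <- fixture_config()
  cnt <- generate_counts(cfg)
  ref <- "S1"
  mine <- tmm_factors(cnt$counts, ref = ref)
  oracle <- oracle_tmm(cnt$counts, ref_col = 1)
  expect_lt(max(abs(mine$factor - oracle)), 1e-9)
  # and on further seeded 200 x 4 matrices
  withr::with_seed(99, {
    for (r in 1:3) {
      m <- matrix(rnbinom(800, mu = sample(20:200, 200, TRUE), size = 5),
                  200, 4, dimnames = list(NULL, paste0("S", 1:4)))
      expect_lt(max(abs(tmm_factors(m, ref = "S2")$factor -
                          oracle_tmm(m, ref_col = 2))), 1e-9)
    }
  })
})

test_that("TMM agrees with edgeR through the library-size relation", {
  skip_if_not_installed("edgeR")
  cnt <- generate_counts(fixture_config())
  mine <- tmm_factors(cnt$counts, ref = "S1")
  f_edger <- edgeR::calcNormFactors(cnt$counts, method = "TMM", refColumn = 1)
  expected <- f_edger * colSums(cnt$counts)
  expected <- expected / exp(mean(log(expected)))
  expect_equal(mine$factor, unname(expected), tolerance = 1e-9)
})

test_that("TMM recovers planted scaling factors without spiked features", {
  cfg <- fixture_config()
  cfg$counts_spec$n_features <- 2000L
  cfg$counts_spec$spike_fraction <- 0
  cnt <- generate_counts(cfg)
  est <- tmm_factors(cnt$counts)
  expect_lt(max(abs(est$factor / cnt$true_factors - 1)), 0.05)
  # with all true factors equal, estimates are ~1
  cfg$counts_spec$true_factors <- c(1, 1, 1, 1)
  cnt1 <- generate_counts(cfg)
  expect_lt(max(abs(tmm_factors(cnt1$counts)$factor - 1)), 0.05)
})

test_that("TMM factors are invariant to feature order and all-zero features", {
  cnt <- generate_counts(fixture_config())
  base <- tmm_factors(cnt$counts, ref = "S1")
  withr::with_seed(2, shuf <- sample(nrow(cnt$counts)))
  expect_equal(tmm_factors(cnt$counts[shuf, ], ref = "S1")$factor, base$factor)
  padded <- rbind(cnt$counts, matrix(0L, 10, 4,
                                     dimnames = list(paste0("z", 1:10), NULL)))
  expect_equal(tmm_factors(padded, ref = "S1")$factor, base$factor)
})

test_that("relative expression follows the ddCt arithmetic", {
  ct <- tibble::tibble(
    gene = rep(c("g", "actin"), each = 4),
    sample = rep(paste0("s", 1:4), 2),
    group = rep(c("ctl", "ctl", "trt", "trt"), 2),
    replicate = rep(c(1, 2, 1, 2), 2),
    ct = c(24, 24, 23, 23, 20, 20, 20, 20))
  ru <- relative_expression(ct, "actin", calibrator = "ctl")
  expect_equal(ru$ru[ru$group == "ctl"], 1)    # calibrator RU = 1
  expect_equal(ru$ru[ru$group == "trt"], 2)    # ddCt = -1 -> RU = 2
  # adding a machine offset per sample cancels in dCt
  ct2 <- ct
  offs <- c(s1 = 1.3, s2 = -0.7, s3 = 2.2, s4 = 0.4)
  ct2$ct <- ct2$ct + offs[ct2$sample]
  expect_equal(relative_expression(ct2, "actin", calibrator = "ctl")$ru, ru$ru)
  # samples without a reference Ct are dropped with a warning
  ct3 <- ct[-(5:5), ]
  expect_warning(relative_expression(ct3, "actin", calibrator = "ctl"),
                 "without reference")
})

test_that("a planted 3-fold change is recovered within 10%", {
  ctf <- generate_ct(fixture_config())
  ru <- relative_expression(ctf$ct, "actin", calibrator = "ON")
  est <- ru$ru[ru$gene == "SPL_A" & ru$group == "OFF"]
  expect_lt(abs(est / 3 - 1), 0.10)
  # flat gene stays near 1
  flat <- ru$ru[ru$gene == "SPL_B" & ru$group != "ON"]
  expect_true(all(abs(log2(flat)) < log2(1.45)))
})

test_that("ANOVA F equals the squared pooled t for two groups; degenerate data give p = 1", {
  withr::with_seed(12, {
    d <- data.frame(value = c(rnorm(6), rnorm(6, 1)),
                    group = rep(c("a", "b"), each = 6))
  })
  fit <- anova_tukey(d)
  tt <- stats::t.test(value ~ group, data = d, var.equal = TRUE)
  expect_equal(fit$f, unname(tt$statistic^2))
  expect_equal(fit$p, tt$p.value)

  flat <- data.frame(value = rep(5, 9), group = rep(c("a", "b", "c"), 3))
  fit0 <- anova_tukey(flat)
  expect_equal(fit0$p, 1)
  expect_false(any(fit0$pairwise$significant))
  expect_equal(length(unique(fit0$letters$letter)), 1L)
})

test_that("near-identical groups are never flagged; tidy/glance expose the fit", {
  withr::with_seed(14, {
    d <- data.frame(value = 3 + rnorm(15, sd = 1e-4),
                    group = rep(c("a", "b", "c"), each = 5))
  })
  fit <- anova_tukey(d)
  expect_false(any(fit$pairwise$significant))
  expect_equal(nrow(tidy(fit)), 3)
  g <- glance(fit)
  expect_equal(g$df.residual, 12)
  expect_equal(g$statistic, fit$f)
})

test_that("Tukey-Kramer significance pattern matches a permutation oracle", {
  withr::with_seed(4242, {
    d <- data.frame(value = c(rnorm(5, 0), rnorm(5, 0), rnorm(5, 2)),
                    group = rep(c("g1", "g2", "g3"), each = 5))
  })
  fit <- anova_tukey(d, alpha = 0.05)

  # permutation oracle: family-wise max-|q| null distribution
  q_stats <- function(values, groups) {
    ns <- table(groups)
    means <- tapply(values, groups, mean)
    mse <- sum(tapply(values, groups, function(x) sum((x - mean(x))^2))) /
      (length(values) - length(ns))
    combs <- utils::combn(names(means), 2)
    vapply(seq_len(ncol(combs)), function(k) {
      a <- combs[1, k]; b <- combs[2, k]
      abs(means[[a]] - means[[b]]) /
        sqrt(mse / 2 * (1 / ns[[a]] + 1 / ns[[b]]))
    }, numeric(1))
  }
  obs <- q_stats(d$value, d$group)
  withr::with_seed(555, {
    B <- 100000
    maxq <- vapply(seq_len(B), function(b) {
      max(q_stats(d$value, sample(d$group)))
    }, numeric(1))
  })
  p_perm <- vapply(obs, function(q) mean(maxq >= q), numeric(1))
  expect_equal(fit$pairwise$significant, p_perm < 0.05)
  # the null pair is never flagged and the planted effect is detected
  expect_false(fit$pairwise$significant[fit$pairwise$group_a == "g1" &
                                          fit$pairwise$group_b == "g2"])
  expect_true(any(fit$pairwise$significant))

  # p-values are invariant under a common affine transform
  d2 <- d; d2$value <- 3.7 * d2$value - 11
  fit2 <- anova_tukey(d2)
  expect_equal(fit2$p, fit$p)
  expect_equal(fit2$pairwise$p_adj, fit$pairwise$p_adj)
  expect_equal(fit2$letters$letter, fit$letters$letter)
})

test_that("letter displays group non-different means under one letter", {
  withr::with_seed(9, {
    d <- data.frame(value = c(rnorm(6, 0, .3), rnorm(6, 0.2, .3), rnorm(6, 8, .3)),
                    group = rep(c("lo1", "lo2", "hi"), each = 6))
  })
  fit <- anova_tukey(d)
  lt <- stats::setNames(fit$letters$letter, fit$letters$group)
  expect_equal(lt[["lo1"]], lt[["lo2"]])
  expect_false(lt[["hi"]] == lt[["lo1"]])
})
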