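# Binding-site scanning under the positional mismatch rule.

test_that("binding signature is the reverse complement and an involution", {
  expect_equal(binding_signature(strrep("A", 20)), strrep("T", 20))
  m <- mir156_sequence()
  expect_equal(binding_signature(binding_signature(m)), m)
  # RNA input is accepted
  expect_equal(binding_signature("UGACAGAAGAGAGUGAGCAC"),
               binding_signature(m))
  expect_error(binding_signature("ACGTN"), "contains N")
})

test_that("mismatch rule validates its arguments", {
  expect_error(mismatch_rule(max_mismatches = 4), "exceeds")
  r <- mismatch_rule()
  expect_equal(r$allowed_positions, c(1L, 7L, 9L))
  expect_equal(r$max_mismatches, 2L)
  expect_false(r$wobble_counts_as_match)
})

test_that("sites are accepted only with mismatches at allowed positions", {
  m <- mir156_sequence()
  sig <- binding_signature(m)
  L <- nchar(sig)
  mutate_at_mirna_pos <- function(site, positions) {
    ch <- strsplit(site, "")[[1]]
    for (p in positions) {
      j <- L - p + 1
      ch[j] <- setdiff(c("A", "C", "G", "T"), ch[j])[1]
    }
    paste(ch, collapse = "")
  }
  withr::with_seed(21, {
    flank5 <- random_dna_str(150); flank3 <- random_dna_str(150)
  })
  # perfect site
  s0 <- find_target_sites(c(t = paste0(flank5, sig, flank3)), m)
  expect_equal(nrow(s0), 1)
  expect_equal(s0$start, 150L)
  expect_equal(s0$mismatch_positions, "")
  # mismatches at 7 and 9: accepted with the exact position set
  s79 <- find_target_sites(
    c(t = paste0(flank5, mutate_at_mirna_pos(sig, c(7, 9)), flank3)), m)
  expect_equal(s79$n_mismatch, 2L)
  expect_equal(s79$mismatch_positions, "7,9")
  # same site mutated at position 5: rejected
  s5 <- find_target_sites(
    c(t = paste0(flank5, mutate_at_mirna_pos(sig, 5), flank3)), m)
  expect_equal(nrow(s5), 0)
  # three mismatches, all at allowed positions: rejected
  s179 <- find_target_sites(
    c(t = paste0(flank5, mutate_at_mirna_pos(sig, c(1, 7, 9)), flank3)), m)
  expect_equal(nrow(s179), 0)
  # windows containing N never match
  sN <- find_target_sites(c(t = paste0(flank5, sub("T", "N", sig), flank3)), m)
  expect_equal(nrow(sN), 0)
})

test_that("exactly 37 distinct site variants are accepted under the default rule", {
  vars <- enumerate_accepted_sites(mir156_sequence())
  expect_equal(length(vars), 37)  # 1 exact + 9 single + 27 double
  # each enumerated variant is found by the scanner...
  withr::with_seed(3, {
    flank <- random_dna_str(60)
  })
  for (v in vars) {
    hit <- find_target_sites(c(t = paste0(flank, v, flank)), mir156_sequence())
    expect_true(60L %in% hit$start)
  }
  # ...and a brute-force enumeration over all Hamming<=2 20-mers agrees
  sig <- strsplit(binding_signature(mir156_sequence()), "")[[1]]
  L <- length(sig)
  accepted <- 0
  for (i in seq_len(L)) {
    for (bi in setdiff(c("A", "C", "G", "T"), sig[i])) {
      v1 <- sig; v1[i] <- bi
      hits <- naive_site_scan(paste(v1, collapse = ""), mir156_sequence())
      accepted <- accepted + (length(hits) > 0)
      for (j in seq_len(L)) {
        if (j <= i) next
        for (bj in setdiff(c("A", "C", "G", "T"), sig[j])) {
          v2 <- v1; v2[j] <- bj
          hits2 <- naive_site_scan(paste(v2, collapse = ""), mir156_sequence())
          accepted <- accepted + (length(hits2) > 0)
        }
      }
    }
  }
  expect_equal(accepted + 1, 37)  # + the exact signature
})

test_that("scanner equals the naive per-window Hamming oracle on random transcripts", {
  m <- mir156_sequence()
  withr::with_seed(77, {
    for (r in 1:100) {
      # random background plus occasional planted (possibly illegal) variants
      s <- random_dna_str(sample(120:400, 1))
      if (r %% 3 == 0) {
        v <- planted <- strsplit(binding_signature(m), "")[[1]]
        k <- sample(0:3, 1)
        pos <- sample(20, k)
        for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
        at <- sample(nchar(s) - 21, 1)
        substring(s, at, at + 19) <- paste(v, collapse = "")
      }
      mine <- find_target_sites(c(t = s), m)
      oracle <- naive_site_scan(s, m)
      expect_equal(nrow(mine), length(oracle))
      if (length(oracle) > 0) {
        expect_equal(mine$start, vapply(oracle, `[[`, integer(1), "start"))
        expect_equal(mine$mismatch_positions,
                     vapply(oracle, function(h) paste(h$pos, collapse = ","),
                            character(1)))
      }
    }
  })
})

test_that("zero allowed mismatches reduces to exact string search", {
  m <- mir156_sequence()
  sig <- binding_signature(m)
  withr::with_seed(13, s <- paste0(random_dna_str(100), sig,
                                   random_dna_str(50), sig, random_dna_str(30)))
  rule0 <- mismatch_rule(max_mismatches = 0, allowed_positions = 1)
  mine <- find_target_sites(c(t = s), m, rule0)
  exact <- as.integer(gregexpr(sig, s, fixed = TRUE)[[1]]) - 1L
  expect_equal(mine$start, exact)
})

test_that("enlarging the allowed positions never loses sites", {
  m <- mir156_sequence()
  withr::with_seed(55, {
    for (r in 1:20) {
      s <- random_dna_str(300)
      v <- strsplit(binding_signature(m), "")[[1]]
      pos <- sample(20, 2)
      for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
      at <- sample(250, 1)
      substring(s, at, at + 19) <- paste(v, collapse = "")
      n_small <- nrow(find_target_sites(c(t = s), m, mismatch_rule()))
      n_large <- nrow(find_target_sites(
        c(t = s), m, mismatch_rule(allowed_positions = c(1, 5, 7, 9, 12))))
      n_all <- nrow(find_target_sites(
        c(t = s), m, mismatch_rule(allowed_positions = 1:20)))
      expect_gte(n_large, n_small)
      expect_gte(n_all, n_large)
    }
  })
})

test_that("reverse-complement scanning yields mirror-coordinate sites", {
  m <- mir156_sequence()
  sig <- binding_signature(m)
  rule0 <- mismatch_rule(max_mismatches = 0, allowed_positions = 1)
  withr::with_seed(8, s <- paste0(random_dna_str(80), sig, random_dna_str(40)))
  fwd <- find_target_sites(c(t = s), m, rule0)
  # scanning the reverse complement for the reverse-complement signature:
  # the miRNA whose signature is revcomp(sig) is sig itself
  rev_sites <- find_target_sites(
    c(t = splfam:::reverse_complement(s)), sig, rule0)
  expect_equal(sort(nchar(s) - 20L - rev_sites$start), sort(fwd$start))
})

test_that("site location labels regions and flags boundary-spanning sites", {
  part <- tibble::tibble(
    transcript_id = "t",
    region = c("FIVE_UTR", "CDS", "THREE_UTR"),
    start = c(0L, 100L, 493L), end = c(100L, 493L, 900L),
    frame_warning = FALSE)
  mk_site <- function(s) tibble::tibble(transcript_id = "t", start = s,
                                        end = s + 20L, n_mismatch = 0L,
                                        mismatch_positions = "")
  expect_equal(locate_site(mk_site(500L), part)$region, "THREE_UTR")
  sp <- locate_site(mk_site(480L), part)
  expect_equal(sp$region, "SPANNING")
  expect_equal(sp$secondary_region, "CDS")  # midpoint 490 lies in the CDS
  expect_error(locate_site(mk_site(895L), part), "out of bounds")
})

test_that("planted sites in the fixture get the generator's truth labels", {
  fix <- default_fixture()
  sites <- default_sites()
  truth <- fix$truth
  legal <- truth[!is.na(truth$site_legal) & truth$site_legal, ]
  found <- dplyr::inner_join(
    legal, sites, by = c(transcript_id = "transcript_id"))
  expect_equal(nrow(found), nrow(legal))
  expect_equal(found$start, found$site_start)
  expect_equal(found$region, found$site_region)
  expect_equal(found$mismatch_positions.y, found$mismatch_positions.x)
  # illegal planted sites are never reported
  illegal <- truth[!is.na(truth$site_legal) & !truth$site_legal, ]
  expect_equal(nrow(illegal), 2)
  expect_false(any(illegal$transcript_id %in% sites$transcript_id))
})

test_that("BED projection splits intron-crossing sites into genomic blocks", {
  fix <- default_fixture()
  sites <- default_sites()
  bed <- sites_to_bed(sites, fix$transcripts)
  expect_true(all(bed$end > bed$start))
  # total block length per site equals the site length
  per_site <- tapply(bed$end - bed$start, bed$name, sum)
  expect_true(all(per_site == 20L))
  # blocks fall inside the right chromosome and carry the transcript strand
  tx <- fix$transcripts
  for (i in seq_len(nrow(bed))) {
    row <- tx[tx$transcript_id == sub("^miR156_site_(.*)_\\d+$", "\\1",
                                      bed$name[i]), ]
    expect_equal(bed$strand[i], row$strand[1])
  }
  # round-trip: extracting the blocks re-yields the site sequence
  i <- which(!duplicated(bed$name))[1]
  blocks <- bed[bed$name == bed$name[i], ]
  seqs <- substring(fix$genome[[blocks$chrom[1]]],
                    blocks$start + 1L, blocks$end)
  site_seq <- paste(seqs, collapse = "")
  if (blocks$strand[1] == "-") site_seq <- splfam:::reverse_complement(site_seq)
  tid <- sub("^miR156_site_(.*)_\\d+$", "\\1", blocks$name[1])
  st <- sites[sites$transcript_id == tid, ]$start[1]
  spl <- spliced_sequence(fix$transcripts[fix$transcripts$transcript_id == tid, ],
                          fix$genome)
  expect_equal(site_seq, unname(substring(spl, st + 1, st + 20)))
})
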