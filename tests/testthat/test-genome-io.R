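# Genome and annotation I/O: parsing, coordinate conventions, spliced
# sequences, region partitions, translation, ORF search.

test_that("FASTA parsing normalizes, preserves order, and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT", ">chr2", "acg", "uAC"), f)
  g <- read_genome_fasta(f)
  expect_identical(g, c(chr1 = "ACGT", chr2 = "ACGTAC"))

  # wrapped and unwrapped records agree
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s", "ACGTACGTAC", "GTACGT"), f2)
  expect_identical(unname(read_genome_fasta(f2)[1]), "ACGTACGTACGTACGT")

  fd <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), fd)
  expect_error(read_genome_fasta(fd), "duplicate.*a")

  fe <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">b", ""), fe)
  expect_error(read_genome_fasta(fe), "empty sequence")
})

test_that("GFF3 coordinates convert to 0-based half-open and round-trip", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t10\t.\t+\t.\tID=g1",
    "chr1\tx\tmRNA\t1\t10\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tx\texon\t1\t10\t.\t+\t.\tParent=t1"
  ), gff)
  tx <- read_transcript_models(gff)
  expect_equal(tx$exons[[1]], data.frame(start = 0L, end = 10L))
  expect_equal(tx$gene_id, "g1")

  # synthetic fixture round-trips: write -> parse -> identical models
  fix <- default_fixture()
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(fix$transcripts, f)
  back <- read_transcript_models(f)
  back <- back[match(fix$transcripts$transcript_id, back$transcript_id), ]
  expect_equal(back$strand, fix$transcripts$strand)
  for (i in seq_len(nrow(back))) {
    expect_equal(back$exons[[i]], fix$transcripts$exons[[i]],
                 ignore_attr = TRUE)
    expect_equal(back$cds[[i]], fix$transcripts$cds[[i]], ignore_attr = TRUE)
  }
})

test_that("CDS outside exons is a hard error; orphan exons are skipped with warning", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tmRNA\t1\t10\t.\t+\t.\tID=t1",
    "chr1\tx\texon\t1\t5\t.\t+\t.\tParent=t1",
    "chr1\tx\tCDS\t4\t9\t.\t+\t.\tParent=t1"
  ), gff)
  expect_error(read_transcript_models(gff), "outside its exons")

  gff2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tmRNA\t1\t10\t.\t+\t.\tID=t1",
    "chr1\tx\texon\t1\t10\t.\t+\t.\tParent=t1",
    "chr1\tx\texon\t20\t30\t.\t+\t.\tID=orphan"
  ), gff2)
  expect_warning(tx <- read_transcript_models(gff2), "orphan")
  expect_equal(nrow(tx), 1)
})

test_that("spliced sequences follow exon order and strand convention", {
  genome <- c(chrA = "AAACCGGGT")
  tx <- tibble::tibble(
    transcript_id = c("p", "m"), gene_id = c("p", "m"),
    seqid = "chrA", strand = c("+", "-"),
    exons = list(data.frame(start = c(0L, 5L), end = c(3L, 8L)),
                 data.frame(start = c(0L, 5L), end = c(3L, 8L))),
    cds = list(data.frame(start = integer(0), end = integer(0)),
               data.frame(start = integer(0), end = integer(0))))
  s <- spliced_sequence(tx, genome)
  expect_identical(unname(s["p"]), "AAAGGG")
  expect_identical(unname(s["m"]), "CCCTTT")

  bad <- tx[1, ]
  bad$exons <- list(data.frame(start = 0L, end = 99L))
  expect_error(spliced_sequence(bad, genome), "out of chromosome bounds")
})

test_that("reverse-complementing the genome and flipping strands preserves spliced sequences", {
  fix <- default_fixture()
  tx <- fix$transcripts
  orig <- spliced_sequence(tx, fix$genome)
  flipped_genome <- vapply(fix$genome, splfam:::reverse_complement, character(1))
  L <- nchar(fix$genome)
  tx2 <- tx
  tx2$strand <- ifelse(tx$strand == "+", "-", "+")
  for (i in seq_len(nrow(tx2))) {
    n <- L[[tx2$seqid[i]]]
    for (col in c("exons", "cds")) {
      iv <- tx2[[col]][[i]]
      if (nrow(iv) > 0) {
        tx2[[col]][[i]] <- data.frame(start = rev(n - iv$end),
                                      end = rev(n - iv$start))
      }
    }
  }
  expect_identical(spliced_sequence(tx2, flipped_genome), orig)
})

test_that("region partition tiles the transcript and labels regions correctly", {
  tx <- tibble::tibble(
    transcript_id = "t", gene_id = "t", seqid = "c", strand = "+",
    exons = list(data.frame(start = 0L, end = 900L)),
    cds = list(data.frame(start = 100L, end = 493L)))
  p <- region_partition(tx)
  expect_equal(p$region, c("FIVE_UTR", "CDS", "THREE_UTR"))
  expect_equal(p$start, c(0L, 100L, 493L))
  expect_equal(p$end, c(100L, 493L, 900L))

  tx$cds <- list(data.frame(start = integer(0), end = integer(0)))
  p2 <- region_partition(tx)
  expect_equal(p2$region, "NONCODING")
  expect_equal(c(p2$start, p2$end), c(0L, 900L))

  # every transcript in the synthetic genome tiles exactly
  fix <- default_fixture()
  part <- region_partition(fix$transcripts)
  lens <- tapply(part$end - part$start, part$transcript_id, sum)
  spl <- nchar(spliced_sequence(fix$transcripts, fix$genome))
  expect_equal(as.vector(lens[names(spl)]), unname(spl))
  # regions are contiguous and disjoint per transcript
  for (tid in unique(part$transcript_id)) {
    p <- part[part$transcript_id == tid, ]
    expect_equal(p$start[-1], p$end[-nrow(p)])
  }
})

test_that("minus-strand partition matches the generator's truth", {
  fix <- default_fixture()
  tr <- fix$truth[fix$truth$is_family & !is.na(fix$truth$site_region), ]
  reps <- fix$transcripts[match(tr$transcript_id,
                                fix$transcripts$transcript_id), ]
  expect_true(any(reps$strand == "-"))  # mixture of strands exercised
  part <- region_partition(reps)
  sites <- tibble::tibble(transcript_id = tr$transcript_id,
                          start = tr$site_start,
                          end = tr$site_start + 20L,
                          n_mismatch = 0L, mismatch_positions = "")
  located <- locate_site(sites, part)
  expect_equal(located$region, tr$site_region)
})

test_that("translation follows the standard code and flags internal stops", {
  expect_identical(translate_cds("ATGAAATGA"), "MK")
  expect_error(translate_cds("ATGTAAAAATGA"), "internal stop.*2")
  expect_error(translate_cds("ATGAA"), "multiple of 3")
})

test_that("longest ORF matches exhaustive sense-frame enumeration", {
  # two equal-length ORFs: the 5'-most is reported
  seq <- paste0("CC", "ATGAAACCCTGA", "TT", "ATGGGGAAATAG")
  orf <- longest_orf(seq)
  expect_equal(orf$start, 2L)
  expect_equal(orf$protein, "MKP")

  brute_orf <- function(s) {
    ch <- strsplit(s, "")[[1]]
    best <- NULL
    for (start in seq_along(ch)) {
      if (start + 2 > length(ch)) break
      if (paste(ch[start:(start + 2)], collapse = "") != "ATG") next
      k <- start
      while (k + 5 <= length(ch)) {
        cod <- paste(ch[(k + 3):(k + 5)], collapse = "")
        if (cod %in% c("TAA", "TAG", "TGA")) {
          len <- k + 5 - start + 1
          if (is.null(best) || len > best$len) {
            best <- list(start = start - 1L, end = start - 1L + len, len = len)
          }
          break
        }
        k <- k + 3
      }
    }
    best
  }
  withr::with_seed(11, {
    for (rep in 1:5) {
      s <- random_dna_str(2000)
      mine <- longest_orf(s)
      ref <- brute_orf(s)
      if (is.null(ref)) {
        expect_null(mine)
      } else {
        expect_equal(mine$start, ref$start)
        expect_equal(mine$end, ref$end)
      }
    }
  })
})
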