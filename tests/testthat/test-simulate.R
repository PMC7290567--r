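test_that("reference construction is deterministic, seed-sensitive and bounded", {
  r1 <- build_reference(16569, seed = 1)
  r2 <- build_reference(16569, seed = 1)
  r3 <- build_reference(16569, seed = 2)
  expect_equal(r1$length, 16569L)
  expect_equal(nchar(r1$sequence), 16569L)
  expect_true(r1$circular)
  expect_identical(r1$sequence, r2$sequence)
  expect_false(identical(r1$sequence, r3$sequence))
  expect_false(grepl("[^ACGT]", r1$sequence))
  expect_error(build_reference(500, seed = 1), "at least 1000")
})

test_that("genotype application realises homoplasmic variants and keeps heteroplasmy as mixture", {
  ref <- build_reference(2000, seed = 3)
  empty <- apply_genotype(ref, NULL, cell_genotype("c"))
  expect_identical(empty$sequence, ref$sequence)
  expect_equal(nrow(empty$truth), 0)

  p <- 777L
  rb <- substring(ref$sequence, p, p)
  ab <- setdiff(c("A", "C", "G", "T"), rb)[1]
  g <- cell_genotype("c", extra_hom = data.frame(pos = p, ref = rb, alt = ab))
  hap <- apply_genotype(ref, NULL, g)
  diff_at <- which(strsplit(hap$sequence, "")[[1]] != strsplit(ref$sequence, "")[[1]])
  expect_equal(diff_at, p)

  # two-level haplogroup with 2 + 3 defining variants: truth has all 5
  pos <- c(100, 200, 300, 400, 500)
  rb <- substring(ref$sequence, pos, pos)
  ab <- vapply(rb, function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  tok <- function(i) paste0(pos[i], rb[i], ">", ab[i], collapse = ",")
  tree <- phylotree(data.frame(
    haplogroup = c("R", "Ra"), parent = c("-", "R"),
    variants = c(tok(1:2), tok(3:5))))
  hap2 <- apply_genotype(ref, tree, cell_genotype("c", haplogroup = "Ra"))
  expect_equal(sort(hap2$truth$pos), pos)
  expect_true(all(hap2$truth$fraction == 1))

  # reference-allele mismatch is rejected with the position named
  bad <- cell_genotype("c", extra_hom = data.frame(pos = 5, ref = "N", alt = "A"))
  expect_error(apply_genotype(ref, NULL, bad), "5")
})

test_that("read generation conserves counts and respects the bias models", {
  ref <- build_reference(8000, seed = 4)
  hap <- apply_genotype(ref, NULL, cell_genotype("c"))

  bulk <- protocol_model("BULK", dup_rate = 0, error_rate = 0)
  rs <- generate_reads(hap, bulk, depth = 100, seed = 9)
  expect_equal(nrow(rs), round(100 * 8000 / 100))
  expect_equal(nrow(rs), attr(rs, "n_requested"))
  expect_true(all(nchar(rs$seq) == nchar(rs$qual)))
  expect_true(all(rs$origin == "mt"))
  g <- gini(depth_profile(rs, L = ref$length))
  expect_lt(g, 0.1)

  # determinism
  rs2 <- generate_reads(hap, bulk, depth = 100, seed = 9)
  expect_identical(rs$seq, rs2$seq)

  # MALBAC-like dropout ~90% leaves ~10% of the genome covered
  mal <- protocol_model("MALBAC", dropout = 0.9)
  rm <- generate_reads(hap, mal, depth = 50, seed = 10)
  br <- coverage_stats(depth_profile(rm, L = ref$length), min_depth = 1)$breadth_pct
  expect_gt(br, 3)
  expect_lt(br, 25)

  # duplicates are exact copies of existing fragments at the stated rate
  atac <- protocol_model("ATAC", dup_rate = 0.3, error_rate = 0)
  ra <- generate_reads(hap, atac, depth = 20, seed = 11)
  expect_equal(sum(ra$is_dup), round(0.3 * nrow(ra)))
  dups <- ra[ra$is_dup, ]
  orig <- ra[!ra$is_dup, ]
  key <- paste(orig$start, orig$strand, orig$seq)
  expect_true(all(paste(dups$start, dups$strand, dups$seq) %in% key))
})

test_that("sampled heteroplasmy is binomial around the true fraction", {
  ref <- build_reference(2000, seed = 5)
  p <- 1000L
  rb <- substring(ref$sequence, p, p)
  ab <- setdiff(c("A", "C", "G", "T"), rb)[1]
  g <- cell_genotype("c", het = data.frame(pos = p, ref = rb, alt = ab,
                                           fraction = 0.3))
  hap <- apply_genotype(ref, NULL, g)
  bulk <- protocol_model("BULK", dup_rate = 0, error_rate = 0)
  rs <- generate_reads(hap, bulk, depth = 1000, seed = 6)
  off <- (p - rs$start) %% ref$length
  cover <- off < nchar(rs$seq)
  base <- substr(ifelse(rs$strand == "-", scmito:::revcomp(rs$seq), rs$seq),
                 off + 1, off + 1)[cover]
  af <- mean(base == ab)
  dp <- length(base)
  expect_gt(dp, 500)
  expect_lt(abs(af - 0.3), 3 * sqrt(0.3 * 0.7 / dp))
})

test_that("mean observed heteroplasmy converges to h over seeds", {
  ref <- build_reference(1500, seed = 8)
  bulk <- protocol_model("BULK", dup_rate = 0, error_rate = 0)
  for (h in c(0.1, 0.5, 0.9)) {
    p <- 700L
    rb <- substring(ref$sequence, p, p)
    ab <- setdiff(c("A", "C", "G", "T"), rb)[1]
    g <- cell_genotype("c", het = data.frame(pos = p, ref = rb, alt = ab,
                                             fraction = h))
    hap <- apply_genotype(ref, NULL, g)
    afs <- vapply(1:8, function(s) {
      rs <- generate_reads(hap, bulk, depth = 150, seed = s)
      off <- (p - rs$start) %% ref$length
      cover <- off < nchar(rs$seq)
      base <- substr(ifelse(rs$strand == "-", scmito:::revcomp(rs$seq), rs$seq),
                     off + 1, off + 1)[cover]
      mean(base == ab)
    }, 0)
    n_tot <- 8 * 150  # approximate total covering reads
    expect_lt(abs(mean(afs) - h), 4 * sqrt(h * (1 - h) / n_tot))
  }
})

test_that("NumtS insertion respects divergence and records true intervals", {
  ref <- build_reference(4000, seed = 12)
  hap <- apply_genotype(ref, NULL, cell_genotype("c"))

  m0 <- numts_model(count = 2, len_min = 400, len_max = 400, divergence = 0,
                    contig_length = 4000)
  nz <- insert_numts(hap, m0, seed = 13)
  for (i in seq_len(nrow(nz$truth))) {
    tr <- nz$truth[i, ]
    got <- substr(nz$contigs[[1]], tr$start, tr$end)
    src <- scmito:::circular_substr(hap$sequence, tr$mt_start, tr$mt_len)
    expect_identical(got, src)
    expect_equal(tr$n_sub, 0)
  }

  m3 <- numts_model(count = 3, len_min = 500, len_max = 500, divergence = 0.03,
                    contig_length = 6000)
  nd <- insert_numts(hap, m3, seed = 14)
  for (i in seq_len(nrow(nd$truth))) {
    tr <- nd$truth[i, ]
    got <- strsplit(substr(nd$contigs[[1]], tr$start, tr$end), "")[[1]]
    src <- strsplit(scmito:::circular_substr(hap$sequence, tr$mt_start,
                                             tr$mt_len), "")[[1]]
    hamming <- sum(got != src)
    expect_equal(hamming, tr$n_sub)  # truth interval round-trips
    expect_lt(abs(tr$n_sub - 15), 3 * sqrt(500 * 0.03 * 0.97) + 1e-9)
  }

  expect_error(insert_numts(hap, numts_model(count = 10, len_min = 900,
                                             len_max = 900,
                                             contig_length = 4000), seed = 1),
               "too short")
})

test_that("FASTQ round trip preserves reads and qualities", {
  ref <- build_reference(1200, seed = 15)
  hap <- apply_genotype(ref, NULL, cell_genotype("c"))
  rs <- generate_reads(hap, protocol_model("BULK"), depth = 5, seed = 16)
  path <- tempfile(fileext = ".fastq")
  write_fastq(rs, path)
  back <- read_fastq(path)
  expect_identical(back$id, rs$id)
  expect_identical(back$seq, rs$seq)
  expect_identical(back$qual, rs$qual)
})
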