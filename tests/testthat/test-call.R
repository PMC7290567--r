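test_that("pileup applies the base-quality threshold and tallies alleles", {
  ref <- build_reference(2000, seed = 51)
  p <- 500L
  base_at <- function(s, i) substr(s, i, i)
  rd <- substr(ref$sequence, 481, 520)  # covers 481..520
  alt <- setdiff(c("A", "C", "G", "T"), base_at(ref$sequence, p))[1]
  rd_alt <- rd
  substr(rd_alt, 20, 20) <- alt  # position 500

  # 10 reads: 7 ref + 3 alt, all Q35; plus one Q29 alt read (excluded)
  a <- mk_aln(start = rep(481L, 11), cigar = rep("40M", 11),
              seq = c(rep(rd, 7), rep(rd_alt, 3), rd_alt),
              qual = c(rep(q2s(rep(35, 40)), 10), q2s(rep(29, 40))),
              id = sprintf("r%02d", 1:11), L = ref$length)
  pp <- build_pileup(a, ref, min_base_quality = 30)
  expect_equal(pp$filtered_depth[p], 10)
  expect_equal(pp$raw_depth[p], 11)
  expect_equal(unname(pp$counts[alt, p]), 3)
  expect_equal(unname(pp$counts[base_at(ref$sequence, p), p]), 7)
  expect_equal(pp$filtered_depth[1], 0)  # uncovered site

  calls <- call_variants(pp, ref, min_support = 3)
  hit <- calls[calls$pos == p & calls$alt == alt, ]
  expect_equal(hit$support, 3)
  expect_equal(hit$total, 10)
  expect_equal(hit$af, 0.3)
})

test_that("variant calling enforces minimum support and reports AF", {
  ref <- build_reference(2000, seed = 52)
  rd <- substr(ref$sequence, 101, 140)
  alt_of <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  alt <- alt_of(substr(ref$sequence, 120, 120))
  rd_alt <- rd
  substr(rd_alt, 20, 20) <- alt

  mk <- function(n_alt, n_ref) {
    mk_aln(start = rep(101L, n_alt + n_ref), cigar = rep("40M", n_alt + n_ref),
           seq = c(rep(rd_alt, n_alt), rep(rd, n_ref)),
           id = sprintf("r%03d", seq_len(n_alt + n_ref)), L = ref$length)
  }
  # 4 supporting reads: below the >=5 threshold, no call
  pp4 <- build_pileup(mk(4, 10), ref)
  expect_equal(nrow(call_variants(pp4, ref)[call_variants(pp4, ref)$pos == 120, ]), 0)

  # 5 of 100 -> AF 0.05
  pp5 <- build_pileup(mk(5, 95), ref)
  c5 <- call_variants(pp5, ref)
  expect_equal(c5$af[c5$pos == 120], 0.05)

  # 20 of 50 -> AF 0.4
  pp20 <- build_pileup(mk(20, 30), ref)
  c20 <- call_variants(pp20, ref)
  expect_equal(c20$af[c20$pos == 120], 0.4)
})

test_that("indels near read ends are suppressed, anchored ones called", {
  ref <- build_reference(2000, seed = 53)
  rd <- substr(ref$sequence, 101, 140)
  # insertion of CCC 3 bases from the read end on all supporting reads:
  # 35 aligned, 3 inserted, 2 aligned -> end distance 2 (< 5) -> dropped
  ins_near <- paste0(substr(rd, 1, 35), "CCC", substr(rd, 36, 37))
  a1 <- mk_aln(start = rep(101L, 6), cigar = rep("35M3I2M", 6),
               seq = ins_near, id = sprintf("r%d", 1:6), L = ref$length)
  pp1 <- build_pileup(a1, ref)
  expect_equal(nrow(call_variants(pp1, ref)[call_variants(pp1, ref)$type == "ins", ]), 0)

  # well-anchored insertion after ref pos 120 (20 aligned, 3 ins, 20 aligned)
  ins_mid <- paste0(substr(rd, 1, 20), "CCC", substr(rd, 21, 40))
  a2 <- mk_aln(start = rep(101L, 6), cigar = rep("20M3I20M", 6),
               seq = ins_mid, id = sprintf("r%d", 1:6), L = ref$length)
  pp2 <- build_pileup(a2, ref)
  ic <- call_variants(pp2, ref)
  ic <- ic[ic$type == "ins", ]
  expect_equal(ic$pos, 120)
  expect_equal(ic$alt, paste0(substr(ref$sequence, 120, 120), "CCC"))
  expect_equal(ic$support, 6)

  # 2-base deletion: read skips ref 121-122
  del_rd <- paste0(substr(rd, 1, 20), substr(rd, 23, 40))
  a3 <- mk_aln(start = rep(101L, 6), cigar = rep("20M2D18M", 6),
               seq = del_rd, id = sprintf("r%d", 1:6), L = ref$length)
  pp3 <- build_pileup(a3, ref)
  dc <- call_variants(pp3, ref)
  dc <- dc[dc$type == "del", ]
  expect_equal(dc$pos, 120)
  expect_equal(dc$ref, substr(ref$sequence, 120, 122))
  expect_equal(dc$alt, substr(ref$sequence, 120, 120))
})

test_that("raising min_support never increases the number of calls", {
  ref <- build_reference(2000, seed = 54)
  tree <- random_phylotree(ref, levels = 1, children = 2, seed = 55)
  g <- random_genotype(ref, tree, n_extra_hom = 2, n_het = 3, seed = 56)
  sim <- simulate_cell(ref, tree, g, protocol_model("MDA"), depth = 30,
                       seed = 57)
  aln <- filter_numts(align_reads(sim$reads, build_index(ref)))
  pp <- build_pileup(aln, ref)
  n_calls <- vapply(c(1, 3, 5, 10, 20),
                    function(ms) nrow(call_variants(pp, ref, min_support = ms)),
                    0L)
  expect_true(all(diff(n_calls) <= 0))
})

fake_pileup <- function(counts, L) {
  structure(list(counts = counts, filtered_depth = as.integer(colSums(counts)),
                 raw_depth = as.integer(colSums(counts)),
                 ins = data.frame(pos = integer(0), seq = character(0),
                                  end_dist = integer(0), read = integer(0)),
                 del = data.frame(pos = integer(0), len = integer(0),
                                  end_dist = integer(0), read = integer(0)),
                 min_base_quality = 30L, L = L),
            class = "mito_pileup")
}

test_that("consensus applies the 0.8 heteroplasmy rule and splits contigs", {
  ref <- build_reference(1000, seed = 58)
  L <- ref$length
  refbase <- strsplit(ref$sequence, "")[[1]]
  counts <- matrix(0L, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(L)) counts[refbase[i], i] <- 20L

  # site 100: AF 0.85 alternate; site 200: AF 0.50 alternate
  alt100 <- setdiff(c("A", "C", "G", "T"), refbase[100])[1]
  counts[refbase[100], 100] <- 3L; counts[alt100, 100] <- 17L  # 0.85
  alt200 <- setdiff(c("A", "C", "G", "T"), refbase[200])[1]
  counts[refbase[200], 200] <- 10L; counts[alt200, 200] <- 10L  # 0.50
  pp <- fake_pileup(counts, L)
  calls <- call_variants(pp, ref)
  asm <- build_consensus(pp, calls, ref, hf_threshold = 0.8, min_depth = 5)
  expect_equal(asm$n_contigs, 1)
  expect_equal(asm$breadth_pct, 100)
  cons <- asm$contigs$sequence[1]
  expect_equal(substr(cons, 100, 100), alt100)   # >= 0.8: alternate written
  expect_equal(substr(cons, 200, 200), refbase[200])  # < 0.8: reference kept

  # an internal uncovered gap of 100 sites splits the assembly
  counts2 <- counts
  counts2[, 401:500] <- 0L
  pp2 <- fake_pileup(counts2, L)
  asm2 <- build_consensus(pp2, call_variants(pp2, ref), ref)
  expect_equal(asm2$n_contigs, 2)
  expect_equal(asm2$breadth_pct, 100 * (L - 100) / L)
  expect_equal(asm2$callable$start, c(1, 501))
  expect_equal(asm2$callable$end, c(400, 1000))
})

test_that("error-free uniform coverage reproduces the haplotype exactly", {
  ref <- build_reference(2000, seed = 59)
  tree <- random_phylotree(ref, levels = 1, children = 2, seed = 60)
  g <- random_genotype(ref, tree, n_extra_hom = 3, n_het = 0, seed = 61)
  hap <- apply_genotype(ref, tree, g)
  proto <- protocol_model("BULK", dup_rate = 0, error_rate = 0)
  reads <- generate_reads(hap, proto, depth = 40, seed = 62)
  aln <- filter_numts(align_reads(reads, build_index(ref)))
  pp <- build_pileup(aln, ref)
  calls <- call_variants(pp, ref)
  asm <- build_consensus(pp, calls, ref)
  expect_equal(asm$n_contigs, 1)
  expect_identical(asm$contigs$sequence[1], hap$sequence)
})

test_that("VCF output round-trips through an independent parser", {
  ref <- build_reference(2000, seed = 63)
  refbase <- strsplit(ref$sequence, "")[[1]]
  calls <- data.frame(
    pos = c(150L, 750L, 1200L),
    ref = c(refbase[150], refbase[750], paste0(refbase[1200:1202], collapse = "")),
    alt = c(setdiff(c("A", "C", "G", "T"), refbase[150])[1],
            setdiff(c("A", "C", "G", "T"), refbase[750])[1],
            refbase[1200]),
    type = c("snp", "snp", "del"),
    support = c(95L, 5L, 40L), total = c(95L, 100L, 80L),
    stringsAsFactors = FALSE)
  calls$af <- calls$support / calls$total
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, ref, "cell1", path)
  back <- read_vcf(path)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$ref, calls$ref)
  expect_equal(back$alt, calls$alt)
  expect_equal(back$type, calls$type)
  expect_equal(back$total, calls$total)
  expect_equal(back$af, calls$af, tolerance = 1e-6)

  # snp at 750 with AF 1: the exact record layout
  one <- calls[2, ]; one$af <- 1; one$support <- 100L
  write_vcf(one, ref, "cell1", path)
  line <- grep("^[^#]", readLines(path), value = TRUE)
  expect_match(line, paste0("^chrM\t750\t\\.\t", one$ref, "\t", one$alt))
  expect_match(line, "DP=100;AF=1")

  # empty call set -> header-only VCF
  write_vcf(calls[0, ], ref, "cell1", path)
  expect_equal(length(grep("^[^#]", readLines(path))), 0)
  expect_equal(nrow(read_vcf(path)), 0)

  expect_error(write_vcf(calls[c(2, 1), ], ref, "x", path), "sorted")
})

test_that("deletion records are left-anchored in VCF", {
  ref <- build_reference(2000, seed = 64)
  rd <- substr(ref$sequence, 101, 140)
  del_rd <- paste0(substr(rd, 1, 20), substr(rd, 23, 40))
  a <- mk_aln(start = rep(101L, 6), cigar = rep("20M2D18M", 6), seq = del_rd,
              id = sprintf("r%d", 1:6), L = ref$length)
  pp <- build_pileup(a, ref)
  calls <- call_variants(pp, ref)
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls[calls$type == "del", ], ref, "c", path)
  line <- grep("^[^#]", readLines(path), value = TRUE)
  f <- strsplit(line, "\t")[[1]]
  expect_equal(f[2], "120")  # anchor base before the deleted run
  expect_equal(f[4], substr(ref$sequence, 120, 122))
  expect_equal(f[5], substr(ref$sequence, 120, 120))
})
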