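# SAM parsing, read filtering/clipping, damage profiling, pileup, coverage
# and consensus.

test_that("SAM records parse with CIGAR resolution and report malformed lines", {
  ref_len <- 50L
  sam <- make_sam(list(
    list(id = "r1", flag = 0, pos = 5, cigar = "4M", seq = "ACGT"),
    list(id = "r2", flag = 16, pos = 10, cigar = "2M1D2M", seq = "GGTT"),
    list(id = "r3", flag = 4, pos = 0, cigar = "*", seq = "AAAA"),
    list(id = "r4", flag = 0, pos = 20, cigar = "2S3M", seq = "TTACG")),
    ref_len = ref_len)
  reads <- read_sam_text(sam)
  expect_length(reads, 4)
  expect_equal(reads[[1]]$aligned_pairs$ref_pos, 5:8)
  expect_equal(reads[[1]]$aligned_pairs$base, c("A", "C", "G", "T"))
  expect_equal(reads[[2]]$strand, "-")
  expect_equal(reads[[2]]$aligned_pairs$ref_pos, c(10, 11, 13, 14)) # deletion skips 12
  expect_false(reads[[3]]$mapped)
  expect_equal(reads[[4]]$aligned_pairs$base, c("A", "C", "G"))     # soft clip consumed
  bad <- c(sam[1:2], "r5\t0\tref")
  f <- tempfile(); writeLines(bad, f)
  expect_error(read_sam(f), "line 3")
})

test_that("filtering drops unmapped, low-MAPQ and excluded reads; clipping is idempotent", {
  sam <- make_sam(list(
    list(id = "keep", flag = 0, pos = 1, mapq = 30, cigar = "10M", seq = strrep("A", 10)),
    list(id = "lowq", flag = 0, pos = 1, mapq = 29, cigar = "10M", seq = strrep("A", 10)),
    list(id = "unmapped", flag = 4, pos = 0, mapq = 0, cigar = "*", seq = "AAAA"),
    list(id = "excluded", flag = 0, pos = 1, mapq = 60, cigar = "10M", seq = strrep("A", 10))))
  reads <- read_sam_text(sam)
  flt <- filter_reads(reads, mapq_min = 30, clip_bases = 0,
                      exclude_ids = "excluded")
  expect_equal(vapply(flt, `[[`, character(1), "read_id"), "keep")
  # clip_bases = 0 leaves aligned pairs untouched
  expect_equal(flt[[1]]$aligned_pairs$ref_pos, 1:10)
  # clipping removes two bases from each end, once
  flt2 <- filter_reads(reads, mapq_min = 30, clip_bases = 2)
  expect_equal(flt2[[1]]$aligned_pairs$ref_pos, 3:8)
  expect_true(flt2[[1]]$clipped)
  flt3 <- filter_reads(flt2, mapq_min = 30, clip_bases = 2)
  expect_identical(flt3, flt2)
  # set arithmetic on the exclusion list
  many <- read_sam_text(make_sam(lapply(1:10, function(i) {
    list(id = paste0("r", i), flag = 0, pos = i, cigar = "5M", seq = "ACGTA")
  }), ref_len = 60))
  expect_length(filter_reads(many, 30, 0, exclude_ids = c("r2", "r5", "r9")), 7)
})

test_that("damage counting is orientation-aware and matches hand counts", {
  # forward read: ref CCCC, read TCCC -> C->T only at 5' offset 1
  reads <- read_sam_text(make_sam(list(
    list(id = "f", flag = 0, pos = 1, cigar = "4M", seq = "TCCC")), ref_len = 4))
  prof <- damage_profile(reads, "CCCC", max_offset = 4)
  expect_equal(prof$five_prime_ct[1], 1.0)
  expect_equal(prof$five_prime_ct[2:4], c(0, 0, 0))
  # minus-strand read: stored GGGA over ref GGGG is C->T at the read's 5' end
  mreads <- read_sam_text(make_sam(list(
    list(id = "m", flag = 16, pos = 1, cigar = "4M", seq = "GGGA")), ref_len = 4))
  mprof <- damage_profile(mreads, "GGGG", max_offset = 4)
  expect_equal(mprof$five_prime_ct[1], 1.0)
  expect_equal(mprof$five_prime_ct[2:4], c(0, 0, 0))
  expect_true(all(is.na(mprof$five_prime_ga)))   # no G in read orientation
  # reads identical to the reference show zero damage everywhere defined
  clean <- read_sam_text(make_sam(list(
    list(id = "c", flag = 0, pos = 1, cigar = "8M", seq = "ACGTACGT")), ref_len = 8))
  cprof <- damage_profile(clean, "ACGTACGT", max_offset = 8)
  for (fld in c("five_prime_ct", "three_prime_ct", "five_prime_ga", "three_prime_ga")) {
    expect_true(all(cprof[[fld]] == 0, na.rm = TRUE))
  }
  expect_error(damage_profile(list(), "ACGT"), "empty")
  long <- read_sam_text(make_sam(list(
    list(id = "l", flag = 0, pos = 1, cigar = "8M", seq = "ACGTACGT")), ref_len = 8))
  expect_error(damage_profile(filter_reads(long, 0, 2), "ACGTACGT"), "un-clipped")
})

test_that("damage-profile rates recover the generator's per-offset truth", {
  ref <- fix_reference(3000, seed = 5)
  dm <- damage_model(terminal_rate = 0.3, decay = 0.5, base_error = 0,
                     library_type = "double")
  sim <- simulate_reads(ref, n_reads = 2000, damage = dm, seed = 11)
  f <- tempfile(fileext = ".sam"); writeLines(sim$sam, f)
  reads <- read_sam(f)
  prof <- damage_profile(reads, ref, max_offset = 10)
  for (k in 1:6) {
    p <- 0.3 * 0.5^(k - 1)
    for (fld in c("five_prime_ct", "three_prime_ga")) {
      n <- prof[[paste0(fld, "_n")]][k]
      if (n >= 200) {
        se <- sqrt(p * (1 - p) / n)
        expect_lt(abs(prof[[fld]][k] - p), 3 * se + 1e-9)
      }
    }
  }
  unlink(f)
})

test_that("authentication separates damaged from modern libraries", {
  ref <- fix_reference(3000, seed = 5)
  damaged <- simulate_reads(ref, 1500, damage_model(0.3, 0.5, 0.01, "double"),
                            seed = 3)
  modern <- simulate_reads(ref, 1500, damage_model(0, 1, 0.01, "double"),
                           seed = 4)
  to_reads <- function(sim) {
    f <- tempfile(fileext = ".sam"); writeLines(sim$sam, f)
    on.exit(unlink(f)); read_sam(f)
  }
  pa <- damage_profile(to_reads(damaged), ref)
  expect_true(authenticate(pa)$authentic)
  pm <- damage_profile(to_reads(modern), ref)
  expect_false(authenticate(pm)$authentic)
  # degenerate profile: no opportunities at the terminals -> inconclusive
  one <- read_sam_text(make_sam(list(
    list(id = "x", flag = 0, pos = 1, cigar = "4M", seq = "AAAA")), ref_len = 4))
  pr <- damage_profile(one, "AAAA", max_offset = 4)
  expect_true(is.na(authenticate(pr)$authentic))
})

test_that("pileup depth equals brute-force interval stabbing", {
  ref <- strrep("A", 60)
  recs <- lapply(1:10, function(i) {
    list(id = paste0("t", i), flag = 0, pos = 1, cigar = "50M",
         seq = strrep("A", 50))
  })
  pile <- pileup(read_sam_text(make_sam(recs, ref_len = 60)), ref)
  expect_equal(pile$depth, c(rep(10L, 50), rep(0L, 10)))
  # staggered reads vs a counting oracle
  set.seed(21)
  starts <- sample(1:40, 25, replace = TRUE)
  lens <- sample(5:20, 25, replace = TRUE)
  recs <- lapply(seq_along(starts), function(i) {
    l <- min(lens[i], 60 - starts[i] + 1)
    list(id = paste0("s", i), flag = 0, pos = starts[i],
         cigar = paste0(l, "M"), seq = strrep("A", l))
  })
  pile2 <- pileup(read_sam_text(make_sam(recs, ref_len = 60)), ref)
  oracle <- integer(60)
  for (i in seq_along(starts)) {
    l <- min(lens[i], 60 - starts[i] + 1)
    span <- starts[i]:(starts[i] + l - 1)
    oracle[span] <- oracle[span] + 1L
  }
  expect_equal(pile2$depth, oracle)
  expect_equal(pileup(list(), ref)$depth, integer(60))
})

test_that("coverage statistics report breadth and mean depth", {
  # 241 tiled 40-mers cover positions 1..9640 of a 10000-bp reference
  ref <- strrep("A", 10000)
  recs <- lapply(0:240, function(i) {
    list(id = paste0("t", i), flag = 0, pos = 40 * i + 1, cigar = "40M",
         seq = strrep("A", 40))
  })
  pile <- pileup(read_sam_text(make_sam(recs, ref_len = 10000)), ref)
  cov <- coverage_stats(pile, depth_floor = 1)
  expect_equal(cov$breadth_pct, 96.4)
  expect_equal(cov$mean_depth, 9640 / 10000)
  # uniform depth 10
  deep <- lapply(1:10, function(i) {
    list(id = paste0("d", i), flag = 0, pos = 1, cigar = "100M",
         seq = strrep("A", 100))
  })
  pile10 <- pileup(read_sam_text(make_sam(deep, ref_len = 100)), strrep("A", 100))
  expect_equal(coverage_stats(pile10)$mean_depth, 10)
  expect_equal(coverage_stats(pile10)$breadth_pct, 100)
  # no reads at all
  empty <- coverage_stats(pileup(list(), strrep("A", 100)))
  expect_equal(empty$breadth_pct, 0)
  expect_equal(empty$mean_depth, 0)
})

test_that("consensus calling respects depth, fraction and tie rules", {
  ref <- "A"
  mk <- function(bases) {
    recs <- lapply(seq_along(bases), function(i) {
      list(id = paste0("b", i), flag = 0, pos = 1, cigar = "1M", seq = bases[i])
    })
    pileup(read_sam_text(make_sam(recs, ref_len = 1)), ref)
  }
  expect_equal(consensus(mk(c(rep("A", 9), "G")), 2, 0.7), "A")
  expect_equal(consensus(mk("A"), 2, 0.7), "N")              # below min depth
  expect_equal(consensus(mk(c(rep("A", 5), rep("G", 5))), 2, 0.7), "N")  # tie
  expect_equal(consensus(mk(c("A", "A", "G")), 2, 0.7), "N") # fraction 2/3 < 0.7
})

test_that("error-free consensus reproduces the haplotype; clipping removes terminal damage", {
  ref <- fix_reference(2000, seed = 5)
  tree <- fix_tree(ref)
  hap <- simulate_haplotype(tree, "H1", ref, n_private = 0)
  clean <- simulate_reads(hap, 700, damage_model(0, 1, 0), seed = 2)
  f <- tempfile(fileext = ".sam"); writeLines(clean$sam, f)
  reads <- read_sam(f); unlink(f)
  pile <- pileup(filter_reads(reads, 30, 0), hap)
  cons <- consensus(pile)
  covered <- which(pile$depth >= 2)
  expect_equal(substring(cons, covered, covered),
               substring(hap, covered, covered))
  # damaged reads at modest depth: 2-base clipping removes >= 95% of the
  # consensus discrepancies induced by terminal damage at offsets 1-2
  # (classified through the generator's truth log)
  raw_term <- 0L; clip_term <- 0L
  for (s in 41:50) {
    dmg <- simulate_reads(hap, 120, damage_model(0.8, 0.1, 0), seed = s,
                          fragment_length_mean = 35, fragment_length_sd = 5)
    f <- tempfile(fileext = ".sam"); writeLines(dmg$sam, f)
    rd <- read_sam(f); unlink(f)
    tr <- dmg$truth
    tr <- tr[tr$end %in% c("5p", "3p") & tr$offset <= 2, , drop = FALSE]
    term_pos <- unique(ifelse(
      (tr$strand == "+") == (tr$end == "5p"),
      tr$start + tr$offset - 1L,          # event at the leftmost reference end
      tr$start + tr$length - tr$offset))  # event at the rightmost reference end
    count_term <- function(clip) {
      pl <- pileup(filter_reads(rd, 30, clip), hap)
      cs <- consensus(pl, min_depth = 1, min_fraction = 0.5)
      ok <- which(pl$depth >= 1)
      bad <- ok[substring(cs, ok, ok) != substring(hap, ok, ok) &
                  substring(cs, ok, ok) != "N"]
      sum(bad %in% term_pos)
    }
    raw_term <- raw_term + count_term(0)
    clip_term <- clip_term + count_term(2)
  }
  expect_gt(raw_term, 20)   # the scenario actually produces discrepancies
  expect_lte(clip_term, 0.05 * raw_term)
})
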