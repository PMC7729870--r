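# Fitch scoring, exhaustive and NNI parsimony search, alignment masking.

test_that("Fitch score matches hand-worked and degenerate examples", {
  p <- sequence_panel(c("A", "B", "C"), c("ACGT", "ACGA", "GCGA"))
  expect_equal(fitch_score("((A,B),C);", p), 2)
  same <- sequence_panel(c("A", "B", "C"), rep("ACGTT", 3))
  expect_equal(fitch_score("((A,B),C);", same), 0)
  two <- sequence_panel(c("A", "B"), c("ACGTAA", "TCGTGC"))
  expect_equal(fitch_score("(A,B);", two), 3)      # pairwise Hamming
  # N and gaps are wildcards, not a fifth state
  amb <- sequence_panel(c("A", "B", "C"), c("ANGT", "AC-T", "ACGT"))
  expect_equal(fitch_score("((A,B),C);", amb), 0)
  expect_error(fitch_score("((A,B),D);", p), "match panel ids")
})

test_that("Fitch equals brute-force minimisation over internal labellings", {
  set.seed(17)
  topo5 <- "(((A,B),C),(D,E));"
  nested <- list(list(list("A", "B"), "C"), list("D", "E"))
  for (rep in 1:8) {
    seqs <- vapply(1:5, function(i) {
      paste(sample(c("A", "C", "G", "T", "N"), 6, replace = TRUE,
                   prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    }, character(1))
    panel <- sequence_panel(LETTERS[1:5], seqs)
    got <- fitch_score(topo5, panel)
    # oracle: per site, enumerate all internal-node base assignments on the
    # rooted shape and count changed edges
    chars <- do.call(rbind, strsplit(seqs, ""))
    to_tree <- function(nd) {
      if (is.character(nd)) return(match(nd, LETTERS[1:5]))
      lapply(nd, to_tree)
    }
    tr <- to_tree(nested)
    want <- sum(vapply(1:6, function(s) {
      st <- chars[, s]
      st[st == "N"] <- NA
      fitch_oracle_tree(tr, st)
    }, numeric(1)))
    expect_equal(got, want)
  }
})

test_that("Fitch agrees with an independent parsimony implementation", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 6
    seqs <- vapply(1:n, function(i) {
      paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    }, character(1))
    panel <- sequence_panel(paste0("t", 1:n), seqs)
    tr <- ape::rtree(n, tip.label = panel$ids)
    dat <- phangorn::phyDat(t(sapply(strsplit(seqs, ""), identity)))
    names(dat) <- panel$ids
    expect_equal(fitch_score(tr, panel),
                 as.integer(phangorn::parsimony(tr, dat, method = "fitch")))
  }
})

test_that("exhaustive search agrees with scoring every topology explicitly", {
  p4 <- sequence_panel(LETTERS[1:4], c("AAAA", "AAAT", "TTTA", "TTTT"))
  mp <- mp_search(p4, "exhaustive")
  all3 <- c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));")
  scores <- vapply(all3, fitch_score, numeric(1), panel = p4)
  expect_equal(mp$score, min(scores))
  # ten shared derived sites force a sibling pair
  shared <- strrep("G", 10)
  other <- strrep("A", 10)
  p <- sequence_panel(c("s1", "s2", "o1", "o2", "o3"),
                      c(paste0(shared, "ACGTAC"), paste0(shared, "ACGTGC"),
                        paste0(other, "ACTTAC"), paste0(other, "AGGTAC"),
                        paste0(other, "TCGTAC")))
  mps <- mp_search(p, "exhaustive")
  expect_true(grepl("\\(s1,s2\\)|\\(s2,s1\\)", mps$newick))
  # three taxa: the single unrooted topology
  p3 <- sequence_panel(c("A", "B", "C"), c("ACGT", "ACGA", "GCGA"))
  mp3 <- mp_search(p3, "exhaustive")
  expect_equal(mp3$score, fitch_score("((A,B),C);", p3))
  expect_error(mp_search(sequence_panel(paste0("t", 1:10),
                                        rep(strrep("A", 4), 10)), "exhaustive"),
               "9 taxa")
})

test_that("optimal score is invariant to panel record order", {
  set.seed(33)
  seqs <- vapply(1:6, function(i) {
    paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
  }, character(1))
  ids <- paste0("x", 1:6)
  s1 <- mp_search(sequence_panel(ids, seqs), "exhaustive")$score
  perm <- sample(6)
  s2 <- mp_search(sequence_panel(ids[perm], seqs[perm]), "exhaustive")$score
  expect_equal(s2, s1)
})

test_that("exhaustive search recovers the generating 6-taxon topology", {
  # mutate along a fixed tree with many changes per edge
  set.seed(47)
  L <- 400
  root_seq <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mutate <- function(s, k) {
    idx <- sample(L, k)
    s[idx] <- vapply(s[idx], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                     character(1))
    s
  }
  # generating topology: ((t1,t2),(t3,t4),(t5,t6)) unrooted
  nAB <- mutate(root_seq, 30); nCD <- mutate(root_seq, 30); nEF <- mutate(root_seq, 30)
  tips <- list(t1 = mutate(nAB, 15), t2 = mutate(nAB, 15),
               t3 = mutate(nCD, 15), t4 = mutate(nCD, 15),
               t5 = mutate(nEF, 15), t6 = mutate(nEF, 15))
  panel <- sequence_panel(names(tips), vapply(tips, paste, character(1), collapse = ""))
  mp <- mp_search(panel, "exhaustive")
  got <- ape::unroot(mp$tree)
  want <- ape::unroot(ape::read.tree(text = "((t1,t2),(t3,t4),(t5,t6));"))
  expect_equal(ape::dist.topo(got, want)[1], 0)
})

test_that("NNI search never beats exhaustive and usually matches it", {
  set.seed(59)
  n_match <- 0L
  n_panels <- 50L
  for (i in seq_len(n_panels)) {
    seqs <- vapply(1:6, function(j) {
      paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = "")
    }, character(1))
    panel <- sequence_panel(paste0("t", 1:6), seqs)
    se <- mp_search(panel, "exhaustive")$score
    sn <- mp_search(panel, "nni", seed = i)$score
    expect_gte(sn, se)
    if (sn == se) n_match <- n_match + 1L
  }
  expect_gte(n_match, 0.9 * n_panels)
})

test_that("alignment masking gaps hypervariable columns via the reference row", {
  ref <- fix_reference(16570, seed = 2)           # covers control-region numbering
  alt <- ref
  substr(alt, 16519, 16519) <- if (substr(ref, 16519, 16519) == "A") "C" else "A"
  substr(alt, 16189, 16189) <- if (substr(ref, 16189, 16189) == "A") "C" else "A"
  panel <- sequence_panel(c("rCRS", "s1"), c(ref, alt))
  masked <- mask_alignment(panel, mask_policy(), ref_row = "rCRS")
  s1 <- masked$sequences[2]
  expect_equal(substr(s1, 16519, 16519), "-")     # masked point gapped out
  expect_equal(substr(s1, 16189, 16189), substr(alt, 16189, 16189))  # exception kept
  expect_equal(substr(masked$sequences[1], 310, 310), "-")
  # empty policy leaves the panel untouched
  empty <- mask_policy(excluded_ranges = list(), excluded_points = integer(0),
                       exceptions = integer(0))
  expect_identical(mask_alignment(panel, empty, ref_row = "rCRS"), panel)
  expect_error(mask_alignment(panel, mask_policy(), ref_row = "nope"),
               "reference row")
  # gap-aware column mapping: an insertion shifts columns but not numbering
  ins_ref <- paste0(substr(ref, 1, 100), "-", substring(ref, 101))
  ins_alt <- paste0(substr(alt, 1, 100), "A", substring(alt, 101))
  p2 <- sequence_panel(c("rCRS", "s1"), c(ins_ref, ins_alt))
  m2 <- mask_alignment(p2, mask_policy(), ref_row = "rCRS")
  expect_equal(substr(m2$sequences[2], 16520, 16520), "-")  # np 16519 at column 16520
})
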