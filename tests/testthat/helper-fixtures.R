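# Shared synthetic fixtures, built in code at test time.

# small mitochondrial stand-in reference + fictional haplogroup tree
fix_reference <- function(length = 2000L, seed = 5L) {
  simulate_reference(length, seed = seed)
}

fix_tree <- function(reference = fix_reference(), seed = 101L) {
  fixture_haplogroup_tree(reference, seed = seed)
}

# SAM text for hand-crafted reads: list of lists with fields
# id, flag, pos, mapq, cigar, seq
make_sam <- function(records, ref_name = "ref", ref_len = 100L) {
  c("@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:", ref_name, "\tLN:", ref_len),
    vapply(records, function(r) {
      paste(r$id, r$flag, ref_name, r$pos, r$mapq %||% 60,
            r$cigar, "*", 0, 0, r$seq, strrep("I", nchar(r$seq)), sep = "\t")
    }, character(1)))
}

read_sam_text <- function(lines) {
  f <- tempfile(fileext = ".sam")
  writeLines(lines, f)
  on.exit(unlink(f))
  read_sam(f)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent piecewise-linear interpolation oracle (loop, no approx())
interp_oracle <- function(x, y, xout) {
  vapply(xout, function(q) {
    i <- max(which(x <= q))
    if (x[i] == q) return(y[i])
    y[i] + (y[i + 1] - y[i]) * (q - x[i]) / (x[i + 1] - x[i])
  }, numeric(1))
}

# brute-force Fitch oracle: minimum changes over all internal labellings
# tree given as nested list (leaf = taxon index, internal = list of two)
fitch_oracle_tree <- function(tree, leaf_states) {
  internals <- 0L
  walk <- function(nd) {
    if (!is.list(nd)) return(invisible(NULL))
    internals <<- internals + 1L
    lapply(nd, walk)
    invisible(NULL)
  }
  walk(tree)
  bases <- c("A", "C", "G", "T")
  best <- Inf
  grid <- rep(list(bases), internals)
  combos <- do.call(expand.grid, c(grid, stringsAsFactors = FALSE))
  for (r in seq_len(nrow(combos))) {
    lab <- as.character(combos[r, ])
    k <- 0L
    changes <- 0L
    state_of <- function(nd) {
      if (!is.list(nd)) return(leaf_states[nd])
      k <<- k + 1L
      my <- lab[k]
      for (ch in nd) {
        s <- state_of(ch)
        if (!is.na(s) && s != my) changes <<- changes + 1L
      }
      my
    }
    state_of(tree)
    best <- min(best, changes)
  }
  best
}
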