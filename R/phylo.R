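# Maximum parsimony: Fitch small-parsimony scoring over site patterns, an
# exhaustive search over unrooted binary topologies for small panels, and a
# stepwise-addition + NNI hill-climbing search for larger ones.

#' Build an aligned sequence panel
#'
#' @param ids Unique record ids.
#' @param sequences Aligned sequences (equal length; A/C/G/T/N/-).
#' @param haplogroups Optional haplogroup labels per record.
#' @return An object of class `sequence_panel`.
#' @export
sequence_panel <- function(ids, sequences, haplogroups = NULL) {
  stopifnot(length(ids) == length(sequences))
  if (anyDuplicated(ids)) stop("panel ids must be unique")
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("all panel sequences must have equal length")
  structure(list(ids = as.character(ids), sequences = toupper(sequences),
                 haplogroups = haplogroups, alignment_length = L),
            class = "sequence_panel")
}

#' Read an aligned FASTA panel
#'
#' Record ids may carry a `"|haplogroup"` suffix, which is split off into
#' the panel's haplogroup labels.
#'
#' @param path Aligned FASTA path.
#' @return A [sequence_panel()].
#' @export
read_panel <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  full <- names(ss)
  ids <- sub("\\|.*$", "", full)
  hap <- ifelse(grepl("\\|", full), sub("^[^|]*\\|", "", full), NA_character_)
  sequence_panel(ids, as.character(ss), hap)
}

#' Mask alignment columns at hypervariable reference positions
#'
#' Alignment columns are mapped to reference nucleotide positions through a
#' designated reference row (gap-aware cumulative position); columns landing
#' on masked positions are replaced by gaps in every record. Insertion
#' columns (gap in the reference row) are left untouched.
#'
#' @param panel A [sequence_panel()] containing the reference record.
#' @param policy A [mask_policy()].
#' @param ref_row Id of the reference record in the panel.
#' @return The masked [sequence_panel()].
#' @export
mask_alignment <- function(panel, policy = mask_policy(), ref_row) {
  stopifnot(inherits(panel, "sequence_panel"))
  masked <- masked_positions(policy)
  if (length(masked) == 0L) return(panel)
  if (missing(ref_row) || !ref_row %in% panel$ids) {
    stop("reference row required to map alignment columns to reference positions")
  }
  ref_chars <- strsplit(panel$sequences[match(ref_row, panel$ids)], "")[[1]]
  np <- cumsum(ref_chars != "-")
  np[ref_chars == "-"] <- NA_integer_
  drop_col <- !is.na(np) & np %in% masked
  if (!any(drop_col)) return(panel)
  panel$sequences <- vapply(panel$sequences, function(s) {
    ch <- strsplit(s, "")[[1]]
    ch[drop_col] <- "-"
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  panel
}

# ---- Fitch machinery -------------------------------------------------------

# base -> bit set; N, gap and anything unrecognised act as the full set
# (missing data), never as a fifth state
.FITCH_CODE <- c(A = 1L, C = 2L, G = 4L, T = 8L)

# site-pattern compression: codes matrix (patterns x taxa) + pattern weights
.encode_panel <- function(panel) {
  mat <- do.call(rbind, strsplit(panel$sequences, ""))  # taxa x sites
  codes <- matrix(.FITCH_CODE[mat], nrow = nrow(mat))
  codes[is.na(codes)] <- 15L
  key <- apply(codes, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  weights <- as.integer(table(factor(key, levels = key[first])))
  list(codes = t(codes[, first, drop = FALSE]),  # patterns x taxa
       weights = weights, ids = panel$ids)
}

# Fitch score of an unrooted tree given as a 2-column edge matrix; tips are
# node ids 1..n_tips indexing the columns of `codes`
.fitch_edges <- function(edges, n_tips, codes, weights) {
  n_nodes <- max(edges)
  adj <- vector("list", n_nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  score <- 0L
  rec <- function(node, parent) {
    kids <- setdiff(adj[[node]], parent)
    if (length(kids) == 0L) return(codes[, node])
    cur <- NULL
    for (ch in kids) {
      s <- rec(ch, node)
      if (is.null(cur)) { cur <- s; next }
      inter <- bitwAnd(cur, s)
      zero <- inter == 0L
      if (any(zero)) {
        score <<- score + sum(weights[zero])
        inter[zero] <- bitwOr(cur, s)[zero]
      }
      cur <- inter
    }
    cur
  }
  # root the traversal at a tip's neighbour with no parent, so that tip joins
  # the fold as an ordinary child; pairwise folding at the trifurcation is
  # Fitch on a rooted resolution, whose score equals the unrooted score
  # (partial trees during stepwise addition may lack low-numbered tips)
  anchor <- intersect(seq_len(n_tips), unique(as.vector(edges)))[1L]
  root <- adj[[anchor]][1L]
  rec(root, 0L)
  score
}

# canonical newick of an unrooted tree: rooted at the neighbour of the
# lexicographically smallest tip label, subtrees sorted by their strings
.canonical_newick <- function(edges, tip_labels) {
  n_tips <- length(tip_labels)
  n_nodes <- max(edges)
  adj <- vector("list", n_nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  rec <- function(node, parent) {
    kids <- setdiff(adj[[node]], parent)
    if (length(kids) == 0L) return(tip_labels[node])
    parts <- sort(vapply(kids, rec, character(1), parent = node))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  anchor <- which.min(rank(tip_labels, ties.method = "first"))
  root <- adj[[anchor]][1L]
  paste0(rec(root, 0L), ";")
}

# enumerate all unrooted binary topologies over n >= 3 tips by inserting each
# new tip on every edge; calls fn(edges) for each complete topology
.enumerate_topologies <- function(n, fn) {
  grow <- function(edges, t) {
    if (t > n) { fn(edges); return(invisible(NULL)) }
    w <- n + (t - 2L)   # id of the internal node created by inserting tip t
    for (i in seq_len(nrow(edges))) {
      u <- edges[i, 1]; v <- edges[i, 2]
      e2 <- rbind(edges[-i, , drop = FALSE], c(u, w), c(w, v), c(w, t))
      grow(e2, t + 1L)
    }
  }
  grow(rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L)), 4L)
}

# the two NNI rearrangements across each internal edge
.nni_neighbours <- function(edges, n_tips) {
  adj <- vector("list", max(edges))
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  out <- list()
  internal <- edges[, 1] > n_tips & edges[, 2] > n_tips
  swap_edge <- function(edges, from, to, new_other) {
    hit <- which((edges[, 1] == from & edges[, 2] == to) |
                   (edges[, 2] == from & edges[, 1] == to))[1]
    edges[hit, ] <- c(from, new_other)
    edges
  }
  for (i in which(internal)) {
    u <- edges[i, 1]; v <- edges[i, 2]
    ab <- setdiff(adj[[u]], v)
    cd <- setdiff(adj[[v]], u)
    for (x in cd) {
      e2 <- swap_edge(edges, u, ab[2], x)   # move u's second subtree to v
      e2 <- swap_edge(e2, v, x, ab[2])
      out[[length(out) + 1L]] <- e2
    }
  }
  out
}

#' Fitch parsimony score of a tree
#'
#' Sum over alignment sites of the minimum number of substitutions the
#' topology requires (Fitch union/intersection counting). `N` and gaps act
#' as missing data (the full base set), never as a fifth state.
#'
#' @param topology An `ape::phylo` tree or a newick string whose tip labels
#'   are exactly the panel ids.
#' @param panel A [sequence_panel()].
#' @return Integer parsimony score.
#' @export
fitch_score <- function(topology, panel) {
  stopifnot(inherits(panel, "sequence_panel"))
  tr <- if (is.character(topology)) ape::read.tree(text = topology) else topology
  if (!inherits(tr, "phylo")) stop("topology must be a phylo object or newick string")
  if (!setequal(tr$tip.label, panel$ids) ||
      length(tr$tip.label) != length(panel$ids)) {
    stop("tree tip labels must match panel ids exactly")
  }
  if (length(tr$tip.label) > 2L) tr <- ape::unroot(tr)
  enc <- .encode_panel(panel)
  # permute code columns into the tree's tip numbering
  codes <- enc$codes[, match(tr$tip.label, panel$ids), drop = FALSE]
  .fitch_edges(tr$edge, length(tr$tip.label), codes, enc$weights)
}

#' Maximum-parsimony tree search
#'
#' `mode = "exhaustive"` enumerates every unrooted binary topology (allowed
#' up to 9 taxa) and returns a minimum-score tree, breaking ties toward the
#' lexicographically smallest canonical newick. `mode = "nni"` runs
#' `n_starts` stepwise random-addition starts (orders drawn from `seed`),
#' hill-climbs each with best-improvement nearest-neighbour interchanges to
#' a local optimum, and keeps the best tree found.
#'
#' @param panel A [sequence_panel()] with >= 3 taxa.
#' @param mode `"exhaustive"` or `"nni"`.
#' @param seed Integer seed for the NNI addition orders (ignored for
#'   exhaustive search, which is fully deterministic).
#' @param n_starts Number of random-addition starts in NNI mode (default 5).
#' @return A list of class `parsimony_tree`: `tree` (`ape::phylo`,
#'   unrooted), `newick` (canonical), `score`, `n_taxa`, `mode`.
#' @export
mp_search <- function(panel, mode = c("exhaustive", "nni"), seed = 1L,
                      n_starts = 5L) {
  stopifnot(inherits(panel, "sequence_panel"))
  mode <- match.arg(mode)
  n <- length(panel$ids)
  if (n < 3L) stop("need >= 3 taxa")
  enc <- .encode_panel(panel)
  codes <- enc$codes
  weights <- enc$weights
  sc <- function(edges) .fitch_edges(edges, n, codes, weights)

  if (mode == "exhaustive") {
    if (n > 9L) {
      stop("exhaustive search is limited to 9 taxa ((2n-5)!! topologies); ",
           "use mode = 'nni' for larger panels")
    }
    best_score <- Inf
    best_edges <- list()
    .enumerate_topologies(n, function(edges) {
      s <- sc(edges)
      if (s < best_score) {
        best_score <<- s
        best_edges <<- list(edges)
      } else if (s == best_score) {
        best_edges[[length(best_edges) + 1L]] <<- edges
      }
    })
    nwks <- vapply(best_edges, .canonical_newick, character(1),
                   tip_labels = panel$ids)
    pick <- which.min(rank(nwks, ties.method = "first"))
    edges <- best_edges[[pick]]
    score <- as.integer(best_score)
  } else {
    one_start <- function(ord) {
      edges <- rbind(c(n + 1L, ord[1]), c(n + 1L, ord[2]), c(n + 1L, ord[3]))
      for (k in seq.int(4L, n)) {
        t <- ord[k]
        w <- n + (k - 2L)
        cand_best <- NULL; cand_score <- Inf
        for (i in seq_len(nrow(edges))) {
          u <- edges[i, 1]; v <- edges[i, 2]
          e2 <- rbind(edges[-i, , drop = FALSE], c(u, w), c(w, v), c(w, t))
          s <- sc(e2)
          if (s < cand_score) { cand_score <- s; cand_best <- e2 }
        }
        edges <- cand_best
      }
      score <- sc(edges)
      repeat {   # best-improvement NNI until a local optimum
        nb <- .nni_neighbours(edges, n)
        ss <- vapply(nb, sc, integer(1))
        if (!length(ss) || min(ss) >= score) break
        pick <- which.min(ss)
        edges <- nb[[pick]]
        score <- ss[pick]
      }
      list(edges = edges, score = as.integer(score))
    }
    set.seed(seed)
    best <- NULL
    for (st in seq_len(n_starts)) {
      res <- one_start(sample.int(n))
      if (is.null(best) || res$score < best$score) best <- res
    }
    edges <- best$edges
    score <- best$score
  }

  nwk <- .canonical_newick(edges, panel$ids)
  structure(list(tree = ape::read.tree(text = nwk), newick = nwk,
                 score = score, n_taxa = n, mode = mode),
            class = "parsimony_tree")
}

#' @export
print.parsimony_tree <- function(x, ...) {
  cat(sprintf("Maximum-parsimony tree (%s search): %d taxa, score %d\n  %s\n",
              x$mode, x$n_taxa, x$score, x$newick))
  invisible(x)
}

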