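# mtDNA variant calling against a reference, hypervariable-site masking, and
# haplogroup assignment by scoring an observed variant set against a
# defining-variant tree (PhyloTree-style).

#' Build a variant table
#'
#' @param position 1-based nucleotide positions on the reference.
#' @param ref,alt Reference and alternate bases (A/C/G/T; `ref != alt`).
#' @return A data frame with columns `position`, `ref`, `alt`.
#' @export
variant_table <- function(position = integer(0), ref = character(0), alt = character(0)) {
  stopifnot(length(position) == length(ref), length(position) == length(alt))
  if (any(ref == alt)) stop("ref and alt must differ")
  data.frame(position = as.integer(position), ref = toupper(ref),
             alt = toupper(alt), stringsAsFactors = FALSE)
}

#' Call substitution variants of a consensus against a reference
#'
#' Both sequences must be the same length (pre-aligned; no indel handling).
#' Positions where the consensus is N (or the reference is not A/C/G/T) are
#' recorded as uncovered, not as variants.
#'
#' @param consensus Consensus sequence (character scalar, may contain N).
#' @param reference Reference sequence of equal length.
#' @return A list of class `variant_set`: `variants` (a [variant_table()])
#'   and `uncovered` (integer positions not callable).
#' @export
call_variants <- function(consensus, reference) {
  cs <- strsplit(toupper(consensus), "")[[1]]
  rf <- strsplit(toupper(reference), "")[[1]]
  if (length(cs) != length(rf)) {
    stop(sprintf("alignment required: consensus length %d != reference length %d",
                 length(cs), length(rf)))
  }
  callable <- cs %in% c("A", "C", "G", "T") & rf %in% c("A", "C", "G", "T")
  diff <- callable & cs != rf
  structure(list(
    variants = variant_table(which(diff), rf[diff], cs[diff]),
    uncovered = which(!callable)),
    class = "variant_set")
}

#' Hypervariable-site mask policy
#'
#' Defaults mask the mtDNA control-region stretches whose length
#' polymorphisms are uninformative for classification: nps 303--315,
#' 522--523 and 16180--16193 plus point 16519, with np 16189 retained as an
#' exception (a haplogroup-defining site inside a masked stretch).
#'
#' @param excluded_ranges List of length-2 integer vectors `[start, end]`.
#' @param excluded_points Integer positions.
#' @param exceptions Integer positions retained despite being excluded;
#'   must lie inside the excluded set.
#' @return A list of class `mask_policy`.
#' @export
mask_policy <- function(excluded_ranges = list(c(303L, 315L), c(522L, 523L),
                                               c(16180L, 16193L)),
                        excluded_points = 16519L,
                        exceptions = 16189L) {
  excl <- unique(c(unlist(lapply(excluded_ranges, function(r) seq.int(r[1], r[2]))),
                   excluded_points))
  if (!all(exceptions %in% excl)) {
    stop("exceptions must fall inside the excluded ranges/points")
  }
  structure(list(excluded_ranges = excluded_ranges,
                 excluded_points = as.integer(excluded_points),
                 exceptions = as.integer(exceptions)),
            class = "mask_policy")
}

#' Positions removed by a mask policy
#'
#' @param policy A [mask_policy()].
#' @return Sorted integer vector of masked positions (exceptions excluded).
#' @export
masked_positions <- function(policy) {
  stopifnot(inherits(policy, "mask_policy"))
  excl <- unique(c(unlist(lapply(policy$excluded_ranges,
                                 function(r) seq.int(r[1], r[2]))),
                   policy$excluded_points))
  sort(setdiff(excl, policy$exceptions))
}

#' Apply a mask policy to a variant set
#'
#' Removes variants at masked positions; idempotent and order-insensitive.
#'
#' @param variants A [variant_table()] or `variant_set`.
#' @param policy A [mask_policy()].
#' @return Same type as `variants`, with masked positions removed.
#' @export
apply_mask <- function(variants, policy = mask_policy()) {
  masked <- masked_positions(policy)
  if (inherits(variants, "variant_set")) {
    variants$variants <- variants$variants[!variants$variants$position %in% masked, ,
                                           drop = FALSE]
    rownames(variants$variants) <- NULL
    return(variants)
  }
  out <- variants[!variants$position %in% masked, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- haplogroup trees ------------------------------------------------------

.parse_variant_strings <- function(strs) {
  ok <- grepl("^[ACGTacgt][0-9]+[ACGTacgt]$", strs)
  dropped <- strs[!ok]
  if (length(dropped)) {
    warning("dropping non-substitution/annotated defining variants: ",
            paste(dropped, collapse = ", "))
  }
  strs <- toupper(strs[ok])
  variant_table(as.integer(sub("^[ACGT]([0-9]+)[ACGT]$", "\\1", strs)),
                substr(strs, 1, 1),
                substring(strs, nchar(strs)))
}

.format_variant_strings <- function(vt) {
  if (nrow(vt) == 0L) return(character(0))
  paste0(vt$ref, vt$position, vt$alt)
}

#' Construct a haplogroup tree
#'
#' A rooted tree whose edges carry defining substitution variants. Node
#' labels must be unique; the root carries no defining variants.
#'
#' @param labels Character vector of node labels (first = root).
#' @param parent Integer vector of parent indices (`NA` for the root).
#' @param variants List of [variant_table()]s, one per node (defining
#'   variants on the edge into that node).
#' @return An object of class `haplogroup_tree`.
#' @export
haplogroup_tree <- function(labels, parent, variants) {
  stopifnot(length(labels) == length(parent), length(labels) == length(variants))
  if (anyDuplicated(labels)) stop("node labels must be unique")
  if (sum(is.na(parent)) != 1L) stop("tree must have exactly one root")
  root <- which(is.na(parent))
  # acyclicity / single-root check: every node must reach the root
  for (i in seq_along(labels)) {
    seen <- integer(0); j <- i
    while (!is.na(parent[j])) {
      if (j %in% seen) stop("tree contains a cycle")
      seen <- c(seen, j); j <- parent[j]
    }
    if (j != root) stop("multiple roots detected")
  }
  structure(list(labels = labels, parent = as.integer(parent),
                 variants = variants, root = root),
            class = "haplogroup_tree")
}

#' Depth of each tree node
#'
#' @param tree A [haplogroup_tree()].
#' @return Integer vector of root distances (root = 0), named by label.
#' @export
tree_depths <- function(tree) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  d <- integer(length(tree$labels))
  for (i in seq_along(d)) {
    j <- i
    while (!is.na(tree$parent[j])) { d[i] <- d[i] + 1L; j <- tree$parent[j] }
  }
  names(d) <- tree$labels
  d
}

#' Defining variants accumulated along the root-to-node path
#'
#' When a position mutates more than once along the path the later state
#' overrides the earlier one; a mutation back to the reference base removes
#' the position from the expected set.
#'
#' @param tree A [haplogroup_tree()].
#' @param label Node label.
#' @return A [variant_table()] of expected variants for that node.
#' @export
path_variants <- function(tree, label) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  i <- match(label, tree$labels)
  if (is.na(i)) stop("unknown haplogroup label: ", label)
  chain <- integer(0)
  while (!is.na(i)) { chain <- c(i, chain); i <- tree$parent[i] }
  acc <- variant_table()
  for (j in chain) {
    vt <- tree$variants[[j]]
    if (is.null(vt) || nrow(vt) == 0L) next
    for (k in seq_len(nrow(vt))) {
      pos <- vt$position[k]
      hit <- which(acc$position == pos)
      if (length(hit)) {
        if (vt$alt[k] == acc$ref[hit]) acc <- acc[-hit, , drop = FALSE]  # back to reference
        else acc$alt[hit] <- vt$alt[k]
      } else {
        acc <- rbind(acc, vt[k, , drop = FALSE])
      }
    }
  }
  acc <- acc[order(acc$position), , drop = FALSE]
  rownames(acc) <- NULL
  acc
}

#' Import a PhyloTree-style haplogroup tree from JSON
#'
#' Expects nested objects `{label, variants, children}` with variants as
#' strings like `"A1234G"`. Indel and annotated (back-mutation `"!"`)
#' variants are dropped with a warning. If `reference` is given, each kept
#' variant's reference base is validated against it.
#'
#' @param path JSON path.
#' @param reference Optional reference sequence to validate variants against.
#' @return A [haplogroup_tree()].
#' @export
read_haplogroup_tree <- function(path, reference = NULL) {
  node <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  labels <- character(0); parent <- integer(0); variants <- list()
  walk <- function(nd, parent_idx) {
    labels[[length(labels) + 1L]] <<- nd$label
    parent[[length(parent) + 1L]] <<- parent_idx
    idx <- length(labels)
    vs <- unlist(nd$variants)
    variants[[idx]] <<- if (length(vs)) .parse_variant_strings(vs) else variant_table()
    for (ch in nd$children) walk(ch, idx)
  }
  walk(node, NA_integer_)
  tree <- haplogroup_tree(labels, parent, variants)
  if (!is.null(reference)) {
    rf <- strsplit(toupper(reference), "")[[1]]
    for (vt in tree$variants) {
      if (nrow(vt) == 0L) next
      if (any(vt$position > length(rf))) stop("defining variant beyond reference length")
      bad <- vt$ref != rf[vt$position]
      if (any(bad)) {
        stop("defining variant(s) inconsistent with reference: ",
             paste(.format_variant_strings(vt[bad, , drop = FALSE]), collapse = ", "))
      }
    }
  }
  tree
}

#' Export a haplogroup tree to JSON
#'
#' @param tree A [haplogroup_tree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplogroup_tree <- function(tree, path) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  build <- function(i) {
    kids <- which(!is.na(tree$parent) & tree$parent == i)
    list(label = tree$labels[i],
         variants = as.list(.format_variant_strings(tree$variants[[i]])),
         children = lapply(kids, build))
  }
  jsonlite::write_json(build(tree$root), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# ---- assignment ------------------------------------------------------------

#' Assign an mtDNA haplogroup
#'
#' Scores the observed variant set against every node of a defining-variant
#' tree with the Kulczynski measure
#' `score = (found/expected + found/(found + private)) / 2`,
#' where `expected` counts the node's path variants at covered positions,
#' `found` those actually observed, and `private` the observed variants not
#' on the path. Degenerate ratios (0/0) count as 1, so a
#' reference-identical sequence scores 1 at the root. Uncovered positions
#' reduce `expected` rather than counting as mismatches. Ties go to the
#' deeper node, then to the lexicographically smaller label.
#'
#' @param variants A `variant_set` from [call_variants()], or a
#'   [variant_table()] (then supply `uncovered`).
#' @param tree A [haplogroup_tree()].
#' @param uncovered Integer positions without coverage (ignored when
#'   `variants` is a `variant_set`).
#' @return A list of class `haplogroup_call`: `best_label`, `score`,
#'   `expected`, `found`, `private` (variant table), `runner_ups`
#'   (data frame of the next-best labels/scores).
#' @export
assign_haplogroup <- function(variants, tree, uncovered = integer(0)) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  if (inherits(variants, "variant_set")) {
    uncovered <- variants$uncovered
    variants <- variants$variants
  }
  if (length(tree$labels) == 0L) stop("empty haplogroup tree")
  obs_key <- paste0(variants$position, variants$alt)
  depths <- tree_depths(tree)

  per_node <- lapply(seq_along(tree$labels), function(i) {
    pv <- path_variants(tree, tree$labels[i])
    pv <- pv[!pv$position %in% uncovered, , drop = FALSE]   # uncovered shrink "expected"
    expected <- nrow(pv)
    path_key <- paste0(pv$position, pv$alt)
    found <- sum(obs_key %in% path_key)
    private <- variants[!obs_key %in% path_key, , drop = FALSE]
    t1 <- if (expected == 0L) 1 else found / expected
    t2 <- if (found + nrow(private) == 0L) 1 else found / (found + nrow(private))
    list(label = tree$labels[i], score = (t1 + t2) / 2, expected = expected,
         found = found, private = private, depth = depths[i])
  })
  scores <- vapply(per_node, `[[`, numeric(1), "score")
  dd <- vapply(per_node, `[[`, numeric(1), "depth")
  labs <- vapply(per_node, `[[`, character(1), "label")
  o <- order(-scores, -dd, labs)
  best <- per_node[[o[1]]]
  runners <- data.frame(label = labs[o[-1]][seq_len(min(5L, length(o) - 1L))],
                        score = scores[o[-1]][seq_len(min(5L, length(o) - 1L))],
                        stringsAsFactors = FALSE)
  structure(list(best_label = best$label, score = best$score,
                 expected = best$expected, found = best$found,
                 private = best$private, runner_ups = runners),
            class = "haplogroup_call")
}

#' @export
print.haplogroup_call <- function(x, ...) {
  cat(sprintf("Haplogroup call: %s (score %.3f; %d/%d defining variants found, %d private)\n",
              x$best_label, x$score, x$found, x$expected, nrow(x$private)))
  invisible(x)
}
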