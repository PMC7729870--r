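# Ancient-DNA processing: read filtering/terminal clipping, deamination
# damage profiles for authentication, pileup, coverage statistics and a
# damage-aware consensus. Damage is profiled BEFORE clipping; consensus is
# built AFTER clipping, mirroring standard aDNA practice.

.BASES <- c("A", "C", "G", "T", "N")

#' Filter and clip aligned reads
#'
#' Removes unmapped records, records below a mapping-quality threshold and
#' records whose id appears on an exclusion list (the pluggable stand-in for
#' external contaminant / numt screens), then masks the first and last
#' `clip_bases` aligned bases of each surviving read (dropped from
#' `aligned_pairs`). Already-clipped reads are not clipped again, so the
#' operation is idempotent. Reads left with no aligned bases are dropped.
#'
#' @param reads List of `aligned_read` from [read_sam()].
#' @param mapq_min Minimum mapping quality kept (default 30).
#' @param clip_bases Number of aligned bases masked at each read end
#'   (default 2; 0 disables clipping).
#' @param exclude_ids Optional character vector of read ids to drop.
#' @return Filtered list of `aligned_read`.
#' @export
filter_reads <- function(reads, mapq_min = 30, clip_bases = 2, exclude_ids = NULL) {
  stopifnot(clip_bases >= 0)
  kept <- Filter(function(r) {
    r$mapped && r$mapq >= mapq_min && !(r$read_id %in% exclude_ids)
  }, reads)
  out <- lapply(kept, function(r) {
    if (clip_bases > 0 && !r$clipped) {
      n <- length(r$aligned_pairs$ref_pos)
      keep <- if (n > 2 * clip_bases) seq.int(clip_bases + 1L, n - clip_bases) else integer(0)
      r$aligned_pairs$ref_pos <- r$aligned_pairs$ref_pos[keep]
      r$aligned_pairs$base <- r$aligned_pairs$base[keep]
      r$clipped <- TRUE
    }
    r
  })
  Filter(function(r) length(r$aligned_pairs$ref_pos) > 0L, out)
}

# Read-orientation reference/read base vectors for one read: minus-strand
# reads are complemented and reversed so index 1 is the read's own 5' end.
.read_orientation <- function(r, ref_chars) {
  refb <- ref_chars[r$aligned_pairs$ref_pos]
  readb <- r$aligned_pairs$base
  if (r$strand == "-") {
    refb <- .revcomp_chars(refb)
    readb <- .revcomp_chars(readb)
  }
  list(refb = refb, readb = readb)
}

#' Terminal deamination damage profile
#'
#' Post-mortem cytosine deamination shows up as C->T substitutions
#' concentrated at fragment ends (and complementary G->A, whose end depends
#' on the library chemistry). For each offset from the 5' and 3' read ends
#' (read orientation; minus-strand reads are complemented and reversed) the
#' profile counts an opportunity when the reference base is C (or G) and a
#' hit when the read base is T (or A), pooled over reads.
#'
#' Must be computed on un-clipped reads: clipping removes exactly the
#' terminal positions being profiled.
#'
#' @param reads List of `aligned_read` (un-clipped).
#' @param reference Reference sequence: character scalar or FASTA path.
#' @param max_offset Deepest offset profiled from each end (default 25).
#' @return Object of class `damage_profile`: per-offset rate vectors
#'   `five_prime_ct`, `three_prime_ct`, `five_prime_ga`, `three_prime_ga`
#'   (NA where no opportunities) and matching `*_n` opportunity counts.
#' @export
damage_profile <- function(reads, reference, max_offset = 25) {
  if (length(reads) == 0L) stop("undefined profile: empty read set")
  if (any(vapply(reads, function(r) isTRUE(r$clipped), logical(1)))) {
    stop("damage_profile requires un-clipped reads (profile precedes clipping)")
  }
  if (length(reference) == 1L && file.exists(reference)) {
    reference <- read_fasta_seq(reference)
  }
  ref_chars <- strsplit(toupper(reference), "")[[1]]

  oriented <- lapply(reads, .read_orientation, ref_chars = ref_chars)
  lens <- vapply(oriented, function(ro) length(ro$refb), integer(1))
  refb <- unlist(lapply(oriented, `[[`, "refb"), use.names = FALSE)
  readb <- unlist(lapply(oriented, `[[`, "readb"), use.names = FALSE)
  off5 <- unlist(lapply(lens, seq_len), use.names = FALSE)
  off3 <- unlist(lapply(lens, function(L) rev(seq_len(L))), use.names = FALSE)

  rate_at <- function(end_off, from, to) {
    opp <- tabulate(end_off[refb == from & end_off <= max_offset], nbins = max_offset)
    hit <- tabulate(end_off[refb == from & readb == to & end_off <= max_offset],
                    nbins = max_offset)
    rate <- ifelse(opp > 0, hit / opp, NA_real_)
    list(rate = rate, n = opp)
  }
  ct5 <- rate_at(off5, "C", "T"); ct3 <- rate_at(off3, "C", "T")
  ga5 <- rate_at(off5, "G", "A"); ga3 <- rate_at(off3, "G", "A")
  structure(list(max_offset = max_offset,
                 five_prime_ct = ct5$rate, five_prime_ct_n = ct5$n,
                 three_prime_ct = ct3$rate, three_prime_ct_n = ct3$n,
                 five_prime_ga = ga5$rate, five_prime_ga_n = ga5$n,
                 three_prime_ga = ga3$rate, three_prime_ga_n = ga3$n),
            class = "damage_profile")
}

#' Write a damage profile as TSV
#'
#' Columns: offset, end (5p/3p), class (CT/GA), hits, opportunities, rate.
#'
#' @param profile A `damage_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_damage_tsv <- function(profile, path) {
  rows <- do.call(rbind, lapply(list(
    c("5p", "CT", "five_prime_ct"), c("3p", "CT", "three_prime_ct"),
    c("5p", "GA", "five_prime_ga"), c("3p", "GA", "three_prime_ga")), function(spec) {
      rate <- profile[[spec[3]]]
      n <- profile[[paste0(spec[3], "_n")]]
      data.frame(offset = seq_along(rate), end = spec[1], class = spec[2],
                 hits = round(ifelse(is.na(rate), 0, rate) * n),
                 opportunities = n, rate = rate)
    }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.pooled_rate <- function(rate, n, offsets) {
  offsets <- offsets[offsets <= length(rate)]
  hits <- sum(ifelse(is.na(rate[offsets]), 0, rate[offsets]) * n[offsets])
  opp <- sum(n[offsets])
  list(rate = if (opp > 0) hits / opp else NA_real_, opportunities = opp)
}

#' Authenticate a read set from its damage profile
#'
#' Declares a library consistent with ancient DNA when the pooled terminal
#' deamination rate exceeds `min_ratio` times the pooled interior rate
#' (floored at `pseudo_rate` so clean interiors do not divide by zero) at
#' both analysed ends. Double-stranded libraries are checked on 5' C->T and
#' 3' G->A; single-stranded libraries on C->T at both ends.
#'
#' @param profile A `damage_profile`.
#' @param terminal_offsets Offsets treated as terminal (default 1:2).
#' @param interior_offsets Offsets treated as interior baseline
#'   (default 11:25).
#' @param min_ratio Required terminal/interior fold elevation (default 3).
#' @param library_type `"double"` or `"single"` stranded.
#' @param pseudo_rate Floor for the interior rate (default 0.005).
#' @param min_opportunities Minimum pooled terminal opportunities per end
#'   below which the call is inconclusive (`authentic = NA`).
#' @return List with `authentic` (TRUE/FALSE/NA), per-end statistics and a
#'   human-readable `summary`.
#' @export
authenticate <- function(profile, terminal_offsets = 1:2, interior_offsets = 11:25,
                         min_ratio = 3, library_type = c("double", "single"),
                         pseudo_rate = 0.005, min_opportunities = 50) {
  stopifnot(inherits(profile, "damage_profile"))
  library_type <- match.arg(library_type)
  ends <- if (library_type == "double") {
    list(five_prime = "five_prime_ct", three_prime = "three_prime_ga")
  } else {
    list(five_prime = "five_prime_ct", three_prime = "three_prime_ct")
  }
  stats <- lapply(ends, function(field) {
    term <- .pooled_rate(profile[[field]], profile[[paste0(field, "_n")]],
                         terminal_offsets)
    intr <- .pooled_rate(profile[[field]], profile[[paste0(field, "_n")]],
                         interior_offsets)
    baseline <- max(intr$rate, pseudo_rate, na.rm = TRUE)
    list(class = field, terminal_rate = term$rate,
         terminal_opportunities = term$opportunities,
         interior_rate = intr$rate, baseline = baseline,
         elevated = !is.na(term$rate) && term$rate >= min_ratio * baseline,
         conclusive = term$opportunities >= min_opportunities)
  })
  authentic <- if (!all(vapply(stats, `[[`, logical(1), "conclusive"))) {
    NA
  } else {
    all(vapply(stats, `[[`, logical(1), "elevated"))
  }
  fmt <- function(s) sprintf("%s terminal %.3f vs interior baseline %.3f (n=%d)",
                             s$class, s$terminal_rate, s$baseline,
                             s$terminal_opportunities)
  verdict <- if (is.na(authentic)) "inconclusive (insufficient opportunities)"
             else if (authentic) "consistent with ancient DNA"
             else "no terminal damage elevation"
  list(authentic = authentic, ends = stats, library_type = library_type,
       summary = paste0(verdict, "; ", paste(vapply(stats, fmt, character(1)),
                                             collapse = "; ")))
}

#' Pileup of aligned reads over a reference
#'
#' Per-position base counts accumulated over every read's aligned pairs.
#'
#' @param reads List of `aligned_read` (filtered/clipped as desired).
#' @param reference Reference sequence: character scalar or FASTA path.
#' @return Object of class `pileup`: list with `counts` (positions x
#'   A/C/G/T/N integer matrix), `depth`, `ref_base`, `reference_length`.
#' @export
pileup <- function(reads, reference) {
  if (length(reference) == 1L && file.exists(reference)) {
    reference <- read_fasta_seq(reference)
  }
  ref_chars <- strsplit(toupper(reference), "")[[1]]
  L <- length(ref_chars)
  counts <- matrix(0L, nrow = L, ncol = 5L, dimnames = list(NULL, .BASES))
  pos_all <- unlist(lapply(reads, function(r) r$aligned_pairs$ref_pos))
  base_all <- unlist(lapply(reads, function(r) r$aligned_pairs$base))
  if (length(pos_all)) {
    if (any(pos_all < 1L | pos_all > L)) stop("aligned position outside reference")
    base_all[!base_all %in% .BASES] <- "N"
    tb <- table(factor(pos_all, levels = seq_len(L)),
                factor(base_all, levels = .BASES))
    counts <- matrix(as.integer(tb), nrow = L, dimnames = list(NULL, .BASES))
  }
  structure(list(counts = counts, depth = as.integer(rowSums(counts)),
                 ref_base = ref_chars, reference_length = L),
            class = "pileup")
}

#' Breadth and depth of coverage
#'
#' @param pile A [pileup()].
#' @param depth_floor Minimum depth for a position to count as covered
#'   (default 1).
#' @return List of class `coverage_stats` with `reference_length`,
#'   `breadth_pct` (percent of positions at depth >= floor, 1 decimal) and
#'   `mean_depth`.
#' @export
coverage_stats <- function(pile, depth_floor = 1) {
  stopifnot(inherits(pile, "pileup"), pile$reference_length > 0)
  structure(list(reference_length = pile$reference_length,
                 depth_floor = depth_floor,
                 breadth_pct = round(100 * sum(pile$depth >= depth_floor) /
                                       pile$reference_length, 1),
                 mean_depth = sum(pile$depth) / pile$reference_length),
            class = "coverage_stats")
}

#' Call a consensus sequence from a pileup
#'
#' Substitution-only consensus: a position is called with its modal base
#' (among A/C/G/T) when depth >= `min_depth` and the modal base carries at
#' least `min_fraction` of the total depth; otherwise, and on ties, the
#' position is emitted as N.
#'
#' @param pile A [pileup()].
#' @param min_depth Minimum depth to call a base (default 2).
#' @param min_fraction Minimum modal-base fraction of depth (default 0.7).
#' @return Consensus as a character scalar (length = reference length).
#' @export
consensus <- function(pile, min_depth = 2, min_fraction = 0.7) {
  stopifnot(inherits(pile, "pileup"))
  acgt <- pile$counts[, c("A", "C", "G", "T"), drop = FALSE]
  top <- apply(acgt, 1L, max)
  tied <- rowSums(acgt == top) > 1L
  modal <- c("A", "C", "G", "T")[max.col(acgt, ties.method = "first")]
  callable <- pile$depth >= min_depth & top >= min_fraction * pile$depth &
    top > 0L & !tied
  out <- rep("N", pile$reference_length)
  out[callable] <- modal[callable]
  paste(out, collapse = "")
}
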