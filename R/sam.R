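# Plain-text SAM parsing with CIGAR resolution. The pipeline consumes
# already-aligned reads against a single (mitochondrial) reference; only the
# fields needed downstream are kept.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcomp_chars <- function(x) unname(.COMPLEMENT[rev(x)])

#' Read a FASTA file as a plain character sequence
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; returns the first
#' record as an uppercase character scalar.
#'
#' @param path FASTA path.
#' @return Character scalar (named with the record id).
#' @export
read_fasta_seq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 1L) stop("no sequences in ", path)
  out <- toupper(as.character(ss[[1]]))
  names(out) <- names(ss)[1]
  out
}

#' Write a named sequence to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Resolve one CIGAR string into per-base (ref_pos, read_base) pairs.
# M/=/X consume both; I/S consume the read; D/N consume the reference;
# H consumes neither. Inserted bases are dropped (no indel consensus).
.resolve_cigar <- function(cigar, pos, seq_chars) {
  ops_len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(ops) == 0L || length(ops) != length(ops_len)) {
    stop("malformed CIGAR: ", cigar)
  }
  ref_pos <- integer(0)
  read_idx <- integer(0)
  rp <- pos
  ri <- 1L
  for (k in seq_along(ops)) {
    n <- ops_len[k]
    op <- ops[k]
    if (op %in% c("M", "=", "X")) {
      ref_pos <- c(ref_pos, seq.int(rp, length.out = n))
      read_idx <- c(read_idx, seq.int(ri, length.out = n))
      rp <- rp + n; ri <- ri + n
    } else if (op %in% c("I", "S")) {
      ri <- ri + n
    } else if (op %in% c("D", "N")) {
      rp <- rp + n
    } # H, P consume nothing
  }
  list(ref_pos = ref_pos, base = seq_chars[read_idx])
}

#' Parse a SAM text file
#'
#' Reads a plain-text SAM file aligned against a single reference and
#' resolves each record's CIGAR into per-base `(ref_pos, read_base)` aligned
#' pairs (1-based reference coordinates, bases as stored, i.e. forward
#' reference orientation). Header lines (`@`) are skipped; a malformed
#' record aborts with its line number.
#'
#' @param path SAM path.
#' @return A list of `aligned_read` objects, each a list with `read_id`,
#'   `mapped`, `strand` (`"+"`/`"-"`), `mapq`, `ref_start`, `aligned_pairs`
#'   (list with `ref_pos`, `base`) and `clipped` (FALSE on parse).
#' @export
read_sam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- vector("list", length(lines))
  n_out <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "@")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) stop(sprintf("malformed SAM record at line %d (%d fields)", i, length(f)))
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    mapq <- suppressWarnings(as.integer(f[5]))
    if (is.na(flag) || is.na(pos) || is.na(mapq)) {
      stop(sprintf("malformed SAM record at line %d: non-numeric FLAG/POS/MAPQ", i))
    }
    mapped <- !bitwAnd(flag, 4L) && f[3] != "*" && f[6] != "*"
    pairs <- if (mapped) {
      .resolve_cigar(f[6], pos, strsplit(toupper(f[10]), "")[[1]])
    } else {
      list(ref_pos = integer(0), base = character(0))
    }
    n_out <- n_out + 1L
    out[[n_out]] <- structure(list(
      read_id = f[1],
      mapped = mapped,
      strand = if (bitwAnd(flag, 16L)) "-" else "+",
      mapq = mapq,
      ref_start = pos,
      aligned_pairs = pairs,
      clipped = FALSE), class = "aligned_read")
  }
  out[seq_len(n_out)]
}
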