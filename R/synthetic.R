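# Synthetic-data generators: reference sequences, a fictional haplogroup
# fixture tree, haplotypes walked from the tree, ancient reads with
# parameterised terminal deamination, calibration curves with closed-form
# posteriors, and bivariate isotope reference clusters. Every generator is a
# deterministic function of its arguments and seed.

#' Simulate a random reference sequence
#'
#' Uniform A/C/G/T sequence used as a stand-in mitochondrial reference for
#' tests and demonstrations (the real 16,569-bp reference is user-supplied).
#'
#' @param length Sequence length in bp (default 16569, the mtDNA convention).
#' @param seed Integer seed.
#' @return Character scalar.
#' @export
simulate_reference <- function(length = 16569L, seed = 1L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Fictional haplogroup fixture tree
#'
#' A ~24-node defining-variant tree with haplogroup-style labels, generated
#' against an arbitrary reference: defining positions are drawn (without
#' replacement, deterministically from `seed`) outside the default
#' hypervariable mask, and each variant is the transition of the reference
#' base, so the tree is valid on the supplied reference by construction.
#' Purely synthetic -- node labels echo real haplogroup nomenclature but the
#' variants are fictional.
#'
#' @param reference Reference sequence the tree is defined on.
#' @param seed Integer seed for defining-position placement.
#' @return A [haplogroup_tree()].
#' @export
fixture_haplogroup_tree <- function(reference, seed = 101L) {
  labels <- c("mt-MRCA", "L1", "L1c", "M", "D", "D4", "G", "N", "A", "B",
              "B2", "B2a", "R", "HV", "H", "H1", "H1e", "H1e2", "H1e2b",
              "H3", "V", "J", "T", "X")
  parents <- c(NA, "mt-MRCA", "L1", "mt-MRCA", "M", "D", "M", "mt-MRCA",
               "N", "N", "B", "B2", "N", "R", "HV", "H", "H1", "H1e",
               "H1e2", "H", "HV", "R", "R", "N")
  n_var <- c(0, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 1, 2, 2, 2, 1, 1, 2, 2,
             2, 2, 2, 2)
  ref_chars <- strsplit(toupper(reference), "")[[1]]
  L <- length(ref_chars)
  if (L < 400L) stop("reference too short for the fixture tree")
  allowed <- setdiff(seq_len(L), masked_positions(mask_policy()))
  allowed <- allowed[ref_chars[allowed] %in% c("A", "C", "G", "T")]
  set.seed(seed)
  pos <- sample(allowed, sum(n_var))
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  take <- 0L
  variants <- lapply(seq_along(labels), function(i) {
    if (n_var[i] == 0L) return(variant_table())
    p <- sort(pos[take + seq_len(n_var[i])])
    take <<- take + n_var[i]
    variant_table(p, ref_chars[p], unname(transition[ref_chars[p]]))
  })
  haplogroup_tree(labels, match(parents, labels), variants)
}

#' Simulate a haplotype from a haplogroup tree
#'
#' Applies every defining variant on the root-to-node path to the
#' reference, then adds `n_private` random substitutions at positions free
#' of any defining variant (tree-wide) and of the default hypervariable
#' mask, so private variation never perturbs the haplogroup signal.
#'
#' @param tree A [haplogroup_tree()].
#' @param node_label Label of the node to emulate.
#' @param reference Reference sequence the tree is defined on.
#' @param n_private Number of private substitutions (default 0).
#' @param seed Integer seed for private-site placement.
#' @return Character scalar haplotype sequence.
#' @export
simulate_haplotype <- function(tree, node_label, reference, n_private = 0L, seed = 1L) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  ch <- strsplit(toupper(reference), "")[[1]]
  pv <- path_variants(tree, node_label)
  if (nrow(pv)) {
    if (any(ch[pv$position] != pv$ref)) {
      stop("tree defining variants inconsistent with reference")
    }
    ch[pv$position] <- pv$alt
  }
  if (n_private > 0L) {
    defining <- unique(unlist(lapply(tree$variants, function(v) v$position)))
    free <- setdiff(seq_along(ch), c(defining, masked_positions(mask_policy())))
    set.seed(seed)
    sites <- sample(free, n_private)
    for (p in sites) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
  }
  paste(ch, collapse = "")
}

#' Damage model for ancient-read simulation
#'
#' Terminal deamination probability decays geometrically with the offset
#' from the read end: `p(k) = terminal_rate * decay^(k - 1)`.
#' Double-stranded libraries deaminate C->T at the 5' end and show the
#' complementary G->A at the 3' end; single-stranded libraries show C->T at
#' both ends.
#'
#' @param terminal_rate Damage probability at offset 1 (in `[0, 1]`).
#' @param decay Multiplicative per-offset decay in `(0, 1]`.
#' @param base_error Uniform per-base sequencing error probability.
#' @param library_type `"double"` or `"single"`.
#' @return A list of class `damage_model`.
#' @export
damage_model <- function(terminal_rate = 0.3, decay = 0.5, base_error = 0.001,
                         library_type = c("double", "single")) {
  library_type <- match.arg(library_type)
  stopifnot(terminal_rate >= 0, terminal_rate <= 1,
            decay > 0, decay <= 1, base_error >= 0, base_error <= 1)
  structure(list(terminal_rate = terminal_rate, decay = decay,
                 base_error = base_error, library_type = library_type),
            class = "damage_model")
}

#' Simulate ancient reads as SAM records
#'
#' Fragments are drawn with truncated-normal lengths at uniform start
#' positions and uniform strand; damage is applied in read orientation
#' according to the [damage_model()], then uniform base errors; records are
#' emitted as valid SAM (match-only CIGAR, MAPQ 60) together with a truth
#' log of every injected event.
#'
#' @param reference Reference (haplotype) sequence reads are drawn from.
#' @param n_reads Number of reads.
#' @param damage A [damage_model()].
#' @param fragment_length_mean,fragment_length_sd,min_length Truncated-normal
#'   fragment length parameters, bp (defaults 60 / 15 / 25, typical of
#'   ancient DNA).
#' @param seed Integer seed.
#' @param ref_name Reference name written to the SAM header.
#' @return A list of class `read_simulation`: `sam` (character vector of SAM
#'   lines), `truth` (data frame: read_id, start, length, strand, offset,
#'   end, event for every injected change), and the simulation parameters.
#' @export
simulate_reads <- function(reference, n_reads, damage = damage_model(),
                           fragment_length_mean = 60, fragment_length_sd = 15,
                           min_length = 25, seed = 1L,
                           ref_name = "synthetic_mt") {
  stopifnot(inherits(damage, "damage_model"), n_reads > 0, min_length >= 20)
  L <- nchar(reference)
  if (L < min_length) stop("reference shorter than min_length")
  ref_chars <- strsplit(toupper(reference), "")[[1]]
  set.seed(seed)

  lens <- integer(n_reads)
  filled <- 0L
  while (filled < n_reads) {
    draw <- round(stats::rnorm(n_reads, fragment_length_mean, fragment_length_sd))
    draw <- draw[draw >= min_length & draw <= L]
    take <- min(length(draw), n_reads - filled)
    lens[filled + seq_len(take)] <- draw[seq_len(take)]
    filled <- filled + take
  }
  starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L), integer(1))
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)

  sam <- character(n_reads)
  truth <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    id <- sprintf("sim_%05d", i)
    frag <- ref_chars[starts[i]:(starts[i] + lens[i] - 1L)]
    rd <- if (strands[i] == "-") .revcomp_chars(frag) else frag  # read orientation
    events <- list()
    p_off <- damage$terminal_rate * damage$decay^(seq_len(lens[i]) - 1L)
    # 5' C->T
    hit5 <- which(rd == "C" & stats::runif(lens[i]) < p_off)
    if (length(hit5)) {
      rd[hit5] <- "T"
      events[[length(events) + 1L]] <- data.frame(
        offset = hit5, end = "5p",
        event = if (damage$library_type == "double") "CT" else "CT",
        stringsAsFactors = FALSE)
    }
    # 3' end: G->A (double-stranded) or C->T (single-stranded)
    off3 <- rev(seq_len(lens[i]))
    from3 <- if (damage$library_type == "double") "G" else "C"
    to3 <- if (damage$library_type == "double") "A" else "T"
    hit3 <- which(rd == from3 & stats::runif(lens[i]) < p_off[off3])
    if (length(hit3)) {
      rd[hit3] <- to3
      events[[length(events) + 1L]] <- data.frame(
        offset = off3[hit3], end = "3p", event = paste0(from3, to3),
        stringsAsFactors = FALSE)
    }
    # uniform sequencing errors
    err <- which(stats::runif(lens[i]) < damage$base_error)
    for (p in err) {
      rd[p] <- sample(setdiff(c("A", "C", "G", "T"), rd[p]), 1L)
    }
    if (length(err)) {
      events[[length(events) + 1L]] <- data.frame(
        offset = err, end = "err", event = "error", stringsAsFactors = FALSE)
    }
    if (length(events)) {
      ev <- do.call(rbind, events)
      ev <- cbind(read_id = id, start = starts[i], length = lens[i],
                  strand = strands[i], ev)
      truth[[i]] <- ev
    }
    seq_out <- if (strands[i] == "-") paste(.revcomp_chars(rd), collapse = "")
               else paste(rd, collapse = "")
    flag <- if (strands[i] == "-") 16L else 0L
    sam[i] <- paste(id, flag, ref_name, starts[i], 60L,
                    paste0(lens[i], "M"), "*", 0L, 0L, seq_out,
                    strrep("I", lens[i]), sep = "\t")
  }
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", ref_name, "\tLN:", L))
  truth_df <- if (any(!vapply(truth, is.null, logical(1)))) {
    do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
  } else {
    data.frame(read_id = character(0), start = integer(0), length = integer(0),
               strand = character(0), offset = integer(0), end = character(0),
               event = character(0), stringsAsFactors = FALSE)
  }
  structure(list(sam = c(header, sam), truth = truth_df, n_reads = n_reads,
                 damage = damage, seed = seed, ref_name = ref_name,
                 reference_length = L),
            class = "read_simulation")
}

#' Write simulated reads to a SAM file
#'
#' @param sim A [simulate_reads()] result.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sim, path) {
  stopifnot(inherits(sim, "read_simulation"))
  writeLines(sim$sam, path)
  invisible(path)
}

#' Synthesize a calibration curve with known shape
#'
#' `constant`: `mu(theta) = c`; `linear`: `mu(theta) = a + b * theta`
#' (with `b = 1`, `a = 0` the calendar posterior of a date is a discretised
#' Gaussian -- a closed-form oracle); `wiggle`: linear plus a sinusoid of
#' given amplitude and period, for constructing multi-modal posteriors with
#' a known number of likelihood crossings.
#'
#' @param kind `"constant"`, `"linear"` or `"wiggle"`.
#' @param domain Length-2 calendar range, cal BP.
#' @param knot_step Knot spacing in years (default 1).
#' @param c Constant level (kind = "constant").
#' @param a,b Intercept/slope (kinds "linear" and "wiggle").
#' @param amplitude,period Sinusoid parameters (kind = "wiggle").
#' @param sigma Curve one-sigma error, recycled over knots.
#' @param name Curve name.
#' @return A [calibration_curve()].
#' @export
synth_curve <- function(kind = c("constant", "linear", "wiggle"),
                        domain, knot_step = 1, c = 0, a = 0, b = 1,
                        amplitude = 0, period = 100, sigma = 0,
                        name = paste0("synthetic_", kind[1])) {
  kind <- match.arg(kind)
  if (domain[1] >= domain[2]) stop("domain must be non-empty")
  theta <- seq(domain[1], domain[2], by = knot_step)
  mu <- switch(kind,
               constant = rep(c, length(theta)),
               linear = a + b * theta,
               wiggle = a + b * theta + amplitude * sin(2 * pi * theta / period))
  calibration_curve(name, theta, mu, rep_len(sigma, length(theta)))
}

#' Write a calibration curve in ".14c" column format
#'
#' @param curve A [calibration_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", attr(curve, "name")), con)
  writeLines("# cal BP, 14C age BP, sigma, Delta14C, sigma", con)
  writeLines(sprintf("%g,%g,%g,0,0", curve$cal_bp, curve$c14_age,
                     curve$c14_sigma), con)
  invisible(path)
}

#' Synthesize a bivariate isotope reference cluster
#'
#' Draws `n` (d13C, d15N) pairs from a bivariate normal distribution --
#' a stand-in for an empirical dietary reference population.
#'
#' @param n Number of individuals (>= 3).
#' @param mean Length-2 mean `(d13C, d15N)`.
#' @param covariance 2x2 positive-definite covariance.
#' @param seed Integer seed.
#' @param label Cluster label.
#' @return A [reference_cluster()].
#' @export
synth_isotope_cluster <- function(n, mean = c(-19, 12),
                                  covariance = matrix(c(0.6, 0.3, 0.3, 1.0), 2),
                                  seed = 1L, label = "synthetic") {
  if (n < 3L) stop("n must be >= 3")
  if (!isTRUE(all.equal(covariance, t(covariance)))) {
    stop("covariance must be symmetric")
  }
  ch <- tryCatch(chol(covariance), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) <= 0)) {
    stop("covariance must be positive-definite")
  }
  set.seed(seed)
  z <- matrix(stats::rnorm(2 * n), ncol = 2)
  xy <- sweep(z %*% ch, 2, mean, `+`)
  reference_cluster(label, xy[, 1], xy[, 2])
}
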