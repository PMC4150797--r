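#' Default chromatin-state alphabet
#'
#' The four coarse chromatin types used throughout: transcriptionally active
#' chromatin, HP1-like constitutive heterochromatin, Polycomb-like facultative
#' heterochromatin, and the gene-poor repressive "black" chromatin.
#'
#' @export
default_alphabet <- function() c("active", "HP1", "Polycomb", "black")

#' Epigenomic sequence of a copolymer
#'
#' An `epi_sequence` holds one chromatin-state label per monomer of the
#' coarse-grained chain, together with the genomic span each monomer
#' represents (`bin_size`, default 10 kb) and an optional genomic anchor.
#' The chain of labels is the primary sequence of the block copolymer.
#'
#' @param states character vector of state labels, one per monomer.
#' @param alphabet ordered character vector of allowed labels. Defaults to
#'   the labels of `states` in order of first appearance.
#' @param bin_size genomic span per monomer in bp (> 0).
#' @param anchor optional `list(chrom =, start =)` genomic anchor
#'   (0-based start, in bp).
#' @return an object of class `epi_sequence`.
#' @export
epi_sequence <- function(states, alphabet = NULL, bin_size = 10000,
                         anchor = NULL) {
  states <- as.character(states)
  if (length(states) < 1L)
    stop("an epigenomic sequence needs at least one monomer")
  if (is.null(alphabet))
    alphabet <- unique(states)
  alphabet <- as.character(alphabet)
  if (!all(states %in% alphabet))
    stop("states contain labels outside the alphabet: ",
         paste(setdiff(states, alphabet), collapse = ", "))
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stop("bin_size must be a single positive number")
  if (!is.null(anchor)) {
    if (!is.list(anchor) || is.null(anchor$chrom) || is.null(anchor$start))
      stop("anchor must be list(chrom =, start =)")
    if (anchor$start < 0) stop("anchor start must be >= 0")
  }
  structure(
    list(states = states, alphabet = alphabet,
         bin_size = as.numeric(bin_size), anchor = anchor),
    class = "epi_sequence")
}

#' @export
length.epi_sequence <- function(x) length(x$states)

#' @export
print.epi_sequence <- function(x, ...) {
  cat(sprintf("epi_sequence: %d monomers x %g bp, alphabet {%s}\n",
              length(x$states), x$bin_size,
              paste(x$alphabet, collapse = ", ")))
  if (!is.null(x$anchor))
    cat(sprintf("  anchor: %s:%d\n", x$anchor$chrom,
                as.integer(x$anchor$start)))
  r <- rle(x$states)
  blocks <- paste0(r$values, r$lengths)
  if (length(blocks) > 12) blocks <- c(head(blocks, 12), "...")
  cat("  blocks:", paste(blocks, collapse = " "), "\n")
  invisible(x)
}

# Coerce a BED4 file path or a data.frame (chrom, start, end, state) into a
# GRanges with a `state` metadata column.
as_state_granges <- function(bed) {
  if (is.character(bed) && length(bed) == 1L) {
    gr <- rtracklayer::import(bed, format = "BED")
    if (is.null(gr$name))
      stop("BED input must carry a state label in column 4")
    gr$state <- as.character(gr$name)
    return(gr)
  }
  if (is.data.frame(bed)) {
    need <- c("chrom", "start", "end", "state")
    if (!all(need %in% names(bed)))
      stop("segmentation data.frame needs columns chrom, start, end, state")
    gr <- GenomicRanges::GRanges(
      seqnames = bed$chrom,
      ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end))
    gr$state <- as.character(bed$state)
    return(gr)
  }
  if (methods::is(bed, "GRanges")) {
    if (is.null(bed$state)) {
      if (is.null(bed$name)) stop("GRanges input needs a state or name column")
      bed$state <- as.character(bed$name)
    }
    return(bed)
  }
  stop("unsupported segmentation input")
}

#' Build a copolymer sequence from an epigenomic segmentation
#'
#' Coarse-grains a BED-like chromatin-state segmentation onto fixed genomic
#' bins covering `[start, end)` of a region. Each bin receives the label with
#' the largest overlap (majority rule); ties are broken by the label that
#' appears first within the bin, then by alphabet order. Bins not covered by
#' any interval receive `default_label`. A label-merge map is applied before
#' binning (e.g. collapsing two active sub-states into one).
#'
#' @param bed a BED4 file path, a data.frame with columns
#'   `chrom, start, end, state` (0-based half-open coordinates), or a
#'   `GRanges` with a `state` column.
#' @param region `c(chrom, start, end)` in bp, 0-based half-open.
#' @param bin_size genomic span per monomer in bp (default 10 kb).
#' @param merge_map optional named character vector mapping raw labels to
#'   merged labels, applied before binning.
#' @param default_label label assigned to uncovered bins (default "black",
#'   the prevalent repressive chromatin type).
#' @param alphabet allowed labels after merging; defaults to
#'   [default_alphabet()].
#' @return an [epi_sequence()] with `N = ceiling((end - start)/bin_size)`
#'   monomers and the region anchor recorded.
#' @export
load_segmentation <- function(bed, region, bin_size = 10000,
                              merge_map = NULL,
                              default_label = "black",
                              alphabet = NULL) {
  if (length(region) != 3L)
    stop("region must be c(chrom, start, end)")
  chrom <- as.character(region[[1]])
  r_start <- as.numeric(region[[2]])
  r_end <- as.numeric(region[[3]])
  if (!(r_end > r_start)) stop("region end must exceed region start")
  if (is.null(alphabet)) alphabet <- default_alphabet()

  gr <- as_state_granges(bed)
  if (!is.null(merge_map)) {
    hit <- gr$state %in% names(merge_map)
    gr$state[hit] <- unname(merge_map[gr$state[hit]])
  }

  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  n_bins <- as.integer(ceiling((r_end - r_start) / bin_size))
  bin_start0 <- r_start + bin_size * (seq_len(n_bins) - 1)   # 0-based
  bin_end0 <- pmin(bin_start0 + bin_size, r_end)
  bins <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = bin_start0 + 1, end = bin_end0))

  hits <- GenomicRanges::findOverlaps(bins, gr)
  if (length(hits) == 0L) stop("no segmentation in region")

  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- IRanges::pintersect(bins[q], gr[s])
  lab <- gr$state[s]
  unknown <- setdiff(unique(lab), alphabet)
  if (length(unknown) > 0L)
    stop("unknown label(s) not in merge map or alphabet: ",
         paste(unknown, collapse = ", "))

  w <- GenomicRanges::width(ov)
  first_pos <- GenomicRanges::start(ov)

  states <- rep(default_label, n_bins)
  for (b in unique(q)) {
    i <- which(q == b)
    tot <- tapply(w[i], lab[i], sum)
    best <- names(tot)[tot == max(tot)]
    if (length(best) > 1L) {
      fp <- tapply(first_pos[i], lab[i], min)[best]
      best <- best[fp == min(fp)]
      if (length(best) > 1L)
        best <- best[order(match(best, alphabet))][1L]
    }
    states[b] <- best
  }
  if (!default_label %in% alphabet)
    stop("default_label must be in the alphabet")

  epi_sequence(states, alphabet = alphabet, bin_size = bin_size,
               anchor = list(chrom = chrom, start = r_start))
}

# Normalise a block specification (named numeric vector or data.frame with
# columns label/length) into a data.frame(label, length).
as_block_frame <- function(blocks) {
  if (is.data.frame(blocks)) {
    if (!all(c("label", "length") %in% names(blocks)))
      stop("block data.frame needs columns label and length")
    out <- data.frame(label = as.character(blocks$label),
                      length = as.numeric(blocks$length))
  } else if (!is.null(names(blocks))) {
    out <- data.frame(label = names(blocks), length = as.numeric(blocks))
  } else {
    stop("blocks must be a named vector or a data.frame(label, length)")
  }
  if (nrow(out) == 0L) stop("empty block pattern")
  if (any(out$length < 1)) stop("block lengths must be >= 1")
  out
}

#' Build a synthetic block copolymer sequence
#'
#' Concatenates a pattern of labelled blocks, repeated `repeats` times. The
#' toy chain \eqn{(A_{10}B_{10})_6} is `make_block_sequence(c(A = 10, B = 10),
#' repeats = 6)`: 120 monomers alternating in runs of 10.
#'
#' @param blocks named numeric vector (names = labels, values = block
#'   lengths) or a data.frame with columns `label` and `length`.
#' @param repeats number of repetitions of the whole pattern (>= 1).
#' @param bin_size genomic span per monomer in bp.
#' @param alphabet optional alphabet; defaults to labels in order of first
#'   appearance.
#' @return an [epi_sequence()].
#' @export
make_block_sequence <- function(blocks, repeats = 1, bin_size = 10000,
                                alphabet = NULL) {
  bf <- as_block_frame(blocks)
  if (repeats < 1) stop("repeats must be >= 1")
  one <- rep(bf$label, times = bf$length)
  epi_sequence(rep(one, times = repeats), alphabet = alphabet,
               bin_size = bin_size)
}

#' Random block sequence (fixture generator)
#'
#' Draws a sequence of `n_blocks` blocks with lengths uniform on
#' `block_length_range` and labels drawn from `alphabet` such that adjacent
#' blocks carry distinct labels. Reproducible for a fixed `seed`.
#'
#' @param n_blocks number of blocks (>= 1).
#' @param block_length_range integer vector `c(min, max)`, min >= 1.
#' @param alphabet labels to draw from; at least 2 needed when
#'   `n_blocks > 1`.
#' @param seed optional integer seed (global RNG state is restored on exit).
#' @param bin_size genomic span per monomer in bp.
#' @return an [epi_sequence()].
#' @export
random_block_sequence <- function(n_blocks, block_length_range = c(5, 15),
                                  alphabet = c("A", "B"), seed = NULL,
                                  bin_size = 10000) {
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  if (block_length_range[1] < 1) stop("minimum block length must be >= 1")
  if (length(alphabet) < 2 && n_blocks > 1)
    stop("alphabet of size 1 cannot make adjacent blocks distinct")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  lens <- sample(seq(block_length_range[1], block_length_range[2]),
                 n_blocks, replace = TRUE)
  labs <- character(n_blocks)
  labs[1] <- sample(alphabet, 1)
  if (n_blocks > 1) {
    for (i in 2:n_blocks)
      labs[i] <- sample(setdiff(alphabet, labs[i - 1]), 1)
  }
  make_block_sequence(data.frame(label = labs, length = lens),
                      alphabet = alphabet, bin_size = bin_size)
}

#' Same-state indicator matrix
#'
#' The binary symmetric matrix with entry 1 when monomers `m` and `n` carry
#' the same chromatin state, 0 otherwise. This is the switch that turns the
#' specific interaction `U_s` on between same-state monomer pairs.
#'
#' @param seq an [epi_sequence()].
#' @return an `N x N` 0/1 matrix with unit diagonal.
#' @export
same_state_indicator <- function(seq) {
  stopifnot(inherits(seq, "epi_sequence"))
  d <- outer(seq$states, seq$states, "==") * 1L
  dimnames(d) <- NULL
  d
}

#' Parse a block-pattern string such as "(A10B10)x6"
#'
#' Grammar: `"(" (LABEL LENGTH)+ ")" "x" REPEATS` with alphabetic labels and
#' integer lengths, e.g. `"(A10B10)x6"` for the 120-monomer toy chain.
#'
#' @param pattern pattern string.
#' @return `list(blocks = named numeric vector, repeats = integer)`.
#' @export
parse_block_pattern <- function(pattern) {
  m <- regmatches(pattern,
                  regexec("^\\(((?:[A-Za-z]+[0-9]+)+)\\)x([0-9]+)$", pattern))[[1]]
  if (length(m) != 3L)
    stop("malformed block pattern: ", pattern,
         " (expected e.g. \"(A10B10)x6\")")
  body <- m[2]
  reps <- as.integer(m[3])
  pieces <- regmatches(body, gregexpr("[A-Za-z]+[0-9]+", body))[[1]]
  labs <- sub("[0-9]+$", "", pieces)
  lens <- as.numeric(sub("^[A-Za-z]+", "", pieces))
  list(blocks = setNames(lens, labs), repeats = reps)
}

#' Write an epigenomic sequence as BED4
#'
#' Consecutive monomers of equal state are merged into intervals; coordinates
#' are 0-based half-open, anchored at the sequence anchor (or `chrom = "seq"`,
#' start 0 when absent).
#'
#' @param seq an [epi_sequence()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_sequence_bed <- function(seq, path) {
  stopifnot(inherits(seq, "epi_sequence"))
  chrom <- if (!is.null(seq$anchor)) seq$anchor$chrom else "seq"
  start0 <- if (!is.null(seq$anchor)) seq$anchor$start else 0
  r <- rle(seq$states)
  ends <- cumsum(r$lengths) * seq$bin_size + start0
  starts <- ends - r$lengths * seq$bin_size
  df <- data.frame(chrom = chrom, start = format(starts, scientific = FALSE,
                                                 trim = TRUE),
                   end = format(ends, scientific = FALSE, trim = TRUE),
                   state = r$values)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the per-monomer label list as plain text
#'
#' @param seq an [epi_sequence()].
#' @param path output file path (one label per line).
#' @return the path, invisibly.
#' @export
write_sequence_labels <- function(seq, path) {
  stopifnot(inherits(seq, "epi_sequence"))
  writeLines(seq$states, path)
  invisible(path)
}
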