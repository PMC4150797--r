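#' Contact map container
#'
#' A symmetric matrix of contact probabilities/frequencies with the
#' proportionality constant `A` of the Gaussian contact formula
#' \eqn{P_{mn} \approx A D_{mn}^{-3/2}}, the genomic bin size and an
#' optional genomic anchor.
#'
#' @param P symmetric non-negative matrix.
#' @param A proportionality constant (NA when unknown, e.g. counted maps).
#' @param bin_size bp per bin.
#' @param anchor optional `list(chrom =, start =)`.
#' @return an object of class `contact_map`.
#' @export
contact_map <- function(P, A = NA_real_, bin_size = 10000, anchor = NULL) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("contact map must be square")
  if (any(P < 0)) stop("contact map entries must be non-negative")
  if (max(abs(P - t(P))) > 1e-8 * max(1, max(P)))
    stop("contact map must be symmetric")
  structure(list(P = P, A = A, bin_size = bin_size, anchor = anchor),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d x %d bins of %g bp (A = %s)\n",
              nrow(x$P), ncol(x$P), x$bin_size, format(x$A)))
  invisible(x)
}

#' @export
dim.contact_map <- function(x) dim(x$P)

#' Contact probabilities from mean squared distances
#'
#' Applies the Gaussian contact formula \eqn{P_{mn} = A D_{mn}^{-3/2}} to
#' the off-diagonal of a distance matrix. With `A = NULL` (default), `A` is
#' chosen so the mean nearest-neighbour contact probability is 1, after
#' which `P` is clipped to at most 1. The diagonal is set to the maximum
#' off-diagonal value (Hi-C diagonals are uninformative and excluded from
#' comparisons).
#'
#' @param D distance matrix with strictly positive off-diagonal entries (or
#'   an `sca_result`).
#' @param A fixed numeric constant, or `NULL` for nearest-neighbour
#'   normalisation.
#' @param bin_size,anchor metadata stored in the map.
#' @return a [contact_map()].
#' @export
contact_probability <- function(D, A = NULL, bin_size = 10000,
                                anchor = NULL) {
  if (inherits(D, "sca_result")) D <- D$D
  D <- as.matrix(D)
  N <- nrow(D)
  off <- row(D) != col(D)
  if (any(D[off] <= 0)) stop("off-diagonal distances must be positive")
  P <- matrix(0, N, N)
  P[off] <- D[off]^(-1.5)
  normalize <- is.null(A)
  if (normalize) {
    nn <- cbind(seq_len(N - 1), 2:N)
    A <- 1 / mean(P[nn])
  }
  P <- A * P
  if (normalize) P[P > 1] <- 1
  diag(P) <- if (N > 1) max(P[off]) else 1
  contact_map(P, A = A, bin_size = bin_size, anchor = anchor)
}

# Matrix view of a contact map or plain matrix.
cm_matrix <- function(x) if (inherits(x, "contact_map")) x$P else as.matrix(x)

#' Compare two contact maps
#'
#' Spearman and Pearson correlations of log-transformed contact frequencies
#' over entries that are positive in both maps and separated by at least
#' `min_separation` bins, plus per-separation-stratum correlations. Zeros
#' (when present among the compared entries) are handled through a
#' pseudocount equal to the smallest positive entry.
#'
#' @param P_model,P_ref [contact_map()]s or plain matrices of equal shape.
#' @param min_separation minimal bin separation included (>= 1).
#' @param n_strata number of separation strata for the stratified report.
#' @return `list(pearson_log, spearman, n_pairs, strata)` where `strata` is
#'   a data.frame with one row per separation stratum.
#' @export
compare_maps <- function(P_model, P_ref, min_separation = 1, n_strata = 4) {
  A <- cm_matrix(P_model)
  B <- cm_matrix(P_ref)
  if (!all(dim(A) == dim(B))) stop("contact maps differ in shape")
  if (min_separation < 1) stop("min_separation must be >= 1")
  N <- nrow(A)
  sep <- abs(row(A) - col(A))
  use <- sep >= min_separation & A > 0 & B > 0
  if (!any(use)) stop("no comparable entries")
  la <- log(A[use])
  lb <- log(B[use])
  s <- sep[use]
  strata_breaks <- unique(round(exp(seq(log(min_separation),
                                        log(max(s) + 1),
                                        length.out = n_strata + 1))))
  stratum <- cut(s, breaks = c(strata_breaks[-length(strata_breaks)] - 0.5,
                               max(s) + 0.5), labels = FALSE)
  strata <- do.call(rbind, lapply(unique(stratum[!is.na(stratum)]), function(k) {
    i <- which(stratum == k)
    data.frame(stratum = k,
               min_sep = min(s[i]), max_sep = max(s[i]),
               n = length(i),
               pearson_log = if (length(i) > 2 && sd(la[i]) > 0 &&
                                 sd(lb[i]) > 0)
                 cor(la[i], lb[i]) else NA_real_,
               spearman = if (length(i) > 2)
                 suppressWarnings(cor(la[i], lb[i], method = "spearman"))
               else NA_real_)
  }))
  list(pearson_log = cor(la, lb),
       spearman = suppressWarnings(cor(la, lb, method = "spearman")),
       n_pairs = sum(use),
       strata = strata[order(strata$stratum), ])
}

#' Read / write contact maps
#'
#' Dense format: whitespace-delimited matrix preceded by a one-line header
#' (`N`, `bin_size`, `A`, optional anchor). Pairs format: three columns
#' `bin_i bin_j count` with 0-based bins; the matrix is symmetrised on read.
#'
#' @param path file path.
#' @param format `"dense"` or `"pairs"`.
#' @return [read_map()] returns a [contact_map()]; [write_map()] the path.
#' @export
read_map <- function(path, format = c("dense", "pairs")) {
  format <- match.arg(format)
  if (file.size(path) == 0) stop("empty contact-map file")
  if (format == "dense") {
    header <- readLines(path, n = 1)
    skip <- 0L
    bin_size <- 10000
    A <- NA_real_
    anchor <- NULL
    if (grepl("^#", header)) {
      skip <- 1L
      if (grepl("bin_size=", header))
        bin_size <- as.numeric(sub(".*bin_size=([0-9.eE+-]+).*", "\\1",
                                   header))
      if (grepl("A=", header)) {
        a_str <- sub(".*A=([^ ]+).*", "\\1", header)
        A <- suppressWarnings(as.numeric(a_str))
      }
      if (grepl("anchor=", header)) {
        a <- sub(".*anchor=([^ ]+).*", "\\1", header)
        parts <- strsplit(a, ":")[[1]]
        if (length(parts) == 2)
          anchor <- list(chrom = parts[1], start = as.numeric(parts[2]))
      }
    }
    lines <- readLines(path)
    if (skip > 0) lines <- lines[-seq_len(skip)]
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty contact-map file")
    rows <- strsplit(trimws(lines), "\\s+")
    nc <- vapply(rows, length, 1L)
    if (length(unique(nc)) != 1L) stop("ragged dense contact-map rows")
    P <- do.call(rbind, lapply(rows, as.numeric))
    if (any(is.na(P))) stop("non-numeric entries in dense contact map")
    if (any(P < 0)) stop("negative counts in contact map")
    return(contact_map(P, A = A, bin_size = bin_size, anchor = anchor))
  }
  df <- read.table(path)
  if (ncol(df) != 3L) stop("pairs format needs 3 columns: i j count")
  if (any(df[[3]] < 0)) stop("negative counts in contact map")
  N <- max(df[[1]], df[[2]]) + 1L
  P <- matrix(0, N, N)
  for (r in seq_len(nrow(df))) {
    i <- df[[1]][r] + 1L
    j <- df[[2]][r] + 1L
    P[i, j] <- df[[3]][r]
    P[j, i] <- df[[3]][r]
  }
  contact_map(P)
}

#' @rdname read_map
#' @param map a [contact_map()] (or plain matrix).
#' @export
write_map <- function(map, path, format = c("dense", "pairs")) {
  format <- match.arg(format)
  if (!inherits(map, "contact_map")) map <- contact_map(map)
  if (format == "dense") {
    con <- file(path, "w")
    on.exit(close(con))
    anchor_str <- if (!is.null(map$anchor))
      sprintf(" anchor=%s:%g", map$anchor$chrom, map$anchor$start) else ""
    writeLines(sprintf("# epifold contact-map N=%d bin_size=%g A=%s%s",
                       nrow(map$P), map$bin_size, format(map$A), anchor_str),
               con)
    write.table(map$P, con, row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  idx <- which(upper.tri(map$P, diag = TRUE) & map$P > 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                   count = map$P[idx])
  write.table(df, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
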