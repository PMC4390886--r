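# Oligomer counting with the strand conventions shared by all survey stages.
#
# Conventions: overlapping occurrences count; matches never span contig
# boundaries; a circular contig additionally exposes the wrap-around windows
# (k-1 start positions at its end); N in the genome matches nothing.

# logical match vector for one contig's codes against per-position code sets
# returns starting positions (1-based within the extended contig slice)
.match_starts <- function(codes, sets, n_pos) {
  k <- length(sets)
  if (n_pos <= 0L) return(integer(0))
  ok <- rep(TRUE, n_pos)
  for (j in seq_len(k)) {
    lk <- logical(5L)
    lk[sets[[j]]] <- TRUE
    ok <- ok & lk[codes[j:(j + n_pos - 1L)]]
  }
  which(ok)
}

# per-contig extended code slices and number of valid start positions
.contig_slices <- function(genome, k) {
  out <- vector("list", n_contigs(genome))
  for (i in seq_len(n_contigs(genome))) {
    codes <- contig_codes(genome, i)
    len <- length(codes)
    if (genome$circular[i] && k > 1L && len >= k) {
      codes <- c(codes, codes[seq_len(k - 1L)])
      n_pos <- len
    } else {
      n_pos <- len - k + 1L
    }
    out[[i]] <- list(codes = codes, n_pos = n_pos, len = len)
  }
  out
}

#' Count occurrences of a pattern in a genome
#'
#' Overlapping matches are counted.  Matches never span contig boundaries;
#' for circular contigs the wrap-around windows are included.  With
#' `strand = "both"`, the forward count of the pattern and the forward count
#' of its reverse complement are summed (a palindromic pattern is therefore
#' counted twice, once per strand).
#'
#' @param genome A [genome_seq()] object.
#' @param pattern IUPAC pattern string; `N` in the genome matches nothing.
#' @param strand `"forward"` (default) or `"both"`.
#' @return Integer count.
#' @examples
#' g <- genome_seq("GAATTC")
#' count_occurrences(g, "GAATTC", strand = "both")  # 2, one per strand
#' @export
count_occurrences <- function(genome, pattern, strand = c("forward", "both")) {
  strand <- match.arg(strand)
  pattern <- check_pattern(pattern)
  stopifnot(inherits(genome, "GenomeSeq"))
  k <- nchar(pattern)
  if (k > max(genome$contig_bounds[, 2] - genome$contig_bounds[, 1])) {
    stop("pattern is longer than every contig", call. = FALSE)
  }
  fwd <- .count_forward(genome, pattern)
  if (strand == "forward") return(fwd)
  fwd + .count_forward(genome, reverse_complement(pattern))
}

.count_forward <- function(genome, pattern) {
  sets <- pattern_sets(pattern)
  slices <- .contig_slices(genome, length(sets))
  sum(vapply(slices, function(s) {
    length(.match_starts(s$codes, sets, s$n_pos))
  }, 1L))
}

# forward-strand match start positions, per contig (1-based within contig;
# circular contigs may report starts in (len-k, len] covering the wrap)
.match_positions <- function(genome, pattern) {
  sets <- pattern_sets(check_pattern(pattern))
  slices <- .contig_slices(genome, length(sets))
  lapply(slices, function(s) .match_starts(s$codes, sets, s$n_pos))
}

#' Strand-collapsed count
#'
#' A palindromic pattern represents both strands already, so its forward
#' count is returned.  A non-palindromic pattern represents itself and its
#' reverse complement, and the two forward counts are averaged, so that
#' palindromic and non-palindromic oligomers are reported on the same scale.
#'
#' @inheritParams count_occurrences
#' @return Numeric (possibly half-integral) count.
#' @export
strand_collapsed_count <- function(genome, pattern) {
  pattern <- check_pattern(pattern)
  if (is_palindromic(pattern)) {
    as.numeric(count_occurrences(genome, pattern, "forward"))
  } else {
    (count_occurrences(genome, pattern, "forward") +
       count_occurrences(genome, reverse_complement(pattern), "forward")) / 2
  }
}

#' Strand-collapsed count per million nucleotides
#'
#' @inheritParams count_occurrences
#' @return `strand_collapsed_count * 1e6 / length`.
#' @export
count_per_million <- function(genome, pattern) {
  stopifnot(inherits(genome, "GenomeSeq"))
  if (genome$length <= 0L) stop("zero-length genome", call. = FALSE)
  strand_collapsed_count(genome, pattern) * 1e6 / genome$length
}

## ---- all-k-mer tabulation -------------------------------------------------

# forward counts of all 4^k concrete k-mers, in lexicographic (A<C<G<T) index
# order; windows containing N are skipped; circular wrap included.
kmer_counts <- function(genome, k) {
  stopifnot(k >= 1L, k <= 12L)
  nbin <- 4L^k
  total <- numeric(nbin)
  for (s in .contig_slices(genome, k)) {
    if (s$n_pos <= 0L) next
    codes <- s$codes
    bad <- codes == 5L
    d <- as.numeric(codes - 1L)
    idx <- numeric(s$n_pos)
    anybad <- rep(FALSE, s$n_pos)
    for (j in seq_len(k)) {
      sel <- j:(j + s$n_pos - 1L)
      idx <- idx * 4 + d[sel]
      anybad <- anybad | bad[sel]
    }
    keep <- idx[!anybad]
    if (length(keep)) total <- total + tabulate(keep + 1, nbins = nbin)
  }
  total
}

# index (0-based) of the reverse complement of each k-mer index 0..4^k-1
rc_index_perm <- function(k) {
  idx <- 0:(4^k - 1)
  rc <- numeric(length(idx))
  rem <- idx
  for (j in seq_len(k)) {          # peel digits from the right
    digit <- rem %% 4
    rem <- rem %/% 4
    rc <- rc * 4 + (3 - digit)     # complement; building left-to-right
  }
  as.integer(rc)
}

# decode 0-based k-mer indices into strings
kmer_string <- function(idx, k) {
  out <- matrix("", nrow = length(idx), ncol = k)
  rem <- idx
  for (j in k:1) {
    out[, j] <- .BASES[rem %% 4 + 1]
    rem <- rem %/% 4
  }
  apply(out, 1L, paste0, collapse = "")
}

# number of G+C bases in each k-mer index 0..4^k-1
kmer_gc_count <- function(k) {
  idx <- 0:(4^k - 1)
  s <- numeric(length(idx))
  rem <- idx
  for (j in seq_len(k)) {
    digit <- rem %% 4
    rem <- rem %/% 4
    s <- s + (digit == 1 | digit == 2)   # C=1, G=2 in 0-based coding
  }
  s
}
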