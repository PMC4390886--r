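# Seeded synthetic-genome generators.  Every generator returns the
# ground-truth bookkeeping (planted positions, counts, fractions) so that
# downstream statistics can be checked against known answers.  Background
# occurrences of planted patterns are counted, not masked, and reported.

#' Generate a random genome
#'
#' I.i.d. bases with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1-gc)/2`.
#'
#' @param length Genome length in nucleotides.
#' @param gc Target GC fraction.
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @param name Genome name.
#' @param circular Circularity flag.
#' @return A [genome_seq()] object.
#' @export
generate_genome <- function(length, gc = 0.5, seed = NULL,
                            name = "synthetic", circular = FALSE) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  if (!is.null(seed)) set.seed(seed)
  p_s <- gc / 2
  p_w <- (1 - gc) / 2
  codes <- sample.int(4L, length, replace = TRUE,
                      prob = c(p_w, p_s, p_s, p_w))
  genome_seq(paste0(.BASES[codes], collapse = ""), name = name,
             circular = circular)
}

# write a concrete oligomer into the genome codes at 1-based start
.write_word <- function(codes, word, start) {
  w <- match(strsplit(word, "")[[1]], .BASES)
  codes[start:(start + length(w) - 1L)] <- w
  codes
}

.rebuild_genome <- function(genome, codes) {
  genome_seq(paste0(.BASES[codes], collapse = ""), name = genome$name,
             circular = genome$circular[1])
}

#' Plant copies of a pattern into a genome
#'
#' Writes exactly `count` non-overlapping copies at spaced random
#' positions (overwriting the background).  The returned bookkeeping
#' separates the planted copies from background occurrences so total
#' counts are known exactly.
#'
#' @param genome A [genome_seq()] object (single contig).
#' @param pattern Concrete oligomer to plant.
#' @param count Number of copies.
#' @param min_spacing Minimum number of nucleotides between planted copies.
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @return A list with `genome` (modified), `positions` (1-based starts),
#'   `n_planted`, `total_forward` (forward-strand occurrences in the
#'   modified genome), `total_collapsed`, and `background` (total minus
#'   planted, on the collapsed scale).
#' @export
plant_pattern <- function(genome, pattern, count, min_spacing = 10L,
                          seed = NULL) {
  stopifnot(inherits(genome, "GenomeSeq"), n_contigs(genome) == 1L)
  pattern <- check_pattern(pattern)
  if (pattern_degeneracy(pattern) > 1L) {
    stop("planted pattern must be concrete", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  k <- nchar(pattern)
  if (count > 0) {
    starts <- .spaced_starts(genome$length, count, k, min_spacing)
    if (is.null(starts)) {
      stop("cannot place ", count, " copies of a ", k,
           "-mer with spacing ", min_spacing, " in ", genome$length, " nt",
           call. = FALSE)
    }
    codes <- genome$codes
    for (s in starts) codes <- .write_word(codes, pattern, s)
    genome <- .rebuild_genome(genome, codes)
  } else {
    starts <- integer(0)
  }
  fwd <- count_occurrences(genome, pattern, "forward")
  coll <- strand_collapsed_count(genome, pattern)
  list(genome = genome, positions = starts, n_planted = length(starts),
       total_forward = fwd, total_collapsed = coll,
       background = coll - length(starts))
}

#' Plant a core oligomer with a palindromic flanking-extension mixture
#'
#' Of `count` planted cores, a fraction receive the extension base on the
#' left and its complement on the right (`x.core.comp(x)`); the remainder
#' receive random flanks whose right base is NOT the complement of the
#' left base, so they extend no palindrome.
#'
#' @param genome A [genome_seq()] object (single contig).
#' @param core Concrete core oligomer.
#' @param ext_base Extension base (`A/C/G/T`).
#' @param fraction Fraction of cores carrying the extension, in `[0, 1]`.
#' @param count Number of planted cores.
#' @param min_spacing Minimum spacing between planted blocks.
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @return A list with `genome`, `core_positions` (starts of the core
#'   itself), `n_extended`, `n_planted`, and `true_fraction`
#'   (`n_extended / n_planted`).
#' @export
plant_extension_mixture <- function(genome, core, ext_base, fraction, count,
                                    min_spacing = 10L, seed = NULL) {
  stopifnot(inherits(genome, "GenomeSeq"), n_contigs(genome) == 1L,
            fraction >= 0, fraction <= 1, count > 0,
            ext_base %in% .BASES)
  core <- check_pattern(core)
  if (!is.null(seed)) set.seed(seed)
  k <- nchar(core)
  width <- k + 2L
  starts <- .spaced_starts(genome$length, count, width, min_spacing)
  if (is.null(starts)) stop("cannot place extension mixture", call. = FALSE)
  n_ext <- round(fraction * count)
  is_ext <- rep(FALSE, count)
  if (n_ext > 0) is_ext[sample.int(count, n_ext)] <- TRUE
  codes <- genome$codes
  for (i in seq_len(count)) {
    s <- starts[i]
    if (is_ext[i]) {
      block <- paste0(ext_base, core, complement_base(ext_base))
    } else {
      l <- sample(.BASES, 1L)
      r <- sample(setdiff(.BASES, complement_base(l)), 1L)
      block <- paste0(l, core, r)
    }
    codes <- .write_word(codes, block, s)
  }
  genome <- .rebuild_genome(genome, codes)
  list(genome = genome, core_positions = starts + 1L, n_extended = n_ext,
       n_planted = count, true_fraction = n_ext / count)
}

#' Plant exact and one-off copies of a consensus with a given spectrum
#'
#' Plants `total` spaced copies of the consensus of which some are one-off
#' deviants, chosen so that [deviation_profile()] (strand-collapsed)
#' recovers the requested per-position fractions.  Because collapsed
#' counting averages position `i` with its palindromic partner
#' `m + 1 - i`, the spectrum should be symmetric (`f[i] = f[m+1-i]`); an
#' asymmetric request is recovered as the symmetrized profile.
#'
#' For a requested fraction `f_i`, the number of planted deviants solves
#' `n_i / (E + n_i) = f_i` where `E` is the number of exact copies, i.e.
#' `n_i = E f_i / (1 - f_i)` with `E = total / (1 + sum_i f_i/(1-f_i))`.
#'
#' @param genome A [genome_seq()] object (single contig).
#' @param consensus Concrete oligomer.
#' @param spectrum Numeric vector of per-position deviation fractions, one
#'   per consensus position, each in `[0, 1)`.
#' @param total Total number of planted copies (exact plus deviant).
#' @param min_spacing Minimum spacing between planted copies.
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @return A list with `genome`, `n_exact`, `n_deviant` (per position),
#'   and `expected_fraction` (the collapsed-profile fractions implied by
#'   the integer bookkeeping, before background noise).
#' @export
plant_deviants <- function(genome, consensus, spectrum, total,
                           min_spacing = 12L, seed = NULL) {
  stopifnot(inherits(genome, "GenomeSeq"), n_contigs(genome) == 1L)
  consensus <- check_pattern(consensus)
  m <- nchar(consensus)
  stopifnot(length(spectrum) == m, all(spectrum >= 0), all(spectrum < 1),
            total > 0)
  if (!is.null(seed)) set.seed(seed)
  a <- spectrum / (1 - spectrum)
  n_exact <- round(total / (1 + sum(a)))
  n_dev <- round(a * n_exact)
  n_total <- n_exact + sum(n_dev)
  starts <- .spaced_starts(genome$length, n_total, m, min_spacing)
  if (is.null(starts)) stop("cannot place deviant spectrum", call. = FALSE)
  words <- rep(consensus, n_total)
  slot <- n_exact
  cons_letters <- strsplit(consensus, "")[[1]]
  for (i in seq_len(m)) {
    if (n_dev[i] == 0) next
    for (j in seq_len(n_dev[i])) {
      slot <- slot + 1L
      w <- cons_letters
      w[i] <- sample(setdiff(.BASES, cons_letters[i]), 1L)
      words[slot] <- paste0(w, collapse = "")
    }
  }
  # planting order is randomized so deviants are not spatially clustered
  ord <- sample.int(n_total)
  codes <- genome$codes
  for (i in seq_len(n_total)) {
    codes <- .write_word(codes, words[ord[i]], starts[i])
  }
  genome <- .rebuild_genome(genome, codes)
  half <- (n_dev + rev(n_dev)) / 2
  list(genome = genome, n_exact = n_exact, n_deviant = n_dev,
       expected_fraction = half / (n_exact + half))
}
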