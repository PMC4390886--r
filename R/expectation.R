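# Expected oligomer counts under composition and Markov null models,
# O/E ratios, the binomial deviation (shade) scale and filtered counts.

#' Shade scale constants
#'
#' The deviation score of an oligomer is the base-10 log of the ratio
#' between the binomial probability of the expected count and that of the
#' observed count.  Scores at or above `extreme` map to the most deviant
#' shade (+/-1), scores at `least` to the least deviant shade (0 boundary),
#' and `filter` is the pass threshold for filtered counts.
#'
#' @param extreme Score mapped to shade +/-1 (default 8000).
#' @param least Score at the no-shade boundary (default 100).
#' @param filter Score threshold for [filtered_count()] (default 1000).
#' @return A list of class `shade_scale`.
#' @export
shade_scale <- function(extreme = 8000, least = 100, filter = 1000) {
  stopifnot(extreme > least, least > 0)
  structure(list(extreme = extreme, least = least, filter = filter),
            class = "shade_scale")
}

#' Expected count under the nucleotide-composition (order-0) model
#'
#' For a concrete oligomer with G+C count `s` and A+T count `w`, the
#' expected number of occurrences per strand is
#' `length * (gc/2)^s * (0.5 - gc/2)^w`.  Degenerate patterns sum over
#' their expansions.
#'
#' @param length Genome length in nucleotides.
#' @param gc Genome GC fraction in `[0, 1]`.
#' @param pattern IUPAC pattern string.
#' @return Expected count (single-strand scale; the formula is
#'   strand-symmetric, so it also serves as the expectation of the
#'   strand-collapsed count).
#' @examples
#' expected_count_order0(1e6, 0.5, "GCGATCGC")  # 15.2587890625
#' @export
expected_count_order0 <- function(length, gc, pattern) {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  pattern <- check_pattern(pattern)
  p_s <- gc / 2
  p_w <- 0.5 - gc / 2
  sets <- pattern_sets(pattern)
  # per-position sum of base probabilities, multiplied across positions,
  # equals the sum over all expansions of their products
  prob <- 1
  base_p <- c(p_w, p_s, p_s, p_w)   # A, C, G, T
  for (s in sets) prob <- prob * sum(base_p[s])
  length * prob
}

## ---- Markov models --------------------------------------------------------

# strand-collapsed count tables of all m-mers, as used by the Markov
# estimator (mean of a word's and its reverse complement's forward counts)
markov_tables <- function(genome, order) {
  stopifnot(order %in% c(1L, 2L))
  tabs <- list()
  for (m in c(order, order + 1L)) {
    cnt <- kmer_counts(genome, m)
    cnt <- (cnt + cnt[rc_index_perm(m) + 1]) / 2
    tabs[[as.character(m)]] <- cnt
  }
  tabs
}

# 0-based index of a concrete oligomer string
.word_index <- function(word) {
  d <- match(strsplit(word, "")[[1]], .BASES) - 1L
  sum(d * 4^(rev(seq_along(d)) - 1))
}

#' Expected count under a Markov null model
#'
#' For a concrete k-mer `w` and order `m`, the standard sub-word
#' count-ratio estimator is used:
#' `E(w) = prod_j N(w[j..j+m]) / prod_j N(w[j..j+m-1])`,
#' where the numerator runs over all `(m+1)`-mer sub-words and the
#' denominator over the interior `m`-mer sub-words, and `N` are the
#' genome's strand-collapsed observed counts.  Degenerate patterns sum
#' over their expansions.
#'
#' @param genome A [genome_seq()] object.
#' @param pattern IUPAC pattern string of length greater than `order`.
#' @param order Markov order, 1 or 2.
#' @param tables Optional precomputed [markov_tables()] (for repeated calls).
#' @return Expected count, or `NA` if a required sub-word count is zero.
#' @export
expected_count_markov <- function(genome, pattern, order = 1L,
                                  tables = NULL) {
  pattern <- check_pattern(pattern)
  order <- as.integer(order)
  stopifnot(order %in% c(1L, 2L))
  k <- nchar(pattern)
  if (k <= order) stop("pattern must be longer than the Markov order",
                       call. = FALSE)
  if (is.null(tables)) tables <- markov_tables(genome, order)
  num_tab <- tables[[as.character(order + 1L)]]
  den_tab <- tables[[as.character(order)]]
  total <- 0
  for (w in expand_pattern(pattern)) {
    e <- .markov_expected_word(w, order, num_tab, den_tab)
    if (is.na(e)) return(NA_real_)
    total <- total + e
  }
  total
}

.markov_expected_word <- function(word, m, num_tab, den_tab) {
  k <- nchar(word)
  num <- 1
  for (j in 1:(k - m)) {
    num <- num * num_tab[.word_index(substr(word, j, j + m)) + 1]
  }
  den <- 1
  if (k - m >= 2) {
    for (j in 2:(k - m)) {
      den <- den * den_tab[.word_index(substr(word, j, j + m - 1)) + 1]
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# vectorized Markov expectations for all 4^k k-mers (0-based index order);
# used by the survey module.  Returns NA where a denominator count is zero.
expected_all_kmers_markov <- function(genome, k, order) {
  tabs <- markov_tables(genome, order)
  num_tab <- tabs[[as.character(order + 1L)]]
  den_tab <- tabs[[as.character(order)]]
  idx <- 0:(4^k - 1)
  sub_idx <- function(j, l) {
    # 0-based index of the length-l sub-word starting at position j (1-based)
    (idx %/% 4^(k - j - l + 1)) %% 4^l
  }
  log_e <- numeric(length(idx))
  ok <- rep(TRUE, length(idx))
  for (j in 1:(k - order)) {
    v <- num_tab[sub_idx(j, order + 1L) + 1]
    ok <- ok & v > 0
    log_e <- log_e + log(ifelse(v > 0, v, 1))
  }
  if (k - order >= 2) {
    for (j in 2:(k - order)) {
      v <- den_tab[sub_idx(j, order) + 1]
      ok <- ok & v > 0
      log_e <- log_e - log(ifelse(v > 0, v, 1))
    }
  }
  out <- exp(log_e)
  out[!ok] <- NA_real_
  out
}

## ---- O/E, deviation score, shades -----------------------------------------

#' Observed/expected ratio
#'
#' @param observed Observed (possibly strand-collapsed) count.
#' @param expected Expected count under a null model.
#' @return `observed / expected`; `NA` when the expectation is not positive
#'   or missing.
#' @export
oe_ratio <- function(observed, expected) {
  ifelse(!is.na(expected) & expected > 0, observed / expected, NA_real_)
}

# continuous-interpolation log (base e) binomial pmf at real-valued x
.log_binom_pmf <- function(x, n, p) {
  lgamma(n + 1) - lgamma(x + 1) - lgamma(n - x + 1) +
    x * log(p) + (n - x) * log1p(-p)
}

#' Binomial deviation score
#'
#' Magnitude of the base-10 log ratio between the binomial probability of
#' the expected count and that of the observed count, with `n = length` and
#' `p = c_exp / length`.  The pmf is evaluated at real-valued counts via
#' log-gamma continuous interpolation (the expected count is rarely an
#' integer).  The score is 0 when observed equals expected and grows with
#' the deviation; the direction of the deviation (enriched or depleted) is
#' carried separately by [shade_category()].
#'
#' @param c_obs Observed count (>= 0).
#' @param c_exp Expected count (> 0).
#' @param length Genome length (number of binomial trials).
#' @return Non-negative deviation score (vectorized).
#' @export
deviation_score <- function(c_obs, c_exp, length) {
  if (any(c_obs < 0)) stop("observed count must be non-negative",
                           call. = FALSE)
  stopifnot(all(c_exp > 0), all(length > 0))
  p <- c_exp / length
  (.log_binom_pmf(c_exp, length, p) -
     .log_binom_pmf(c_obs, length, p)) / log(10)
}

#' Shade category on a [-1, 1] scale
#'
#' Linear interpolation of the deviation score between the least-deviant
#' and most-deviant anchors of the shade scale, signed by the direction of
#' the deviation: positive (red) when observed exceeds expected, negative
#' (green) when below.  Scores below the least-deviant anchor yield 0.
#'
#' @inheritParams deviation_score
#' @param scale A [shade_scale()].
#' @return Numeric in `[-1, 1]` (vectorized).
#' @export
shade_category <- function(c_obs, c_exp, length, scale = shade_scale()) {
  d <- deviation_score(c_obs, c_exp, length)
  mag <- pmin(pmax((d - scale$least) / (scale$extreme - scale$least), 0), 1)
  sign(c_obs - c_exp) * mag
}

#' Filtered normalized count
#'
#' The strand-collapsed count per million nucleotides, let through only when
#' the oligomer is enriched and its deviation score reaches the filter
#' threshold; otherwise 0.  This suppresses noise so that only strongly
#' overrepresented oligomers register.
#'
#' @param genome A [genome_seq()] object.
#' @param pattern IUPAC pattern string.
#' @param scale A [shade_scale()]; its `filter` component is the threshold.
#' @return Count per million, or 0 if the pattern does not pass the filter.
#' @export
filtered_count <- function(genome, pattern, scale = shade_scale()) {
  obs <- strand_collapsed_count(genome, pattern)
  exp0 <- expected_count_order0(genome$length, genome$gc_fraction, pattern)
  if (exp0 <= 0) return(0)
  if (obs > exp0 && deviation_score(obs, exp0, genome$length) >= scale$filter) {
    obs * 1e6 / genome$length
  } else {
    0
  }
}
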