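# Per-genome survey tables: top oligomers, HIP1 summary, palindrome-class
# scans, and O/E with the contribution of an enclosing repeat subtracted.

#' Most overrepresented k-mers of a genome
#'
#' All `4^k` concrete k-mers are counted (overlaps included, both strands
#' via the strand-collapsed convention: reverse-complement pairs are merged
#' into one entry whose count is the mean of the two forward counts, while
#' palindromes stand alone), ranked, and the top `n` returned.
#'
#' @param genome A [genome_seq()] object.
#' @param k Oligomer length (4..12).
#' @param n Number of entries to return (all if fewer exist).
#' @param rank_by `"oe"` (observed/expected, default) or `"count_per_M"`.
#' @param model Null model for expectations: `"order0"`, `"markov1"` or
#'   `"markov2"`.
#' @param reference Optional reference oligomer (default HIP1, `GCGATCGC`);
#'   each entry is annotated with whether it overlaps or is contained in it.
#' @param scale [shade_scale()] used for the `shade` column.
#' @return A `data.frame` with columns `pattern`, `count_raw` (forward
#'   count of the displayed pattern), `count_collapsed`, `count_per_M`,
#'   `expected`, `oe`, `is_palindromic`, `within_reference`, `shade`,
#'   sorted descending by the ranking statistic (ties broken
#'   lexicographically on the alphabetically smaller member of the pair).
#' @export
top_oligomers <- function(genome, k = 8L, n = 12L,
                          rank_by = c("oe", "count_per_M"),
                          model = c("order0", "markov1", "markov2"),
                          reference = "GCGATCGC",
                          scale = shade_scale()) {
  rank_by <- match.arg(rank_by)
  model <- match.arg(model)
  stopifnot(inherits(genome, "GenomeSeq"), k >= 4L, k <= 12L)
  k <- as.integer(k)

  cnt <- kmer_counts(genome, k)
  rc <- rc_index_perm(k)
  idx <- 0:(4^k - 1)
  collapsed <- (cnt + cnt[rc + 1]) / 2
  expected <- .expected_all(genome, k, model)
  keep <- idx <= rc                      # canonical member of each RC pair
  idx <- idx[keep]
  df <- data.frame(
    pattern = kmer_string(idx, k),
    count_raw = as.integer(cnt[keep]),
    count_collapsed = collapsed[keep],
    count_per_M = collapsed[keep] * 1e6 / genome$length,
    expected = expected[keep],
    oe = oe_ratio(collapsed[keep], expected[keep]),
    is_palindromic = idx == rc[keep],
    stringsAsFactors = FALSE
  )
  stat <- if (rank_by == "oe") df$oe else df$count_per_M
  ord <- order(-stat, df$pattern, na.last = TRUE)
  df <- df[ord, , drop = FALSE]
  n <- min(n, nrow(df))
  df <- df[seq_len(n), , drop = FALSE]
  df$within_reference <- if (is.null(reference)) NA else
    vapply(df$pattern, overlaps_reference, TRUE, reference = reference)
  df$shade <- shade_category(df$count_collapsed, df$expected,
                             genome$length, scale)
  rownames(df) <- NULL
  attr(df, "model") <- model
  df
}

.expected_all <- function(genome, k, model) {
  if (model == "order0") {
    s <- kmer_gc_count(k)
    gc <- genome$gc_fraction
    genome$length * (gc / 2)^s * (0.5 - gc / 2)^(k - s)
  } else {
    expected_all_kmers_markov(genome, k,
                              order = if (model == "markov1") 1L else 2L)
  }
}

#' Does an oligomer overlap or lie within a reference oligomer?
#'
#' True when the pattern (or its reverse complement) can be aligned to the
#' reference at some offset such that every overlapping position matches
#' and the overlap is at least `min_overlap` long.  This captures both
#' containment and the staggered overlaps seen among the top 8-mers of
#' HIP1-rich genomes.
#'
#' @param pattern,reference Concrete oligomer strings.
#' @param min_overlap Minimum number of aligned matching positions.
#' @return Logical.
#' @export
overlaps_reference <- function(pattern, reference, min_overlap = 4L) {
  ref <- strsplit(toupper(reference), "")[[1]]
  for (p in unique(c(toupper(pattern), reverse_complement(pattern)))) {
    pl <- strsplit(p, "")[[1]]
    kp <- length(pl); kr <- length(ref)
    for (off in (-(kp - 1L)):(kr - 1L)) {
      lo <- max(0L, off); hi <- min(kr, off + kp)
      if (hi - lo < min_overlap) next
      if (all(ref[(lo + 1L):hi] == pl[(lo - off + 1L):(hi - off)])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' HIP1 summary for one genome
#'
#' Reports the strand-collapsed HIP1 (`GCGATCGC`) count per million and its
#' O/E ratio under the composition and Markov order 1/2 models, together
#' with the genome's most overrepresented 8-mer when that differs from
#' HIP1 (as in per-genome anomaly tables: the top 8-mer is reported only
#' when it is not HIP1 itself).
#'
#' @param genome A [genome_seq()] object.
#' @return A list with elements `hip1_count_per_M`, `hip1_oe_order0`,
#'   `hip1_oe_markov1`, `hip1_oe_markov2`, `top8_pattern`,
#'   `top8_count_per_M`, `top8_oe` (the `top8_*` fields are `NA` when the
#'   top 8-mer is HIP1).
#' @export
hip_summary <- function(genome) {
  hip <- "GCGATCGC"
  obs <- strand_collapsed_count(genome, hip)
  e0 <- expected_count_order0(genome$length, genome$gc_fraction, hip)
  e1 <- expected_count_markov(genome, hip, 1L)
  e2 <- expected_count_markov(genome, hip, 2L)
  top <- top_oligomers(genome, k = 8L, n = 1L, rank_by = "oe",
                       model = "order0", reference = hip)
  is_hip <- top$pattern[1] %in% c(hip, reverse_complement(hip))
  list(
    hip1_count_per_M = obs * 1e6 / genome$length,
    hip1_oe_order0 = oe_ratio(obs, e0),
    hip1_oe_markov1 = oe_ratio(obs, e1),
    hip1_oe_markov2 = oe_ratio(obs, e2),
    top8_pattern = if (is_hip) NA_character_ else top$pattern[1],
    top8_count_per_M = if (is_hip) NA_real_ else top$count_per_M[1],
    top8_oe = if (is_hip) NA_real_ else top$oe[1]
  )
}

## ---- palindrome classes ---------------------------------------------------

# complement of a two-fold IUPAC code
.DEG2 <- c(R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K")

#' Members of a palindrome class
#'
#' Three classes of palindromic oligomers are enumerated:
#' * `palindromic6` - the 64 nondegenerate palindromic 6-mers;
#' * `palindromic5_center_WS` - the 32 palindromic 5-mer patterns whose
#'   central position is the two-fold code `W` (`A/T`) or `S` (`C/G`);
#' * `degenerate_palindromic6` - self-reverse-complementary 6-mer patterns
#'   in which one or two of the three base pairs carry a two-fold
#'   degenerate code from `R Y S W K M` (e.g. `RCCGGY`).
#'
#' @param class Class id.
#' @return Character vector of member patterns.
#' @export
class_members <- function(class = c("palindromic6", "palindromic5_center_WS",
                                    "degenerate_palindromic6")) {
  class <- match.arg(class)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (class == "palindromic6") {
    g <- expand.grid(b3 = .BASES, b2 = .BASES, b1 = .BASES,
                     stringsAsFactors = FALSE)
    return(sort(paste0(g$b1, g$b2, g$b3,
                       comp[g$b3], comp[g$b2], comp[g$b1])))
  }
  if (class == "palindromic5_center_WS") {
    g <- expand.grid(ctr = c("W", "S"), b2 = .BASES, b1 = .BASES,
                     stringsAsFactors = FALSE)
    return(sort(paste0(g$b1, g$b2, g$ctr, comp[g$b2], comp[g$b1])))
  }
  # degenerate_palindromic6: choose, for each of the 3 pairs, a concrete
  # base or a two-fold code; keep patterns with 1 or 2 degenerate pairs
  choices <- c(.BASES, names(.DEG2))
  g <- expand.grid(p3 = choices, p2 = choices, p1 = choices,
                   stringsAsFactors = FALSE)
  ndeg <- (g$p1 %in% names(.DEG2)) + (g$p2 %in% names(.DEG2)) +
    (g$p3 %in% names(.DEG2))
  g <- g[ndeg >= 1 & ndeg <= 2, , drop = FALSE]
  pair_right <- function(p) ifelse(p %in% .BASES, comp[p], .DEG2[p])
  sort(paste0(g$p1, g$p2, g$p3,
              pair_right(g$p3), pair_right(g$p2), pair_right(g$p1)))
}

#' Most overrepresented member of a palindrome class
#'
#' Every member pattern of the class is counted (strand-collapsed; all
#' members are palindromic so the forward count stands) and its O/E ratio
#' computed; the member with the maximal ratio is returned, annotated with
#' whether every one of its expansions lies within HIP1.
#'
#' @param genome A [genome_seq()] object.
#' @param class Class id, see [class_members()].
#' @param model Null model (`"order0"`, `"markov1"`, `"markov2"`).
#' @return List with `pattern`, `observed`, `expected`, `oe` and
#'   `within_hip1` (`TRUE` iff every expansion of the member occurs as a
#'   substring of `GCGATCGC` or its reverse complement).
#' @export
best_in_class <- function(genome, class = c("palindromic6",
                                            "palindromic5_center_WS",
                                            "degenerate_palindromic6"),
                          model = c("order0", "markov1", "markov2")) {
  class <- match.arg(class)
  model <- match.arg(model)
  members <- class_members(class)
  k <- nchar(members[1])
  cnt <- kmer_counts(genome, k)
  e_all <- .expected_all(genome, k, model)
  best <- NULL
  for (pat in members) {
    exp_idx <- vapply(expand_pattern(pat), .word_index, 1) + 1
    obs <- sum(cnt[exp_idx])          # palindromic pattern: forward count
    e <- sum(e_all[exp_idx])
    oe <- oe_ratio(obs, e)
    if (is.na(oe)) next
    if (is.null(best) || oe > best$oe) {
      best <- list(pattern = pat, observed = obs, expected = e, oe = oe)
    }
  }
  if (is.null(best)) stop("no class member has a defined O/E", call. = FALSE)
  best$within_hip1 <- all(vapply(expand_pattern(best$pattern),
                                 .within_string, TRUE, s = "GCGATCGC"))
  best
}

.within_string <- function(word, s) {
  grepl(word, s, fixed = TRUE) ||
    grepl(word, reverse_complement(s), fixed = TRUE)
}

#' O/E ratio of an inner oligomer with an enclosing repeat subtracted
#'
#' The observed strand-collapsed count of `inner` is reduced by the
#' occurrences attributable to the enclosing repeat `hip` (its
#' strand-collapsed count times the multiplicity of `inner` within the
#' `hip` string), floored at zero; the expectation is left unadjusted.
#' This answers, e.g., how over- or underrepresented `GATC` is once the
#' copies inside HIP1 are removed.
#'
#' @param genome A [genome_seq()] object.
#' @param inner IUPAC pattern occurring within `hip`.
#' @param hip Enclosing concrete oligomer (default HIP1).
#' @param model Null model for the expectation of `inner`.
#' @return The adjusted O/E ratio.
#' @export
oe_excluding_hip <- function(genome, inner, hip = "GCGATCGC",
                             model = c("order0", "markov1", "markov2")) {
  model <- match.arg(model)
  inner <- check_pattern(inner)
  hip <- check_pattern(hip)
  mult <- (.count_in_string(inner, hip) +
             .count_in_string(reverse_complement(inner), hip)) / 2
  if (mult == 0) {
    stop("'", inner, "' is not a substring of '", hip, "'", call. = FALSE)
  }
  obs <- strand_collapsed_count(genome, inner) -
    strand_collapsed_count(genome, hip) * mult
  obs <- max(obs, 0)
  e <- switch(model,
    order0 = expected_count_order0(genome$length, genome$gc_fraction, inner),
    markov1 = expected_count_markov(genome, inner, 1L),
    markov2 = expected_count_markov(genome, inner, 2L))
  oe_ratio(obs, e)
}

# overlapping matches of an IUPAC pattern within a short concrete string
.count_in_string <- function(pattern, s) {
  sets <- pattern_sets(pattern)
  codes <- match(strsplit(toupper(s), "")[[1]], .BASES)
  codes[is.na(codes)] <- 5L
  n_pos <- length(codes) - length(sets) + 1L
  if (n_pos <= 0L) return(0L)
  length(.match_starts(c(codes, 5L), sets, n_pos))
}
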