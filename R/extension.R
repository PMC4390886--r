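# Iterative detection of conserved palindromic extensions flanking a core
# oligomer.  At each round the four complementary flank pairs x...comp(x)
# are tried; an extension is kept when enough of the enclosed sequences are
# extended that way (strong: >= 50%; weak: >= 25% and the extension itself
# has O/E > 4 under the composition model).

#' Find conserved palindromic extensions of a core oligomer
#'
#' Starting from the core, each round extends the current sequence `S` by
#' one base on each side, testing the four palindrome-preserving pairs
#' `x.S.comp(x)` and selecting the base `x` maximizing the extension ratio
#' `C(x.S.comp(x)) / C(S)` (counts are strand-collapsed).  The selected
#' extension is tiered:
#' * `strong` when the ratio is at least 0.5;
#' * `weak` when the ratio is at least 0.25 and the O/E ratio of the
#'   extended sequence exceeds 4;
#' * `none` otherwise (search stops).
#' Outer rounds use the previously extended sequence's count as the
#' denominator.  If two bases tie for the maximal ratio, no extension is
#' reported (conservative).  A degenerate core is analysed per
#' reverse-complement class of its expansions, and the reports are merged
#' only when every class agrees on the extension bases and tiers.
#'
#' @param genome A [genome_seq()] object.
#' @param core IUPAC pattern string (concrete in the usual case).
#' @param max_rounds Maximum number of extension rounds (default 4).
#' @param min_count Minimum strand-collapsed core count required (default
#'   20); below it the report carries status `"insufficient occurrences"`.
#' @param weak_min_oe O/E threshold for the weak tier (default 4).
#' @return For a concrete core, an object of class `extension_report`:
#'   a list with `core`, `status`, `rounds` (data.frame with columns
#'   `left`, `right`, `ratio`, `oe_extended`, `tier`), and `encoded` (the
#'   extended sequence with strong extensions in upper case and weak ones
#'   in lower case).  For a degenerate core, a list of such reports (class
#'   `extension_report_set`) with an attribute `merged` saying whether all
#'   expansion classes agreed.
#' @export
find_extensions <- function(genome, core, max_rounds = 4L, min_count = 20,
                            weak_min_oe = 4) {
  core <- check_pattern(core)
  if (pattern_degeneracy(core) > 1L) {
    # group expansions into reverse-complement classes
    exps <- expand_pattern(core)
    seen <- character(0)
    reports <- list()
    for (w in exps) {
      if (w %in% seen) next
      seen <- c(seen, w, reverse_complement(w))
      reports[[length(reports) + 1L]] <-
        find_extensions(genome, w, max_rounds, min_count, weak_min_oe)
    }
    key <- vapply(reports, function(r) {
      paste(r$status, paste(r$rounds$left, r$rounds$tier, collapse = ","))
    }, "")
    out <- structure(reports, class = "extension_report_set",
                     core = core, merged = length(unique(key)) == 1L)
    return(out)
  }

  count_core <- strand_collapsed_count(genome, core)
  rounds <- data.frame(left = character(0), right = character(0),
                       ratio = numeric(0), oe_extended = numeric(0),
                       tier = character(0), stringsAsFactors = FALSE)
  if (count_core < min_count) {
    return(structure(list(core = core, status = "insufficient occurrences",
                          rounds = rounds, encoded = core),
                     class = "extension_report"))
  }

  s <- core
  count_s <- count_core
  left_enc <- character(0)
  right_enc <- character(0)
  for (round in seq_len(max_rounds)) {
    ext <- vapply(.BASES, function(x) {
      paste0(x, s, complement_base(x))
    }, "")
    counts <- vapply(ext, strand_collapsed_count, 1, genome = genome)
    ratios <- counts / count_s
    best <- which(ratios == max(ratios))
    if (length(best) > 1L) break                      # tie: report nothing
    x <- .BASES[best]
    oe_ext <- oe_ratio(counts[best],
                       expected_count_order0(genome$length,
                                             genome$gc_fraction, ext[best]))
    tier <- if (ratios[best] >= 0.5) "strong"
            else if (ratios[best] >= 0.25 && !is.na(oe_ext) &&
                     oe_ext > weak_min_oe) "weak"
            else "none"
    if (tier == "none") break
    rounds <- rbind(rounds, data.frame(
      left = x, right = complement_base(x), ratio = unname(ratios[best]),
      oe_extended = unname(oe_ext), tier = tier, stringsAsFactors = FALSE))
    case <- if (tier == "strong") toupper else tolower
    left_enc <- c(case(x), left_enc)
    right_enc <- c(right_enc, case(complement_base(x)))
    s <- ext[[best]]
    count_s <- counts[[best]]
  }
  structure(list(core = core, status = "ok", rounds = rounds,
                 encoded = paste0(paste0(left_enc, collapse = ""), core,
                                  paste0(right_enc, collapse = ""))),
            class = "extension_report")
}

#' @export
print.extension_report <- function(x, ...) {
  cat(sprintf("Extension report for core %s (%s)\n", x$core, x$status))
  if (nrow(x$rounds)) {
    for (i in seq_len(nrow(x$rounds))) {
      r <- x$rounds[i, ]
      cat(sprintf("  round %d: %s...%s ratio %.3f O/E %.2f [%s]\n",
                  i, r$left, r$right, r$ratio, r$oe_extended, r$tier))
    }
  }
  cat("  encoded:", x$encoded, "\n")
  invisible(x)
}

#' @export
print.extension_report_set <- function(x, ...) {
  cat(sprintf("Extension reports for degenerate core %s (merged: %s)\n",
              attr(x, "core"), attr(x, "merged")))
  for (r in x) print(r)
  invisible(x)
}
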