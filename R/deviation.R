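# Per-position one-off deviation fractions from a consensus oligomer.
#
# The fraction at position i follows the N-substituted pattern formula:
#   f_i = (C(consensus with N at i) - C(consensus)) / C(consensus with N at i)
# so multi-position deviants are counted only at positions where all other
# positions match the consensus.

#' Per-position one-off deviation profile
#'
#' For each position `i` of the consensus, the consensus with `N`
#' substituted at `i` is counted and the fraction of those occurrences that
#' deviate from the consensus is reported.  By default counts are
#' strand-collapsed (the N-substituted pattern of a palindromic consensus
#' is generally non-palindromic, so it is averaged with its reverse
#' complement, which symmetrizes the profile across the palindrome axis);
#' `collapse = FALSE` counts the forward strand only.
#'
#' An optional context rule restricts the statistic to occurrences whose
#' immediate flanking bases satisfy it, e.g. `CGATCG` occurrences not
#' preceded by `G` and not followed by `C`.
#'
#' @param genome A [genome_seq()] object.
#' @param consensus Concrete oligomer (no `N`).
#' @param context Optional flank rule: a list with any of `left_required`,
#'   `left_forbidden`, `right_required`, `right_forbidden`, each a vector
#'   of bases.  A flank beyond a linear contig end satisfies forbidden
#'   rules and fails required ones.
#' @param collapse Use strand-collapsed counts (default `TRUE`).
#' @return A `data.frame` of class `deviation_profile` with columns
#'   `position`, `deviant`, `total`, `fraction` (`NA` when the position's
#'   total is zero), and attributes `consensus` and `context`.
#' @export
deviation_profile <- function(genome, consensus, context = NULL,
                              collapse = TRUE) {
  consensus <- check_pattern(consensus)
  if (grepl("N", consensus, fixed = TRUE)) {
    stop("consensus must not contain N", call. = FALSE)
  }
  if (pattern_degeneracy(consensus) > 1L) {
    stop("consensus must be a concrete oligomer", call. = FALSE)
  }
  if (!is.null(context)) .check_context(context)
  m <- nchar(consensus)
  count_fun <- function(pat) {
    .context_count(genome, pat, context, collapse = collapse)
  }
  c_cons <- count_fun(consensus)
  total <- deviant <- numeric(m)
  for (i in seq_len(m)) {
    pat <- consensus
    substr(pat, i, i) <- "N"
    total[i] <- count_fun(pat)
    deviant[i] <- total[i] - c_cons
  }
  out <- data.frame(position = seq_len(m), deviant = deviant, total = total,
                    fraction = ifelse(total > 0, deviant / total, NA_real_))
  structure(out, class = c("deviation_profile", "data.frame"),
            consensus = consensus, context = context)
}

#' Context-restricted deviation profile
#'
#' Convenience wrapper around [deviation_profile()] for asking, e.g.,
#' whether the bias against deviation from the central bases of a 6-mer
#' persists when the 6-mer is not embedded in a larger repeat (such as
#' `CGATCG` occurrences not flanked by `G`...`C`).
#'
#' @inheritParams deviation_profile
#' @param core Concrete oligomer, typically length 6.
#' @export
context_deviation <- function(genome, core, context, collapse = TRUE) {
  deviation_profile(genome, core, context = context, collapse = collapse)
}

.check_context <- function(context) {
  allowed <- c("left_required", "left_forbidden",
               "right_required", "right_forbidden")
  bad <- setdiff(names(context), allowed)
  if (length(bad)) stop("unknown context field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (side in c("left", "right")) {
    req <- context[[paste0(side, "_required")]]
    forb <- context[[paste0(side, "_forbidden")]]
    if (!is.null(req) && !all(req %in% .BASES))
      stop("context bases must be A/C/G/T", call. = FALSE)
    if (!is.null(forb) && !all(forb %in% .BASES))
      stop("context bases must be A/C/G/T", call. = FALSE)
    if (!is.null(req) && (length(intersect(req, forb)) > 0 ||
                          all(.BASES %in% forb))) {
      stop("contradictory context rule on ", side, " flank", call. = FALSE)
    }
    if (!is.null(forb) && all(.BASES %in% forb) && is.null(req)) {
      stop("contradictory context rule on ", side, " flank", call. = FALSE)
    }
  }
  invisible(context)
}

# count pattern occurrences satisfying a flank context rule; collapse
# averages with the reverse-complement pattern under the mirrored rule
.context_count <- function(genome, pattern, context, collapse = TRUE) {
  if (is.null(context)) {
    return(if (collapse) strand_collapsed_count(genome, pattern)
           else as.numeric(count_occurrences(genome, pattern, "forward")))
  }
  fwd <- .context_count_forward(genome, pattern, context)
  if (!collapse) return(as.numeric(fwd))
  rc_pat <- reverse_complement(pattern)
  comp_set <- function(v) if (is.null(v)) NULL else
    unname(c(A = "T", C = "G", G = "C", T = "A")[v])
  mirrored <- list(left_required = comp_set(context$right_required),
                   left_forbidden = comp_set(context$right_forbidden),
                   right_required = comp_set(context$left_required),
                   right_forbidden = comp_set(context$left_forbidden))
  (fwd + .context_count_forward(genome, rc_pat, mirrored)) / 2
}

.context_count_forward <- function(genome, pattern, context) {
  sets <- pattern_sets(pattern)
  k <- length(sets)
  total <- 0L
  for (i in seq_len(n_contigs(genome))) {
    codes <- contig_codes(genome, i)
    len <- length(codes)
    circ <- genome$circular[i]
    ext <- if (circ && k > 1L && len >= k) c(codes, codes[seq_len(k - 1L)])
           else codes
    n_pos <- if (circ && len >= k) len else len - k + 1L
    starts <- .match_starts(ext, sets, n_pos)
    if (!length(starts)) next
    left_code <- ifelse(starts > 1L, codes[pmax(starts - 1L, 1L)],
                        if (circ) codes[len] else NA_integer_)
    right_pos <- starts + k
    right_code <- ifelse(right_pos <= len, codes[pmin(right_pos, len)],
                         if (circ) codes[(right_pos - 1L) %% len + 1L]
                         else NA_integer_)
    ok <- rep(TRUE, length(starts))
    ok <- ok & .flank_ok(left_code, context$left_required,
                         context$left_forbidden)
    ok <- ok & .flank_ok(right_code, context$right_required,
                         context$right_forbidden)
    total <- total + sum(ok)
  }
  total
}

.flank_ok <- function(code, required, forbidden) {
  ok <- rep(TRUE, length(code))
  if (!is.null(required)) {
    req_codes <- match(required, .BASES)
    ok <- ok & !is.na(code) & code %in% req_codes
  }
  if (!is.null(forbidden)) {
    forb_codes <- match(forbidden, .BASES)
    ok <- ok & (is.na(code) | !(code %in% forb_codes))
  }
  ok
}

#' @export
print.deviation_profile <- function(x, ...) {
  cat(sprintf("Deviation profile of %s%s\n", attr(x, "consensus"),
              if (is.null(attr(x, "context"))) "" else " (context-restricted)"))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
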