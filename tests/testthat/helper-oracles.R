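# Independent oracles used across the suite.  These deliberately share no
# code with the package: counting goes through PCRE lookahead regexes (or a
# plain character loop for small cases), expectations through direct
# arithmetic on oracle-counted sub-words.

.ORACLE_IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
                   R = "AG", Y = "CT", S = "CG", W = "AT",
                   K = "GT", M = "AC", B = "CGT", D = "AGT",
                   H = "ACT", V = "ACG", N = "ACGT")

# overlapping forward-strand matches via PCRE lookahead
oracle_count <- function(seqstr, pattern, circular = FALSE) {
  k <- nchar(pattern)
  if (circular && k > 1L) {
    seqstr <- paste0(seqstr, substr(seqstr, 1L, k - 1L))
  }
  cls <- vapply(strsplit(pattern, "")[[1]], function(l) {
    paste0("[", .ORACLE_IUPAC[[l]], "]")
  }, "")
  rx <- paste0("(?=", paste0(cls, collapse = ""), ")")
  m <- gregexpr(rx, seqstr, perl = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}

# slow position-by-position scan (for spot checks of the regex oracle)
oracle_count_slow <- function(seqstr, pattern, circular = FALSE) {
  k <- nchar(pattern)
  s <- strsplit(seqstr, "")[[1]]
  L <- length(s)
  if (circular && k > 1L) { s <- c(s, s[seq_len(k - 1L)]); npos <- L }
  else npos <- L - k + 1L
  sets <- strsplit(.ORACLE_IUPAC[strsplit(pattern, "")[[1]]], "")
  n <- 0L
  for (i in seq_len(max(npos, 0L))) {
    ok <- TRUE
    for (j in seq_along(sets)) {
      if (!(s[i + j - 1L] %in% sets[[j]])) { ok <- FALSE; break }
    }
    if (ok) n <- n + 1L
  }
  n
}

oracle_rc <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
            S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
            D = "H", H = "D", N = "N")
  paste0(rev(comp[strsplit(pattern, "")[[1]]]), collapse = "")
}

oracle_collapsed <- function(seqstr, pattern, circular = FALSE) {
  rc <- oracle_rc(pattern)
  if (identical(pattern, rc)) {
    oracle_count(seqstr, pattern, circular)
  } else {
    (oracle_count(seqstr, pattern, circular) +
       oracle_count(seqstr, rc, circular)) / 2
  }
}

# Markov expectation from oracle-counted strand-collapsed sub-words
oracle_markov_expected <- function(seqstr, word, order, circular = FALSE) {
  k <- nchar(word)
  num <- 1
  for (j in 1:(k - order)) {
    num <- num * oracle_collapsed(seqstr, substr(word, j, j + order),
                                  circular)
  }
  den <- 1
  if (k - order >= 2) {
    for (j in 2:(k - order)) {
      den <- den * oracle_collapsed(seqstr, substr(word, j, j + order - 1L),
                                    circular)
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# random IUPAC pattern with bounded degeneracy
random_pattern <- function(k, letters = c("A", "C", "G", "T",
                                          "R", "Y", "S", "W")) {
  repeat {
    p <- paste0(sample(letters, k, replace = TRUE), collapse = "")
    if (hipscan::pattern_degeneracy(p) <= 16L) return(p)
  }
}

# all concrete k-mer strings
kmer_string_all <- function(k) {
  apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)), 1, paste0,
        collapse = "")
}

# genome made of a fixed background letter with words written at positions
compose_genome <- function(length, words, starts, background = "A",
                           circular = FALSE) {
  s <- rep(background, length)
  for (i in seq_along(words)) {
    w <- strsplit(words[i], "")[[1]]
    s[starts[i]:(starts[i] + length(w) - 1L)] <- w
  }
  hipscan::genome_seq(paste0(s, collapse = ""), circular = circular)
}
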