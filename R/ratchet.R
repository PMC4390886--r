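# Stochastic simulator of a G-meC-directed mismatch-repair ratchet.
#
# Each generation the genome replicates; replication errors appear on the
# daughter strand and each mismatch is resolved in precedence order:
#   (a) a methylated parental site within the repair radius R directs
#       repair toward the parent: the mutation is LOST;
#   (b) otherwise, if the daughter strand (with the mutation) carries a
#       MTase recognition site whose methylatable C sits in a G-meC
#       context overlapping or adjacent to the mutated position, the MTase
#       methylates it with probability p_meth before the mismatch is
#       resolved: the mutation is FIXED and the new site becomes (and
#       stays) methylated;
#   (c) otherwise the mismatch is resolved at random (fixed w.p. 1/2).
# Rule (a) makes methylated sites effectively immortal and shields their
# neighborhoods, so qualifying sites accumulate until most of the genome
# lies within R of one: the ratchet's set point.

.CODE_G <- 3L
.CODE_C <- 2L

#' Ratchet simulation parameters
#'
#' @param length Genome length in nucleotides.
#' @param gc GC fraction of the starting random genome.
#' @param circular Treat the genome as circular (default `TRUE`, avoiding
#'   edge effects in spacing statistics).
#' @param mu Mutation (replication error) rate per site per generation.
#' @param p_meth Probability that the MTase methylates a qualifying
#'   nascent-strand site before mismatch resolution.
#' @param repair_radius Effective range R (nt) over which a methylated
#'   site directs mismatch repair (default 1000, the distance at which
#'   methylation-directed repair efficiency falls off).
#' @param mtase_pattern MTase recognition oligomer (default `CGATCG`);
#'   must be a concrete palindrome whose first base is the methylated C
#'   (so the G-meC context is a `G` immediately before the site, or
#'   equivalently on the other strand a `C` immediately after it).
#' @param generations Number of generations to simulate.
#' @param seed RNG seed.
#' @param init_site_per_nt Initial density of planted methylated sites.
#' @return A list of class `ratchet_params`.
#' @export
ratchet_params <- function(length = 200000L, gc = 0.5, circular = TRUE,
                           mu = 1e-4, p_meth = 1, repair_radius = 1000L,
                           mtase_pattern = "CGATCG", generations = 20000L,
                           seed = 1L, init_site_per_nt = 1e-4) {
  mtase_pattern <- check_pattern(mtase_pattern)
  stopifnot(mu >= 0, mu <= 1e-2, p_meth >= 0, p_meth <= 1,
            repair_radius >= 1, length >= 4 * nchar(mtase_pattern),
            gc >= 0, gc <= 1, init_site_per_nt >= 0)
  if (pattern_degeneracy(mtase_pattern) > 1L ||
      !is_palindromic(mtase_pattern) ||
      substr(mtase_pattern, 1, 1) != "C") {
    stop("mtase_pattern must be a concrete palindrome starting with C",
         call. = FALSE)
  }
  structure(list(length = as.integer(length), gc = gc, circular = circular,
                 mu = mu, p_meth = p_meth,
                 repair_radius = as.integer(repair_radius),
                 mtase_pattern = mtase_pattern,
                 generations = as.integer(generations),
                 seed = as.integer(seed),
                 init_site_per_nt = init_site_per_nt),
            class = "ratchet_params")
}

# wrap a 1-based position onto 1..L
.wrap <- function(pos, L) (pos - 1L) %% L + 1L

# is there a qualifying (G-meC context) occurrence of the pattern starting
# at position p of `codes`?  Context: G before the site or C after it.
.qualifies <- function(codes, p, pat_codes, L, circular) {
  k <- length(pat_codes)
  idx <- p:(p + k - 1L)
  if (circular) idx <- .wrap(idx, L) else if (p < 1L || p + k - 1L > L)
    return(FALSE)
  if (any(codes[idx] != pat_codes)) return(FALSE)
  before <- if (circular) codes[.wrap(p - 1L, L)]
            else if (p > 1L) codes[p - 1L] else NA_integer_
  after <- if (circular) codes[.wrap(p + k, L)]
           else if (p + k <= L) codes[p + k] else NA_integer_
  isTRUE(before == .CODE_G) || isTRUE(after == .CODE_C)
}

# all qualifying starts within the window of sites overlapping or adjacent
# to position pos (candidate starts pos-k .. pos+1), evaluated on the
# daughter strand, i.e. with `new_base` substituted at pos.  Works on a
# small extracted window so the genome is never copied.
.qualifying_near <- function(codes, pos, new_base, pat_codes, L, circular) {
  k <- length(pat_codes)
  gpos <- (pos - k - 1L):(pos + k + 1L)
  if (circular) {
    w <- codes[.wrap(gpos, L)]
  } else {
    w <- rep(NA_integer_, length(gpos))
    inb <- gpos >= 1L & gpos <= L
    w[inb] <- codes[gpos[inb]]
  }
  w[k + 2L] <- new_base                  # the mutated position
  out <- integer(0)
  for (off in 0:(k + 1L)) {              # genome start s = pos - k + off
    si <- off + 2L                       # window index of that start
    seg <- w[si:(si + k - 1L)]
    if (anyNA(seg) || any(seg != pat_codes)) next
    if (isTRUE(w[si - 1L] == .CODE_G) || isTRUE(w[si + k] == .CODE_C)) {
      out <- c(out, pos - k + off)
    }
  }
  if (circular && length(out)) out <- .wrap(out, L)
  out
}

# vectorized revalidation of the methylated-site registry
.validate_sites <- function(codes, sites, pat_codes, L, circular) {
  if (!length(sites)) return(sites)
  k <- length(pat_codes)
  get_codes <- function(idx) {
    if (circular) return(codes[.wrap(idx, L)])
    out <- rep(NA_integer_, length(idx))
    inb <- idx >= 1L & idx <= L
    out[inb] <- codes[idx[inb]]
    out
  }
  m <- matrix(get_codes(rep(sites, each = k) +
                          rep.int(0:(k - 1L), length(sites))), nrow = k)
  patok <- colSums(m == pat_codes) == k
  patok[is.na(patok)] <- FALSE
  before <- get_codes(sites - 1L)
  after <- get_codes(sites + k)
  ctx <- (!is.na(before) & before == .CODE_G) |
    (!is.na(after) & after == .CODE_C)
  sites[patok & ctx]
}

#' Initialize the ratchet state
#'
#' Generates a seeded random genome at the requested GC fraction and plants
#' `init_site_per_nt * length` spaced recognition sites, each written with
#' a `G` immediately to its left so that it carries the G-meC context; all
#' planted sites start methylated.  Background occurrences of the pattern
#' that arise by chance in the random genome are left unmethylated.
#'
#' @param params A [ratchet_params()] object.
#' @return A list of class `ratchet_state` with fields `codes` (integer
#'   base codes), `sites` (sorted methylated site start positions),
#'   `generation`, and the parameters.
#' @export
init_state <- function(params) {
  stopifnot(inherits(params, "ratchet_params"))
  set.seed(params$seed)
  L <- params$length
  p_s <- params$gc / 2
  p_w <- (1 - params$gc) / 2
  codes <- sample.int(4L, L, replace = TRUE, prob = c(p_w, p_s, p_s, p_w))
  pat_codes <- match(strsplit(params$mtase_pattern, "")[[1]], .BASES)
  k <- length(pat_codes)
  n_init <- round(params$init_site_per_nt * L)
  sites <- integer(0)
  if (n_init > 0) {
    width <- k + 1L                      # G + pattern
    starts <- .spaced_starts(L, n_init, width, min_spacing = 2L * k)
    if (is.null(starts)) {
      stop("requested initial site density cannot be placed without overlap",
           call. = FALSE)
    }
    for (s in starts) {
      codes[s] <- .CODE_G
      codes[(s + 1L):(s + k)] <- pat_codes
    }
    sites <- starts + 1L                 # pattern start positions
  }
  structure(list(codes = codes, sites = sort(sites), generation = 0L,
                 params = params, pat_codes = pat_codes),
            class = "ratchet_state")
}

# sorted spaced start positions for n blocks of `width` nt with at least
# `min_spacing` nt between blocks, within a length-L genome; NULL if the
# blocks do not fit
.spaced_starts <- function(L, n, width, min_spacing = 0L) {
  slack <- L - n * width - (n - 1L) * min_spacing
  if (slack < 0L) return(NULL)
  extra <- sort(sample.int(slack + 1L, n, replace = TRUE)) - 1L
  as.integer((seq_len(n) - 1L) * (width + min_spacing) + extra + 1L)
}

# circular (or linear) distance from pos to the nearest site start;
# sites must be sorted
.nearest_site_dist <- function(sites, pos, L, circular) {
  n <- length(sites)
  if (n == 0L) return(Inf)
  i <- findInterval(pos, sites)
  cand <- c(sites[max(i, 1L)], sites[min(i + 1L, n)])
  if (circular) cand <- c(cand, sites[1], sites[n])
  d <- abs(pos - cand)
  if (circular) d <- pmin(d, L - d)
  min(d)
}

# resolve one mismatch; returns list(outcome, new_sites) where outcome is
# one of "lost_parental", "fixed_methylation", "fixed_random",
# "lost_random".  u_meth and u_fix are the uniform draws used by rules (b)
# and (c); pass explicit values to force outcomes (used by tests).
.resolve_mismatch <- function(codes, sites, pos, new_base, params, pat_codes,
                              u_meth = stats::runif(1),
                              u_fix = stats::runif(1)) {
  L <- params$length
  if (.nearest_site_dist(sites, pos, L, params$circular) <=
      params$repair_radius) {
    return(list(outcome = "lost_parental", new_sites = integer(0)))
  }
  near <- .qualifying_near(codes, pos, new_base, pat_codes, L,
                           params$circular)
  if (length(near) > 0L && u_meth <= params$p_meth) {
    return(list(outcome = "fixed_methylation", new_sites = near))
  }
  if (u_fix <= 0.5) {
    list(outcome = "fixed_random", new_sites = integer(0))
  } else {
    list(outcome = "lost_random", new_sites = integer(0))
  }
}

#' Advance the ratchet state by one generation
#'
#' Draws replication errors at rate `mu` per site, resolves each in the
#' precedence order (a) parental-methylation-directed repair, (b)
#' nascent-strand methylation fixation, (c) random resolution, applies the
#' fixed mutations, and rebuilds the methylated-site registry.
#'
#' @param state A `ratchet_state`.
#' @param params A [ratchet_params()]; defaults to the state's own.
#' @return The updated state, with a `tally` attribute counting the
#'   generation's outcomes.
#' @export
ratchet_step <- function(state, params = state$params) {
  L <- params$length
  codes <- state$codes
  sites <- state$sites
  pat_codes <- state$pat_codes
  tally <- c(lost_parental = 0L, fixed_methylation = 0L,
             fixed_random = 0L, lost_random = 0L)
  n_mut <- stats::rbinom(1L, L, params$mu)
  if (n_mut > 0L) {
    pos <- sort(sample.int(L, n_mut))
    for (p in pos) {
      old <- codes[p]
      new_base <- sample.int(4L, 1L)
      while (new_base == old) new_base <- sample.int(4L, 1L)
      res <- .resolve_mismatch(codes, sites, p, new_base, params, pat_codes)
      tally[res$outcome] <- tally[res$outcome] + 1L
      if (res$outcome %in% c("fixed_methylation", "fixed_random")) {
        codes[p] <- new_base
      }
      if (length(res$new_sites)) {
        sites <- sort(unique(c(sites, res$new_sites)))
      }
    }
  }
  # registry rebuild: confirm every methylated site still qualifies
  sites <- .validate_sites(codes, sites, pat_codes, L, params$circular)
  state$codes <- codes
  state$sites <- sites
  state$generation <- state$generation + 1L
  attr(state, "tally") <- tally
  state
}

# circular inter-site spacings (or linear gaps) of the current state
.site_spacings <- function(sites, L, circular) {
  if (length(sites) < 2L) return(numeric(0))
  d <- diff(sites)
  if (circular) d <- c(d, L - sites[length(sites)] + sites[1])
  d
}

#' Run the ratchet simulation
#'
#' @param params A [ratchet_params()] object.
#' @param record_every Record trajectory statistics every this many
#'   generations (default 10; outcome tallies are accumulated over the
#'   recording interval).
#' @return A list of class `ratchet_trajectory` with `params`,
#'   `trajectory` (data.frame: `generation`, `site_count`, `mean_spacing`,
#'   `median_spacing`, `lost_parental`, `fixed_methylation`,
#'   `fixed_random`, `lost_random`) and `final_state`.
#' @export
ratchet_run <- function(params, record_every = 10L) {
  state <- init_state(params)
  gens <- params$generations
  rows <- vector("list", ceiling(gens / record_every))
  acc <- c(lost_parental = 0L, fixed_methylation = 0L,
           fixed_random = 0L, lost_random = 0L)
  ri <- 0L
  for (g in seq_len(gens)) {
    state <- ratchet_step(state, params)
    acc <- acc + attr(state, "tally")
    if (g %% record_every == 0L || g == gens) {
      sp <- .site_spacings(state$sites, params$length, params$circular)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        generation = g,
        site_count = length(state$sites),
        mean_spacing = if (length(sp)) mean(sp) else NA_real_,
        median_spacing = if (length(sp)) stats::median(sp) else NA_real_,
        lost_parental = acc[["lost_parental"]],
        fixed_methylation = acc[["fixed_methylation"]],
        fixed_random = acc[["fixed_random"]],
        lost_random = acc[["lost_random"]])
      acc[] <- 0L
    }
  }
  structure(list(params = params,
                 trajectory = do.call(rbind, rows[seq_len(ri)]),
                 final_state = state),
            class = "ratchet_trajectory")
}

#' Convert a ratchet state to a GenomeSeq
#'
#' @param state A `ratchet_state`.
#' @return A [genome_seq()] object holding the current sequence.
#' @export
ratchet_genome <- function(state) {
  genome_seq(paste0(.BASES[state$codes], collapse = ""),
             name = "ratchet", circular = state$params$circular)
}

#' Deviation spectrum of an evolved ratchet genome
#'
#' Delegates to [deviation_profile()] on the simulated sequence, asking
#' how sites one-off from the consensus (HIP1 by default) are distributed
#' across positions after the ratchet has acted.
#'
#' @param state A `ratchet_state` (e.g. `final_state` of [ratchet_run()]).
#' @param consensus Consensus oligomer (default `GCGATCGC`).
#' @return A [deviation_profile()].
#' @export
trajectory_deviation_spectrum <- function(state, consensus = "GCGATCGC") {
  deviation_profile(ratchet_genome(state), consensus)
}

#' Equilibrium mean inter-site spacing of a ratchet trajectory
#'
#' Averages the recorded mean spacing over the final fraction of the run,
#' after the site count has plateaued.
#'
#' @param run A `ratchet_trajectory`.
#' @param tail_fraction Final fraction of generations to average over.
#' @return Mean inter-site spacing in nucleotides.
#' @export
equilibrium_spacing <- function(run, tail_fraction = 0.25) {
  tr <- run$trajectory
  cut <- stats::quantile(tr$generation, 1 - tail_fraction)
  mean(tr$mean_spacing[tr$generation >= cut], na.rm = TRUE)
}

#' @export
print.ratchet_trajectory <- function(x, ...) {
  tr <- x$trajectory
  last <- tr[nrow(tr), ]
  cat(sprintf(paste0("Ratchet run: L=%d, R=%d, mu=%g, p_meth=%g, ",
                     "%d generations\n"),
              x$params$length, x$params$repair_radius, x$params$mu,
              x$params$p_meth, x$params$generations))
  cat(sprintf("  final sites: %d (mean spacing %.0f nt)\n",
              last$site_count, last$mean_spacing))
  invisible(x)
}
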