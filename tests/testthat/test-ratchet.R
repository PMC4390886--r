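# Independent rule-table classifier used as the oracle for mismatch
# resolution.  It works on character strings and shares no code with the
# simulator's window-based implementation.
oracle_classify <- function(seqstr, sites, pos, new_base, R,
                            pattern = "CGATCG") {
  L <- nchar(seqstr)
  k <- nchar(pattern)
  circ_dist <- function(a, b) {
    d <- abs(a - b)
    min(d, L - d)
  }
  if (length(sites) && min(vapply(sites, circ_dist, 1, b = pos)) <= R) {
    return("lost_parental")
  }
  s <- strsplit(seqstr, "")[[1]]
  s[pos] <- new_base
  doubled <- c(s, s)                       # circular scan
  for (start in 1:L) {
    seg <- paste0(doubled[start:(start + k - 1L)], collapse = "")
    if (seg != pattern) next
    before <- doubled[if (start == 1L) L else start - 1L]
    after <- doubled[start + k]
    if (before != "G" && after != "C") next
    # overlapping or adjacent to the mutated position (circular)
    span <- ((start - 2L):(start + k - 1L)) %% L + 1L
    if (pos %in% span) {
      return("methylation_eligible")
    }
  }
  "random"
}

test_that("identical parameters and seed give identical trajectories", {
  p <- ratchet_params(length = 20000L, mu = 5e-4, generations = 200L,
                      seed = 19, init_site_per_nt = 2e-4)
  r1 <- ratchet_run(p)
  r2 <- ratchet_run(p)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$final_state$codes, r2$final_state$codes)
})

test_that("no mutation rate means no change", {
  p <- ratchet_params(length = 5000L, mu = 0, generations = 1L, seed = 4,
                      init_site_per_nt = 1e-3)
  st <- init_state(p)
  st2 <- ratchet_step(st)
  expect_identical(st2$codes, st$codes)
  expect_identical(st2$sites, st$sites)
  expect_equal(st2$generation, 1L)
})

test_that("initial states plant qualifying methylated sites", {
  p <- ratchet_params(length = 100000L, generations = 1L, seed = 23,
                      init_site_per_nt = 1e-4)
  st <- init_state(p)
  expect_length(st$sites, 10L)
  g <- ratchet_genome(st)
  # every planted site matches the pattern and carries the G-meC context,
  # verified by an independent scan of the sequence
  s <- strsplit(g$residues, "")[[1]]
  for (site in st$sites) {
    expect_equal(paste0(s[site:(site + 5L)], collapse = ""), "CGATCG")
    expect_true(s[site - 1L] == "G" || s[site + 6L] == "C")
  }
  # zero density: no methylated sites
  p0 <- ratchet_params(length = 5000L, generations = 1L, seed = 2,
                       init_site_per_nt = 0)
  expect_length(init_state(p0)$sites, 0L)
})

test_that("a mutation completing a G-meC site is fixed and methylated", {
  p <- ratchet_params(length = 40L, mu = 1e-4, p_meth = 1,
                      generations = 1L, seed = 6, init_site_per_nt = 0)
  st <- init_state(p)
  # write A CGATCG at positions 10..16; mutating that A to G creates the
  # G-meC context immediately left of the site
  codes <- st$codes
  word <- match(strsplit("ACGATCG", "")[[1]], c("A", "C", "G", "T"))
  codes[10:16] <- word
  codes[17] <- 1L                          # A after the site: no C context
  codes[9] <- 1L                           # and none before
  res <- hipscan:::.resolve_mismatch(codes, integer(0), 10L, 3L, p,
                                     st$pat_codes, u_meth = 0, u_fix = 1)
  expect_equal(res$outcome, "fixed_methylation")
  expect_equal(res$new_sites, 11L)
})

test_that("mismatch resolution matches an exhaustive rule-table oracle", {
  p <- ratchet_params(length = 60L, mu = 1e-4, p_meth = 1,
                      repair_radius = 8L, generations = 1L, seed = 33,
                      init_site_per_nt = 0)
  st <- init_state(p)
  codes <- st$codes
  # plant one methylated site (G + CGATCG) at positions 29..35
  word <- match(strsplit("GCGATCG", "")[[1]], c("A", "C", "G", "T"))
  codes[29:35] <- word
  sites <- 30L
  seqstr <- paste0(c("A", "C", "G", "T")[codes], collapse = "")
  bases <- c("A", "C", "G", "T")
  for (pos in 1:60) {
    for (nb in setdiff(1:4, codes[pos])) {
      want <- oracle_classify(seqstr, sites, pos, bases[nb],
                              R = p$repair_radius)
      res <- hipscan:::.resolve_mismatch(codes, sites, pos, nb, p,
                                         st$pat_codes,
                                         u_meth = 0, u_fix = 0.3)
      got <- switch(res$outcome,
                    lost_parental = "lost_parental",
                    fixed_methylation = "methylation_eligible",
                    fixed_random = "random",
                    lost_random = "random")
      expect_equal(got, want,
                   label = sprintf("pos %d -> %s", pos, bases[nb]))
    }
  }
})

test_that("without methylation the ratchet degenerates to neutral drift", {
  p <- ratchet_params(length = 20000L, mu = 5e-3, p_meth = 0,
                      generations = 150L, seed = 41, init_site_per_nt = 0)
  run <- ratchet_run(p, record_every = 150L)
  tr <- run$trajectory
  fixed <- sum(tr$fixed_random) + sum(tr$fixed_methylation)
  lost <- sum(tr$lost_random) + sum(tr$lost_parental)
  expect_equal(sum(tr$fixed_methylation), 0)
  expect_equal(sum(tr$lost_parental), 0)
  expect_gt(fixed + lost, 1e4)
  expect_lt(abs(fixed / lost - 1), 0.1)
})

test_that("methylated sites are protected and their count never ratchets down", {
  p <- ratchet_params(length = 30000L, mu = 1e-4, p_meth = 1,
                      repair_radius = 1000L, generations = 500L, seed = 47,
                      init_site_per_nt = 2e-4)
  run <- ratchet_run(p, record_every = 10L)
  counts <- run$trajectory$site_count
  expect_gte(mean(diff(counts) >= 0), 0.95)
  expect_gte(counts[length(counts)], counts[1])
})

test_that("dense initial sites with p_meth 1 block all fixation", {
  # spacing ~500 nt << R = 2000: every position is within R of a site
  p <- ratchet_params(length = 10000L, mu = 2e-3, p_meth = 1,
                      repair_radius = 2000L, generations = 50L, seed = 53,
                      init_site_per_nt = 2e-3)
  run <- ratchet_run(p, record_every = 50L)
  tr <- run$trajectory
  expect_equal(sum(tr$fixed_random) + sum(tr$fixed_methylation), 0)
  expect_gt(sum(tr$lost_parental), 100)
  expect_identical(run$final_state$sites, init_state(p)$sites)
})

test_that("a zero-generation state has the init genome's deviation profile", {
  p <- ratchet_params(length = 50000L, generations = 0L, seed = 61,
                      init_site_per_nt = 1e-4)
  st <- init_state(p)
  prof <- trajectory_deviation_spectrum(st)
  direct <- deviation_profile(ratchet_genome(st), "GCGATCGC")
  expect_equal(prof$fraction, direct$fraction)
})
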