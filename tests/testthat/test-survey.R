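test_that("top oligomers rank a planted repeat first and flag its overlaps", {
  g <- generate_genome(300000, 0.45, seed = 101)
  planted <- plant_pattern(g, "GCGATCGC", 300, seed = 102)  # 1000/Mnt
  top <- top_oligomers(planted$genome, k = 8, n = 12)
  expect_equal(top$pattern[1], "GCGATCGC")
  expect_true(top$is_palindromic[1])
  expect_true(top$within_reference[1])
  # staggered overlaps of the planted repeat rise with it
  expect_gt(sum(top$within_reference), 1)
  expect_equal(top$oe[1],
               top$count_collapsed[1] / top$expected[1])
  expect_equal(top$count_per_M[1],
               top$count_collapsed[1] * 1e6 / planted$genome$length)
  expect_gt(top$shade[1], 0.03)
  expect_equal(top$shade[1],
               shade_category(top$count_collapsed[1], top$expected[1],
                              planted$genome$length))
})

test_that("a triplet-repeat genome surfaces its repeat phases", {
  g <- genome_seq(strrep("ACG", 500))
  top <- top_oligomers(g, k = 8, n = 3, rank_by = "count_per_M",
                       reference = NULL)
  phases <- c("ACGACGAC", "CGACGACG", "GACGACGA")
  canonical <- vapply(phases, function(p) {
    min(p, reverse_complement(p))
  }, "")
  expect_setequal(top$pattern, unique(canonical))
})

test_that("no oligomer is strongly overrepresented in an unplanted genome", {
  g <- generate_genome(2e6, 0.5, seed = 55)
  top <- top_oligomers(g, k = 8, n = 1)
  expect_lt(top$oe[1], 5)
})

test_that("the collapsed top list is invariant under reverse-complementing the genome", {
  g <- generate_genome(50000, 0.4, seed = 77)
  g_rc <- genome_seq(reverse_complement(g$residues))
  t1 <- top_oligomers(g, k = 6, n = 20, reference = NULL)
  t2 <- top_oligomers(g_rc, k = 6, n = 20, reference = NULL)
  expect_equal(t1$pattern, t2$pattern)
  expect_equal(t1$count_collapsed, t2$count_collapsed)
})

test_that("hip_summary echoes planted parameters and handles HIP-free genomes", {
  g <- generate_genome(200000, 0.45, seed = 201)
  planted <- plant_pattern(g, "GCGATCGC", 200, seed = 202)  # 1000/Mnt
  s <- hip_summary(planted$genome)
  expect_equal(s$hip1_count_per_M,
               planted$total_collapsed * 1e6 / 2e5)
  expect_gt(s$hip1_count_per_M, 1000 * 0.98)
  expect_lt(s$hip1_count_per_M, 1000 * 1.10)
  e0 <- expected_count_order0(2e5, planted$genome$gc_fraction, "GCGATCGC")
  expect_equal(s$hip1_oe_order0, planted$total_collapsed / e0)
  # the top 8-mer IS HIP1, so the top8 fields are suppressed
  expect_true(is.na(s$top8_pattern))
  expect_true(is.finite(s$hip1_oe_markov1))
  expect_true(is.finite(s$hip1_oe_markov2))

  # a genome with a different dominant 8-mer reports it
  g2 <- generate_genome(200000, 0.45, seed = 203)
  planted2 <- plant_pattern(g2, "GGGATCCC", 200, seed = 204)
  s2 <- hip_summary(planted2$genome)
  expect_equal(s2$top8_pattern, "GGGATCCC")
  expect_gt(s2$top8_oe, s2$hip1_oe_order0)

  # zero HIP1 occurrences: count and O/E are both 0
  g3 <- compose_genome(5000, "GGGG", 100, background = "A")
  s3 <- hip_summary(g3)
  expect_equal(s3$hip1_count_per_M, 0)
  expect_equal(s3$hip1_oe_order0, 0)
})

test_that("palindrome classes have the right membership", {
  p6 <- class_members("palindromic6")
  expect_length(p6, 64)
  expect_true(all(vapply(p6, is_palindromic, TRUE)))
  expect_true("GGCGCC" %in% p6 && "CGATCG" %in% p6)
  p5 <- class_members("palindromic5_center_WS")
  expect_length(p5, 32)
  expect_true(all(vapply(p5, is_palindromic, TRUE)))
  expect_true("GCSGC" %in% p5)
  d6 <- class_members("degenerate_palindromic6")
  expect_true(all(vapply(d6, is_palindromic, TRUE)))
  expect_true(all(vapply(d6, function(p) {
    nd <- sum(strsplit(p, "")[[1]] %in% c("R", "Y", "S", "W", "K", "M"))
    nd %in% c(2L, 4L)
  }, TRUE)))
  expect_true("RCCGGY" %in% d6)
  expect_false("GGCGCC" %in% d6)
})

test_that("best_in_class finds planted palindromes and knows HIP1 containment", {
  g <- generate_genome(100000, 0.45, seed = 301)
  planted <- plant_pattern(g, "GGCGCC", 300, seed = 302)
  best <- best_in_class(planted$genome, "palindromic6")
  expect_equal(best$pattern, "GGCGCC")
  expect_false(best$within_hip1)

  g2 <- generate_genome(100000, 0.45, seed = 303)
  planted2 <- plant_pattern(g2, "GCGATCGC", 300, seed = 304)
  best2 <- best_in_class(planted2$genome, "palindromic6")
  expect_equal(best2$pattern, "CGATCG")
  expect_true(best2$within_hip1)

  # exhaustive scan oracle for the planted-GGCGCC case
  oe_all <- vapply(class_members("palindromic6"), function(p) {
    strand_collapsed_count(planted$genome, p) /
      expected_count_order0(1e5, planted$genome$gc_fraction, p)
  }, 1)
  expect_equal(best$oe, unname(max(oe_all)))

  # a planted degenerate palindrome dominates its class
  g3 <- generate_genome(100000, 0.5, seed = 305)
  p3a <- plant_pattern(g3, "ACCGGC", 150, seed = 306)
  p3b <- plant_pattern(p3a$genome, "GCCGGT", 150, seed = 307)
  best3 <- best_in_class(p3b$genome, "degenerate_palindromic6")
  expect_equal(best3$pattern, "RCCGGY")
})

test_that("subtracting an enclosing repeat removes its contribution to O/E", {
  # every GATC lies inside a planted HIP1: subtracted O/E is 0
  n <- 40
  starts <- seq(10, by = 50, length.out = n)
  g <- compose_genome(3000, rep("GCGATCGC", n), starts, background = "A")
  expect_equal(oe_excluding_hip(g, "GATC"), 0)
  plain_oe <- strand_collapsed_count(g, "GATC") /
    expected_count_order0(g$length, g$gc_fraction, "GATC")
  expect_gt(plain_oe, 0)

  # no HIP occurrences: subtracted O/E equals the plain O/E
  g2 <- compose_genome(3000, rep("TGATCA", n), starts, background = "A")
  plain2 <- strand_collapsed_count(g2, "GATC") /
    expected_count_order0(g2$length, g2$gc_fraction, "GATC")
  expect_equal(oe_excluding_hip(g2, "GATC"), plain2)

  # mixed genome: hand-computed subtraction
  g3 <- compose_genome(4000, c(rep("GCGATCGC", 30), rep("TGATCA", 20)),
                       seq(10, by = 60, length.out = 50), background = "A")
  obs <- strand_collapsed_count(g3, "GATC") -
    strand_collapsed_count(g3, "GCGATCGC") * 1
  want <- obs / expected_count_order0(g3$length, g3$gc_fraction, "GATC")
  expect_equal(oe_excluding_hip(g3, "GATC"), want)
  expect_lte(oe_excluding_hip(g3, "GATC"),
             plain_oe_of <- strand_collapsed_count(g3, "GATC") /
               expected_count_order0(g3$length, g3$gc_fraction, "GATC"))

  expect_error(oe_excluding_hip(g3, "TTTT"), "not a substring")
})
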