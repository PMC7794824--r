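aln_from <- function(rows) {
  aligned_set(data.frame(id = paste0("s", seq_along(rows)), description = "",
                         taxon = NA, residues = rows, stringsAsFactors = FALSE))
}

test_that("column consensus follows the strict >50% rule", {
  cc <- column_conservation(aln_from(c("L", "L", "L", "L")))
  expect_equal(cc$consensus_residue, "L")
  expect_equal(cc$identity_fraction, 1)
  expect_equal(cc$class, "consensus-identical")

  # 3 of 6 is not strictly more than half
  cc2 <- column_conservation(aln_from(c("L", "L", "L", "V", "V", "V")))
  expect_true(is.na(cc2$consensus_residue))
  expect_false(cc2$class == "consensus-identical")

  # L and V share the aliphatic group: identity 4/6, similarity 6/6
  cc3 <- column_conservation(aln_from(c("L", "L", "L", "L", "V", "V")))
  expect_equal(cc3$consensus_residue, "L")
  expect_equal(cc3$identity_fraction, 4 / 6)
  expect_equal(cc3$similarity_fraction, 1)

  # gaps are excluded from the denominator
  cc4 <- column_conservation(aln_from(c("L", "L", "-", "-")))
  expect_equal(cc4$identity_fraction, 1)
  cc5 <- column_conservation(aln_from(c("-", "-", "-")))
  expect_equal(cc5$class, "no-consensus")

  expect_error(column_conservation(aln_from("LLNKVA")), "single-sequence")
})

test_that("identity depends only on the non-gap residue multiset", {
  a <- column_conservation(aln_from(c("L", "L", "V", "-")))
  b <- column_conservation(aln_from(c("L", "-", "L", "V", "-", "-")))
  expect_equal(a$identity_fraction, b$identity_fraction)
})

test_that("conservation outputs are invariant to sequence order", {
  m <- make_msa(12, 30, motif_columns = 10:15, rng_seed = 3)
  aln <- m$alignment
  shuffled <- aln
  set.seed(1)
  shuffled$records <- shuffled$records[sample(nrow(aln$records)), ]
  expect_equal(column_conservation(aln)$identity_fraction,
               column_conservation(shuffled)$identity_fraction)
  c1 <- motif_flank_contrast(aln, 10:15, c(1:9, 16:30), 200, seed_rng = 8)
  c2 <- motif_flank_contrast(shuffled, 10:15, c(1:9, 16:30), 200, seed_rng = 8)
  expect_equal(c1, c2)
})

test_that("motif-vs-flank contrast detects conserved motifs and not null ones", {
  # conserved motif columns against diverged flanks
  m1 <- make_msa(20, 60, motif_columns = 28:33, motif_rate = 0.05,
                 flank_rate = 0.5, rng_seed = 5)
  r1 <- motif_flank_contrast(m1$alignment, m1$motif_columns, m1$flank_columns,
                             1000, seed_rng = 9)
  expect_gt(r1$contrast, 0.2)
  expect_lt(r1$permutation_p, 0.05)
  expect_equal(r1$contrast, r1$motif_mean - r1$flank_mean)

  # uniformly conserved alignment: motif does not stand out
  m2 <- make_msa(20, 60, motif_columns = 28:33, motif_rate = 0.05,
                 flank_rate = 0.05, rng_seed = 5)
  r2 <- motif_flank_contrast(m2$alignment, m2$motif_columns, m2$flank_columns,
                             1000, seed_rng = 9)
  expect_lt(abs(r2$contrast), 0.1)
  expect_gt(r2$permutation_p, 0.05)

  # two identical exchangeable columns: contrast 0, p exactly 1
  aln <- aln_from(c("LL", "LL", "VV"))
  r3 <- motif_flank_contrast(aln, 1, 2, 100, seed_rng = 2)
  expect_equal(r3$contrast, 0)
  expect_equal(r3$permutation_p, 1)

  expect_error(motif_flank_contrast(aln, 1, 1, 100), "disjoint")
  expect_error(motif_flank_contrast(aln, integer(), 2, 100), "non-empty")
})

test_that("the permutation p-value is super-uniform under exchangeability", {
  ps <- vapply(1:200, function(b) {
    m <- make_msa(12, 40, motif_columns = 1:6, motif_rate = 0.3,
                  flank_rate = 0.3, rng_seed = 2000 + b)
    motif_flank_contrast(m$alignment, 1:6, 7:40, permutations = 200,
                         seed_rng = b)$permutation_p
  }, numeric(1))
  expect_lte(mean(ps <= 0.05), 0.08)
  expect_true(all(ps > 0))
})
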