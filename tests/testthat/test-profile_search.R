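test_that("seed windows extract motif regions with neutral terminal padding", {
  recs <- data.frame(id = "myb29", description = "", taxon = NA,
                     residues = PEP_MYB29, stringsAsFactors = FALSE)
  hit <- scan_motif(recs, "core")
  s5 <- build_seed(recs, hit, flank = 5)
  expect_equal(s5$members, PEP_MYB29)  # 5+6+5 exactly spans the 16-mer
  expect_equal(s5$motif_offset, 6L)

  s0 <- build_seed(recs, hit, flank = 0)
  expect_equal(s0$members, "LLNKVA")

  short <- data.frame(id = "s", description = "", taxon = NA,
                      residues = "ALLNKVAYQW", stringsAsFactors = FALSE)
  h2 <- scan_motif(short, "core")
  expect_equal(h2$start, 2L)
  sp <- build_seed(short, h2, flank = 5)
  expect_equal(sp$members, "....ALLNKVAYQW..")
  expect_equal(nchar(sp$members), 16L)

  expect_error(build_seed(recs, hit, flank = 21), "0-20")
  expect_error(build_seed(recs, hit[0, ], flank = 5), "empty")
})

test_that("profile estimation matches closed forms and normalisation", {
  # single member, vanishing pseudocount: columns become point masses and
  # the member scores 6 * log2(20) bits under a uniform background
  m <- estimate_profile("LLNKVA", pseudocount = 1e-9)
  expect_equal(score_windows(m, "LLNKVA"), 6 * log2(20), tolerance = 1e-6)

  # a column with all 20 residues equally present has zero log-odds
  m20 <- estimate_profile(AA_CANONICAL, pseudocount = 0.5)
  expect_equal(unname(m20$log_odds[1, ]), rep(0, 20), tolerance = 1e-12)

  # probabilities recovered from log-odds sum to 1, padded members included
  mp <- estimate_profile(c("LLNKVA", "..NKVA"), pseudocount = 0.5)
  probs <- 2^mp$log_odds * rep(mp$background, each = mp$length)
  expect_equal(unname(rowSums(probs)), rep(1, mp$length), tolerance = 1e-9)

  expect_error(estimate_profile("LLNKVA", pseudocount = 0),
               "pseudocount")
  bad_bg <- stats::setNames(c(0, rep(1 / 19, 19)), AA_CANONICAL)
  expect_error(estimate_profile("LLNKVA", background = bad_bg), "positive")
})

test_that("window scores are additive over per-column log-odds", {
  set.seed(12)
  members <- replicate(6, random_seq(10))
  model <- estimate_profile(members)
  s <- random_seq(60)
  chars <- strsplit(s, "")[[1]]
  got <- score_windows(model, s)
  for (w in seq_along(got)) {
    manual <- sum(vapply(seq_len(model$length), function(j) {
      model$log_odds[j, chars[w + j - 1]]
    }, numeric(1)))
    expect_equal(got[w], manual, tolerance = 1e-12)
  }
  # pad scores zero, masked X scores -Inf
  expect_equal(score_windows(model, strrep(".", 10)), 0)
  expect_equal(score_windows(model, paste0("X", random_seq(9))), -Inf)
})

test_that("empirical E-values are non-increasing in score and never negative", {
  set.seed(3)
  null <- rnorm(20000)
  ev <- mimscout:::make_evalue_fun(null, 5000)
  s <- seq(-4, 12, by = 0.05)
  e <- ev(s)
  expect_true(all(e >= 0))
  expect_true(all(diff(e) <= 1e-12))
  # continuous at the empirical maximum
  mx <- max(null)
  expect_equal(ev(mx), ev(mx + 1e-9), tolerance = 1e-3)
})

test_that("profile search recovers planted motifs and respects taxonomy", {
  gen <- make_proteome(list(context_spec("r2r3_like"), context_spec("negative")),
                       15, rng_seed = 5)
  seed <- benchmark_seed(n_members = 24)
  hits <- search_profile(gen$records, seed, evalue_cutoff = 1e-3,
                         max_iterations = 3, null_windows = 3e4, seed_rng = 2)
  truth_keys <- paste(gen$truth$sequence_id, gen$truth$start)
  hit_keys <- paste(hits$sequence_id, hits$start + seed$flank)
  expect_gte(sum(truth_keys %in% hit_keys), 14L)
  expect_equal(sum(grepl("negative", hits$sequence_id)), 0L)
  expect_true(all(hits$evalue <= 1e-3))
  expect_true(all(hits$iteration_found >= 1L & hits$iteration_found <= 3L))

  # identical inputs and RNG seed give identical hit lists
  again <- search_profile(gen$records, seed, evalue_cutoff = 1e-3,
                          max_iterations = 3, null_windows = 3e4, seed_rng = 2)
  expect_identical(hits, again)

  # max_iterations = 1 is a plain one-pass search
  one <- search_profile(gen$records, seed, evalue_cutoff = 1e-3,
                        max_iterations = 1, null_windows = 3e4, seed_rng = 2)
  expect_true(all(one$iteration_found == 1L))

  # excluding every taxon empties the database
  tagged <- gen$records
  tagged$taxon <- "Brassicales"
  expect_error(search_profile(tagged, seed, exclude_taxa = "Brassicales"),
               "empty")
  expect_error(search_profile(gen$records, seed, evalue_cutoff = 0),
               "cutoff")
})

test_that("flank sweep tabulates hits per flank with union and intersection", {
  gen <- make_proteome(list(context_spec("r2r3_like"), context_spec("negative")),
                       8, rng_seed = 19)
  seedgen <- make_proteome(context_spec("r2r3_like"), 24, rng_seed = 99)
  seed_hits <- merge(scan_motif(seedgen$records, "strict"),
                     seedgen$truth[c("sequence_id", "start")])
  sweep <- flank_sweep(seedgen$records, seed_hits, gen$records,
                       flanks = c(0, 5), null_windows = 2e4, seed_rng = 4)
  expect_equal(sweep$table$flank, c(0, 5))
  expect_equal(nrow(sweep$table), 2L)
  for (fl in c("0", "5")) {
    keys <- paste(sweep$per_flank[[fl]]$sequence_id,
                  sweep$per_flank[[fl]]$start + as.integer(fl))
    expect_true(all(keys %in% paste(sweep$union$sequence_id, sweep$union$start)))
  }
  inter_keys <- paste(sweep$intersection$sequence_id, sweep$intersection$start)
  keys0 <- paste(sweep$per_flank[["0"]]$sequence_id, sweep$per_flank[["0"]]$start)
  expect_true(all(inter_keys %in% keys0))
  expect_error(flank_sweep(seedgen$records, seed_hits, gen$records, flanks = 21),
               "0-20")
})
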