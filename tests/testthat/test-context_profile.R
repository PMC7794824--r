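test_that("composition tracks match hand counts and saturate correctly", {
  rk <- composition_track(PEP_MYB29, c("R", "K"), c("D", "E"), window = 15)
  # window centred at 8 covers residues 1-15: K5, K9, R13 and no D/E
  expect_equal(rk$values[8], 3 / 15)
  expect_equal(rk$name, "+RK-DE")
  expect_equal(length(rk$values), nchar(PEP_MYB29))

  polyg <- composition_track(strrep("G", 40), c("R", "K"), c("D", "E"))
  expect_true(all(polyg$values == 0))
  polyk <- composition_track(strrep("K", 40), c("R", "K"), c("D", "E"))
  expect_true(all(polyk$values == 1))
  polyd <- composition_track(strrep("D", 40), c("R", "K"), c("D", "E"))
  expect_true(all(polyd$values == -1))

  expect_error(composition_track("AAAA", c("R", "K"), c("K", "D")), "disjoint")
  expect_error(composition_track("AAAA", "R", "D", window = 14), "odd")
})

test_that("the disorder proxy is bounded and ranks compositions as packaged", {
  expect_equal(disorder_proxy(strrep("P", 50))$values, rep(1, 50))
  expect_equal(disorder_proxy(strrep("W", 50))$values, rep(0, 50))

  # an order-biased segment followed by a disorder-biased one separates
  # by at least 0.2 in mean proxy
  gen <- make_proteome(context_spec("negative"), 10, rng_seed = 31)
  seps <- vapply(gen$records$residues, function(s) {
    p <- disorder_proxy(s)$values
    mean(p[81:200]) - mean(p[1:80])
  }, numeric(1))
  expect_true(all(seps >= 0.2))
})

test_that("tracks are window-local: concatenation matches away from the seam", {
  set.seed(23)
  for (rep in 1:20) {
    a <- random_seq(80)
    b <- random_seq(90)
    ab <- paste0(a, b)
    w <- 15
    ta <- composition_track(a, c("R", "K"), c("D", "E"), w)$values
    tab <- composition_track(ab, c("R", "K"), c("D", "E"), w)$values
    keep <- 1:(80 - w)  # positions whose window cannot reach the seam
    expect_equal(tab[keep], ta[keep])
    pa <- disorder_proxy(a, 21)$values
    pab <- disorder_proxy(ab, 21)$values
    expect_equal(pab[1:(80 - 21)], pa[1:(80 - 21)])
  }
})

test_that("track values stay within their declared ranges on random input", {
  set.seed(29)
  for (rep in 1:200) {
    s <- random_seq(sample(15:120, 1))
    ct <- composition_track(s, c("P", "S", "T"), c("R", "K"))$values
    expect_true(all(ct >= -1 & ct <= 1))
    dp <- disorder_proxy(s)$values
    expect_true(all(dp >= 0 & dp <= 1))
  }
})

test_that("the three-feature signature separates motif contexts", {
  gen <- make_proteome(list(context_spec("r2r3_like"), context_spec("trihelix_like")),
                       30, rng_seed = 17)
  calls <- vapply(seq_len(nrow(gen$truth)), function(i) {
    tr <- gen$truth[i, ]
    s <- gen$records$residues[gen$records$id == tr$sequence_id]
    classify_context(s, tr)$overall_call
  }, logical(1))
  kind <- gen$truth$kind
  expect_gte(mean(calls[kind == "r2r3_like"]), 0.9)
  expect_gte(mean(!calls[kind == "trihelix_like"]), 0.9)
})

test_that("individual signature features behave as defined", {
  # a uniform sequence without R/K can never satisfy the charge feature
  s <- paste0(strrep("G", 40), "GLNGGA", strrep("G", 40))
  hit <- scan_motif(s, "core")
  sig <- classify_context(s, hit)
  expect_false(sig$net_charge_positive)
  expect_false(sig$overall_call)

  # hits near a terminus are evaluated on what exists and flagged
  s2 <- paste0("LLNKVA", strrep("P", 60))
  sig2 <- classify_context(s2, scan_motif(s2, "core")[1, ])
  expect_true(sig2$truncated)

  expect_error(classify_context("AAAA", list(start = 2, end = 9)), "outside")
})

test_that("the signature ignores residues far from the hit", {
  gen <- make_proteome(context_spec("r2r3_like"), 5, rng_seed = 53)
  for (i in 1:5) {
    tr <- gen$truth[i, ]
    s <- gen$records$residues[gen$records$id == tr$sequence_id]
    # replace everything further than proxy window + 25 from the hit
    margin <- 21 + 25
    lo <- max(1, tr$start - margin)
    chars <- strsplit(s, "")[[1]]
    if (lo > 1) chars[1:(lo - 1)] <- "W"
    s2 <- paste(chars, collapse = "")
    a <- classify_context(s, tr)
    b <- classify_context(s2, tr)
    expect_equal(a$order_dip, b$order_dip)
    expect_equal(a$net_charge_positive, b$net_charge_positive)
    expect_equal(a$flank_bias, b$flank_bias)
  }
})
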