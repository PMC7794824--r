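test_that("random-coil prediction reduces to the base table when corrections vanish", {
  model <- random_coil_model()
  zeroed <- model
  zeroed$neighbor_corrections[] <- 0
  zeroed$temperature_coefficient[] <- 0
  zeroed$pH_correction$delta[] <- 0
  got <- random_coil_shifts("ALNKVA", zeroed,
                            temperature_C = zeroed$reference_temperature_C,
                            pH = zeroed$pH_correction$reference_pH)
  expect_equal(got, unname(model$base_shift[strsplit("ALNKVA", "")[[1]]]))
})

test_that("proline neighbour corrections are additive by construction", {
  model <- random_coil_model()
  g_pro <- random_coil_shifts("PGP", model)[2]
  g_ala <- random_coil_shifts("AGA", model)[2]
  expect_equal(g_pro - g_ala,
               unname(model$neighbor_corrections["P", "-1"] +
                        model$neighbor_corrections["P", "+1"]))
  expect_error(random_coil_shifts("ALZ", model), "Z")
})

test_that("SCS is zero for model-generated coil shifts and linear in offsets", {
  st <- make_shift_table(PEP_ASR3, rep(0, 16), noise_sd_ppm = 0, rng_seed = 1)
  prof <- scs_profile(st$shifts)
  expect_equal(prof$scs_ca_ppm, rep(0, 16), tolerance = 1e-12)
  expect_false(any(prof$transient_helix))

  shifted <- st$shifts
  shifted$ca_shift_ppm <- shifted$ca_shift_ppm + 0.36
  prof2 <- scs_profile(shifted)
  expect_equal(prof2$scs_ca_ppm, prof$scs_ca_ppm + 0.36, tolerance = 1e-12)
  expect_true(all(prof2$transient_helix))

  bad <- st$shifts
  bad$residue_code[3] <- "W"
  expect_error(scs_profile(bad, sequence = PEP_ASR3), "mismatch")
})

test_that("peak SCS converts to fractional helicity at 3 ppm per full helix", {
  flat25 <- make_shift_table(PEP_ASR3, rep(0.25, 16), noise_sd_ppm = 0, rng_seed = 1)
  est <- helicity(scs_profile(flat25$shifts))
  expect_equal(est$peak_scs_ppm, 0.75, tolerance = 1e-9)
  expect_equal(est$fractional_helicity, 0.25, tolerance = 1e-9)

  flat12 <- make_shift_table(PEP_MYB29, rep(0.12, 16), noise_sd_ppm = 0, rng_seed = 1)
  expect_equal(helicity(scs_profile(flat12$shifts))$fractional_helicity, 0.12,
               tolerance = 1e-9)

  zero <- make_shift_table(PEP_MYB29, rep(0, 16), noise_sd_ppm = 0, rng_seed = 1)
  est0 <- helicity(scs_profile(zero$shifts))
  expect_equal(est0$fractional_helicity, 0)
  expect_length(est0$helix_segment, 0)
})

test_that("a mid-peptide helicity profile yields a contiguous helix with an L-N dip", {
  # bell-shaped profile peaking at 0.12 mid-peptide, dip at the motif L,N
  prof <- 0.12 * sin(seq(0, pi, length.out = 16))^2
  st <- make_shift_table(PEP_MYB29, prof, dip_positions = c(7, 8),
                         noise_sd_ppm = 0, first_index = 184L, rng_seed = 6)
  scs <- scs_profile(st$shifts)
  est <- helicity(scs)
  peak_idx <- scs$residue_index[which.max(scs$scs_ca_ppm)]
  expect_length(est$helix_segment, 2)
  expect_true(est$helix_segment[1] <= peak_idx && peak_idx <= est$helix_segment[2])
  # the dip residues (L190, N191) sit below their immediate neighbours
  v <- scs$scs_ca_ppm[match(189:192, scs$residue_index)]
  expect_lt(v[2], v[1])
  expect_lt(v[3], v[4])
  expect_equal(est$fractional_helicity, 0.12, tolerance = 0.02)
})

test_that("helicity is monotone in SCS and clamped to [0, 1]", {
  set.seed(44)
  for (rep in 1:50) {
    n <- sample(5:20, 1)
    scs <- rnorm(n, 0.2, 0.5)
    prof <- data.frame(residue_index = seq_len(n),
                       residue_code = sample(AA_CANONICAL, n, replace = TRUE),
                       scs_ca_ppm = scs, transient_helix = scs > 0.1)
    class(prof) <- c("scs_profile", "data.frame")
    h1 <- helicity(prof)$fractional_helicity
    expect_gte(h1, 0); expect_lte(h1, 1)
    bumped <- prof
    i <- sample(n, 1)
    bumped$scs_ca_ppm[i] <- bumped$scs_ca_ppm[i] + runif(1, 0, 2)
    expect_gte(helicity(bumped)$fractional_helicity, h1)
  }
})

test_that("true helicity is recovered within 0.02 under realistic shift noise", {
  for (h in c(0.05, 0.25)) {
    est <- vapply(1:25, function(r) {
      st <- make_shift_table(PEP_ASR3, rep(h, 16), noise_sd_ppm = 0.02,
                             rng_seed = 7000 + r)
      helicity(scs_profile(st$shifts))$fractional_helicity
    }, numeric(1))
    expect_lt(abs(mean(est) - h), 0.02)
  }
})
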