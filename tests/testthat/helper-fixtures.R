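# Shared fixtures built in code.

# the two synthetic MIM peptides characterised by NMR
PEP_MYB29 <- "SSTSKLLNKVAARASS"
PEP_ASR3  <- "DSLVAVLNKLADAVAK"

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

write_tmp_shift_tsv <- function(rows, meta = character()) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(meta, "residue_index\tresidue_code\tca_shift_ppm", rows), f)
  f
}

random_seq <- function(n) paste(sample(mimscout::AA_CANONICAL, n, replace = TRUE),
                                collapse = "")

# independent brute-force motif matcher: explicit window enumeration with
# per-position set membership, no regular expressions
brute_force_scan <- function(s, pattern) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  w <- length(pattern$positions)
  starts <- integer(0)
  if (length(chars) >= w) {
    for (i in seq_len(length(chars) - w + 1L)) {
      ok <- TRUE
      for (j in seq_len(w)) {
        allowed <- pattern$positions[[j]]
        if (is.null(allowed)) allowed <- mimscout::AA_CANONICAL
        if (!(chars[i + j - 1L] %in% allowed)) { ok <- FALSE; break }
      }
      if (ok) starts <- c(starts, i)
    }
  }
  starts
}

# degeneracy-covering seed for profile-search benchmarks: n motif-region
# 16-mers whose planted strict instances jointly span [LF]...[KR][VL]
benchmark_seed <- function(n_members = 24L, flank = 5L, rng_seed = 99L) {
  gen <- mimscout::make_proteome(mimscout::context_spec("r2r3_like"),
                                 n_members, rng_seed = rng_seed)
  hits <- merge(mimscout::scan_motif(gen$records, "strict"),
                gen$truth[c("sequence_id", "start")])
  mimscout::build_seed(gen$records, hits, flank)
}
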