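# Synthetic fixtures with known ground truth: proteomes with planted
# motifs in controlled sequence contexts, alignments with controlled
# column conservation, and chemical-shift tables with known helicity.
#
# The generators define the benchmark conditions the rest of the package
# is validated against; their composition vectors were chosen once so
# that the packaged disorder proxy separates order- and disorder-biased
# segments by at least 0.2 on its [0, 1] scale (see the methods
# vignette), and are exposed so users can build their own variants.

# default residue-frequency vectors (named, each sums to 1)
idr_composition_default <- function() {
  c(P = 0.12, S = 0.14, T = 0.10, G = 0.12, E = 0.10, K = 0.10,
    R = 0.06, Q = 0.08, N = 0.06, D = 0.06, A = 0.06)
}

ordered_composition_default <- function() {
  c(L = 0.20, V = 0.18, I = 0.14, F = 0.10, W = 0.04, A = 0.16,
    M = 0.04, Y = 0.04, C = 0.02, G = 0.04, S = 0.04)
}

# motif flanks for r2r3_like records: strongly proline-biased,
# disorder-promoting, P/S/T-rich with few K/R (+PST-RK expectation
# 0.85 - 0.15 = 0.70) and free of D/E so the motif neighbourhood keeps
# a positive net charge (the motif's own K/R position supplies it).
flank_composition_default <- function() {
  c(P = 0.70, S = 0.10, T = 0.05, K = 0.10, R = 0.05)
}

# width of the rewritten flank region on each side of a planted
# r2r3_like motif: wide enough (25 + half the proxy window) that every
# window feeding the order-dip reference lies inside rewritten sequence
R2R3_FLANK_REWRITE <- 35L

check_composition <- function(comp, what) {
  if (any(!names(comp) %in% AA_CANONICAL) || any(comp < 0) ||
      abs(sum(comp) - 1) > 1e-9) {
    stop(what, " must be a named non-negative frequency vector over the ",
         "canonical residues summing to 1", call. = FALSE)
  }
  comp
}

sample_composition <- function(n, comp) {
  paste(sample(names(comp), n, replace = TRUE, prob = comp), collapse = "")
}

# exact-count sample: a random permutation of the residue multiset whose
# counts realise `comp` as closely as possible (largest-remainder
# rounding), so e.g. a rewritten motif flank meets its compositional
# target exactly rather than only in expectation
sample_composition_exact <- function(n, comp) {
  ideal <- n * comp / sum(comp)
  counts <- floor(ideal)
  short <- n - sum(counts)
  if (short > 0) {
    top_up <- order(ideal - counts, decreasing = TRUE)[seq_len(short)]
    counts[top_up] <- counts[top_up] + 1L
  }
  paste(sample(rep(names(comp), counts)), collapse = "")
}

# sample one concrete instance of a degenerate pattern
sample_pattern_instance <- function(pattern) {
  paste(vapply(pattern$positions, function(p) {
    if (is.null(p)) sample(AA_CANONICAL, 1) else p[sample.int(length(p), 1)]
  }, character(1)), collapse = "")
}

#' Specify a synthetic sequence context
#'
#' Describes one class of synthetic records: an ordered (folded-domain
#' -like) segment followed by an intrinsically disordered segment, with
#' an optional planted motif.
#' * `r2r3_like`: a strict-pattern motif instance planted inside the
#'   disordered segment, with 15-residue flanks rewritten from a
#'   P/S/T-biased, D/E-free composition (so the three-feature context
#'   signature holds by construction);
#' * `trihelix_like`: a core-pattern instance planted inside the ordered
#'   segment (the false-positive situation);
#' * `negative`: no motif; rejection sampling guarantees no chance
#'   core-pattern match anywhere.
#'
#' @param kind `"r2r3_like"`, `"trihelix_like"` or `"negative"`.
#' @param idr_length,ordered_length Segment lengths (defaults 120, 80).
#' @param idr_composition,ordered_composition,flank_composition Named
#'   frequency vectors; see the defaults in the source.
#' @param motif_pattern Pattern to plant; defaults to `"strict"` for
#'   `r2r3_like`, `"core"` for `trihelix_like`, none for `negative`.
#' @param flank_bias Target mean of the `+PST-RK` track over the
#'   rewritten flanks (default 0.70).  The constructor checks that the
#'   supplied `flank_composition` realises this target: its expected
#'   `+PST-RK` value must match `flank_bias` within 0.02.
#' @param taxon Optional taxon tag stamped on the generated records.
#' @return Object of class `context_spec`.
#' @export
context_spec <- function(kind = c("r2r3_like", "trihelix_like", "negative"),
                         idr_length = 120L, ordered_length = 80L,
                         idr_composition = idr_composition_default(),
                         ordered_composition = ordered_composition_default(),
                         flank_composition = flank_composition_default(),
                         motif_pattern = NULL, flank_bias = 0.70,
                         taxon = NA_character_) {
  kind <- match.arg(kind)
  flank_composition <- check_composition(flank_composition, "flank_composition")
  realized <- sum(flank_composition[names(flank_composition) %in% c("P", "S", "T")]) -
    sum(flank_composition[names(flank_composition) %in% c("R", "K")])
  if (kind == "r2r3_like" && abs(realized - flank_bias) > 0.02) {
    stop(sprintf(paste0("flank_composition realises a +PST-RK bias of %.2f, ",
                        "not the flank_bias target %.2f"), realized, flank_bias),
         call. = FALSE)
  }
  if (is.null(motif_pattern) && kind != "negative") {
    motif_pattern <- if (kind == "r2r3_like") "strict" else "core"
  }
  if (!is.null(motif_pattern)) motif_pattern <- resolve_pattern(motif_pattern)
  structure(list(
    kind = kind,
    idr_length = as.integer(idr_length),
    ordered_length = as.integer(ordered_length),
    idr_composition = check_composition(idr_composition, "idr_composition"),
    ordered_composition = check_composition(ordered_composition, "ordered_composition"),
    flank_composition = check_composition(flank_composition, "flank_composition"),
    motif_pattern = motif_pattern,
    flank_bias = flank_bias,
    taxon = taxon
  ), class = "context_spec")
}

#' Generate a synthetic proteome with planted motifs
#'
#' Each record is an ordered segment followed by a disordered segment
#' sampled from the spec's composition vectors.  Motif-bearing specs
#' plant one concrete pattern instance at a uniformly chosen in-segment
#' position (disordered segment with rewritten flanks for `r2r3_like`;
#' ordered segment for `trihelix_like`).  Negative records are
#' rejection-sampled until free of any chance core-pattern match.
#'
#' @param specs A [context_spec()] or list of them.
#' @param n_per_spec Records per spec (>= 1).
#' @param rng_seed Integer seed; output is fully deterministic given
#'   specs and seed.
#' @return List with `records` (sequence-set data frame) and `truth`
#'   (data frame of planted hits: `sequence_id`, `kind`, `start`, `end`,
#'   `matched_span`, `pattern_name`; negatives contribute no rows).
#' @export
make_proteome <- function(specs, n_per_spec, rng_seed = 1L) {
  if (inherits(specs, "context_spec")) specs <- list(specs)
  stopifnot(n_per_spec >= 1)
  core <- builtin_patterns()$core
  with_seed(rng_seed, {
    recs <- list()
    truth <- list()
    serial <- 0L
    for (spec in specs) {
      for (i in seq_len(n_per_spec)) {
        serial <- serial + 1L
        id <- sprintf("%s_%04d", spec$kind, serial)
        if (spec$kind == "negative") {
          ok <- FALSE
          for (try in seq_len(1000L)) {
            ordered <- sample_composition(spec$ordered_length, spec$ordered_composition)
            idr <- sample_composition(spec$idr_length, spec$idr_composition)
            seqstr <- paste0(ordered, idr)
            if (nrow(scan_motif(seqstr, core)) == 0L) { ok <- TRUE; break }
          }
          if (!ok) {
            stop("rejection sampling failed 1000 times; ",
                 "change the negative composition", call. = FALSE)
          }
        } else {
          ordered <- sample_composition(spec$ordered_length, spec$ordered_composition)
          idr <- sample_composition(spec$idr_length, spec$idr_composition)
          instance <- sample_pattern_instance(spec$motif_pattern)
          w <- nchar(instance)
          if (spec$kind == "r2r3_like") {
            # motif inside the IDR, with rewritten exact-composition
            # flanks kept inside the IDR segment
            fl <- R2R3_FLANK_REWRITE
            lo <- fl + 1L
            hi <- spec$idr_length - w + 1L - fl
            pos_in_idr <- sample(lo:hi, 1L)
            left <- sample_composition_exact(fl, spec$flank_composition)
            right <- sample_composition_exact(fl, spec$flank_composition)
            idr_chars <- str_chars(idr)
            idr_chars[(pos_in_idr - fl):(pos_in_idr - 1L)] <- str_chars(left)
            idr_chars[pos_in_idr:(pos_in_idr + w - 1L)] <- str_chars(instance)
            idr_chars[(pos_in_idr + w):(pos_in_idr + w + fl - 1L)] <- str_chars(right)
            idr <- paste(idr_chars, collapse = "")
            start <- spec$ordered_length + pos_in_idr
          } else {
            pos <- sample(seq_len(spec$ordered_length - w + 1L), 1L)
            ordered_chars <- str_chars(ordered)
            ordered_chars[pos:(pos + w - 1L)] <- str_chars(instance)
            ordered <- paste(ordered_chars, collapse = "")
            start <- pos
          }
          seqstr <- paste0(ordered, idr)
          truth[[length(truth) + 1L]] <- data.frame(
            sequence_id = id, kind = spec$kind,
            start = start, end = start + w - 1L,
            matched_span = instance,
            pattern_name = spec$motif_pattern$name,
            stringsAsFactors = FALSE)
        }
        recs[[length(recs) + 1L]] <- data.frame(
          id = id, description = "", taxon = spec$taxon,
          residues = seqstr, stringsAsFactors = FALSE)
      }
    }
    list(records = do.call(rbind, recs),
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(sequence_id = character(), kind = character(),
                      start = integer(), end = integer(),
                      matched_span = character(), pattern_name = character(),
                      stringsAsFactors = FALSE))
  })
}

#' Generate an alignment with controlled column conservation
#'
#' Samples a uniform-random ancestral row; each derived row copies it
#' and substitutes every column independently with its column-class
#' rate (a substitution is a uniform draw from the 19 other residues).
#' No phylogeny is simulated: rows are i.i.d. given the ancestor, which
#' is sufficient for exercising the conservation contrast.
#'
#' @param n_sequences,n_columns Alignment dimensions.
#' @param motif_columns Integer set of motif column indices.
#' @param motif_rate,flank_rate Per-column substitution probabilities
#'   in \[0, 1\] for motif and non-motif columns.
#' @param rng_seed Integer seed.
#' @return List with `alignment` (an `aligned_set`), `motif_columns`
#'   and `flank_columns`.
#' @export
make_msa <- function(n_sequences, n_columns, motif_columns,
                     motif_rate = 0.05, flank_rate = 0.5, rng_seed = 1L) {
  stopifnot(n_sequences >= 1, n_columns >= 1,
            all(motif_columns >= 1), all(motif_columns <= n_columns),
            motif_rate >= 0, motif_rate <= 1,
            flank_rate >= 0, flank_rate <= 1)
  motif_columns <- unique(as.integer(motif_columns))
  rate <- rep(flank_rate, n_columns)
  rate[motif_columns] <- motif_rate
  with_seed(rng_seed, {
    ancestor <- sample(AA_CANONICAL, n_columns, replace = TRUE)
    rows <- character(n_sequences)
    for (i in seq_len(n_sequences)) {
      row <- ancestor
      mutate <- stats::runif(n_columns) < rate
      if (any(mutate)) {
        row[mutate] <- vapply(which(mutate), function(j) {
          sample(setdiff(AA_CANONICAL, ancestor[j]), 1L)
        }, character(1))
      }
      rows[i] <- paste(row, collapse = "")
    }
    aln <- aligned_set(new_seq_set(
      id = sprintf("seq_%03d", seq_len(n_sequences)),
      description = rep("", n_sequences),
      taxon = rep(NA_character_, n_sequences),
      residues = rows))
    list(alignment = aln, motif_columns = motif_columns,
         flank_columns = setdiff(seq_len(n_columns), motif_columns))
  })
}

#' Generate a chemical-shift table with known helicity
#'
#' Observed C-alpha shifts are the model's sequence-corrected
#' random-coil prediction plus `helicity_profile * full_helix_delta`
#' plus Gaussian noise.  Optional `dip_positions` have their local
#' helicity multiplied by 0.8, emulating the lowered helicity at the
#' motif's core L-N residues.
#'
#' @param sequence Residue string.
#' @param helicity_profile Per-residue fractional helicity in \[0, 1\],
#'   same length as the sequence.
#' @param dip_positions Optional integer positions whose helicity is
#'   multiplied by 0.8.
#' @param noise_sd_ppm Gaussian noise standard deviation in ppm
#'   (default 0.02).
#' @param temperature_C,pH Recording conditions stored in the table
#'   metadata (defaults 5 degrees C, pH 7.0).
#' @param first_index Residue index of the first residue (default 1;
#'   use e.g. 184 for a peptide numbered in protein coordinates).
#' @param rng_seed Integer seed.
#' @param model Random-coil model used for generation.
#' @param full_helix_delta Full-helix shift difference (ppm).
#' @return List with `shifts` (a `shift_table`) and `truth_helicity`
#'   (the maximum of the dip-adjusted helicity profile).
#' @export
make_shift_table <- function(sequence, helicity_profile, dip_positions = NULL,
                             noise_sd_ppm = 0.02, temperature_C = 5, pH = 7.0,
                             first_index = 1L, rng_seed = 1L,
                             model = random_coil_model(),
                             full_helix_delta = FULL_HELIX_DELTA_PPM) {
  x <- str_chars(toupper(sequence))
  stopifnot(length(helicity_profile) == length(x),
            all(helicity_profile >= 0), all(helicity_profile <= 1))
  h <- helicity_profile
  if (!is.null(dip_positions)) {
    stopifnot(all(dip_positions >= 1), all(dip_positions <= length(x)))
    h[dip_positions] <- h[dip_positions] * 0.8
  }
  rc <- random_coil_shifts(paste(x, collapse = ""), model, temperature_C, pH)
  noise <- with_seed(rng_seed, stats::rnorm(length(x), 0, noise_sd_ppm))
  observed <- rc + h * full_helix_delta + noise
  tab <- data.frame(residue_index = seq_along(x) + as.integer(first_index) - 1L,
                    residue_code = x,
                    ca_shift_ppm = observed,
                    stringsAsFactors = FALSE)
  shifts <- structure(tab, class = c("shift_table", "data.frame"),
                      temperature_C = temperature_C, pH = pH)
  list(shifts = shifts, truth_helicity = max(h))
}
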