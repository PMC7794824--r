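# End-to-end orchestration: scan -> context classification ->
# optional conservation contrast and helicity summary -> report files.
#
# The module-level functions remain the primary programmatic interface;
# run_pipeline() composes them with one reproducibility seed that fans
# out to per-stage seeds by fixed offsets, so any stage can be rerun in
# isolation with the same result.

STAGE_SEED_OFFSET <- c(profile = 101L, conservation = 202L, shifts = 303L)

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with documented
#' defaults.  The serialized configuration is written verbatim into the
#' output directory of [run_pipeline()].
#'
#' @param pattern Scan pattern: builtin name or pattern string
#'   (default `"core"`, the most inclusive definition; context
#'   classification then separates true-motif-like from false-positive
#'   contexts).
#' @param flank Seed flank length for the optional profile search.
#' @param evalue_cutoff,iterations Profile-search significance cutoff
#'   and refinement rounds.
#' @param exclude_taxa Taxon tags removed before profile search.
#' @param run_profile_search Whether to run the iterative profile
#'   search in addition to pattern scanning (default `FALSE`).
#' @param window,proxy_window,dip_depth,idr_cut,idr_min_length,
#'   flank_width,neighborhood Context-signature thresholds; see
#'   [classify_context()].
#' @param motif_columns,flank_columns Alignment column sets for the
#'   conservation contrast (required when an MSA is supplied).
#' @param permutations Permutations for the conservation null.
#' @param rng_seed Global seed; per-stage seeds are derived at fixed
#'   offsets.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(pattern = "core", flank = 5L,
                            evalue_cutoff = 1e-3, iterations = 5L,
                            exclude_taxa = character(),
                            run_profile_search = FALSE,
                            window = 15L, proxy_window = 21L,
                            dip_depth = 0.05, idr_cut = 0.5,
                            idr_min_length = 30L, flank_width = 15L,
                            neighborhood = 25L,
                            motif_columns = integer(), flank_columns = integer(),
                            permutations = 1000L, rng_seed = 1L) {
  structure(list(pattern = pattern, flank = flank,
                 evalue_cutoff = evalue_cutoff, iterations = iterations,
                 exclude_taxa = exclude_taxa,
                 run_profile_search = run_profile_search,
                 window = window, proxy_window = proxy_window,
                 dip_depth = dip_depth, idr_cut = idr_cut,
                 idr_min_length = idr_min_length, flank_width = flank_width,
                 neighborhood = neighborhood,
                 motif_columns = motif_columns, flank_columns = flank_columns,
                 permutations = permutations, rng_seed = rng_seed),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the end-to-end candidate analysis
#'
#' Scans the input sequences for the configured motif pattern,
#' classifies every hit's disordered-sequence context, optionally runs
#' the iterative profile search and the motif-vs-flank conservation
#' contrast, and writes a TSV report plus a JSON summary, the verbatim
#' configuration and a log into `out_dir`.  Candidates are tiered:
#' `validated-context` (core match whose context signature holds),
#' `context-mismatch` (core match whose signature fails — the
#' trihelix-like false-positive outcome), and `search-only` (profile
#' hits with no pattern match).  Outputs are deterministic given the
#' configuration seed; nothing is written if any stage fails.
#'
#' @param config A [pipeline_config()].
#' @param fasta Path to the sequence FASTA.
#' @param msa Optional path to an aligned FASTA for the conservation
#'   contrast.
#' @param shifts Optional path to a C-alpha shift table for the
#'   helicity summary.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `report` (candidate data frame),
#'   `conservation` (or `NULL`), `helicity` (or `NULL`) and the paths
#'   written.
#' @export
run_pipeline <- function(config, fasta, msa = NULL, shifts = NULL, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  db <- stage("sequence_io", {
    x <- read_fasta(fasta)
    if (nrow(x) == 0L) stop("input FASTA contains no sequences")
    x
  })
  pattern <- resolve_pattern(config$pattern)
  hits <- stage("motif_scan", scan_motif(db, pattern))
  patterns <- builtin_patterns()

  report <- NULL
  if (nrow(hits)) {
    sig_rows <- vector("list", nrow(hits))
    for (i in seq_len(nrow(hits))) {
      seqstr <- db$residues[db$id == hits$sequence_id[i]]
      sig <- stage("context_profile", classify_context(
        seqstr, hits[i, ], window = config$window,
        proxy_window = config$proxy_window, dip_depth = config$dip_depth,
        idr_cut = config$idr_cut, idr_min_length = config$idr_min_length,
        flank_width = config$flank_width, neighborhood = config$neighborhood))
      span <- hits$matched_span[i]
      sig_rows[[i]] <- cbind(
        data.frame(taxon = db$taxon[db$id == hits$sequence_id[i]],
                   matched_span = span,
                   matches_core = nrow(scan_motif(span, patterns$core)) > 0,
                   matches_strict = nrow(scan_motif(span, patterns$strict)) > 0,
                   matches_phi = nrow(scan_motif(span, patterns$phi)) > 0,
                   stringsAsFactors = FALSE),
        as.data.frame(sig))
    }
    report <- do.call(rbind, sig_rows)
    report$tier <- ifelse(report$overall_call, "validated-context", "context-mismatch")
    report <- report[c("sequence_id", "taxon", "start", "end", "matched_span",
                       "matches_core", "matches_strict", "matches_phi",
                       "order_dip", "dip_depth", "idr_context", "idr_length",
                       "net_charge_positive", "net_charge_mean",
                       "flank_bias", "flank_mean", "truncated",
                       "overall_call", "tier")]
  } else {
    report <- data.frame(sequence_id = character(), taxon = character(),
                         start = integer(), end = integer(),
                         matched_span = character(), matches_core = logical(),
                         matches_strict = logical(), matches_phi = logical(),
                         order_dip = logical(), dip_depth = numeric(),
                         idr_context = logical(), idr_length = integer(),
                         net_charge_positive = logical(),
                         net_charge_mean = numeric(), flank_bias = logical(),
                         flank_mean = numeric(), truncated = logical(),
                         overall_call = logical(), tier = character(),
                         stringsAsFactors = FALSE)
  }

  profile_hits <- NULL
  if (isTRUE(config$run_profile_search) && nrow(hits)) {
    profile_hits <- stage("profile_search", {
      seed <- build_seed(db, hits, config$flank)
      search_profile(db, seed, exclude_taxa = config$exclude_taxa,
                     evalue_cutoff = config$evalue_cutoff,
                     max_iterations = config$iterations,
                     seed_rng = config$rng_seed + STAGE_SEED_OFFSET[["profile"]])
    })
    extra <- !paste(profile_hits$sequence_id, profile_hits$start) %in%
      paste(report$sequence_id, report$start)
    if (any(extra)) {
      add <- profile_hits[extra, , drop = FALSE]
      pad <- report[rep(NA_integer_, nrow(add)), , drop = FALSE]
      pad$sequence_id <- add$sequence_id
      pad$start <- add$start
      pad$end <- add$start + (config$flank * 2L + 6L) - 1L
      pad$tier <- "search-only"
      report <- rbind(report, pad)
    }
  }

  conservation <- NULL
  if (!is.null(msa)) {
    conservation <- stage("conservation", {
      aln <- read_alignment(msa)
      motif_flank_contrast(aln, config$motif_columns, config$flank_columns,
                           permutations = config$permutations,
                           seed_rng = config$rng_seed +
                             STAGE_SEED_OFFSET[["conservation"]])
    })
  }

  helicity_summary <- NULL
  if (!is.null(shifts)) {
    helicity_summary <- stage("nmr_helicity", {
      tab <- read_shift_table(shifts)
      prof <- scs_profile(tab)
      est <- helicity(prof)
      list(profile = prof, estimate = est)
    })
  }

  report <- report[order(report$sequence_id, report$start), , drop = FALSE]
  rownames(report) <- NULL

  # all stages succeeded: write outputs
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(report = file.path(out_dir, "report.tsv"),
                config = file.path(out_dir, "config.json"),
                summary = file.path(out_dir, "summary.json"),
                log = file.path(out_dir, "run.log"))
  utils::write.table(report, paths$report, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                       digits = NA, null = "null")
  summary <- list(
    n_sequences = nrow(db),
    n_hits = nrow(report),
    tiers = as.list(table(report$tier)),
    conservation = if (!is.null(conservation)) as.list(conservation) else NULL,
    helicity = if (!is.null(helicity_summary)) list(
      peak_scs_ppm = helicity_summary$estimate$peak_scs_ppm,
      fractional_helicity = helicity_summary$estimate$fractional_helicity,
      helix_segment = helicity_summary$estimate$helix_segment) else NULL)
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA,
                       null = "null")
  writeLines(c(
    sprintf("mimscout %s on R %s.%s",
            as.character(utils::packageVersion("mimscout")),
            R.version$major, R.version$minor),
    sprintf("config_md5 %s", unname(tools::md5sum(paths$config))),
    sprintf("rng_seed %d", as.integer(config$rng_seed)),
    sprintf("pattern %s", pattern$name),
    sprintf("sequences %d hits %d", nrow(db), nrow(report))
  ), paths$log)

  invisible(list(report = report, profile_hits = profile_hits,
                 conservation = conservation, helicity = helicity_summary,
                 paths = paths))
}
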