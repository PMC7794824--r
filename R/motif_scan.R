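# Degenerate motif patterns and window scanning.
#
# The MYC-interaction motif (MIM) is the hexamer [L/F]LN[K/R][V/L]A whose
# core positions (L2, N3, A6) are absolutely required for MYC binding.
# Patterns are per-position allowed-residue sets; "x" positions accept any
# canonical residue but never the mask symbol "X".

#' Construct a degenerate motif pattern
#'
#' Parses a bracket-set pattern string such as `"[LF]LN[KR][VL]A"` or
#' `"xLNxxA"` into a per-position allowed-residue representation.
#' `x`/`X` denotes "any canonical residue"; `[...]` a residue set; a bare
#' letter a singleton.  Case-insensitive.
#'
#' @param text Pattern string.
#' @param name Pattern name used in hit tables (defaults to `text`).
#' @param core_positions Integer positions that are absolutely required
#'   for function (must be non-"any" positions); optional.
#' @return An object of class `motif_pattern`: list with `name`,
#'   `positions` (list of character vectors, `NULL` = any) and
#'   `core_mask` (logical per position).
#' @export
#' @examples
#' motif_pattern("[LF]LN[KR][VL]A", name = "strict", core_positions = c(2, 3, 6))
motif_pattern <- function(text, name = text, core_positions = NULL) {
  text <- toupper(text)
  tokens <- regmatches(text, gregexpr("\\[[A-Z]+\\]|[A-Z]", text))[[1]]
  if (paste(tokens, collapse = "") != text) {
    stop("cannot parse motif pattern: ", text, call. = FALSE)
  }
  positions <- lapply(tokens, function(tok) {
    if (tok == "X") return(NULL)  # any canonical residue
    letters <- str_chars(gsub("\\[|\\]", "", tok))
    bad <- setdiff(letters, AA_CANONICAL)
    if (length(bad)) {
      stop("non-canonical letter(s) in pattern: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    unique(letters)
  })
  if (length(positions) < 3L) stop("motif pattern must have length >= 3", call. = FALSE)
  core_mask <- rep(FALSE, length(positions))
  if (!is.null(core_positions)) {
    stopifnot(all(core_positions >= 1), all(core_positions <= length(positions)))
    if (any(vapply(positions[core_positions], is.null, logical(1)))) {
      stop("core positions must be non-'any' positions", call. = FALSE)
    }
    core_mask[core_positions] <- TRUE
  }
  structure(list(name = name, positions = positions, core_mask = core_mask),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  txt <- vapply(x$positions, function(p) {
    if (is.null(p)) "x"
    else if (length(p) == 1L) p
    else paste0("[", paste(p, collapse = ""), "]")
  }, character(1))
  cat(sprintf("motif_pattern '%s': %s (core at %s)\n", x$name,
              paste(txt, collapse = ""),
              paste(which(x$core_mask), collapse = ",")))
  invisible(x)
}

#' Built-in MIM patterns
#'
#' The three motif definitions used for MIM discovery:
#' * `core`:   `xLNxxA` — only the absolutely required positions fixed;
#' * `strict`: `[LF]LN[KR][VL]A` — the consensus observed in the
#'   confirmed MIM-containing MYB transcription factors;
#' * `phi`:    `[LVFI]LN[KR][IFLV]A` — the broader pattern used for
#'   tolerance fine-tuning in pattern-constrained similarity searches.
#'
#' All three mark positions 2, 3 and 6 (L, N, A) as core.
#'
#' @return Named list of three [motif_pattern()] objects.
#' @export
builtin_patterns <- function() {
  list(
    core   = motif_pattern("xLNxxA", name = "core", core_positions = c(2, 3, 6)),
    strict = motif_pattern("[LF]LN[KR][VL]A", name = "strict",
                           core_positions = c(2, 3, 6)),
    phi    = motif_pattern("[LVFI]LN[KR][IFLV]A", name = "phi",
                           core_positions = c(2, 3, 6))
  )
}

# Resolve a pattern argument: a motif_pattern, a builtin name, or a
# pattern string.
resolve_pattern <- function(pattern) {
  if (inherits(pattern, "motif_pattern")) return(pattern)
  if (is.character(pattern) && length(pattern) == 1L) {
    builtins <- builtin_patterns()
    if (pattern %in% names(builtins)) return(builtins[[pattern]])
    return(motif_pattern(pattern))
  }
  stop("pattern must be a motif_pattern, a builtin name, or a pattern string",
       call. = FALSE)
}

# Character class for one pattern position; "any" still excludes the
# mask symbol X (and gaps) by enumerating the canonical alphabet.
position_class <- function(allowed) {
  set <- if (is.null(allowed)) AA_CANONICAL else allowed
  paste0("[", paste(set, collapse = ""), "]")
}

empty_hits <- function() {
  data.frame(sequence_id = character(), start = integer(), end = integer(),
             matched_span = character(), pattern_name = character(),
             stringsAsFactors = FALSE)
}

#' Scan sequences for motif matches
#'
#' Reports every (possibly overlapping) window whose residues all lie in
#' the pattern's allowed sets, sorted by sequence then start.  Sequences
#' shorter than the pattern yield no hits.
#'
#' @param x A sequence-set data frame from [read_fasta()], a (optionally
#'   named) character vector of residue strings, or a single string.
#' @param pattern A [motif_pattern()], the name of a built-in pattern
#'   (`"core"`, `"strict"`, `"phi"`), or a pattern string.
#' @return Data frame of hits: `sequence_id`, `start`, `end` (1-based,
#'   inclusive), `matched_span`, `pattern_name`.
#' @export
#' @examples
#' scan_motif("SSTSKLLNKVAARASS", "core")   # the MYB29 MIM peptide
scan_motif <- function(x, pattern) {
  pattern <- resolve_pattern(pattern)
  if (is.data.frame(x)) {
    seqs <- x$residues
    ids <- x$id
  } else {
    seqs <- as.character(x)
    ids <- names(seqs)
    if (is.null(ids)) {
      ids <- if (length(seqs) == 1L) "seq1" else paste0("seq", seq_along(seqs))
    }
  }
  w <- length(pattern$positions)
  rx <- paste0("(?=", paste(vapply(pattern$positions, position_class, character(1)),
                            collapse = ""), ")")
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    if (nchar(s) < w) next
    m <- gregexpr(rx, s, perl = TRUE)[[1]]
    starts <- as.integer(m[m > 0])
    if (length(starts) == 0L || m[1] == -1L) next
    out[[i]] <- data.frame(
      sequence_id = ids[i], start = starts, end = starts + w - 1L,
      matched_span = substring(s, starts, starts + w - 1L),
      pattern_name = pattern$name, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty_hits())
  res <- do.call(rbind, out)
  res <- res[order(match(res$sequence_id, ids), res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Shift peptide-local hit coordinates into protein coordinates
#'
#' Synthetic motif peptides are numbered 1..n; this maps a hit found in
#' peptide coordinates onto the parent protein given where the peptide
#' starts in the protein.  For example the core match in the ASR3 MIM
#' peptide (peptide start 6) maps to protein residues 299-304 when the
#' peptide begins at protein residue 294.
#'
#' @param hits Hit data frame from [scan_motif()].
#' @param peptide_start_in_protein 1-based protein position of the
#'   peptide's first residue.
#' @return The hit data frame with `start`/`end` shifted; spans unchanged.
#' @export
map_to_protein <- function(hits, peptide_start_in_protein) {
  stopifnot(peptide_start_in_protein >= 1)
  offset <- as.integer(peptide_start_in_protein) - 1L
  hits$start <- hits$start + offset
  hits$end <- hits$end + offset
  hits
}
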