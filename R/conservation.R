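# Alignment-column conservation with the strict >50% consensus rule and
# a motif-vs-flank conservation contrast with a permutation null.
#
# A short linear motif embedded in an otherwise weakly constrained
# disordered region is expected to stand out as an island of
# conservation; a core-pattern match inside a conserved folded domain is
# not.  The contrast statistic below formalises that visual comparison.

#' Per-column conservation of a multiple sequence alignment
#'
#' For each column, gaps are excluded from the denominator.  A consensus
#' residue is defined only when strictly more than 50% of the non-gap
#' entries share one residue.  `identity_fraction` is the share of the
#' most frequent residue; `similarity_fraction` the share identical to
#' the consensus or in the same physicochemical group.  Column classes:
#' `consensus-identical` (consensus defined), `consensus-similar` (no
#' identity consensus, but one similarity group covers > 50%),
#' `unconserved` otherwise, and `no-consensus` for all-gap columns.
#'
#' @param msa An `aligned_set` with at least two sequences.
#' @param similarity_groups Partition of the 20 residues into groups of
#'   similar residues; default [similarity_groups_default()].
#' @return Data frame with one row per column: `column`,
#'   `consensus_residue` (`NA` when undefined), `identity_fraction`,
#'   `similarity_fraction`, `class`.
#' @export
column_conservation <- function(msa, similarity_groups = similarity_groups_default()) {
  stopifnot(inherits(msa, "aligned_set"))
  if (nrow(msa$records) < 2L) {
    stop("conservation is undefined for a single-sequence alignment", call. = FALSE)
  }
  group_of <- character(0)
  for (g in seq_along(similarity_groups)) {
    group_of[similarity_groups[[g]]] <- g
  }
  chars <- do.call(rbind, strsplit(msa$records$residues, "", fixed = TRUE))
  ncol_msa <- msa$column_count
  out <- data.frame(column = seq_len(ncol_msa),
                    consensus_residue = NA_character_,
                    identity_fraction = NA_real_,
                    similarity_fraction = NA_real_,
                    class = "no-consensus",
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol_msa)) {
    col <- chars[, j]
    col <- col[col != "-"]
    if (length(col) == 0L) next
    tab <- sort(table(col), decreasing = TRUE)
    top <- names(tab)[1]
    ident <- as.numeric(tab[1]) / length(col)
    out$identity_fraction[j] <- ident
    if (ident > 0.5) {
      out$consensus_residue[j] <- top
      sim <- mean(col == top | (!is.na(group_of[col]) &
                                  group_of[col] == group_of[top]))
      out$similarity_fraction[j] <- sim
      out$class[j] <- "consensus-identical"
    } else {
      grp <- group_of[col]
      grp_share <- if (all(is.na(grp))) 0 else max(table(grp[!is.na(grp)])) / length(col)
      out$similarity_fraction[j] <- max(ident, grp_share)
      out$class[j] <- if (grp_share > 0.5) "consensus-similar" else "unconserved"
    }
  }
  out
}

#' Motif-vs-flank conservation contrast with a permutation null
#'
#' Contrasts the mean per-column identity fraction of the motif columns
#' against that of flank columns, and assesses it by permuting the
#' motif/flank labels over the pooled columns:
#' `p = (1 + #\{permuted contrast >= observed\}) / (1 + permutations)`.
#' All-gap columns (identity undefined) are excluded from the means.
#'
#' @param msa An `aligned_set` (>= 2 sequences).
#' @param motif_columns,flank_columns Disjoint, non-empty integer sets
#'   of column indices.
#' @param permutations Number of label permutations (default 1000).
#' @param seed_rng Integer RNG seed for the permutations.
#' @param similarity_groups Passed to [column_conservation()].
#' @return One-row data frame (class `conservation_contrast`):
#'   `motif_mean`, `flank_mean`, `contrast` (= motif_mean - flank_mean),
#'   `permutation_p`.
#' @export
motif_flank_contrast <- function(msa, motif_columns, flank_columns,
                                 permutations = 1000L, seed_rng = 1L,
                                 similarity_groups = similarity_groups_default()) {
  motif_columns <- unique(as.integer(motif_columns))
  flank_columns <- unique(as.integer(flank_columns))
  if (length(motif_columns) == 0L || length(flank_columns) == 0L) {
    stop("motif and flank column sets must be non-empty", call. = FALSE)
  }
  if (length(intersect(motif_columns, flank_columns))) {
    stop("motif and flank column sets must be disjoint", call. = FALSE)
  }
  cc <- column_conservation(msa, similarity_groups)
  if (any(c(motif_columns, flank_columns) > nrow(cc))) {
    stop("column index outside the alignment", call. = FALSE)
  }
  ident <- cc$identity_fraction
  pool_idx <- c(motif_columns, flank_columns)
  pool <- ident[pool_idx]
  usable <- !is.na(pool)
  pool <- pool[usable]
  is_motif <- c(rep(TRUE, length(motif_columns)),
                rep(FALSE, length(flank_columns)))[usable]
  if (!any(is_motif) || all(is_motif)) {
    stop("motif or flank set has no usable (non-all-gap) column", call. = FALSE)
  }
  n_motif <- sum(is_motif)
  motif_mean <- mean(pool[is_motif])
  flank_mean <- mean(pool[!is_motif])
  observed <- motif_mean - flank_mean
  perm_ge <- with_seed(seed_rng, {
    cnt <- 0L
    for (b in seq_len(permutations)) {
      lab <- sample(length(pool), n_motif)
      perm <- mean(pool[lab]) - mean(pool[-lab])
      if (perm >= observed - 1e-12) cnt <- cnt + 1L
    }
    cnt
  })
  out <- data.frame(motif_mean = motif_mean, flank_mean = flank_mean,
                    contrast = observed,
                    permutation_p = (1 + perm_ge) / (1 + permutations))
  class(out) <- c("conservation_contrast", "data.frame")
  out
}
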