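# Sliding-window compositional tracks, a composition-based disorder
# proxy, and the three-feature classification of a motif hit's sequence
# context.
#
# Confirmed MIM regions in R2R3 MYB transcription factors share three
# context features: (1) the motif coincides with a local dip of order
# inside a large intrinsically disordered region; (2) the motif region
# carries an overall positive net charge (+RK-DE); (3) the flanks are
# biased towards small hydrophilic disorder-promoting residues and away
# from positive charge (+PST-RK).  Candidate hits lacking this signature
# (e.g. core matches inside ordered trihelix domains) are flagged.

# truncated-window rolling mean of a numeric vector: at position i the
# window is the intersection of i-h..i+h with 1..n and the denominator
# is the number of positions actually covered.
rolling_mean_trunc <- function(v, window) {
  n <- length(v)
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(v))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

check_window <- function(window) {
  if (length(window) != 1L || window < 3L || window %% 2L == 0L) {
    stop("window must be a single odd integer >= 3", call. = FALSE)
  }
}

#' Sliding-window residue-set composition track
#'
#' At each position, the fraction of residues from `plus_set` minus the
#' fraction from `minus_set` within a window centred there (both counted
#' over the residues the window actually covers, so values near termini
#' use a truncated denominator).  Values lie in \[-1, 1\].
#'
#' @param sequence A residue string or a one-row sequence-set data frame.
#' @param plus_set,minus_set Disjoint character vectors of residues
#'   contributing +1 and -1.
#' @param window Odd window width >= 3 (default 15).
#' @return Object of class `composition_track`: list with `name` (e.g.
#'   `"+RK-DE"`), `values` (one per residue), `window`, `plus_set`,
#'   `minus_set`.
#' @export
#' @examples
#' composition_track("SSTSKLLNKVAARASS", c("R", "K"), c("D", "E"))$values[8]
composition_track <- function(sequence, plus_set, minus_set, window = 15L) {
  check_window(window)
  if (length(intersect(plus_set, minus_set))) {
    stop("plus_set and minus_set must be disjoint", call. = FALSE)
  }
  s <- if (is.data.frame(sequence)) sequence$residues[1] else sequence
  x <- str_chars(s)
  contrib <- as.numeric(x %in% plus_set) - as.numeric(x %in% minus_set)
  structure(list(
    name = paste0("+", paste(plus_set, collapse = ""),
                  "-", paste(minus_set, collapse = "")),
    values = rolling_mean_trunc(contrib, window),
    window = as.integer(window),
    plus_set = plus_set, minus_set = minus_set
  ), class = "composition_track")
}

#' Composition-based disorder proxy track
#'
#' Window mean of a packaged per-residue disorder-propensity scale
#' (TOP-IDP; high for P, E, S, K, G, Q, strongly negative for W, F, I,
#' Y, V), min-max rescaled to \[0, 1\] over the scale's range.  This is a
#' fast compositional stand-in for sequence-specific disorder
#' predictors, adequate for contrasting disorder- vs order-biased
#' segments; it knows nothing about long-range contacts.
#'
#' @param sequence Residue string or one-row sequence-set data frame.
#' @param window Odd window width >= 3 (default 21).
#' @return Object of class `disorder_track`: list with `values` in
#'   \[0, 1\] (one per residue), `window`, `scale_name`.
#' @export
disorder_proxy <- function(sequence, window = 21L) {
  check_window(window)
  s <- if (is.data.frame(sequence)) sequence$residues[1] else sequence
  x <- str_chars(s)
  raw <- TOP_IDP[x]
  raw[is.na(raw)] <- mean(TOP_IDP)  # masked X: neutral propensity
  scaled <- (raw - min(TOP_IDP)) / (max(TOP_IDP) - min(TOP_IDP))
  structure(list(values = unname(rolling_mean_trunc(scaled, window)),
                 window = as.integer(window), scale_name = "TOP-IDP"),
            class = "disorder_track")
}

# maximal runs of `cond == TRUE`; returns data frame of start/end/length
true_runs <- function(cond) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

#' Classify the sequence context of a motif hit
#'
#' Evaluates the three-feature MIM-context signature for one hit:
#' \describe{
#'   \item{order dip within an IDR}{the disorder proxy averaged over the
#'     hit span is lower than its average over the surrounding
#'     `neighborhood` residues on each side (span excluded) by at least
#'     `dip_depth`, and the whole span lies inside a maximal run of
#'     proxy >= `idr_cut` of length >= `idr_min_length`;}
#'   \item{positive net charge}{mean of the `+RK-DE` track over the hit
#'     span extended by 5 residues each side is > 0;}
#'   \item{flank bias}{mean of the `+PST-RK` track over the two
#'     `flank_width`-residue flanks is > 0.}
#' }
#' `overall_call` is `TRUE` iff all three features hold.  Hits closer to
#' a terminus than a flank/neighborhood width are evaluated on the
#' residues that exist and flagged `truncated`.
#'
#' @param sequence Residue string or one-row sequence-set data frame.
#' @param hit One row of a [scan_motif()] hit data frame (or any list
#'   with `start` and `end`).
#' @param window Composition-track window (default 15).
#' @param proxy_window Disorder-proxy window (default 21).
#' @param dip_depth Minimum proxy drop defining a local order dip
#'   (default 0.05).
#' @param idr_cut Proxy level defining "disordered" (default 0.5).
#' @param idr_min_length Minimum IDR run length in residues (default 30).
#' @param flank_width Flank extent for the composition-bias feature
#'   (default 15).
#' @param neighborhood Residues on each side used as the dip reference
#'   (default 25).
#' @return One-row data frame (class `context_signature`):
#'   `sequence_id`, `start`, `end`, `order_dip`, `dip_depth`,
#'   `idr_context`, `idr_length`, `net_charge_positive`,
#'   `net_charge_mean`, `flank_bias`, `flank_mean`, `truncated`,
#'   `overall_call`.
#' @export
classify_context <- function(sequence, hit, window = 15L, proxy_window = 21L,
                             dip_depth = 0.05, idr_cut = 0.5,
                             idr_min_length = 30L, flank_width = 15L,
                             neighborhood = 25L) {
  s <- if (is.data.frame(sequence)) sequence$residues[1] else sequence
  n <- nchar(s)
  start <- as.integer(hit$start)
  end <- as.integer(hit$end)
  if (start < 1L || end > n || start > end) {
    stop("hit span outside the sequence", call. = FALSE)
  }
  span <- start:end
  proxy <- disorder_proxy(s, proxy_window)$values
  rk <- composition_track(s, c("R", "K"), c("D", "E"), window)$values
  pst <- composition_track(s, c("P", "S", "T"), c("R", "K"), window)$values

  clip <- function(idx) idx[idx >= 1L & idx <= n]
  left_nb <- clip((start - neighborhood):(start - 1L))
  right_nb <- clip((end + 1L):(end + neighborhood))
  surround <- c(left_nb, right_nb)
  truncated <- length(left_nb) < neighborhood || length(right_nb) < neighborhood

  depth <- if (length(surround)) mean(proxy[surround]) - mean(proxy[span]) else NA_real_
  order_dip <- isTRUE(depth >= dip_depth)

  runs <- true_runs(proxy >= idr_cut)
  containing <- runs[runs$start <= start & runs$end >= end, , drop = FALSE]
  idr_length <- if (nrow(containing)) containing$length[1] else 0L
  idr_context <- idr_length >= idr_min_length

  charge_idx <- clip((start - 5L):(end + 5L))
  net_charge_mean <- mean(rk[charge_idx])
  net_charge_positive <- net_charge_mean > 0

  left_fl <- clip((start - flank_width):(start - 1L))
  right_fl <- clip((end + 1L):(end + flank_width))
  truncated <- truncated || length(left_fl) < flank_width ||
    length(right_fl) < flank_width
  flank_idx <- c(left_fl, right_fl)
  flank_mean <- if (length(flank_idx)) mean(pst[flank_idx]) else NA_real_
  flank_bias <- isTRUE(flank_mean > 0)

  out <- data.frame(
    sequence_id = if (!is.null(hit$sequence_id)) hit$sequence_id else NA_character_,
    start = start, end = end,
    order_dip = order_dip, dip_depth = depth,
    idr_context = idr_context, idr_length = idr_length,
    net_charge_positive = net_charge_positive, net_charge_mean = net_charge_mean,
    flank_bias = flank_bias, flank_mean = flank_mean,
    truncated = truncated,
    overall_call = order_dip && idr_context && net_charge_positive && flank_bias,
    stringsAsFactors = FALSE)
  class(out) <- c("context_signature", "data.frame")
  out
}
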