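# Secondary chemical shifts (SCS) from sequence-corrected random-coil
# C-alpha references, and conversion of the SCS profile to transient
# helix calls and fractional helicity.
#
# Positive C-alpha SCS reports helical propensity; residues with
# SCS > 0.1 ppm are called transiently helical.  Fractional helicity is
# the peak SCS divided by the full-helix shift difference of 3.0 ppm,
# which maps a 0.75 ppm peak to 25% helicity and a 0.36 ppm peak to 12%.

FULL_HELIX_DELTA_PPM <- 3.0
TRANSIENT_HELIX_SCS_PPM <- 0.1

#' Packaged random-coil C-alpha shift model
#'
#' Sequence-corrected random-coil reference in the style of the
#' peptide-derived coil libraries used for intrinsically disordered
#' proteins: per-residue base C-alpha shifts, additive neighbour
#' corrections for neighbours at offsets -2..+2 (parameterised here for
#' proline neighbours, the dominant effect; all other neighbour terms
#' are zero), a linear temperature correction, and a
#' Henderson-Hasselbalch pH correction for the ionizable residues D, E
#' and H.  The packaged coefficient values are this package's own
#' edition of such a reference set; all synthetic shift tables are
#' generated from, and analysed against, this same model, so helicity
#' estimates are self-consistent whichever published edition the values
#' most resemble.
#'
#' @return Object of class `random_coil_model`: list with `base_shift`
#'   (named 20-vector, ppm), `neighbor_corrections` (20 x 4 matrix,
#'   neighbour residue x offset in c("-2","-1","+1","+2")),
#'   `temperature_coefficient` (named 20-vector, ppm per degree C),
#'   `reference_temperature_C`, and `pH_correction` (list with `pKa`,
#'   `delta` and `reference_pH`).
#' @export
random_coil_model <- function() {
  base <- c(
    A = 52.8, C = 58.6, D = 54.2, E = 56.8, F = 58.1,
    G = 45.4, H = 55.4, I = 61.6, K = 56.7, L = 55.5,
    M = 55.8, N = 53.3, P = 63.5, Q = 56.2, R = 56.5,
    S = 58.7, T = 62.0, V = 62.6, W = 57.6, Y = 58.3
  )
  nc <- matrix(0, nrow = 20, ncol = 4,
               dimnames = list(AA_CANONICAL, c("-2", "-1", "+1", "+2")))
  # a residue directly preceding a proline is shifted most strongly;
  # the residue following a proline less so
  nc["P", "+1"] <- -1.85
  nc["P", "-1"] <- -0.30
  structure(list(
    base_shift = base,
    neighbor_corrections = nc,
    temperature_coefficient = stats::setNames(rep(-0.003, 20), AA_CANONICAL),
    reference_temperature_C = 25,
    pH_correction = list(
      pKa = c(D = 3.86, E = 4.34, H = 6.45),
      delta = c(D = -0.25, E = -0.40, H = -0.55),
      reference_pH = 6.5
    )
  ), class = "random_coil_model")
}

#' Sequence-corrected random-coil C-alpha shifts
#'
#' Per residue: base shift + neighbour corrections for the residues at
#' offsets -2..+2 (neighbours beyond the termini contribute 0) +
#' temperature coefficient times (T - reference temperature) + pH
#' correction (protonation-fraction change relative to the model's
#' reference pH, for D, E, H).
#'
#' @param sequence Residue string (canonical letters only).
#' @param model A [random_coil_model()].
#' @param temperature_C Sample temperature in degrees C (0-100,
#'   default 5).
#' @param pH Sample pH (0-14, default 7.0).
#' @return Numeric vector of predicted coil shifts (ppm), one per
#'   residue.
#' @export
random_coil_shifts <- function(sequence, model = random_coil_model(),
                               temperature_C = 5, pH = 7.0) {
  stopifnot(temperature_C > 0, temperature_C < 100, pH > 0, pH < 14)
  x <- str_chars(toupper(sequence))
  missing <- setdiff(unique(x), names(model$base_shift))
  if (length(missing)) {
    stop("residue(s) missing from the random-coil table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- length(x)
  shifts <- unname(model$base_shift[x])
  offsets <- c(-2L, -1L, 1L, 2L)
  cols <- c("-2", "-1", "+1", "+2")
  for (k in seq_along(offsets)) {
    nb <- seq_len(n) + offsets[k]
    ok <- nb >= 1L & nb <= n
    shifts[ok] <- shifts[ok] + model$neighbor_corrections[x[nb[ok]], cols[k]]
  }
  shifts <- shifts + unname(model$temperature_coefficient[x]) *
    (temperature_C - model$reference_temperature_C)
  ph <- model$pH_correction
  f_prot <- function(pka, p) 1 / (1 + 10^(p - pka))
  for (res in names(ph$pKa)) {
    idx <- x == res
    if (any(idx)) {
      shifts[idx] <- shifts[idx] + ph$delta[[res]] *
        (f_prot(ph$pKa[[res]], pH) - f_prot(ph$pKa[[res]], ph$reference_pH))
    }
  }
  shifts
}

#' Secondary chemical shift profile
#'
#' SCS = observed C-alpha shift minus the sequence-corrected random-coil
#' prediction, per residue.  Residues with SCS > 0.1 ppm are flagged as
#' transiently helical.
#'
#' @param shifts A `shift_table` from [read_shift_table()] (temperature
#'   and pH are taken from its attributes).
#' @param sequence Residue string covering the table's index range; by
#'   default reconstructed from the table's `residue_code` column, which
#'   requires contiguous indices.  Supply the sequence explicitly when
#'   the table has gaps.
#' @param model A [random_coil_model()].
#' @return Data frame of class `scs_profile`: `residue_index`,
#'   `residue_code`, `scs_ca_ppm`, `transient_helix`.
#' @export
scs_profile <- function(shifts, sequence = NULL, model = random_coil_model()) {
  idx <- shifts$residue_index
  first <- idx[1]
  if (is.null(sequence)) {
    if (!all(diff(idx) == 1L)) {
      stop("shift table indices are not contiguous; supply `sequence`",
           call. = FALSE)
    }
    sequence <- paste(shifts$residue_code, collapse = "")
  }
  seq_chars <- str_chars(toupper(sequence))
  pos <- idx - first + 1L
  if (any(pos < 1L | pos > length(seq_chars))) {
    stop("shift table indices extend beyond the supplied sequence", call. = FALSE)
  }
  mismatch <- which(seq_chars[pos] != toupper(shifts$residue_code))
  if (length(mismatch)) {
    stop(sprintf("sequence/table mismatch at residue index %d ('%s' vs '%s')",
                 idx[mismatch[1]], seq_chars[pos[mismatch[1]]],
                 shifts$residue_code[mismatch[1]]), call. = FALSE)
  }
  temperature_C <- attr(shifts, "temperature_C")
  pH <- attr(shifts, "pH")
  if (is.null(temperature_C)) temperature_C <- 5
  if (is.null(pH)) pH <- 7.0
  rc <- random_coil_shifts(paste(seq_chars, collapse = ""), model,
                           temperature_C, pH)
  scs <- shifts$ca_shift_ppm - rc[pos]
  out <- data.frame(residue_index = idx,
                    residue_code = toupper(shifts$residue_code),
                    scs_ca_ppm = scs,
                    transient_helix = scs > TRANSIENT_HELIX_SCS_PPM,
                    stringsAsFactors = FALSE)
  class(out) <- c("scs_profile", "data.frame")
  out
}

#' Fractional helicity from an SCS profile
#'
#' The peak (maximum) C-alpha SCS is converted to fractional helicity by
#' dividing by the full-helix shift difference (3.0 ppm), clamped to
#' \[0, 1\].  The helix segment is the maximal contiguous run of
#' transient-helix residues (SCS > 0.1) containing the peak; it is empty
#' when the peak itself does not exceed 0.1 ppm.
#'
#' @param profile An `scs_profile`.
#' @param method `"peak"` (default) divides the peak SCS by
#'   `full_helix_delta`; `"segment_mean"` divides the mean SCS over the
#'   helix segment instead.
#' @param full_helix_delta Full-helix C-alpha shift difference in ppm
#'   (default 3.0).
#' @return List of class `helicity_estimate`: `peak_scs_ppm`,
#'   `fractional_helicity` in \[0, 1\], `helix_segment` (integer vector
#'   `c(first, last)` of residue indices, or `integer(0)`).
#' @export
#' @examples
#' prof <- data.frame(residue_index = 1:3, residue_code = c("A", "L", "A"),
#'                    scs_ca_ppm = c(0.1, 0.75, 0.2),
#'                    transient_helix = c(FALSE, TRUE, TRUE))
#' class(prof) <- c("scs_profile", "data.frame")
#' helicity(prof)$fractional_helicity  # 0.25
helicity <- function(profile, method = c("peak", "segment_mean"),
                     full_helix_delta = FULL_HELIX_DELTA_PPM) {
  method <- match.arg(method)
  stopifnot(nrow(profile) >= 1L)
  peak_pos <- which.max(profile$scs_ca_ppm)
  peak <- profile$scs_ca_ppm[peak_pos]
  segment <- integer(0)
  if (peak > TRANSIENT_HELIX_SCS_PPM) {
    runs <- true_runs(profile$scs_ca_ppm > TRANSIENT_HELIX_SCS_PPM)
    r <- runs[runs$start <= peak_pos & runs$end >= peak_pos, , drop = FALSE]
    segment <- c(profile$residue_index[r$start[1]], profile$residue_index[r$end[1]])
  }
  stat <- if (method == "peak" || length(segment) == 0L) peak else
    mean(profile$scs_ca_ppm[profile$residue_index >= segment[1] &
                              profile$residue_index <= segment[2]])
  structure(list(peak_scs_ppm = peak,
                 fractional_helicity = min(1, max(0, stat / full_helix_delta)),
                 helix_segment = segment),
            class = "helicity_estimate")
}

#' @export
print.helicity_estimate <- function(x, ...) {
  seg <- if (length(x$helix_segment)) {
    sprintf("%d-%d", x$helix_segment[1], x$helix_segment[2])
  } else "none"
  cat(sprintf("peak SCS %.3f ppm -> %.1f%% helicity (helix segment %s)\n",
              x$peak_scs_ppm, 100 * x$fractional_helicity, seg))
  invisible(x)
}
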