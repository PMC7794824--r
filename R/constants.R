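# Shared alphabets and residue-property scales.

#' The twenty canonical amino-acid one-letter codes
#'
#' Alphabetically ordered vector of the canonical residue codes used
#' throughout the package.  Sequences containing anything else are rejected
#' (policy `"strict"`) or masked to `"X"` (policy `"mask"`).
#'
#' @format Character vector of length 20.
#' @export
AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Internal symbol used to pad seed-alignment members truncated by a
# sequence terminus; scores 0 bits and contributes background counts.
PAD_SYMBOL <- "."

# TOP-IDP disorder propensity scale (Campen et al. 2008): per-residue
# tendency to occur in intrinsically disordered regions.  High values for
# P, E, K, S, Q; strongly negative for W, F, Y, I.  Used (after min-max
# rescaling to [0, 1]) as the packaged composition-based disorder proxy.
TOP_IDP <- c(
  A =  0.060, C =  0.020, D =  0.192, E =  0.736, F = -0.697,
  G =  0.166, H =  0.303, I = -0.486, K =  0.586, L = -0.326,
  M = -0.397, N =  0.007, P =  0.987, Q =  0.318, R =  0.180,
  S =  0.341, T =  0.059, V = -0.121, W = -0.884, Y = -0.510
)

#' Default physicochemical similarity groups
#'
#' Partition of the 20 canonical residues into groups considered
#' "similar" when classifying alignment columns: aliphatic/hydrophobic
#' (AVLIM), aromatic (FWY), small hydroxyl (ST), basic (KR), acidic (DE),
#' amide (NQ), and the singletons C, G, P, H.
#'
#' @return A named list of character vectors partitioning [AA_CANONICAL].
#' @export
similarity_groups_default <- function() {
  list(
    aliphatic = c("A", "V", "L", "I", "M"),
    aromatic  = c("F", "W", "Y"),
    hydroxyl  = c("S", "T"),
    basic     = c("K", "R"),
    acidic    = c("D", "E"),
    amide     = c("N", "Q"),
    C = "C", G = "G", P = "P", H = "H"
  )
}

# Run code with a temporarily-fixed RNG state, restoring (or clearing)
# the caller's state afterwards.  All stochastic entry points funnel
# their `seed_rng`/`rng_seed` argument through this helper so identical
# seeds give identical results without disturbing the session RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Split a residue string into single characters.
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
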