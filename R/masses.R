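# Residue mass tables and peptide mass arithmetic.
#
# Average masses are the working default throughout: the intended use case is
# 4-5 kDa peptides measured on ion-trap instruments reporting m/z to two
# decimals, where isotope envelopes are unresolved and deconvolved masses are
# average-scale quantities. Monoisotopic masses are provided for completeness.

# Standard residue masses in Da (residue = amino acid minus water).
.RESIDUE_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.RESIDUE_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.WATER_MONO <- 18.010565
.WATER_AVG <- 18.0153
.PROTON <- 1.007276

.AA3 <- c(
  G = "Gly", A = "Ala", S = "Ser", P = "Pro", V = "Val", T = "Thr",
  C = "Cys", L = "Leu", I = "Ile", N = "Asn", D = "Asp", Q = "Gln",
  K = "Lys", E = "Glu", M = "Met", H = "His", F = "Phe", R = "Arg",
  Y = "Tyr", W = "Trp"
)

.match_scale <- function(scale) {
  match.arg(scale, c("average", "monoisotopic"))
}

#' Residue and constant mass table
#'
#' Masses of the 20 standard amino acid residues on the monoisotopic and
#' average scales, together with the water and proton constants used by all
#' mass arithmetic in the package.
#'
#' @return A list with components `residues` (data frame with columns
#'   `residue`, `mono_mass`, `avg_mass`), `water_mono`, `water_avg` and
#'   `proton`, all in Da.
#' @examples
#' residue_mass_table()$water_avg
#' @export
residue_mass_table <- function() {
  list(
    residues = data.frame(
      residue = names(.RESIDUE_AVG),
      mono_mass = unname(.RESIDUE_MONO[names(.RESIDUE_AVG)]),
      avg_mass = unname(.RESIDUE_AVG),
      stringsAsFactors = FALSE
    ),
    water_mono = .WATER_MONO,
    water_avg = .WATER_AVG,
    proton = .PROTON
  )
}

.residue_masses <- function(scale) {
  if (scale == "average") .RESIDUE_AVG else .RESIDUE_MONO
}

.water_mass <- function(scale) {
  if (scale == "average") .WATER_AVG else .WATER_MONO
}

.check_seq <- function(seq, arg = "seq") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(sprintf("`%s` must be a single amino-acid string", arg), call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% names(.RESIDUE_AVG)))
  if (length(bad) > 0L) {
    stop(sprintf(
      "unknown residue '%s' at position %d of `%s`",
      chars[bad[1L]], bad[1L], arg
    ), call. = FALSE)
  }
  chars
}

#' Neutral peptide mass from an amino-acid sequence
#'
#' Sums the residue masses of `seq` on the chosen scale and adds one water
#' mass (the peptide termini). The empty sequence therefore returns the mass
#' of water.
#'
#' @param seq Amino-acid string using the 20 standard one-letter codes.
#' @param scale `"average"` (default) or `"monoisotopic"`.
#' @return Neutral mass in Da.
#' @examples
#' peptide_mass("G")            # 75.0672 Da
#' peptide_mass("GG") - peptide_mass("G")  # one Gly residue, 57.0519 Da
#' @export
peptide_mass <- function(seq, scale = c("average", "monoisotopic")) {
  scale <- .match_scale(scale)
  if (length(seq) > 1L) {
    return(vapply(seq, peptide_mass, numeric(1L), scale = scale,
                  USE.NAMES = !is.null(names(seq))))
  }
  masses <- .residue_masses(scale)
  if (!nzchar(seq)) {
    return(.water_mass(scale))
  }
  chars <- .check_seq(seq)
  sum(masses[chars]) + .water_mass(scale)
}

#' Count dehydratable residues (Ser + Thr)
#'
#' @param seq Amino-acid string.
#' @return Number of Ser and Thr residues in `seq`.
#' @export
count_ser_thr <- function(seq) {
  chars <- .check_seq(seq)
  sum(chars %in% c("S", "T"))
}

#' Mass of a peptide after n dehydrations
#'
#' Lanthipeptide maturation dehydrates Ser/Thr to Dha/Dhb, each event removing
#' one water. The dehydration count can therefore not exceed the Ser+Thr
#' count of the sequence.
#'
#' @param seq Amino-acid string.
#' @param n_dehydr Non-negative integer number of dehydrations.
#' @inheritParams peptide_mass
#' @return Neutral mass in Da of the `n_dehydr`-fold dehydrated peptide.
#' @examples
#' dehydrated_mass("AST", 2)  # two waters lighter than peptide_mass("AST")
#' @export
dehydrated_mass <- function(seq, n_dehydr, scale = c("average", "monoisotopic")) {
  scale <- .match_scale(scale)
  if (!is.numeric(n_dehydr) || length(n_dehydr) != 1L || is.na(n_dehydr) ||
      n_dehydr < 0 || n_dehydr != round(n_dehydr)) {
    stop("`n_dehydr` must be a single non-negative integer", call. = FALSE)
  }
  st <- count_ser_thr(seq)
  if (n_dehydr > st) {
    stop(sprintf(
      "n_dehydr (%d) exceeds the Ser+Thr count of the sequence (%d)",
      as.integer(n_dehydr), st
    ), call. = FALSE)
  }
  peptide_mass(seq, scale) - n_dehydr * .water_mass(scale)
}

#' Deconvolve a neutral mass from one (m/z, z) signal
#'
#' Applies the positive electrospray convention for an \eqn{[M+zH]^{z+}} ion:
#' \eqn{M = z (m/z - m_p)} with \eqn{m_p = 1.007276} Da.
#'
#' @param mz Observed mass-to-charge ratio in Thomson.
#' @param z Positive integer charge state.
#' @return Neutral mass M in Da. Vectorised over `mz`/`z`.
#' @examples
#' mass_from_mz(1135.07, 4)  # 4536.25 Da
#' @export
mass_from_mz <- function(mz, z) {
  .check_signal(mz, z)
  z * (mz - .PROTON)
}

#' m/z of an [M+zH]z+ ion from a neutral mass
#'
#' Exact inverse of [mass_from_mz()] at full floating-point precision.
#'
#' @param M Neutral mass in Da, positive.
#' @param z Positive integer charge state.
#' @return m/z in Thomson. Vectorised.
#' @examples
#' mz_from_mass(4536.25, 4)  # 1135.07 Th
#' @export
mz_from_mass <- function(M, z) {
  if (!is.numeric(M) || any(is.na(M)) || any(M <= 0)) {
    stop("`M` must be positive", call. = FALSE)
  }
  if (!is.numeric(z) || any(is.na(z)) || any(z < 1) || any(z != round(z))) {
    stop("`z` must be a positive integer charge (z = 0 is not an ion)",
         call. = FALSE)
  }
  (M + z * .PROTON) / z
}

.check_signal <- function(mz, z) {
  if (!is.numeric(mz) || any(is.na(mz)) || any(mz <= 0)) {
    stop("`mz` must be positive", call. = FALSE)
  }
  if (!is.numeric(z) || any(is.na(z)) || any(z < 1) || any(z != round(z))) {
    stop("`z` must be a positive integer charge", call. = FALSE)
  }
  invisible(TRUE)
}

#' Consensus neutral mass across charge states
#'
#' Deconvolves every supplied signal and checks that the per-signal masses
#' agree within `window` Da; disagreement beyond the window means the signals
#' cannot come from one analyte and is reported as an error rather than
#' averaged away. The full-precision `value` is the mean of the per-signal
#' masses. The `integer_report` follows the convention of low-resolution
#' ion-trap reporting for multiply charged peptides: it truncates (floors)
#' the mass deconvolved from the highest charge state, whose m/z error per
#' unit mass is smallest.
#'
#' @param signals Data frame with numeric columns `mz` and `z`, one row per
#'   observed signal of the same analyte.
#' @param window Maximum allowed spread (max - min, Da) of the per-signal
#'   deconvolved masses. Default 3 Da, the observed spread of 3+/4+ pairs on
#'   two-decimal ion-trap data.
#' @return An object of class `neutral_mass`: a list with `value` (Da, full
#'   precision), `integer_report` (integer Da), `source_signals` (the input
#'   data frame with a `mass` column added) and `scale`.
#' @examples
#' consensus_mass(data.frame(mz = c(1512.89, 1135.07), z = c(3, 4)))
#' @export
consensus_mass <- function(signals, window = 3) {
  if (!is.data.frame(signals) || !all(c("mz", "z") %in% names(signals)) ||
      nrow(signals) < 1L) {
    stop("`signals` must be a data frame with columns `mz` and `z` and at least one row",
         call. = FALSE)
  }
  .check_signal(signals$mz, signals$z)
  masses <- mass_from_mz(signals$mz, signals$z)
  spread <- max(masses) - min(masses)
  if (spread > window) {
    stop(sprintf(
      paste0("conflicting signal set: deconvolved masses span %.2f Da ",
             "(window %.2f Da); no consensus emitted"),
      spread, window
    ), call. = FALSE)
  }
  top <- which(signals$z == max(signals$z))
  structure(
    list(
      value = mean(masses),
      integer_report = as.integer(floor(mean(masses[top]))),
      source_signals = cbind(signals, mass = masses),
      scale = "average"
    ),
    class = "neutral_mass"
  )
}

#' @export
print.neutral_mass <- function(x, ...) {
  cat(sprintf("Neutral mass: %.4f Da (reported %d Da) from %d signal(s), z = %s\n",
              x$value, x$integer_report, nrow(x$source_signals),
              paste(sort(unique(x$source_signals$z)), collapse = "/")))
  invisible(x)
}

#' Number of dehydrations explaining a mass deficit
#'
#' Divides an observed mass deficit (calculated unmodified mass minus
#' observed mass) by the water mass and rounds to the nearest integer. The
#' residual from an exact multiple is returned for quality control; residuals
#' above `residual_threshold` flag the call as low confidence.
#'
#' @param deficit Non-negative mass deficit in Da.
#' @inheritParams peptide_mass
#' @param residual_threshold Residual (Da) above which the count is flagged
#'   low confidence. Default 2 Da.
#' @return List with `n` (integer), `residual` (Da) and `low_confidence`
#'   (logical).
#' @examples
#' infer_dehydration_count(144)  # n = 8: loss of eight waters
#' @export
infer_dehydration_count <- function(deficit,
                                    scale = c("average", "monoisotopic"),
                                    residual_threshold = 2.0) {
  scale <- .match_scale(scale)
  if (!is.numeric(deficit) || length(deficit) != 1L || is.na(deficit) ||
      deficit < 0) {
    stop("`deficit` must be a single non-negative number", call. = FALSE)
  }
  w <- .water_mass(scale)
  n <- round(deficit / w)
  residual <- abs(deficit - n * w)
  list(n = as.integer(n), residual = residual,
       low_confidence = residual > residual_threshold)
}

#' Residues whose mass explains an inter-peptide mass difference
#'
#' Finds every standard residue whose residue mass on the chosen scale lies
#' within `tol` of `delta`. Leu and Ile are isobaric and always co-reported:
#' if one is within tolerance both appear. An empty result means no
#' single-residue explanation exists at this tolerance, which is a valid
#' answer, not an error.
#'
#' @param delta Positive mass difference in Da.
#' @param tol Matching tolerance in Da. Default 0.5.
#' @inheritParams peptide_mass
#' @return Character vector of one-letter codes (possibly empty), named by
#'   three-letter codes.
#' @examples
#' residue_from_delta(57)   # Gly
#' residue_from_delta(113)  # Leu/Ile isobaric pair
#' @export
residue_from_delta <- function(delta, tol = 0.5,
                               scale = c("average", "monoisotopic")) {
  scale <- .match_scale(scale)
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta <= 0) {
    stop("`delta` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(tol) || length(tol) != 1L || is.na(tol) || tol <= 0) {
    stop("`tol` must be positive", call. = FALSE)
  }
  masses <- .residue_masses(scale)
  hit <- names(masses)[abs(masses - delta) <= tol]
  if (any(c("L", "I") %in% hit)) {
    hit <- union(hit, c("L", "I"))
  }
  # stable, mass-ordered output
  hit <- hit[order(masses[hit])]
  stats::setNames(hit, .AA3[hit])
}
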