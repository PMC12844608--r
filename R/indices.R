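#' Partial relative yield total
#'
#' The partial relative yield total (partial land equivalent ratio) of one
#' component: its mixture performance relative to the sown share of its pure
#' stand, `idm / (sdm * z)`. A value of 1 means the component yields exactly
#' its sown share of the pure stand.
#'
#' @param idm Component performance inside the mixture.
#' @param sdm Pure-stand performance of the same component; must be > 0.
#' @param z Sown proportion of the component in the mixture, in (0, 1].
#' @return Dimensionless partial RYT.
#' @export
#' @examples
#' ryt_partial(1.48, 4.03, 0.5) # clover partial RYT, ~0.73
ryt_partial <- function(idm, sdm, z) {
  if (any(sdm <= 0)) abort_undefined("ryt", "ryt_partial undefined: sdm must be > 0")
  if (any(z <= 0) || any(z > 1)) abort_undefined("ryt", "ryt_partial undefined: z must be in (0, 1]")
  idm / (sdm * z)
}

#' Total relative yield total
#'
#' Sum of the two partial relative yield totals. Values above 1 indicate a
#' yield advantage of the mixture over pure stands; 1 means parity.
#' Numerically identical to the land equivalent ratio.
#'
#' @param ryt_ir,ryt_c Partial RYT of the two components.
#' @return Dimensionless total RYT.
#' @export
ryt_total <- function(ryt_ir, ryt_c) {
  if (any(!is.finite(ryt_ir)) || any(!is.finite(ryt_c))) {
    abort_undefined("ryt_total", "ryt_total undefined: partial RYTs must be finite")
  }
  ryt_ir + ryt_c
}

#' Land equivalent coefficient
#'
#' Measures the strength of the interaction between the component crops. For
#' a two-crop mixture, values above 0.25 (the product of two components each
#' at minimum 50% relative productivity) indicate an advantage.
#'
#' Two variants are provided. `"ryt_product"` (default) is the product of the
#' two partial RYTs, i.e. with sown proportions in the denominators.
#' `"raw_ratio_product"` is the product of the raw mixture/pure-stand ratios
#' `(idm_ir/sdm_ir) * (idm_c/sdm_c)` without sown proportions. At z = 0.5/0.5
#' the two differ by a factor of 4; the default follows the RYT-product
#' definition, which is the one on the scale of reported LEC values near 1
#' for this kind of trial.
#'
#' @param pair A stand pair (see [stand_pair()]).
#' @param variant `"ryt_product"` or `"raw_ratio_product"`.
#' @return Dimensionless LEC.
#' @export
lec <- function(pair, variant = c("ryt_product", "raw_ratio_product")) {
  variant <- match.arg(variant)
  p <- as_stand_pair(pair)
  if (p$sdm_ir <= 0 || p$sdm_c <= 0) {
    abort_undefined("lec", "lec undefined: pure-stand performances must be > 0")
  }
  if (variant == "ryt_product") {
    ryt_partial(p$idm_ir, p$sdm_ir, p$z_ir) * ryt_partial(p$idm_c, p$sdm_c, p$z_c)
  } else {
    (p$idm_ir / p$sdm_ir) * (p$idm_c / p$sdm_c)
  }
}

#' System productivity index
#'
#' Converts the secondary crop's (clover) yield into primary-crop (grass)
#' equivalents via the ratio of pure-stand productivities:
#' `idm_ir + (sdm_ir / sdm_c) * idm_c`. Reported in kg/ha: dry-matter
#' inputs in t/ha are scaled by 1000; nitrogen-basis inputs are already
#' kg/ha.
#'
#' @param pair A stand pair.
#' @return SPI in kg/ha of primary-crop equivalents.
#' @export
spi <- function(pair) {
  p <- as_stand_pair(pair)
  if (p$sdm_c <= 0) abort_undefined("spi", "spi undefined: sdm_c must be > 0")
  scale <- if (identical(p$basis, "dmy")) 1000 else 1
  (p$idm_ir + (p$sdm_ir / p$sdm_c) * p$idm_c) * scale
}

#' Area-time equivalent ratio
#'
#' A modification of the relative yield total that weights each component's
#' partial RYT by the fraction of the system's duration it occupies the
#' field: `(ryt_ir * d_ir + ryt_c * d_c) / t_total`. When both components
#' occupy the field for the whole duration (d_ir = d_c = t_total, as in a
#' fully overlapping winter catch crop mixture) ATER equals the total RYT.
#'
#' @param ryt_ir,ryt_c Partial RYT of the two components.
#' @param d_ir,d_c Days each component occupies the field.
#' @param t_total Days the system occupies the field; must be > 0.
#' @return Dimensionless ATER.
#' @export
ater <- function(ryt_ir, ryt_c, d_ir, d_c, t_total) {
  if (any(t_total <= 0)) abort_undefined("ater", "ater undefined: t_total must be > 0")
  (ryt_ir * d_ir + ryt_c * d_c) / t_total
}

#' Percentage yield difference
#'
#' Percent difference in yield between the intercrop and its pure stands,
#' `100 * (idm_ir/sdm_ir + idm_c/sdm_c - 1)`. Zero marks a neutral mixture
#' (each component at exactly half its pure stand under 50:50 sowing); 100
#' marks full compensation (each component matching its pure stand).
#'
#' @param pair A stand pair.
#' @return PYD in percent.
#' @export
pyd <- function(pair) {
  p <- as_stand_pair(pair)
  if (p$sdm_ir <= 0 || p$sdm_c <= 0) {
    abort_undefined("pyd", "pyd undefined: pure-stand performances must be > 0")
  }
  100 * (p$idm_ir / p$sdm_ir + p$idm_c / p$sdm_c - 1)
}

#' Land-use efficiency
#'
#' A composite of the total RYT and the ATER expressed as a percentage.
#' The default variant computes `(ryt_total + ater/2) * 100`; the
#' `"conventional"` variant computes the plain mean
#' `((ryt_total + ater) / 2) * 100`. With equal durations the two coincide
#' only at RYT = 0, so the choice matters; the default is the form on the
#' scale of LUE values above 300% reported for strongly complementary
#' mixtures with RYT = ATER above 2.
#'
#' @param ryt_total Total relative yield total.
#' @param ater Area-time equivalent ratio.
#' @param variant `"paper_printed"` (default) or `"conventional"`.
#' @return LUE in percent.
#' @export
lue <- function(ryt_total, ater, variant = c("paper_printed", "conventional")) {
  variant <- match.arg(variant)
  if (any(!is.finite(ryt_total)) || any(!is.finite(ater))) {
    abort_undefined("lue", "lue undefined: inputs must be finite")
  }
  if (variant == "paper_printed") (ryt_total + ater / 2) * 100
  else ((ryt_total + ater) / 2) * 100
}

#' Competitive ratio
#'
#' Ratio of the two components' relative yields, adjusted for sown
#' proportions: `cr_ir = [(idm_ir/sdm_ir) / (idm_c/sdm_c)] * (z_c/z_ir)`.
#' The stronger competitor has CR > 1. `cr_c` is returned as the exact
#' reciprocal so that `cr_ir * cr_c == 1` holds identically. A zero mixture
#' performance of the other crop yields an infinite ratio (flagged value,
#' not an error), so batch pipelines keep running.
#'
#' @param pair A stand pair.
#' @return Named list with `cr_ir` and `cr_c`.
#' @export
competitive_ratio <- function(pair) {
  p <- as_stand_pair(pair)
  if (p$sdm_ir <= 0 || p$sdm_c <= 0) {
    abort_undefined("cr", "competitive ratio undefined: pure-stand performances must be > 0")
  }
  if (p$z_ir <= 0 || p$z_c <= 0) {
    abort_undefined("cr", "competitive ratio undefined: sown proportions must be > 0")
  }
  cr_ir <- ((p$idm_ir / p$sdm_ir) / (p$idm_c / p$sdm_c)) * (p$z_c / p$z_ir)
  list(cr_ir = cr_ir, cr_c = 1 / cr_ir)
}

#' Aggressivity
#'
#' Signed difference of the components' relative yields,
#' `a_ir = idm_ir/(sdm_ir*z_ir) - idm_c/(sdm_c*z_c)`; positive for the
#' dominant species. Antisymmetric by construction: `a_c = -a_ir` exactly.
#'
#' @param pair A stand pair.
#' @return Named list with `a_ir` and `a_c`.
#' @export
aggressivity <- function(pair) {
  p <- as_stand_pair(pair)
  a_ir <- ryt_partial(p$idm_ir, p$sdm_ir, p$z_ir) -
    ryt_partial(p$idm_c, p$sdm_c, p$z_c)
  list(a_ir = a_ir, a_c = -a_ir)
}

#' Relative crowding coefficient
#'
#' Hyperbolic dominance measure per component,
#' `rcc_ir = (idm_ir * z_c) / ((sdm_ir - idm_ir) * z_ir)` and symmetrically
#' for C; the product is the system-level coefficient, with product > 1
#' indicating an intercropping benefit.
#'
#' The denominator vanishes when a component's mixture performance reaches
#' its pure stand: `idm == sdm` returns `Inf` (flagged, not an error), and
#' `idm > sdm` returns the signed (negative-denominator) value with a
#' dominance warning, since the coefficient loses its interpretation there.
#'
#' @param pair A stand pair.
#' @return Named list with `rcc_ir`, `rcc_c` and `rcc_total`
#'   (`= rcc_ir * rcc_c`).
#' @export
rcc <- function(pair) {
  p <- as_stand_pair(pair)
  if (p$sdm_ir <= 0 || p$sdm_c <= 0) {
    abort_undefined("rcc", "rcc undefined: pure-stand performances must be > 0")
  }
  one <- function(idm, sdm, z_self, z_other, comp) {
    den <- (sdm - idm) * z_self
    if (den == 0) return(Inf)
    if (den < 0) {
      warn(paste0("rcc_", comp, ": mixture performance exceeds the pure stand; ",
                  "coefficient is negative and loses its crowding interpretation"),
           class = "intercrop_dominance_warning")
    }
    (idm * z_other) / den
  }
  rcc_ir <- one(p$idm_ir, p$sdm_ir, p$z_ir, p$z_c, "ir")
  rcc_c <- one(p$idm_c, p$sdm_c, p$z_c, p$z_ir, "c")
  list(rcc_ir = rcc_ir, rcc_c = rcc_c, rcc_total = rcc_ir * rcc_c)
}

#' Actual yield loss
#'
#' Per-sown-share gain (> 0) or loss (< 0) of each component relative to its
#' pure stand: `ayl_i = idm_i / (sdm_i * z_i) - 1`, with the total the sum of
#' the two partials. The sown proportions default to those of the stand pair
#' but can be overridden per call, because AYL is the one index whose
#' published applications vary in the land-share convention they plug in.
#'
#' @param pair A stand pair.
#' @param z_override_ir,z_override_c Optional sown-share overrides in (0, 1].
#' @return Named list with `ayl_ir`, `ayl_c` and `ayl_total`.
#' @export
ayl <- function(pair, z_override_ir = NULL, z_override_c = NULL) {
  p <- as_stand_pair(pair)
  z_ir <- z_override_ir %||% p$z_ir
  z_c <- z_override_c %||% p$z_c
  ayl_ir <- ryt_partial(p$idm_ir, p$sdm_ir, z_ir) - 1
  ayl_c <- ryt_partial(p$idm_c, p$sdm_c, z_c) - 1
  list(ayl_ir = ayl_ir, ayl_c = ayl_c, ayl_total = ayl_ir + ayl_c)
}

#' Percentage of land saved
#'
#' Land spared by intercropping relative to growing the pure stands,
#' `100 - 100 / ryt_total`; monotone increasing in the total RYT, 0 at
#' RYT = 1.
#'
#' @param ryt_total Total relative yield total; must be > 0.
#' @return Percent of land saved.
#' @export
lsav <- function(ryt_total) {
  if (any(!is.finite(ryt_total)) || any(ryt_total <= 0)) {
    abort_undefined("lsav", "lsav undefined: ryt_total must be finite and > 0")
  }
  100 - (1 / ryt_total) * 100
}

#' Competitive balance index
#'
#' Logarithm of the ratio of the two components' relative performances,
#' `log[(idm_ir/sdm_ir) / (idm_c/sdm_c)]`. Zero indicates balanced
#' competition; the sign marks the dominant component. The natural log is
#' the default; base 10 is available.
#'
#' @param pair A stand pair; all four performances must be > 0.
#' @param log_base `"natural"` (default) or `"log10"`.
#' @return Dimensionless signed Cb.
#' @export
cb <- function(pair, log_base = c("natural", "log10")) {
  log_base <- match.arg(log_base)
  p <- as_stand_pair(pair)
  if (any(c(p$sdm_ir, p$sdm_c, p$idm_ir, p$idm_c) <= 0)) {
    abort_undefined("cb", "cb undefined: all four performances must be > 0")
  }
  ratio <- (p$idm_ir / p$sdm_ir) / (p$idm_c / p$sdm_c)
  if (log_base == "natural") log(ratio) else log10(ratio)
}
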