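# Anti-TG2 IgA serology interpretation.
#
# Concentrations (UA/mL) are expressed as multiples of the assay's upper
# limit of normal (ULN, 20 UA/mL for the kit modelled here, so 60 and
# 200 UA/mL are 3x and 10x ULN) and banded into negative / low /
# intermediate / high. Bands are half-open and lower-inclusive, so a
# titer exactly at 10x ULN falls in the high band, matching the
# ">= 10x ULN" no-biopsy convention.

TITER_BANDS <- c("negative", "low", "intermediate", "high")

#' Serology banding configuration
#'
#' @param uln Upper limit of normal of the anti-TG2 IgA assay, in UA/mL.
#' @param low_band_max Upper edge of the low band, as a ULN multiple.
#' @param high_band_min Lower edge of the high band, as a ULN multiple.
#' @return An object of class `serology_config`.
#' @examples
#' serology_config()  # 20 UA/mL ULN, bands at 1x, 3x, 10x
#' @export
serology_config <- function(uln = 20, low_band_max = 3, high_band_min = 10) {
  stopifnot(is.numeric(uln), length(uln) == 1L, is.finite(uln), uln > 0,
            is.numeric(low_band_max), length(low_band_max) == 1L,
            is.numeric(high_band_min), length(high_band_min) == 1L)
  if (!(1 <= low_band_max && low_band_max < high_band_min))
    stop("band multiples must satisfy 1 <= low_band_max < high_band_min")
  structure(list(uln = uln, low_band_max = low_band_max,
                 high_band_min = high_band_min),
            class = "serology_config")
}

#' Express an anti-TG2 concentration as a ULN multiple
#'
#' @param anti_tg2 Concentration(s) in UA/mL, non-negative and finite.
#' @param cfg A [serology_config()].
#' @return Numeric vector `anti_tg2 / uln`.
#' @examples
#' uln_multiple(200)  # 10
#' @export
uln_multiple <- function(anti_tg2, cfg = serology_config()) {
  if (!is.numeric(anti_tg2) || any(!is.finite(anti_tg2)) || any(anti_tg2 < 0))
    stop("anti_tg2 concentrations must be finite and non-negative")
  anti_tg2 / cfg$uln
}

#' Band an anti-TG2 concentration
#'
#' Bands partition `[0, Inf)`: negative on `[0, uln)`, low on
#' `[uln, low_band_max*uln)`, intermediate on
#' `[low_band_max*uln, high_band_min*uln)`, high on
#' `[high_band_min*uln, Inf)`.
#'
#' @inheritParams uln_multiple
#' @return Ordered factor with levels negative < low < intermediate < high.
#' @export
classify_titer <- function(anti_tg2, cfg = serology_config()) {
  m <- uln_multiple(anti_tg2, cfg)
  band <- ifelse(m < 1, "negative",
          ifelse(m < cfg$low_band_max, "low",
          ifelse(m < cfg$high_band_min, "intermediate", "high")))
  factor(band, levels = TITER_BANDS, ordered = TRUE)
}

#' Is a serology panel informative?
#'
#' Low or deficient total IgA makes a negative IgA anti-TG2 result
#' non-informative (the marker is IgA-class), independently of the titer.
#'
#' @param iga_status Character vector with values `normal`, `low` or
#'   `deficient`.
#' @return Character vector: `"reliable"` or `"unreliable_iga"`.
#' @export
serology_reliability <- function(iga_status) {
  bad <- setdiff(unique(as.character(iga_status)),
                 c("normal", "low", "deficient"))
  if (length(bad))
    stop(sprintf("unknown iga_status: %s", paste(bad, collapse = ", ")))
  ifelse(as.character(iga_status) %in% c("low", "deficient"),
         "unreliable_iga", "reliable")
}

#' Write / read a serology configuration as YAML
#'
#' Round-trips the three banding parameters through a YAML file with keys
#' `uln`, `low_band_max`, `high_band_min`.
#'
#' @param cfg A [serology_config()].
#' @param path File path.
#' @return `read_serology_config` returns a [serology_config()];
#'   `write_serology_config` returns `path` invisibly.
#' @export
write_serology_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "serology_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_serology_config
#' @export
read_serology_config <- function(path) {
  x <- yaml::read_yaml(path)
  miss <- setdiff(c("uln", "low_band_max", "high_band_min"), names(x))
  if (length(miss))
    stop(sprintf("config file %s lacks keys: %s", path,
                 paste(miss, collapse = ", ")))
  serology_config(uln = x$uln, low_band_max = x$low_band_max,
                  high_band_min = x$high_band_min)
}
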