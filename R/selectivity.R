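#' Selectivity encodings and the Boltzmann free-energy relation
#'
#' Enantioselectivity is reported in five interchangeable encodings:
#' enantiomeric excess (ee = |%S - %R|), enantiomeric ratio
#' (er = major/minor), its natural log, and the raw S / R percentages.
#' Under Curtin-Hammett control the er is set by the free-energy
#' difference between the diastereomeric transition states,
#' \deqn{\Delta\Delta G^\ddagger = RT \ln(\mathrm{major}/\mathrm{minor}),}
#' with R = 1.98720425e-3 kcal/(mol K); at 298.15 K a 90:10 er
#' corresponds to 1.3 kcal/mol, which is why ~1 kcal/mol errors in
#' computed energies obscure realistic selectivity differences.
#'
#' @name selectivity-metrics
NULL

#' Parse "X:Y" er strings
#'
#' Components are normalized to sum to 100.  The printing convention is
#' R:S by default (S-selective ligands print minor:major, e.g.
#' "11:89"); set `format = "S:R"` for the opposite convention.
#'
#' @param text character vector of "X:Y" strings with positive
#'   components.
#' @param format `"R:S"` (default) or `"S:R"`.
#' @return A [Selectivity-class].
#' @examples
#' parseEr("90:10")          # r = 90, s = 10
#' parseEr("9:1")            # normalized to 90:10
#' @export
parseEr <- function(text, format = c("R:S", "S:R")) {
  format <- match.arg(format)
  parts <- strsplit(as.character(text), ":", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad))
    stop("malformed er string (expected 'X:Y'): ",
         paste(sQuote(text[bad]), collapse = ", "))
  first <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  second <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  if (any(is.na(first)) || any(is.na(second)))
    stop("non-numeric er component in: ",
         paste(sQuote(text[is.na(first) | is.na(second)]), collapse = ", "))
  if (any(first <= 0) || any(second <= 0))
    stop("er components must be strictly positive (log-based metrics ",
         "are undefined at 0 or 100 percent)")
  total <- first + second
  first <- 100 * first / total
  second <- 100 * second / total
  if (format == "R:S") selectivity(r = first, s = second)
  else selectivity(s = first, r = second)
}

#' Format Selectivity records as "R:S" strings
#'
#' @param rec a [Selectivity-class].
#' @param digits decimals per component (default 1).
#' @return character vector of "R:S" strings.
#' @examples
#' formatEr(selectivity(s = 89))   # "11.0:89.0"
#' @export
formatEr <- function(rec, digits = 1) {
  stopifnot(is(rec, "Selectivity"))
  fmt <- sprintf("%%.%df:%%.%df", digits, digits)
  sprintf(fmt, rec@rPercent, rec@sPercent)
}

#' Convert Selectivity records to a scalar metric
#'
#' @param rec a [Selectivity-class].
#' @param metric one of `"ee"` (|%S - %R|), `"er_ratio"` (major/minor),
#'   `"ln_er"` (log of er_ratio), `"s_select"` (%S), `"r_select"` (%R).
#' @return numeric vector on the metric's scale.
#' @examples
#' rec <- parseEr("90:10")
#' toMetric(rec, "ee")        # 80
#' toMetric(rec, "er_ratio")  # 9
#' @export
toMetric <- function(rec, metric = .SELECTIVITY_METRICS) {
  stopifnot(is(rec, "Selectivity"))
  metric <- match.arg(metric)
  s <- rec@sPercent; r <- rec@rPercent
  major <- pmax(s, r); minor <- pmin(s, r)
  switch(metric,
         ee = abs(s - r),
         er_ratio = major / minor,
         ln_er = log(major / minor),
         s_select = s,
         r_select = r)
}

#' Build Selectivity records from a scalar metric
#'
#' Inverse of [toMetric()].  `ee` and `er_ratio` do not identify the
#' major enantiomer, so `majorLabel` resolves the sign; it is ignored
#' for `s_select` / `r_select`.
#'
#' @param value numeric vector on the metric's scale (`ee` in [0, 100),
#'   `er_ratio` > 0, percentages in (0, 100), `ln_er` any finite
#'   value).
#' @param metric as in [toMetric()].
#' @param majorLabel `"S"` or `"R"`.
#' @return A [Selectivity-class].
#' @examples
#' fromMetric(80, "ee", majorLabel = "S")   # 10:90
#' fromMetric(47, "s_select")               # 53:47
#' @export
fromMetric <- function(value, metric = .SELECTIVITY_METRICS,
                       majorLabel = c("S", "R")) {
  metric <- match.arg(metric)
  majorLabel <- match.arg(majorLabel)
  value <- as.numeric(value)
  if (any(!is.finite(value)))
    stop("metric values must be finite")
  majorFrac <- switch(metric,
    ee = {
      if (any(value < 0) || any(value >= 100))
        stop("ee must lie in [0, 100)")
      50 + value / 2
    },
    er_ratio = {
      if (any(value <= 0)) stop("er_ratio must be strictly positive")
      100 * value / (1 + value)
    },
    ln_er = 100 * exp(value) / (1 + exp(value)),
    s_select = ,
    r_select = {
      if (any(value <= 0) || any(value >= 100))
        stop("selectivity percentages must lie strictly inside (0, 100)")
      value
    })
  if (metric == "s_select") return(selectivity(s = majorFrac))
  if (metric == "r_select") return(selectivity(r = majorFrac))
  if (majorLabel == "S") selectivity(s = majorFrac)
  else selectivity(r = majorFrac)
}

#' @describeIn er-thermo free-energy difference between the
#'   diastereomeric transition states implied by an er.
#' @export
erToDdg <- function(rec, temperature = 298.15) {
  stopifnot(is(rec, "Selectivity"))
  if (temperature <= 0) stop("temperature must be strictly positive (K)")
  .GAS_CONSTANT_KCAL * temperature * toMetric(rec, "ln_er")
}

#' Boltzmann relation between er and the transition-state free-energy gap
#'
#' `erToDdg` maps an er to the free-energy difference
#' RT ln(major/minor) (kcal/mol, non-negative); `ddgToEr` inverts it,
#' assigning the major fraction K/(1+K) with K = exp(ddg/RT) to
#' `majorLabel`.  Negative `ddg` is rejected: swap `majorLabel`
#' instead.
#'
#' @param rec a [Selectivity-class].
#' @param ddg free-energy difference(s) in kcal/mol, >= 0.
#' @param majorLabel `"S"` or `"R"`: which enantiomer the energy gap
#'   favours.
#' @param temperature absolute temperature in Kelvin (default 298.15).
#' @return `erToDdg`: numeric kcal/mol. `ddgToEr`: a
#'   [Selectivity-class].
#' @examples
#' erToDdg(parseEr("90:10"))          # ~1.30 kcal/mol at 298.15 K
#' formatEr(ddgToEr(1.3, "R"))        # back to ~90:10
#' @name er-thermo
#' @export
ddgToEr <- function(ddg, majorLabel = c("S", "R"), temperature = 298.15) {
  majorLabel <- match.arg(majorLabel)
  if (temperature <= 0) stop("temperature must be strictly positive (K)")
  ddg <- as.numeric(ddg)
  if (any(!is.finite(ddg)) || any(ddg < 0))
    stop("ddg must be non-negative (swap majorLabel for the opposite ",
         "enantiomer instead of negating the energy)")
  k <- exp(ddg / (.GAS_CONSTANT_KCAL * temperature))
  major <- 100 * k / (1 + k)
  if (majorLabel == "S") selectivity(s = major) else selectivity(r = major)
}
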