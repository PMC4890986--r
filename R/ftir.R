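#' Preprocess an ATR-FTIR spectrum
#'
#' Standard comparability preprocessing applied in order:
#'
#' 1. **baseline correction** — subtract the straight line through the
#'    spectrum's values at the anchor wavenumbers (default 1800 and 900
#'    cm\eqn{^{-1}}, bracketing the analysis region);
#' 2. **offset correction** — subtract the minimum over the analysis region
#'    (1800-900 cm\eqn{^{-1}}), making it zero;
#' 3. **vector normalization** — divide by the Euclidean norm over the full
#'    grid, so the processed spectrum has unit norm.
#'
#' @param spectrum tibble with `wavenumber` (cm^-1, strictly monotone) and
#'   `absorbance`; must span the analysis region with at least 50 points.
#' @param baseline_anchors two anchor wavenumbers, cm^-1.
#' @return the processed `ftir_spectrum` tibble; the `"preprocessing"`
#'   attribute records the three completed steps.
#' @export
preprocess_spectrum <- function(spectrum, baseline_anchors = c(1800, 900)) {
  wn <- spectrum$wavenumber
  ab <- spectrum$absorbance
  region <- wn <= 1800 & wn >= 900
  if (sum(region) < 50) {
    abort("spectrum must cover the 1800-900 cm^-1 analysis region with >= 50 points")
  }
  a_at <- function(target) ab[which.min(abs(wn - target))]
  x1 <- baseline_anchors[1]; x2 <- baseline_anchors[2]
  y1 <- a_at(x1); y2 <- a_at(x2)
  slope <- (y2 - y1) / (x2 - x1)
  ab <- ab - (y1 + slope * (wn - x1))
  ab <- ab - min(ab[region])
  nrm <- sqrt(sum(ab^2))
  if (nrm < 1e-12) abort("spectrum degenerates to zero after baseline and offset correction")
  ab <- ab / nrm
  out <- tibble(wavenumber = wn, absorbance = ab)
  class(out) <- c("ftir_spectrum", class(out))
  attr(out, "preprocessing") <- c(baseline_corrected = TRUE,
                                  offset_corrected = TRUE,
                                  vector_normalized = TRUE)
  attr(out, "ground_truth") <- attr(spectrum, "ground_truth", exact = TRUE)
  out
}

#' Read out the diagnostic FTIR bands
#'
#' Extracts the Amide I peak position (wavenumber of maximum absorbance in
#' 1600-1700 cm\eqn{^{-1}}, conformation-sensitive: ~1656 cm\eqn{^{-1}} for
#' newborn collagen versus ~1632 cm\eqn{^{-1}} for adult collagens) and the
#' carbohydrate-region intensities I1032 and I1082 (maximum absorbance
#' within +/-8 cm\eqn{^{-1}} of 1032 and 1082 cm\eqn{^{-1}}). The primary
#' glycation marker is the ratio I1032/I1082, which increases as
#' carbohydrate signal from advanced glycation end products accumulates;
#' the secondary ratio I1032/I(Amide I) is also reported.
#'
#' All readouts are invariant under multiplication of the spectrum by a
#' positive constant (positions unchanged, the ratios cancel).
#'
#' @param spectrum a (preferably [preprocess_spectrum()]-ed) `ftir_spectrum`
#'   covering 1700-900 cm^-1.
#' @param window half-width of the peak search windows, cm^-1.
#' @return one-row tibble: `amide_I_position`, `I_1032`, `I_1082`, `ratio`
#'   (= I1032/I1082), `ratio_amide` (= I1032/I(Amide I)).
#' @export
band_readout <- function(spectrum, window = 8) {
  wn <- spectrum$wavenumber
  ab <- spectrum$absorbance
  pick <- function(lo, hi, what) {
    sel <- wn >= lo & wn <= hi
    if (!any(sel)) abort(sprintf("window %g-%g cm^-1 (%s) falls outside the grid", lo, hi, what))
    sel
  }
  amide_sel <- pick(1600, 1700, "Amide I")
  amide_pos <- wn[amide_sel][which.max(ab[amide_sel])]
  i_amide <- max(ab[amide_sel])
  i1032 <- max(ab[pick(1032 - window, 1032 + window, "1032")])
  i1082 <- max(ab[pick(1082 - window, 1082 + window, "1082")])
  if (i1082 <= 0) abort("I_1082 is non-positive; the ratio I1032/I1082 is undefined")
  tibble(amide_I_position = amide_pos, I_1032 = i1032, I_1082 = i1082,
         ratio = i1032 / i1082, ratio_amide = i1032 / i_amide)
}

#' Correlate the carbohydrate band ratio with AGE fluorescence
#'
#' Pearson product-moment correlation between per-age I1032/I1082 band
#' ratios and per-age fluorescent-AGE intensities — the quantitative link
#' between the infrared glycation marker and the biochemical one.
#'
#' @param data data frame with columns `ratio` and `fluorescence` (one row
#'   per age condition), or a numeric vector of ratios if `fluorescence` is
#'   given separately.
#' @param fluorescence optional numeric vector when `data` is a vector.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
correlate_ratio_fluorescence <- function(data, fluorescence = NULL) {
  if (is.data.frame(data)) {
    x <- data$ratio; y <- data$fluorescence
  } else {
    x <- data; y <- fluorescence
  }
  stopifnot(length(x) == length(y))
  if (length(x) < 3) abort("need at least 3 age conditions to correlate")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input: correlation is undefined")
  cor(x, y, method = "pearson")
}

#' @export
autoplot.ftir_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wavenumber, y = .data$absorbance)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression("wavenumber (cm"^-1 * ")"), y = "absorbance",
                  title = "ATR-FTIR spectrum")
}
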