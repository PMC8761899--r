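#' @title Genomic- versus phenotypic-selection efficiency
#' @description Breeder's-equation calculator comparing expected genetic
#'   gain per year from genomic selection (GS), dG'_G = i_G r_Ac s_A / t_G,
#'   with that from phenotypic selection (PS), dG'_P = i_P H s_A / t_P,
#'   under equal evaluation budgets: a cheaper genotyping cost lets GS screen
#'   proportionally more candidates, tightening its selected fraction and
#'   raising its selection intensity.
#' @name gain
NULL

half_up <- function(x, digits) floor(x * 10^digits + 0.5 + 1e-9) / 10^digits

#' Standardized selection differential (selection intensity)
#'
#' Large-sample truncation-selection intensity: i = phi(z_p) / p with z_p
#' the upper-p standard-normal quantile and phi the standard-normal density.
#' Strictly decreasing in the selected fraction p.
#'
#' @param p Selected fraction(s) in (0, 1).
#' @return Intensity value(s).
#' @export
selection_intensity <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("selected fraction must be in (0, 1)")
  stats::dnorm(stats::qnorm(1 - p)) / p
}

#' GS accuracy from predictive ability
#'
#' r_Ac = r_ab / H with H the square root of the broad-sense heritability of
#' the phenotypic data the predictions are validated against. Ratios above 1
#' (possible with noisy H) are clamped to 1 and flagged.
#'
#' @param r_ab Predictive ability.
#' @param H Square root of broad-sense heritability (> 0), or a
#'   `heritability` object.
#' @return List with `r_Ac`, `clamped`.
#' @export
gs_accuracy <- function(r_ab, H) {
  if (inherits(H, "heritability")) H <- H$H
  if (H <= 0) stop("H must be positive")
  r <- r_ab / H
  list(r_Ac = min(r, 1), clamped = r > 1, raw = r)
}

#' Cost-constrained selected fraction for GS
#'
#' With per-genotype evaluation costs c_P (phenotypic) and c_G (genomic) and
#' a fixed budget, GS can screen c_P/c_G times more candidates while
#' selecting the same number, so its selected fraction shrinks by that
#' multiplier. The multiplier is kept unrounded internally; display rounding
#' happens only at output.
#'
#' @param c_P,c_G Costs per genotype (> 0); defaults 220 and 60.
#' @param p_P Phenotypic-selection selected fraction in (0, 1).
#' @return List with `multiplier` (c_P/c_G), `p_G`.
#' @export
cost_constrained_fractions <- function(c_P = 220, c_G = 60, p_P = 0.10) {
  stopifnot(c_P > 0, c_G > 0, p_P > 0, p_P < 1)
  multiplier <- c_P / c_G
  p_G <- p_P / multiplier
  if (p_G >= 1) stop("GS selected fraction >= 1")
  list(multiplier = multiplier, p_G = p_G)
}

#' Ratio of GS to PS selection intensity under equal budgets
#'
#' i_G/i_P at the cost-implied GS fraction. By default the computation
#' follows selection-table arithmetic: the GS fraction is display-rounded to
#' one decimal percent, both intensities are rounded to 3 decimals (the
#' precision of printed Falconer tables), and the quotient is reported to 3
#' decimals. `tabular = FALSE` returns the continuous value instead.
#' `compromise_intensity_ratio()` gives the fixed compromise value: the
#' half-up-rounded mean of the tabular ratios at the two reference PS
#' fractions 10% and 20%.
#'
#' @param p_P PS selected fraction.
#' @param c_P,c_G Costs per genotype.
#' @param tabular Use 3-decimal table rounding (default).
#' @return The intensity ratio.
#' @export
intensity_ratio <- function(p_P, c_P = 220, c_G = 60, tabular = TRUE) {
  f <- cost_constrained_fractions(c_P, c_G, p_P)
  if (!tabular) {
    return(selection_intensity(f$p_G) / selection_intensity(p_P))
  }
  i_G <- half_up(selection_intensity(half_up(f$p_G, 3)), 3)
  i_P <- half_up(selection_intensity(p_P), 3)
  half_up(i_G / i_P, 3)
}

#' @rdname intensity_ratio
#' @param base_fractions The two reference PS fractions averaged over.
#' @export
compromise_intensity_ratio <- function(base_fractions = c(0.10, 0.20),
                                       c_P = 220, c_G = 60) {
  ratios <- vapply(base_fractions, intensity_ratio, numeric(1),
                   c_P = c_P, c_G = c_G)
  half_up(mean(ratios), 3)
}

#' Assemble a GS-vs-PS gain scenario
#'
#' @param r_ab GS predictive ability (validation-environment scale).
#' @param H2 Broad-sense heritability of the PS selection scheme (genotype
#'   mean basis over the hypothesized selection environments).
#' @param t_P PS cycle length in years (1 or 2).
#' @param t_G GS cycle length in years (default 0.5: two cycles per year).
#' @param c_P,c_G Evaluation costs per genotype.
#' @param p_P PS selected fraction.
#' @param s_A Standard deviation of breeding values (trait units); the
#'   efficiency ratio is invariant to it.
#' @param intensity `"exact"` (intensities at the cost-implied fractions) or
#'   `"compromise"` (the fixed i_G = 1.381 i_P style ratio from
#'   [compromise_intensity_ratio()]).
#' @return Object of class `gain_scenario` with all intermediate quantities
#'   and the annual gains.
#' @export
gain_scenario <- function(r_ab, H2, t_P = 1, t_G = 0.5, c_P = 220, c_G = 60,
                          p_P = 0.10, s_A = 1,
                          intensity = c("exact", "compromise")) {
  intensity <- match.arg(intensity)
  stopifnot(t_P > 0, t_G > 0, s_A > 0, H2 > 0, H2 <= 1)
  H <- sqrt(H2)
  acc <- gs_accuracy(r_ab, H)
  fr <- cost_constrained_fractions(c_P, c_G, p_P)
  i_P <- selection_intensity(p_P)
  i_G <- if (intensity == "exact") {
    selection_intensity(fr$p_G)
  } else {
    compromise_intensity_ratio(c_P = c_P, c_G = c_G) * i_P
  }
  out <- structure(list(
    r_ab = r_ab, H2 = H2, H = H, r_Ac = acc$r_Ac, accuracy_clamped = acc$clamped,
    t_P = t_P, t_G = t_G, c_P = c_P, c_G = c_G,
    p_P = p_P, p_G = fr$p_G, multiplier = fr$multiplier,
    i_P = i_P, i_G = i_G, s_A = s_A, intensity_rule = intensity
  ), class = "gain_scenario")
  gains <- annual_gains(out)
  out[names(gains)] <- gains
  out
}

#' Expected annual gains and the GS/PS efficiency ratio
#'
#' dG'_G = i_G r_Ac s_A / t_G; dG'_P = i_P H s_A / t_P; the efficiency
#' ratio dG'_G / dG'_P is independent of s_A.
#'
#' @param scenario A `gain_scenario`.
#' @return List with `dG_G` (per cycle), `dG_G_year`, `dG_P_year`,
#'   `efficiency_ratio`.
#' @export
annual_gains <- function(scenario) {
  stopifnot(inherits(scenario, "gain_scenario"))
  with(scenario, {
    dG_G <- i_G * r_Ac * s_A
    dG_G_year <- dG_G / t_G
    dG_P_year <- i_P * H * s_A / t_P
    list(dG_G = dG_G, dG_G_year = dG_G_year, dG_P_year = dG_P_year,
         efficiency_ratio = dG_G_year / dG_P_year)
  })
}

#' @export
print.gain_scenario <- function(x, ...) {
  cat(sprintf("gain_scenario (t_G = %g y, t_P = %g y, costs %g/%g)\n",
              x$t_G, x$t_P, x$c_P, x$c_G))
  cat(sprintf("  fractions: PS %.1f%% -> GS %.2f%% (x%.4g candidates)\n",
              100 * x$p_P, 100 * x$p_G, x$multiplier))
  cat(sprintf("  intensities: i_P = %.3f, i_G = %.3f (%s rule)\n",
              x$i_P, x$i_G, x$intensity_rule))
  cat(sprintf("  r_ab = %.3f, H = %.3f, r_Ac = %.3f%s\n",
              x$r_ab, x$H, x$r_Ac,
              if (x$accuracy_clamped) " (clamped)" else ""))
  cat(sprintf("  annual gains: GS %.4g, PS %.4g -> efficiency ratio %.3f\n",
              x$dG_G_year, x$dG_P_year, x$efficiency_ratio))
  invisible(x)
}
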