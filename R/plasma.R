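# Densitometry-derived metrics: isoelectric-focusing tetramer
# stabilization, thyroxine (T4) binding competition, and gravimetric
# solubility averaging.

#' Tetramer fraction from IEF densitometry
#'
#' Ratio of the TTR tetramer band over total TTR (tetramer + monomer) in a
#' semidenaturing IEF lane.
#'
#' @param tetramer_intensity Net tetramer band volume (>= 0). Vectorized.
#' @param monomer_intensity Net monomer band volume (>= 0).
#' @return Tetramer fraction in \[0, 1\].
#' @export
tetramer_ratio <- function(tetramer_intensity, monomer_intensity) {
  if (any(tetramer_intensity < 0) || any(monomer_intensity < 0))
    stop("band intensities must be >= 0", call. = FALSE)
  total <- tetramer_intensity + monomer_intensity
  if (any(total <= 0))
    stop("tetramer + monomer intensity must be > 0", call. = FALSE)
  tetramer_intensity / total
}

#' Percent tetramer stabilization for a paired treated/control sample
#'
#' \eqn{100 (ratio_{treated} - ratio_{control}) / ratio_{control}}.
#' Treated and control samples must come from the same donor; negative
#' values indicate destabilization.
#'
#' @param ratio_treated Tetramer fraction of the treated sample.
#' @param ratio_control Tetramer fraction of the paired control (> 0).
#' @return Stabilization percentage (may be negative).
#' @export
stabilization_percent <- function(ratio_treated, ratio_control) {
  if (any(!is.finite(ratio_control)) || any(ratio_control <= 0))
    stop("`ratio_control` must be > 0", call. = FALSE)
  100 * (ratio_treated - ratio_control) / ratio_control
}

#' Per-donor stabilization from an IEF densitometry table
#'
#' Pairs treated and control lanes by donor, computes the per-donor
#' stabilization percentage, and summarizes as mean +/- SEM. A donor with
#' a missing control or treated lane is an error.
#'
#' @param table Data frame with columns `donor`, `condition`
#'   (`"control"`/`"treated"`), `tetramer_intensity`, `monomer_intensity`.
#' @return List: `per_donor` (data frame `donor`, `ratio_control`,
#'   `ratio_treated`, `stabilization_pct`), `mean_pct`, `sem_pct`.
#' @export
ief_stabilization <- function(table) {
  stopifnot(all(c("donor", "condition", "tetramer_intensity",
                  "monomer_intensity") %in% names(table)))
  table$ratio <- tetramer_ratio(table$tetramer_intensity,
                                table$monomer_intensity)
  donors <- unique(table$donor)
  rows <- lapply(donors, function(d) {
    ctrl <- table[table$donor == d & table$condition == "control", ]
    trt <- table[table$donor == d & table$condition == "treated", ]
    if (nrow(ctrl) != 1L || nrow(trt) != 1L)
      stop("donor '", d, "' must have exactly one control and one ",
           "treated lane", call. = FALSE)
    data.frame(donor = d, ratio_control = ctrl$ratio,
               ratio_treated = trt$ratio,
               stabilization_pct = stabilization_percent(trt$ratio,
                                                         ctrl$ratio),
               stringsAsFactors = FALSE)
  })
  per_donor <- do.call(rbind, rows)
  s <- per_donor$stabilization_pct
  list(per_donor = per_donor,
       mean_pct = mean(s),
       sem_pct = if (length(s) > 1L) stats::sd(s) / sqrt(length(s))
                 else NA_real_)
}

#' Normalized T4-bound-to-TTR fraction
#'
#' From densitometry of the three major plasma T4 carriers (TBG, albumin,
#' TTR): the fraction of T4 bound to TTR,
#' \eqn{TTR / (TBG + ALB + TTR)}, normalized to the same fraction in the
#' negative (no-compound) control. Displacement percent is
#' \eqn{100 (1 - fraction)}.
#'
#' @param sample Named list or data-frame row with band intensities `tbg`,
#'   `alb`, `ttr` for the compound-treated sample.
#' @param control Same, for the negative control.
#' @return List: `fraction` (normalized bound fraction) and
#'   `displacement_pct`.
#' @examples
#' t4_bound_fraction(list(tbg = 60, alb = 30, ttr = 10),
#'                   list(tbg = 40, alb = 25, ttr = 35))
#' @export
t4_bound_fraction <- function(sample, control) {
  frac <- function(x, who) {
    tot <- x$tbg + x$alb + x$ttr
    if (!is.finite(tot) || tot <= 0)
      stop("total band intensity must be > 0 for the ", who, call. = FALSE)
    x$ttr / tot
  }
  f_ctrl <- frac(control, "control")
  if (f_ctrl <= 0)
    stop("control TTR-bound fraction must be > 0", call. = FALSE)
  f <- frac(sample, "sample") / f_ctrl
  list(fraction = f, displacement_pct = 100 * (1 - f))
}

#' Gravimetric solubility with triplicate averaging
#'
#' Per-assay solubility is `weight_mg / water_mL` (mg/mL). Reported values
#' are rounded half away from zero to 3 decimals, and the mean of the raw
#' per-assay solubilities is rounded the same way.
#'
#' @param weight_mg Solid weights, mg (> 0).
#' @param water_mL Water volumes at total dissolution, mL (> 0).
#' @return List: `per_assay` (raw mg/mL), `per_assay_reported` (rounded),
#'   `mean` (raw), `mean_reported` (rounded).
#' @examples
#' solubility(c(15.4, 14.7, 15.0), c(350, 326, 333))$mean_reported  # 0.045
#' @export
solubility <- function(weight_mg, water_mL) {
  stop_if_not_positive(weight_mg, "weight_mg")
  stop_if_not_positive(water_mL, "water_mL")
  stopifnot(length(weight_mg) == length(water_mL))
  per <- weight_mg / water_mL
  list(per_assay = per,
       per_assay_reported = round_half_up(per, 3),
       mean = mean(per),
       mean_reported = round_half_up(mean(per), 3))
}

#' Group comparison of stabilization percentages
#'
#' Standard one-way ANOVA with Tukey honest-significant-difference
#' contrasts across compounds, reported alongside group means +/- SEM.
#' A thin wrapper over [stats::aov()] and [stats::TukeyHSD()].
#'
#' @param values Stabilization percentages (or any per-sample statistic).
#' @param groups Factor or character vector of compound labels.
#' @return List: `summary` (per-group n, mean, sem), `anova`
#'   (the [stats::aov()] fit), `tukey` (pairwise contrasts).
#' @export
compare_stabilization <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  agg <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               stringsAsFactors = FALSE)
  }))
  fit <- stats::aov(values ~ groups)
  list(summary = agg, anova = fit, tukey = stats::TukeyHSD(fit))
}
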