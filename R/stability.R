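# Statistics for the kinetic-stabilization assays: urea-induced tetramer
# dissociation (Trp fluorescence 355/335 ratio), acid-mediated aggregation
# (turbidity at 340 nm) and cell viability.

#' Fraction of unfolded protein from a 355/335 fluorescence ratio
#'
#' Trp exposure on unfolding red-shifts the emission maximum from ~335 to
#' ~355 nm; the 355/335 intensity ratio is normalized from the fully folded
#' minimum to the fully unfolded maximum (96 h denaturation control):
#' \eqn{f(t) = (r(t) - r_{folded}) / (r_{unfolded} - r_{folded})}, clipped
#' to \[0, 1\].
#'
#' @param ratio Observed 355/335 ratio(s).
#' @param ref_folded Ratio of the fully folded reference (minimum).
#' @param ref_unfolded Ratio of the fully unfolded reference (maximum);
#'   must exceed `ref_folded`.
#' @return Unfolded fraction(s) in \[0, 1\].
#' @export
fraction_unfolded <- function(ratio, ref_folded, ref_unfolded) {
  if (!is.finite(ref_folded) || !is.finite(ref_unfolded) ||
      ref_unfolded <= ref_folded)
    stop("`ref_unfolded` must exceed `ref_folded`", call. = FALSE)
  pmin(pmax((ratio - ref_folded) / (ref_unfolded - ref_folded), 0), 1)
}

#' Fit mono-exponential tetramer dissociation kinetics
#'
#' Tetramer dissociation is the rate-limiting step of TTR unfolding in
#' post-transition urea, so the unfolded fraction follows
#' \eqn{f(t) = plateau\,(1 - e^{-k t})}. The plateau is the asymptotic
#' unfolded fraction; its complement is the fraction of protein protected
#' by the stabilizer, reported as `protection_pct = 100 (1 - plateau)`.
#'
#' @param times Time points, hours (>= 4 points).
#' @param fractions Unfolded fractions in \[0, 1\] (see
#'   [fraction_unfolded()]).
#' @return List of class `dissociation_fit`: `k_obs` (1/h), `plateau`,
#'   `protection_pct`, `converged`, `fitted`, `residuals`, `rss`.
#' @examples
#' t <- seq(0, 96, by = 4)
#' f <- 0.173 * (1 - exp(-0.05 * t))
#' fit_dissociation(t, f)$protection_pct  # 82.7
#' @export
fit_dissociation <- function(times, fractions) {
  stopifnot(length(times) == length(fractions), length(times) >= 4L)
  if (any(fractions < -1e-9) || any(fractions > 1 + 1e-9))
    stop("`fractions` must lie in [0, 1]", call. = FALSE)
  if (max(abs(fractions)) <= 1e-12) {
    # flat zero trace: fully protected, rate unidentified
    return(structure(list(k_obs = 0, plateau = 0, protection_pct = 100,
                          converged = TRUE,
                          fitted = rep(0, length(times)),
                          residuals = fractions, rss = sum(fractions^2)),
                     class = "dissociation_fit"))
  }
  plateau0 <- max(max(fractions), 1e-3)
  # initial rate from the earliest rise; fall back to the time scale
  pos <- which(fractions > 0.05 * plateau0 & times > 0)
  k0 <- if (length(pos) > 0L) {
    i <- pos[1L]
    max(fractions[i] / (plateau0 * times[i]), 1e-4)
  } else 1 / max(times[times > 0], 1)
  dat <- data.frame(t = times, f = fractions)
  fit <- try(minpack.lm::nlsLM(
    f ~ plateau * (1 - exp(-k * t)), data = dat,
    start = list(plateau = plateau0, k = k0),
    lower = c(0, 0), upper = c(1, Inf),
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                         maxiter = 500)),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(k_obs = NA_real_, plateau = NA_real_,
                          protection_pct = NA_real_, converged = FALSE,
                          fitted = rep(NA_real_, length(times)),
                          residuals = rep(NA_real_, length(times)),
                          rss = NA_real_),
                     class = "dissociation_fit"))
  }
  cf <- stats::coef(fit)
  pred <- stats::fitted(fit)
  structure(list(
    k_obs = unname(cf[["k"]]),
    plateau = unname(cf[["plateau"]]),
    protection_pct = 100 * (1 - unname(cf[["plateau"]])),
    converged = TRUE,
    fitted = as.numeric(pred),
    residuals = fractions - as.numeric(pred),
    rss = sum((fractions - pred)^2)
  ), class = "dissociation_fit")
}

#' @export
print.dissociation_fit <- function(x, ...) {
  cat("Mono-exponential dissociation fit\n")
  cat(sprintf("  k_obs = %.4g 1/h, plateau = %.4g\n", x$k_obs, x$plateau))
  cat(sprintf("  protection = %.1f%%\n", x$protection_pct))
  invisible(x)
}

#' Percent aggregation from blank-corrected turbidity
#'
#' \eqn{100 (A_{sample} - A_{compound\,blank}) / (A_{control} -
#' A_{buffer\,blank})}: the sample turbidity is corrected with a compound
#' blank (same compound concentration, no TTR, since some compounds absorb
#' at 340 nm) and referenced to a no-compound control. Negative corrected
#' values (instrument noise near full inhibition) are clipped to 0 with a
#' warning.
#'
#' @param a340_sample Turbidity of the sample at 340 nm.
#' @param a340_control Turbidity of the no-compound control.
#' @param a340_compound_blank Turbidity of the compound-only blank
#'   (default 0).
#' @param a340_buffer_blank Turbidity of the buffer blank (default 0).
#' @return Aggregation percentage (>= 0).
#' @examples
#' aggregation_percent(0.072, 1.0)  # 7.2
#' @export
aggregation_percent <- function(a340_sample, a340_control,
                                a340_compound_blank = 0,
                                a340_buffer_blank = 0) {
  denom <- a340_control - a340_buffer_blank
  if (any(!is.finite(denom)) || any(denom <= 0))
    stop("corrected control turbidity must be > 0", call. = FALSE)
  pct <- 100 * (a340_sample - a340_compound_blank) / denom
  if (any(pct < 0)) {
    warning("negative corrected turbidity clipped to 0")
    pct <- pmax(pct, 0)
  }
  pct
}

#' Percent inhibition of aggregation
#'
#' Complement of [aggregation_percent()], floored at 0.
#'
#' @param aggregation_pct Aggregation percentage (>= 0).
#' @return Inhibition percentage.
#' @export
inhibition_percent <- function(aggregation_pct) {
  if (any(aggregation_pct < 0))
    stop("`aggregation_pct` must be >= 0", call. = FALSE)
  pmax(100 - aggregation_pct, 0)
}

#' Percent cell viability from fluorescence intensities
#'
#' \eqn{100 (I_{sample} - \bar I_{blank}) / (\bar I_{control} -
#' \bar I_{blank})}; uncapped, so values above 100 are possible.
#'
#' @param intensity Sample well fluorescence intensity.
#' @param mean_blank Mean intensity of reagent-only blank wells.
#' @param mean_control Mean intensity of vehicle control wells; must
#'   differ from `mean_blank`.
#' @return Viability percentage.
#' @export
viability_percent <- function(intensity, mean_blank, mean_control) {
  if (!is.finite(mean_control - mean_blank) ||
      mean_control == mean_blank)
    stop("control and blank intensities must differ", call. = FALSE)
  100 * (intensity - mean_blank) / (mean_control - mean_blank)
}

#' Read an unfolding time-course CSV
#'
#' Layout: columns `time_h`, `ratio_355_335`; the folded/unfolded reference
#' ratios are carried as the first comment lines `# ref_folded=...` and
#' `# ref_unfolded=...`.
#'
#' @param path File path.
#' @return List with `times`, `ratio`, `ref_folded`, `ref_unfolded`.
#' @export
read_unfolding_csv <- function(path) {
  hdr <- readLines(path, n = 10L)
  get_ref <- function(key) {
    ln <- grep(paste0("^#\\s*", key, "\\s*="), hdr, value = TRUE)
    if (length(ln) == 0L) stop("missing '", key, "' header in ", path,
                               call. = FALSE)
    as.numeric(sub(".*=\\s*", "", ln[1L]))
  }
  dat <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  list(times = dat$time_h, ratio = dat$ratio_355_335,
       ref_folded = get_ref("ref_folded"),
       ref_unfolded = get_ref("ref_unfolded"))
}

#' Annotate an aggregation table with percentages
#'
#' Adds `aggregation_pct` and `inhibition_pct` columns to a turbidity table
#' with columns `a340_sample`, `a340_control` and optionally
#' `a340_compound_blank`, `a340_buffer_blank`.
#'
#' @param table Aggregation measurement table.
#' @return The table with the two percentage columns added.
#' @export
annotate_aggregation <- function(table) {
  stopifnot(all(c("a340_sample", "a340_control") %in% names(table)))
  cb <- if ("a340_compound_blank" %in% names(table))
    table$a340_compound_blank else 0
  bb <- if ("a340_buffer_blank" %in% names(table))
    table$a340_buffer_blank else 0
  table$aggregation_pct <- aggregation_percent(table$a340_sample,
                                               table$a340_control, cb, bb)
  table$inhibition_pct <- inhibition_percent(table$aggregation_pct)
  table
}
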