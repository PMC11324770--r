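#' Normalize treated wells to vehicle controls
#'
#' Per-well junction area per cell and mean nuclei count are expressed as
#' fold change over the mean of the vehicle wells on the same plate;
#' replicate wells at the same concentration are averaged.
#'
#' @param well_table per-well metrics data.frame from [analyze_plate()]
#'   (columns concentration_um, role, junction_area_per_cell_um2,
#'   mean_nuclei_count)
#' @return data.frame with one row per concentration: `concentration_um`,
#'   `response` (junction fold change), `viability_response` (nuclei-count
#'   fold change), `n_wells`
#' @export
normalize_to_vehicle <- function(well_table) {
  stopifnot(is.data.frame(well_table),
            all(c("concentration_um", "role", "junction_area_per_cell_um2",
                  "mean_nuclei_count") %in% names(well_table)))
  veh <- well_table[well_table$role == "vehicle", ]
  if (nrow(veh) < 1) stop("no vehicle wells present")
  v_j <- mean(veh$junction_area_per_cell_um2, na.rm = TRUE)
  v_n <- mean(veh$mean_nuclei_count)
  if (!is.finite(v_j) || v_j == 0) stop("vehicle junction-per-cell mean is zero or undefined")
  if (v_n == 0) stop("vehicle nuclei-count mean is zero")
  tr <- well_table[well_table$role == "treated", ]
  conc <- sort(unique(tr$concentration_um))
  out <- data.frame(
    concentration_um = conc,
    response = vapply(conc, function(cc) {
      mean(tr$junction_area_per_cell_um2[tr$concentration_um == cc]) / v_j
    }, numeric(1)),
    viability_response = vapply(conc, function(cc) {
      mean(tr$mean_nuclei_count[tr$concentration_um == cc]) / v_n
    }, numeric(1)),
    n_wells = vapply(conc, function(cc) sum(tr$concentration_um == cc), numeric(1)))
  out
}

#' Fit a dose-response curve and estimate the IC50
#'
#' The default "loglinear" method follows the screening convention of
#' linear-regression IC50s: the normalized response is regressed on
#' log10(concentration) over the points bracketing the 0.5 crossing
#' (minimum 3 points) and the fitted line solved for response = 0.5.
#' The alternative "fourpl" method fits a four-parameter logistic with the
#' top constrained near 1 and the bottom bounded at 0, and reports the
#' concentration at which the fitted curve crosses an absolute response of
#' 0.5.
#'
#' An IC50 is only *established* when the establishment rule holds: the
#' mean normalized response reaches `min_response_le` (default 0.5)
#' somewhere within the tested range. Otherwise `ic50_um` is NA and the
#' fit is flagged `NOT_ESTABLISHED`. With non-monotone data showing several
#' 0.5 crossings, the lowest-concentration crossing is used and
#' `multiple_crossings` flagged in the diagnostics.
#'
#' @param concentrations_um positive concentrations (may contain repeats
#'   when replicate response sets are pooled)
#' @param responses normalized responses (fold change over vehicle)
#' @param method "loglinear" (default) or "fourpl"
#' @param min_response_le establishment threshold on the response scale
#' @param compound_id optional label carried in the result
#' @param viability_responses optional parallel viability fold changes
#'   (reported, never mixed into the junction endpoint)
#' @return object of class `ic50_fit` with elements `ic50_um` (NA when not
#'   established), `established`, `method`, `diagnostics` (slope,
#'   residual_sd, flags), and the per-concentration mean response table
#' @export
fit_ic50 <- function(concentrations_um, responses,
                     method = c("loglinear", "fourpl"),
                     min_response_le = 0.5, compound_id = NULL,
                     viability_responses = NULL) {
  method <- match.arg(method)
  stopifnot(length(concentrations_um) == length(responses),
            all(concentrations_um > 0), all(is.finite(responses)))
  conc <- sort(unique(concentrations_um))
  if (length(conc) < 4) stop("need at least 4 distinct concentrations")
  rbar <- vapply(conc, function(cc) mean(responses[concentrations_um == cc]),
                 numeric(1))
  flags <- character(0)
  established <- any(rbar <= min_response_le)
  ic50 <- NA_real_
  slope <- NA_real_
  resid_sd <- NA_real_
  fourpl_pars <- NULL

  # crossing detection on per-concentration means (ascending concentration)
  cross <- which(rbar[-length(rbar)] > min_response_le &
                 rbar[-1] <= min_response_le)
  if (length(cross) > 1) flags <- c(flags, "multiple_crossings")

  if (established) {
    if (!length(cross)) {
      # response is already at or below the threshold at the lowest tested
      # concentration and never crosses downward within the range
      ic50 <- conc[1]
      flags <- c(flags, "crossing_below_range")
    } else if (method == "loglinear") {
      i <- cross[1]
      win <- max(1, i - 1):min(length(conc), i + 2)
      if (length(win) < 3) win <- max(1, i - 2):min(length(conc), i + 2)
      sel <- concentrations_um %in% conc[win]
      fit <- stats::lm(responses[sel] ~ log10(concentrations_um[sel]))
      a <- stats::coef(fit)[1]; b <- stats::coef(fit)[2]
      slope <- unname(b)
      resid_sd <- stats::sd(stats::resid(fit))
      ic50 <- unname(10^((min_response_le - a) / b))
      if (!is.finite(ic50) || ic50 < min(conc) || ic50 > max(conc)) {
        ic50 <- min(max(ic50, min(conc)), max(conc))
        flags <- c(flags, "ic50_clamped_to_range")
      }
    } else {
      i <- if (length(cross)) cross[1] else 1L
      start_ic50 <- sqrt(conc[i] * conc[min(i + 1, length(conc))])
      # bounded least squares on (top, bottom, log10 IC50, hill); multi-start
      # over the slope to avoid local minima on steep curves
      f4 <- function(p) {
        pred <- p[2] + (p[1] - p[2]) /
          (1 + (concentrations_um / 10^p[3])^p[4])
        sum((responses - pred)^2)
      }
      lo <- c(0.5, 0, log10(min(conc)) - 2, 0.2)
      hi <- c(1.5, 0.95, log10(max(conc)) + 2, 6)
      best <- NULL
      for (h0 in c(0.7, 1.5, 3)) {
        cand <- try(stats::optim(c(1, 0, log10(start_ic50), h0), f4,
                                 method = "L-BFGS-B", lower = lo, upper = hi,
                                 control = list(maxit = 500, factr = 1e4)),
                    silent = TRUE)
        if (!inherits(cand, "try-error") &&
            (is.null(best) || cand$value < best$value)) {
          best <- cand
        }
      }
      if (is.null(best)) {
        out <- fit_ic50(concentrations_um, responses, method = "loglinear",
                        min_response_le = min_response_le,
                        compound_id = compound_id,
                        viability_responses = viability_responses)
        out$diagnostics$flags <- c(out$diagnostics$flags,
                                   "fourpl_failed_fallback_loglinear")
        return(out)
      }
      p <- c(top = best$par[1], bottom = best$par[2],
             x50 = 10^best$par[3], h = best$par[4])
      fourpl_pars <- p
      resid_sd <- sqrt(best$value / max(length(responses) - 4, 1))
      slope <- unname(-p["h"])
      # concentration at absolute response = min_response_le
      if (p["top"] > min_response_le && min_response_le > p["bottom"]) {
        ic50 <- unname(p["x50"] * ((p["top"] - min_response_le) /
                                   (min_response_le - p["bottom"]))^(1 / p["h"]))
      } else {
        ic50 <- unname(p["x50"])
        flags <- c(flags, "midpoint_used")
      }
      if (ic50 < min(conc) || ic50 > max(conc)) {
        ic50 <- min(max(ic50, min(conc)), max(conc))
        flags <- c(flags, "ic50_clamped_to_range")
      }
    }
  }
  vbar <- if (!is.null(viability_responses)) {
    vapply(conc, function(cc) mean(viability_responses[concentrations_um == cc]),
           numeric(1))
  } else NULL
  structure(list(
    compound_id = compound_id, concentrations_um = conc, responses = rbar,
    viability_responses = vbar, ic50_um = ic50, established = established,
    method = method, min_response_le = min_response_le,
    fourpl = fourpl_pars,
    diagnostics = list(slope = slope, residual_sd = resid_sd, flags = flags),
    data = data.frame(concentration_um = concentrations_um,
                      response = responses)), class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  id <- if (is.null(x$compound_id)) "" else paste0(" [", x$compound_id, "]")
  cat(sprintf("ic50_fit%s (%s): %s\n", id, x$method,
              if (x$established) sprintf("IC50 = %.3g uM", x$ic50_um)
              else "NOT_ESTABLISHED"))
  cat(sprintf("  %d concentrations, %.3g - %.3g uM; response range %.3g - %.3g\n",
              length(x$concentrations_um), min(x$concentrations_um),
              max(x$concentrations_um), min(x$responses), max(x$responses)))
  if (length(x$diagnostics$flags)) {
    cat("  flags:", paste(x$diagnostics$flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) {
  if (!is.null(object$fourpl)) {
    c(ic50_um = object$ic50_um, object$fourpl)
  } else {
    c(ic50_um = object$ic50_um, slope = object$diagnostics$slope)
  }
}

#' Predicted normalized response at new concentrations
#'
#' For the four-parameter logistic the fitted curve is evaluated directly;
#' for the loglinear method the per-concentration mean responses are
#' interpolated linearly on log10(concentration) with flat extrapolation
#' beyond the tested range.
#' @param object an `ic50_fit`
#' @param newdata numeric concentrations (uM)
#' @param ... unused
#' @export
predict.ic50_fit <- function(object, newdata, ...) {
  stopifnot(all(newdata > 0))
  if (!is.null(object$fourpl)) {
    p <- object$fourpl
    unname(p["bottom"] + (p["top"] - p["bottom"]) /
             (1 + (newdata / p["x50"])^p["h"]))
  } else {
    stats::approx(log10(object$concentrations_um), object$responses,
                  xout = log10(newdata), rule = 2)$y
  }
}

#' @export
plot.ic50_fit <- function(x, ...) {
  graphics::plot(x$concentrations_um, x$responses, log = "x",
                 xlab = "concentration (uM)",
                 ylab = "fold change over vehicle",
                 main = x$compound_id %||% "dose-response", pch = 19, ...)
  cs <- 10^seq(log10(min(x$concentrations_um)), log10(max(x$concentrations_um)),
               length.out = 100)
  graphics::lines(cs, predict(x, cs), col = "steelblue")
  graphics::abline(h = x$min_response_le, lty = 2, col = "grey50")
  if (x$established) graphics::abline(v = x$ic50_um, lty = 2, col = "firebrick")
  invisible(x)
}

#' Binary irritancy call from a dose-response fit
#'
#' POSITIVE when an IC50 was established within the tested concentration
#' range (including a crossing exactly at the highest concentration),
#' NEGATIVE otherwise.
#' @param fit an [fit_ic50()] result
#' @return "POSITIVE" or "NEGATIVE"
#' @export
classify_compound <- function(fit) {
  stopifnot(inherits(fit, "ic50_fit"))
  if (fit$established) "POSITIVE" else "NEGATIVE"
}

#' Cooper predictivity statistics
#'
#' Sensitivity, specificity and accuracy (overall fraction of correct
#' predictions) of binary assay calls against a reference risk annotation.
#' A ratio whose denominator class is empty is NA and flagged.
#'
#' @param predictions data.frame with columns `compound` and `call`
#'   ("POSITIVE"/"NEGATIVE")
#' @param truth data.frame with columns `compound` and `risk` (logical, or
#'   "yes"/"no")
#' @return object of class `cooper_stats` with tp, fn, tn, fp, sensitivity,
#'   specificity, accuracy, flags
#' @export
cooper_statistics <- function(predictions, truth) {
  stopifnot(all(c("compound", "call") %in% names(predictions)),
            all(c("compound", "risk") %in% names(truth)))
  if (!setequal(predictions$compound, truth$compound)) {
    stop("prediction and truth tables must cover the same compounds")
  }
  m <- merge(predictions, truth, by = "compound")
  risk <- if (is.logical(m$risk)) m$risk else tolower(m$risk) %in% c("yes", "true", "1")
  pos <- m$call == "POSITIVE"
  tp <- sum(pos & risk); fn <- sum(!pos & risk)
  tn <- sum(!pos & !risk); fp <- sum(pos & !risk)
  flags <- character(0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else { flags <- c(flags, "no_positives_in_truth"); NA_real_ }
  spec <- if (tn + fp > 0) tn / (tn + fp) else { flags <- c(flags, "no_negatives_in_truth"); NA_real_ }
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = sens, specificity = spec,
                 accuracy = (tp + tn) / nrow(m), flags = flags),
            class = "cooper_stats")
}

#' @export
print.cooper_stats <- function(x, ...) {
  cat(sprintf("Cooper statistics: TP %d, FN %d, TN %d, FP %d\n",
              x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy))
  invisible(x)
}

#' Per-concentration two-sample Student's t test
#'
#' Pooled-variance two-sided Student's t computed from the textbook
#' formula at each concentration, comparing two groups of compound
#' responses. Zero pooled variance with distinct means yields an infinite
#' statistic, reported with p = 0 and a `degenerate` flag. P values are
#' deliberately unadjusted across concentrations (`p_adjusted = FALSE` in
#' the result records this).
#'
#' @param responses data.frame with columns `concentration_um`, `group`
#'   (two levels) and `response`
#' @return data.frame with concentration, group means, t, df, p,
#'   degenerate flag; attribute `p_adjusted` = FALSE
#' @export
per_concentration_test <- function(responses) {
  stopifnot(all(c("concentration_um", "group", "response") %in% names(responses)))
  gl <- unique(responses$group)
  stopifnot(length(gl) == 2)
  conc <- sort(unique(responses$concentration_um))
  rows <- lapply(conc, function(cc) {
    x <- responses$response[responses$concentration_um == cc & responses$group == gl[1]]
    y <- responses$response[responses$concentration_um == cc & responses$group == gl[2]]
    stopifnot(length(x) >= 2, length(y) >= 2)
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    degenerate <- se == 0
    tt <- if (degenerate) {
      if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
    } else (mean(x) - mean(y)) / se
    df <- n1 + n2 - 2
    p <- if (is.infinite(tt)) 0 else 2 * stats::pt(-abs(tt), df)
    data.frame(concentration_um = cc, mean1 = mean(x), mean2 = mean(y),
               t = tt, df = df, p = p, degenerate = degenerate)
  })
  out <- do.call(rbind, rows)
  attr(out, "p_adjusted") <- FALSE
  out
}

#' Bundled validation compound set
#'
#' Nineteen inhaled small molecules with annotated respiratory safety risk
#' (10 with demonstrated respiratory-tract irritancy, 9 with a clean lung
#' safety profile) and the assay IC50 where a dose-response curve could be
#' established. Ships with the package as a plain-text CSV.
#'
#' @return data.frame with columns `compound`, `mechanism`, `risk`
#'   (logical), `ic50_um` (NA when not established)
#' @export
validation_compounds <- function() {
  path <- system.file("extdata", "validation_compounds.csv",
                      package = "tjscreen", mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$risk <- tolower(x$risk) == "yes"
  x
}

#' Assay calls implied by an IC50 table
#'
#' POSITIVE where an IC50 value is present (curve established), NEGATIVE
#' where it is NA.
#' @param tab data.frame with columns `compound` and `ic50_um`
#' @return data.frame with columns `compound`, `call`
#' @export
calls_from_ic50_table <- function(tab) {
  data.frame(compound = tab$compound,
             call = ifelse(is.na(tab$ic50_um), "NEGATIVE", "POSITIVE"),
             stringsAsFactors = FALSE)
}
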