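#' Generation (doubling) time from paired cell counts
#'
#' `t = H * ln(2) / ln(c2 / c1)`: the doubling time of an exponentially
#' growing culture counted `h_elapsed` hours after plating.
#'
#' @param h_elapsed hours between plating and counting (> 0).
#' @param c1 cells at plating (> 0).
#' @param c2 cells at counting; must exceed `c1` for a finite positive
#'   doubling time.
#' @return doubling time in hours.
#' @examples
#' generation_time(48, 1e5, 2e5) # 48: one doubling in 48 h
#' @export
generation_time <- function(h_elapsed, c1, c2) {
  if (h_elapsed <= 0 || c1 <= 0 || c2 <= 0) {
    stop_config("h_elapsed, c1 and c2 must all be > 0")
  }
  if (c2 <= c1) {
    stop_data("no growth: c2 (", c2, ") must exceed c1 (", c1,
              ") for a finite doubling time")
  }
  h_elapsed * log(2) / log(c2 / c1)
}

#' Normalize MTS absorbances to the vehicle control
#'
#' Divides each well's absorbance by the mean of the control wells, so
#' viability is expressed as a fraction of untreated growth and the
#' controls average exactly 1.
#'
#' @param absorbance numeric vector of per-well readings.
#' @param control_wells indices of the vehicle-control wells.
#' @return numeric vector of viability fractions, same length as input.
#' @examples
#' normalize_viability(c(0.8, 0.4), control_wells = 1)
#' @export
normalize_viability <- function(absorbance, control_wells) {
  if (length(control_wells) == 0L) stop_config("control_wells must be nonempty")
  ctrl <- mean(absorbance[control_wells])
  if (!is.finite(ctrl) || ctrl <= 0) {
    stop_data("control mean must be positive, got ", ctrl)
  }
  absorbance / ctrl
}

# 4PL decreasing dose-response curve; d = 0 maps to the upper asymptote.
four_pl <- function(d, ic50, hill, lower, upper) {
  lower + (upper - lower) / (1 + (d / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `v(d) = lower + (upper - lower) / (1 + (d / ic50)^hill)` with the IC50
#' parameterized on the log scale (the relative IC50: the curve's
#' inflection, the GraphPad-style convention). Zero doses stay in the
#' residuals -- they anchor the upper asymptote -- but play no role on the
#' log-dose abscissa. Initialization uses the data's own range (upper = max
#' viability, lower = min, IC50 = dose nearest the half-range crossing)
#' with three hill-slope starts to escape local minima. Non-convergence is
#' reported honestly: `converged = FALSE` and no fabricated IC50.
#'
#' @param dr data.frame with `dose` and `viability` columns (replicates as
#'   repeated rows), e.g. from [simulate_dose_response()].
#' @param fix_lower,fix_upper optionally pin an asymptote (useful with few
#'   distinct doses).
#' @return object of class `dose_response_fit`: `ic50`, `hill`, `lower`,
#'   `upper`, `rss`, `converged`, `ic50_in_range`, `message`.
#' @examples
#' dr <- simulate_dose_response(5.62, 1.2, 0.05, 1,
#'   doses = c(0, 0.5, 1, 2.5, 4, 6, 8, 10), noise_sd = 0)
#' fit_dose_response(dr)$ic50
#' @export
fit_dose_response <- function(dr, fix_lower = NULL, fix_upper = NULL) {
  if (!all(c("dose", "viability") %in% names(dr))) {
    stop_data("dose-response data needs dose and viability columns")
  }
  d <- dr$dose
  v <- dr$viability
  n_free <- 2L + is.null(fix_lower) + is.null(fix_upper)
  if (length(unique(d)) < n_free) {
    stop_data("need at least ", n_free, " distinct doses for ", n_free,
              " free parameters; fix an asymptote or add doses")
  }
  pos <- d[d > 0]
  vmax <- max(v)
  vmin <- min(v)
  half <- (vmax + vmin) / 2
  ic50_start <- pos[which.min(abs(v[d > 0] - half))]
  if (length(ic50_start) == 0L || ic50_start <= 0) ic50_start <- stats::median(pos)

  fail <- structure(
    list(ic50 = NA_real_, hill = NA_real_, lower = NA_real_,
         upper = NA_real_, rss = NA_real_, converged = FALSE,
         ic50_in_range = NA, message = "fit did not converge"),
    class = "dose_response_fit")

  best <- NULL
  for (hill0 in c(0.5, 1, 2)) {
    start <- list(log_ic50 = log(ic50_start), hill = hill0)
    if (is.null(fix_lower)) start$lower <- vmin
    if (is.null(fix_upper)) start$upper <- vmax
    form <- stats::as.formula(paste(
      "v ~",
      if (is.null(fix_lower)) "lower" else deparse(fix_lower), "+ (",
      if (is.null(fix_upper)) "upper" else deparse(fix_upper), "- ",
      if (is.null(fix_lower)) "lower" else deparse(fix_lower),
      ") / (1 + (d / exp(log_ic50))^hill)"
    ))
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = data.frame(d = d, v = v), start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(fail)
  cf <- stats::coef(best$fit)
  lower <- if (is.null(fix_lower)) unname(cf["lower"]) else fix_lower
  upper <- if (is.null(fix_upper)) unname(cf["upper"]) else fix_upper
  ic50 <- exp(unname(cf["log_ic50"]))
  hill <- unname(cf["hill"])
  ok <- is.finite(ic50) && ic50 > 0 && lower < upper && hill > 0
  structure(
    list(ic50 = ic50, hill = hill, lower = lower, upper = upper,
         rss = best$rss,
         converged = ok,
         ic50_in_range = ic50 >= min(pos) && ic50 <= max(pos),
         message = if (ok) "ok" else
           "degenerate fit (non-decreasing curve or inverted asymptotes)"),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "4PL fit: IC50 = %.4g uM (hill %.3g, lower %.3g, upper %.3g, rss %.3g)%s\n",
      x$ic50, x$hill, x$lower, x$upper, x$rss,
      if (isTRUE(x$ic50_in_range)) "" else " [IC50 outside dose range]"))
  } else {
    cat("4PL fit did not converge:", x$message, "\n")
  }
  invisible(x)
}

#' Assign outcome cohorts from disease-free intervals
#'
#' Good responders have a disease-free interval strictly greater than
#' `good_min_days` (default 300); poor responders strictly less than
#' `poor_max_days` (default 100). Everything else -- including records with
#' no DFI -- is labeled `"unclassified"` rather than imputed.
#'
#' @param sheet sample sheet with a `dfi_days` column (NA allowed).
#' @param good_min_days exclusive lower bound for good responders.
#' @param poor_max_days exclusive upper bound for poor responders.
#' @return list with `sheet` (input plus/overwriting `cohort`) and `counts`
#'   (named integer vector: good, poor, unclassified).
#' @examples
#' sheet <- data.frame(sample_id = paste0("d", 1:3),
#'                     dfi_days = c(340, 58, 300))
#' assign_cohorts(sheet)$counts
#' @export
assign_cohorts <- function(sheet, good_min_days = 300, poor_max_days = 100) {
  dfi <- sheet$dfi_days
  if (any(!is.na(dfi) & dfi < 0)) stop_data("negative DFI days")
  cohort <- rep("unclassified", nrow(sheet))
  cohort[!is.na(dfi) & dfi > good_min_days] <- "good"
  cohort[!is.na(dfi) & dfi < poor_max_days] <- "poor"
  sheet$cohort <- cohort
  counts <- c(good = sum(cohort == "good"),
              poor = sum(cohort == "poor"),
              unclassified = sum(cohort == "unclassified"))
  list(sheet = sheet, counts = counts)
}
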