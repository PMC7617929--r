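#' Fit a four-parameter log-logistic halo dose-response model
#'
#' Least-squares fit of `diameter = c + (d - c) / (1 + exp(b * (log(conc) -
#' log(e))))` (see [fourpl()]). Initial values take `d` from the largest and
#' `c` from the smallest per-concentration mean and `e` from the geometric
#' mid-concentration; the slope is multi-started over `b` in {+-0.5, +-1,
#' +-2} and the lowest-RSS converged solution returned. `e` is optimised on
#' the log scale so the inflection stays positive.
#'
#' @param data data.frame with columns `conc_mM` (> 0) and `diameter_mm` for
#'   one strain x carbon source.
#' @return an object of class `fourpl_fit`: parameters `b, c, d, e`, `rss`,
#'   `n`, `converged`, `degenerate` (flat response), approximate standard
#'   errors and 95% confidence intervals (curvature-based), and the `nls`
#'   object. Fewer than 5 distinct concentrations, an all-identical
#'   response, or an inflection estimate more than 10x outside the tested
#'   dose range (unidentifiable sigmoid) give a non-converged result with an
#'   explanation rather than an error.
#' @export
fit_four_pl <- function(data) {
  check_columns(data, c("conc_mM", "diameter_mm"), "data")
  stopifnot(all(data$conc_mM > 0))
  fail <- function(msg) structure(list(b = NA_real_, c = NA_real_, d = NA_real_,
                                       e = NA_real_, rss = NA_real_,
                                       n = nrow(data), converged = FALSE,
                                       degenerate = FALSE, message = msg,
                                       se = NULL, ci = NULL, fit = NULL),
                                  class = "fourpl_fit")
  if (length(unique(data$conc_mM)) < 5)
    return(fail("need >= 5 distinct concentrations for a 4PL fit"))
  if (length(unique(data$diameter_mm)) == 1) {
    out <- fail("all diameters identical: flat (degenerate) response")
    out$degenerate <- TRUE
    out$c <- out$d <- data$diameter_mm[1]
    out$b <- 0; out$e <- exp(mean(log(range(data$conc_mM))))
    out$rss <- 0
    return(out)
  }
  means <- tapply(data$diameter_mm, data$conc_mM, mean)
  d0 <- max(means); c0 <- min(means)
  e0 <- exp(mean(log(range(data$conc_mM))))
  best <- NULL
  for (b0 in c(0.5, -0.5, 1, -1, 2, -2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        diameter_mm ~ c + (d - c) / (1 + exp(b * (log(conc_mM) - loge))),
        data = data,
        start = list(b = b0, c = c0, d = d0, loge = log(e0)),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10,
                                             ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-8 * max(best$rss, 1))
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(fail("no start converged"))
  cf <- coef(best$fit)
  # identifiability guard: an inflection far outside the tested doses means
  # the sigmoid degenerated into an unconstrained log-linear ramp
  e_chk <- exp(cf[["loge"]])
  if (e_chk > 10 * max(data$conc_mM) || e_chk < min(data$conc_mM) / 10) {
    out <- fail(sprintf(
      "inflection estimate %.3g mM lies far outside the tested dose range", e_chk))
    out$rss <- best$rss
    return(out)
  }
  se <- tryCatch(sqrt(diag(vcov(best$fit))), error = function(e) rep(NA_real_, 4))
  names(se) <- names(cf)
  e_hat <- exp(cf[["loge"]])
  se_out <- c(b = unname(se["b"]), c = unname(se["c"]), d = unname(se["d"]),
              e = unname(e_hat * se["loge"]))   # delta method
  ci <- rbind(b = cf[["b"]] + c(-1.96, 1.96) * se_out["b"],
              c = cf[["c"]] + c(-1.96, 1.96) * se_out["c"],
              d = cf[["d"]] + c(-1.96, 1.96) * se_out["d"],
              e = exp(log(e_hat) + c(-1.96, 1.96) * se["loge"]))
  colnames(ci) <- c("lo95", "hi95")
  structure(list(b = cf[["b"]], c = cf[["c"]], d = cf[["d"]], e = e_hat,
                 rss = best$rss, n = nrow(data), converged = TRUE,
                 degenerate = abs(cf[["d"]] - cf[["c"]]) < 1e-8,
                 message = NULL, se = se_out, ci = ci, fit = best$fit),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (!x$converged) {
    cat("fourpl_fit (not converged):", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("fourpl_fit: b=%.4g c=%.4g d=%.4g e=%.4g mM, rss=%.4g, n=%d%s\n",
              x$b, x$c, x$d, x$e, x$rss, x$n,
              if (x$degenerate) " [degenerate/flat]" else ""))
  invisible(x)
}

#' @export
predict.fourpl_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$conc_mM else newdata
  if (!object$converged && !object$degenerate)
    stop("cannot predict from a non-converged 4PL fit")
  if (object$degenerate && object$b == 0) return(rep(object$c, length(x)))
  fourpl(x, object$b, object$c, object$d, object$e)
}

#' Ordinary least-squares linear halo model
#'
#' @param data data.frame with columns `conc_mM` and `diameter_mm`; at least
#'   3 distinct concentrations required.
#' @return an object of class `linear_fit` with `intercept` (mm), `slope`
#'   (mm/mM), `rss`, `n` and the `lm` object.
#' @export
fit_linear <- function(data) {
  check_columns(data, c("conc_mM", "diameter_mm"), "data")
  if (length(unique(data$conc_mM)) < 3)
    stop("need >= 3 distinct concentrations for a linear fit")
  fit <- lm(diameter_mm ~ conc_mM, data = data)
  structure(list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
                 rss = sum(residuals(fit)^2), n = nrow(data), fit = fit),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear_fit: intercept=%.4g mm, slope=%.4g mm/mM, rss=%.4g, n=%d\n",
              x$intercept, x$slope, x$rss, x$n))
  invisible(x)
}

#' @export
predict.linear_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$conc_mM else newdata
  object$intercept + object$slope * x
}

#' Choose between the 4PL and the linear halo model
#'
#' Small-sample corrected information criterion (Gaussian likelihood from the
#' RSS; k = 5 parameters for the 4PL including the error variance, k = 3 for
#' the line). Ties and non-converged 4PL fits fall back to the simpler
#' linear model.
#'
#' @param fourpl a [fit_four_pl()] result.
#' @param linear a [fit_linear()] result on the same data.
#' @return list `choice` ("fourpl" or "linear"), `aicc_fourpl`,
#'   `aicc_linear`, and the two fits.
#' @export
select_model <- function(fourpl, linear) {
  stopifnot(inherits(fourpl, "fourpl_fit"), inherits(linear, "linear_fit"))
  if (fourpl$converged && fourpl$n != linear$n)
    stop("the two fits must be on identical data")
  aicc <- function(rss, n, k) {
    if (n - k - 1 <= 0) return(Inf)
    n * log(max(rss, 1e-300) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  a_lin <- aicc(linear$rss, linear$n, 3)
  a_4pl <- if (fourpl$converged) aicc(fourpl$rss, fourpl$n, 5) else Inf
  choice <- if (a_4pl < a_lin) "fourpl" else "linear"
  list(choice = choice, aicc_fourpl = a_4pl, aicc_linear = a_lin,
       fourpl = fourpl, linear = linear)
}

#' Maximum non-motile baseline diameter
#'
#' The reference halo level a non-motile control (e.g. a fliG-like flagellar
#' rotor mutant) can reach by growth alone: mean control diameter plus two
#' standard deviations.
#'
#' @param data halo table (`strain, diameter_mm`, ...).
#' @param control_strain label of the non-motile control strain.
#' @return baseline diameter, mm.
#' @export
non_motile_baseline <- function(data, control_strain = "fliG") {
  check_columns(data, c("strain", "diameter_mm"), "data")
  ctrl <- data$diameter_mm[data$strain == control_strain]
  if (!length(ctrl))
    stop("no measurements for control strain '", control_strain, "'")
  s <- if (length(ctrl) > 1) sd(ctrl) else 0
  mean(ctrl) + 2 * s
}

#' Fit, select and report halo models for every strain x carbon source
#'
#' @param table a halo measurement table (see [generate_halo_table()]).
#' @param control_strain non-motile control used for the baseline; excluded
#'   from curve fitting.
#' @return list with `fits` (named list of [select_model()] results),
#'   `summary` (one row per strain x carbon: chosen model, parameters, rss,
#'   criterion) and `baseline` (mm).
#' @export
fit_halo_table <- function(table, control_strain = "fliG") {
  check_columns(table, c("strain", "carbon_source", "conc_mM", "diameter_mm"),
                "table")
  baseline <- non_motile_baseline(table, control_strain)
  sub <- table[table$strain != control_strain, , drop = FALSE]
  keys <- unique(sub[, c("strain", "carbon_source")])
  fits <- list()
  rows <- list()
  for (r in seq_len(nrow(keys))) {
    d <- sub[sub$strain == keys$strain[r] &
               sub$carbon_source == keys$carbon_source[r], , drop = FALSE]
    sel <- select_model(fit_four_pl(d), fit_linear(d))
    key <- paste(keys$strain[r], keys$carbon_source[r], sep = ":")
    fits[[key]] <- sel
    rows[[key]] <- data.frame(
      strain = keys$strain[r], carbon_source = keys$carbon_source[r],
      model = sel$choice,
      b = sel$fourpl$b, c = sel$fourpl$c, d = sel$fourpl$d, e = sel$fourpl$e,
      intercept = sel$linear$intercept, slope = sel$linear$slope,
      rss = if (sel$choice == "fourpl") sel$fourpl$rss else sel$linear$rss,
      aicc_fourpl = sel$aicc_fourpl, aicc_linear = sel$aicc_linear)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(fits = fits, summary = summary, baseline = baseline)
}
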