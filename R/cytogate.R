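#' Cytometry gate configuration
#'
#' A reproducible two-stage gate: events below `fl_threshold` fluorescence
#' are unlabelled (not constitutively marked cells) and excluded; labelled
#' events are split by the scatter-plane line `a * fsc + b * ssc >= c`, whose
#' upper-right side is the bacteroid class (bacteroids are larger in forward
#' scatter and more granular in side scatter than undifferentiated bacteria,
#' so `a, b >= 0`). Boundary equality goes to the bacteroid side.
#'
#' @param fl_threshold fluorescence threshold, instrument units.
#' @param a,b,c scatter-boundary coefficients; `(a, b) != (0, 0)`,
#'   `a >= 0`, `b >= 0`.
#' @return an object of class `gate_config`.
#' @export
gate_config <- function(fl_threshold, a, b, c) {
  check_number(fl_threshold, "fl_threshold", 0)
  check_number(a, "a", 0)
  check_number(b, "b", 0)
  check_number(c, "c")
  if (a == 0 && b == 0) stop("boundary coefficients (a, b) must not both be 0")
  structure(list(fl_threshold = fl_threshold, a = a, b = b, c = c),
            class = "gate_config")
}

#' Midline scatter gate between two population means
#'
#' Convenience constructor: the perpendicular bisector of the segment joining
#' the bacteria and bacteroid (fsc, ssc) means.
#'
#' @param bacteria_mean,bacteroid_mean length->=2 vectors; first two entries
#'   are (fsc, ssc).
#' @param fl_threshold fluorescence threshold for labelled events.
#' @return a [gate_config()].
#' @export
midline_gate <- function(bacteria_mean, bacteroid_mean, fl_threshold = 0) {
  u <- bacteroid_mean[1:2] - bacteria_mean[1:2]
  if (any(u <= 0))
    stop("bacteroid mean must exceed bacteria mean in both scatter channels")
  mid <- (bacteroid_mean[1:2] + bacteria_mean[1:2]) / 2
  gate_config(fl_threshold, a = u[1], b = u[2], c = sum(u * mid))
}

#' Apply fluorescence and scatter gates to an event table
#'
#' @param events data.frame `fsc, ssc, fl`; all values must be finite and
#'   non-negative, otherwise the offending row numbers are reported.
#' @param config a [gate_config()].
#' @return `events` with an added `label` column:
#'   `"unlabelled"`, `"bacteria"` or `"bacteroid"`.
#' @export
apply_gates <- function(events, config) {
  stopifnot(inherits(config, "gate_config"))
  check_columns(events, c("fsc", "ssc", "fl"), "events")
  vals <- as.matrix(events[, c("fsc", "ssc", "fl")])
  bad <- which(!apply(is.finite(vals) & vals >= 0, 1, all))
  if (length(bad))
    stop("malformed event rows (non-finite or negative): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" ... (%d total)", length(bad)) else "")
  label <- ifelse(events$fl < config$fl_threshold, "unlabelled",
                  ifelse(config$a * events$fsc + config$b * events$ssc >= config$c,
                         "bacteroid", "bacteria"))
  events$label <- label
  events
}

#' Read cytometry events until enough reasonable ones are collected
#'
#' Mirrors an acquisition rule of counting until a target number of
#' reasonable events: rows are scanned in order and kept while finite; the
#' scan stops once `n_target` reasonable events have been collected. If the
#' table is exhausted first, the result carries `exhausted = TRUE`.
#'
#' @param events data.frame `fsc, ssc, fl`.
#' @param n_target events to collect (default 5000).
#' @return list `events` (the reasonable rows, at most `n_target`),
#'   `exhausted`.
#' @export
collect_events <- function(events, n_target = 5000) {
  check_columns(events, c("fsc", "ssc", "fl"), "events")
  ok <- is.finite(events$fsc) & is.finite(events$ssc) & is.finite(events$fl) &
    events$fsc >= 0 & events$ssc >= 0 & events$fl >= 0
  keep <- which(cumsum(ok) <= n_target & ok)
  list(events = events[keep, , drop = FALSE],
       exhausted = sum(ok) < n_target)
}

#' Summarise a gated nodule sample
#'
#' Scales class counts to cells per gram of nodule:
#' `count * dilution_factor * (resuspension_volume / analysed_volume) /
#' nodule_mass_g`.
#'
#' @param labelled an [apply_gates()] result.
#' @param dilution_factor fold dilution before acquisition (>= 1).
#' @param analysed_volume volume actually analysed by the cytometer.
#' @param nodule_mass_g nodule fresh mass, g (> 0).
#' @param resuspension_volume volume the nodule pellet was resuspended in
#'   (same units as `analysed_volume`; default equal, i.e. ratio 1).
#' @param sample_id label echoed in the output.
#' @return one-row data.frame `sample_id, n_labelled, n_bacteria,
#'   n_bacteroids, bacteria_per_gram, bacteroids_per_gram,
#'   proportion_bacteria`.
#' @export
summarize_nodule_sample <- function(labelled, dilution_factor, analysed_volume,
                                    nodule_mass_g,
                                    resuspension_volume = analysed_volume,
                                    sample_id = "sample") {
  check_columns(labelled, c("label"), "labelled")
  check_number(dilution_factor, "dilution_factor", 1)
  check_number(analysed_volume, "analysed_volume", 0, strict_lower = TRUE)
  check_number(nodule_mass_g, "nodule_mass_g", 0, strict_lower = TRUE)
  check_number(resuspension_volume, "resuspension_volume", 0, strict_lower = TRUE)
  n_bac <- sum(labelled$label == "bacteria")
  n_boid <- sum(labelled$label == "bacteroid")
  n_lab <- n_bac + n_boid
  if (n_lab == 0) warning("no labelled events in sample '", sample_id, "'")
  scale <- dilution_factor * (resuspension_volume / analysed_volume) / nodule_mass_g
  data.frame(sample_id = sample_id, n_labelled = n_lab, n_bacteria = n_bac,
             n_bacteroids = n_boid,
             bacteria_per_gram = n_bac * scale,
             bacteroids_per_gram = n_boid * scale,
             proportion_bacteria = if (n_lab > 0) n_bac / n_lab else NA_real_)
}
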