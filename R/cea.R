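#' Net monetary benefit of a strategy outcome
#'
#' `NMB(lambda) = lambda * QALYs - cost`: the strategy with the highest net
#' monetary benefit at willingness-to-pay `lambda` is preferred.
#'
#' @param outcome An `ats_outcome` from [run_cohort()].
#' @param wtp Willingness-to-pay threshold(s) in USD per QALY (>= 0).
#' @return Numeric vector of NMB values, one per `wtp`.
#' @export
nmb <- function(outcome, wtp) {
  if (any(wtp < 0)) abort("nmb(): willingness-to-pay must be >= 0.")
  wtp * outcome$total_qalys - outcome$total_cost
}

# Ties in NMB resolve to the reference (less invasive) strategy.
NMB_TIE_TOL <- 1e-9

#' Compare two strategy outcomes
#'
#' Computes incremental cost and QALYs (comparator minus reference), the
#' incremental cost-effectiveness ratio or a dominance label, and the net
#' monetary benefit difference with the preferred strategy at each
#' willingness-to-pay threshold. In the published base case the reference is
#' non-operative management and the comparator is operative repair; operative
#' repair costs more and yields fewer QALYs, so the reference dominates and
#' no ICER is defined.
#'
#' @param reference,comparator `ats_outcome` objects from the same parameter
#'   horizon.
#' @param wtp_grid Willingness-to-pay thresholds (USD/QALY); defaults to the
#'   grid in the reference outcome's run settings.
#' @return An object of class `ats_comparison`: a list with `delta_cost`,
#'   `delta_qalys`, `icer` (`NA` unless the comparison is a trade-off),
#'   `classification` (one of `reference_dominates`, `comparator_dominates`,
#'   `trade_off`, `equivalent`) and `nmb` (tibble: `wtp`, `nmb_difference`
#'   as comparator minus reference, `preferred`).
#' @examples
#' p <- base_case_parameters()
#' out <- run_strategies(p)
#' compare_strategies(out$non_operative, out$operative)
#' @export
compare_strategies <- function(reference, comparator, wtp_grid = NULL) {
  if (abs(reference$params$settings$horizon - comparator$params$settings$horizon) > 1e-12) {
    abort("compare_strategies(): outcomes come from different horizons.")
  }
  wtp_grid <- wtp_grid %||% reference$params$settings$wtp_grid
  dc <- comparator$total_cost - reference$total_cost
  dq <- comparator$total_qalys - reference$total_qalys
  tol <- NMB_TIE_TOL
  classification <- if (abs(dc) <= tol && abs(dq) <= tol) {
    "equivalent"
  } else if (dc >= -tol && dq <= tol) {
    "reference_dominates"
  } else if (dc <= tol && dq >= -tol) {
    "comparator_dominates"
  } else {
    "trade_off"
  }
  icer <- if (classification == "trade_off") dc / dq else NA_real_
  nmb_diff <- wtp_grid * dq - dc
  preferred <- ifelse(nmb_diff > tol, comparator$strategy, reference$strategy)
  structure(list(
    reference = reference$strategy, comparator = comparator$strategy,
    reference_cost = reference$total_cost, comparator_cost = comparator$total_cost,
    reference_qalys = reference$total_qalys, comparator_qalys = comparator$total_qalys,
    delta_cost = dc, delta_qalys = dq, icer = icer,
    classification = classification,
    nmb = tibble(wtp = wtp_grid, nmb_difference = nmb_diff, preferred = preferred)
  ), class = "ats_comparison")
}

#' @export
print.ats_comparison <- function(x, ...) {
  cat("<ats_comparison>\n")
  cat(sprintf("  %-14s $%.2f  %.2f QALYs\n", x$reference, x$reference_cost, x$reference_qalys))
  cat(sprintf("  %-14s $%.2f  %.2f QALYs\n", x$comparator, x$comparator_cost, x$comparator_qalys))
  cat(sprintf("  incremental (comparator - reference): $%.2f, %.2f QALYs\n",
              x$delta_cost, x$delta_qalys))
  lab <- switch(x$classification,
                reference_dominates = sprintf("Dominated (%s dominates)", x$reference),
                comparator_dominates = sprintf("%s dominates", x$comparator),
                equivalent = "Equivalent",
                trade_off = sprintf("ICER $%.2f/QALY", x$icer))
  cat("  ", lab, "\n", sep = "")
  for (i in seq_len(nrow(x$nmb))) {
    cat(sprintf("  at $%s/QALY: NMB difference $%.2f, preferred = %s\n",
                format(x$nmb$wtp[i], big.mark = ","), x$nmb$nmb_difference[i],
                x$nmb$preferred[i]))
  }
  invisible(x)
}

#' @rdname compare_strategies
#' @param x An `ats_comparison`.
#' @param ... Unused.
#' @export
tidy.ats_comparison <- function(x, ...) {
  tibble(strategy = c(x$reference, x$comparator),
         total_cost = c(x$reference_cost, x$comparator_cost),
         total_qalys = c(x$reference_qalys, x$comparator_qalys),
         delta_cost = c(NA_real_, x$delta_cost),
         delta_qalys = c(NA_real_, x$delta_qalys),
         icer = c(NA_real_, x$icer),
         classification = c(NA_character_, x$classification))
}

#' @rdname compare_strategies
#' @export
glance.ats_comparison <- function(x, ...) {
  tibble(delta_cost = x$delta_cost, delta_qalys = x$delta_qalys,
         icer = x$icer, classification = x$classification,
         preferred_at_min_wtp = x$nmb$preferred[which.min(x$nmb$wtp)])
}

#' Export a comparison summary as JSON
#'
#' Writes the comparison (totals, incrementals, classification and NMB per
#' willingness-to-pay) to a JSON file mirroring the base-case results table.
#'
#' @param comparison An `ats_comparison`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
export_comparison <- function(comparison, path) {
  x <- comparison
  jsonlite::write_json(list(
    strategies = list(
      reference = list(strategy = x$reference, total_cost = x$reference_cost,
                       total_qalys = x$reference_qalys),
      comparator = list(strategy = x$comparator, total_cost = x$comparator_cost,
                        total_qalys = x$comparator_qalys)),
    incremental = list(delta_cost = x$delta_cost, delta_qalys = x$delta_qalys,
                       icer = x$icer, classification = x$classification),
    nmb = x$nmb
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
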