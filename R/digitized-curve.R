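#' Digitized Kaplan-Meier curve with numbers-at-risk table
#'
#' Container for one arm's survival curve as extracted from a published
#' figure: a grid of (time, survival) coordinates plus the numbers-at-risk
#' table printed under the figure, and optionally the total number of events
#' reported in the text. This is the raw input to [reconstruct_ipd()].
#'
#' @param points data.frame with columns `time_months` and `survival`.
#'   Must contain the anchor point (0, 1).
#' @param risk_table data.frame with columns `time_months` and `n_at_risk`,
#'   the published numbers at risk.
#' @param label character scalar identifying arm/endpoint/cohort.
#' @param total_events optional non-negative integer: total events reported
#'   in the source, used for the final-interval adjustment during
#'   reconstruction.
#'
#' @return An object of class `digitized_curve`: a list with elements
#'   `label`, `points`, `risk_table`, `total_events`. The constructor runs
#'   [validate_curve()], so points come back sorted, de-duplicated and
#'   clamped monotone non-increasing.
#' @seealso [validate_curve()], [reconstruct_ipd()], [read_curve()]
#' @export
digitized_curve <- function(points, risk_table, label = "curve",
                            total_events = NULL) {
  stopifnot(is.data.frame(points), is.data.frame(risk_table))
  if (!all(c("time_months", "survival") %in% names(points)))
    stop("points must have columns time_months, survival")
  if (!all(c("time_months", "n_at_risk") %in% names(risk_table)))
    stop("risk_table must have columns time_months, n_at_risk")
  if (!is.null(total_events)) {
    total_events <- as.integer(total_events)
    if (length(total_events) != 1L || is.na(total_events) || total_events < 0)
      stop("total_events must be a single non-negative integer")
  }
  obj <- structure(
    list(label = as.character(label)[1],
         points = points[, c("time_months", "survival")],
         risk_table = risk_table[, c("time_months", "n_at_risk")],
         total_events = total_events),
    class = "digitized_curve")
  validate_curve(obj)
}

#' Validate and clean a digitized curve
#'
#' Sorts coordinates by time, collapses duplicated times (keeping the last
#' digitized value), clamps survival to be monotone non-increasing (each
#' value replaced by the minimum of itself and its predecessor -- digitization
#' jitter never creates a rising step), and checks the structural invariants:
#' non-negative times, survival in \[0, 1\], the (0, 1) anchor, and a
#' non-increasing risk table.
#'
#' @param curve a `digitized_curve` (or a bare list with the same fields).
#' @return the cleaned `digitized_curve`.
#' @export
validate_curve <- function(curve) {
  pts <- curve$points
  rt <- curve$risk_table
  if (nrow(pts) == 0) stop("curve has no digitized points")
  if (nrow(rt) == 0) stop("curve has an empty risk table")
  if (any(pts$time_months < 0)) stop("negative time in digitized points")
  if (any(rt$time_months < 0)) stop("negative time in risk table")
  if (any(pts$survival < 0 | pts$survival > 1))
    stop("survival values must lie in [0, 1]")
  if (any(rt$n_at_risk < 0)) stop("negative number at risk")

  pts <- pts[order(pts$time_months), , drop = FALSE]
  # duplicate times: keep the last digitized value
  keep <- !duplicated(pts$time_months, fromLast = TRUE)
  pts <- pts[keep, , drop = FALSE]
  if (pts$time_months[1] != 0 || abs(pts$survival[1] - 1) > 1e-9)
    stop("curve must start at S(0)=1")
  pts$survival <- cummin(pts$survival)
  rownames(pts) <- NULL

  rt <- rt[order(rt$time_months), , drop = FALSE]
  rt <- rt[!duplicated(rt$time_months), , drop = FALSE]
  if (is.unsorted(rev(rt$n_at_risk)))
    stop("numbers at risk must be non-increasing over time")
  rownames(rt) <- NULL

  curve$points <- pts
  curve$risk_table <- rt
  class(curve) <- "digitized_curve"
  curve
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat("Digitized KM curve:", x$label, "\n")
  cat("  ", nrow(x$points), "points over [",
      min(x$points$time_months), ",", max(x$points$time_months), "] months\n")
  cat("  risk table:", nrow(x$risk_table), "entries, n(0) =",
      x$risk_table$n_at_risk[1], "\n")
  if (!is.null(x$total_events))
    cat("  reported events:", x$total_events, "\n")
  invisible(x)
}

#' Read a digitized curve from CSV files
#'
#' @param points_file CSV with header `time_months,survival`.
#' @param risk_file CSV with header `time_months,n_at_risk`.
#' @inheritParams digitized_curve
#' @return a validated `digitized_curve`.
#' @export
read_curve <- function(points_file, risk_file, label = basename(points_file),
                       total_events = NULL) {
  for (f in c(points_file, risk_file))
    if (!file.exists(f)) stop("file not found: ", f)
  pts <- utils::read.csv(points_file)
  rt <- utils::read.csv(risk_file)
  digitized_curve(pts, rt, label = label, total_events = total_events)
}
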