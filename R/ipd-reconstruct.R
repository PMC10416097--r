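#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Implements the interval algorithm of Guyot and colleagues: within each
#' numbers-at-risk interval, the number of censorings is iterated (censor
#' times spread uniformly across the interval, the standard
#' non-informative-censoring assumption) until the implied number at risk at
#' the start of the next interval matches the published risk table; event
#' counts at each digitized time follow from inverting the Kaplan-Meier
#' product-limit recursion against the digitized survival drops. The
#' procedure is fully deterministic.
#'
#' In the final interval (no further risk-table anchor) censoring is taken as
#' zero unless `total_events` was supplied with the curve, in which case the
#' final-interval censoring is iterated until the reconstructed event total
#' matches the reported one. Patients still at risk after the last digitized
#' time are censored there: extrapolation beyond the observed curve is the
#' job of the parametric fits, not of the reconstruction.
#'
#' @param curve a validated [digitized_curve()].
#' @return An object of class `pseudo_ipd`: list with `label` and `data`, a
#'   data.frame of one record per initially at-risk patient with columns
#'   `time` (months) and `event` (1 = event, 0 = censored).
#' @references Guyot P, Ades AE, Ouwens MJ, Welton NJ (2012). Enhanced
#'   secondary analysis of survival data: reconstructing the data from
#'   published Kaplan-Meier survival curves. BMC Med Res Methodol 12:9.
#' @export
reconstruct_ipd <- function(curve) {
  curve <- validate_curve(curve)
  t <- curve$points$time_months
  S <- curve$points$survival
  rt <- curve$risk_table
  # risk-table entries beyond the digitized range carry no usable anchor
  rt <- rt[rt$time_months <= max(t) + 1e-9, , drop = FALSE]
  if (nrow(rt) < 1) stop("risk table has no interval inside the digitized range")
  trisk <- rt$time_months
  nrisk <- as.integer(round(rt$n_at_risk))
  K <- length(t)

  lower <- vapply(trisk, function(tr) which(t >= tr - 1e-9)[1], integer(1))
  # merge risk entries that fall between the same digitized points
  keep <- !duplicated(lower)
  lower <- lower[keep]; trisk <- trisk[keep]; nrisk <- nrisk[keep]
  I <- length(lower)
  upper <- c(lower[-1] - 1L, K)

  n.hat <- numeric(K + 1)   # at risk just before t[k]
  d <- integer(K)           # events at t[k]
  ncen <- integer(I)        # censorings per risk interval
  KM <- numeric(K)
  KM[seq_len(max(lower[1] - 1, 0))] <- S[seq_len(max(lower[1] - 1, 0))]
  n.hat[lower[1]] <- nrisk[1]

  interval_end <- function(i) if (i < I) trisk[i + 1] else max(t[K], trisk[I])

  cen_times <- function(i, n) {
    a <- trisk[i]; b <- interval_end(i)
    if (n <= 0 || b <= a) return(numeric(0))
    a + seq_len(n) * (b - a) / (n + 1)
  }

  # one forward pass over interval i given a censoring count; updates
  # d, KM, n.hat in the enclosing frame and returns at-risk after interval
  pass <- function(i, n_cen) {
    ct <- cen_times(i, n_cen)
    idx <- lower[i]:upper[i]
    brk <- c(trisk[i] - 1e-9, t[idx][-1], interval_end(i) + 1e-9)
    for (j in seq_along(idx)) {
      k <- idx[j]
      ck <- sum(ct >= brk[j] & ct < brk[j + 1])
      KMprev <- if (k == 1) 1 else KM[k - 1]
      if (k == 1) {
        d[k] <<- 0L
      } else if (KMprev > 0 && n.hat[k] > 0) {
        d[k] <<- as.integer(round(n.hat[k] * (1 - S[k] / KMprev)))
        d[k] <<- max(d[k], 0L)
      } else d[k] <<- 0L
      if (d[k] > n.hat[k])
        stop("survival drop implies more events than patients at risk in interval ", i)
      KM[k] <<- if (n.hat[k] > 0) KMprev * (1 - d[k] / n.hat[k]) else KMprev
      n.hat[k + 1] <<- n.hat[k] - d[k] - ck
      if (n.hat[k + 1] < 0)
        stop("inconsistent risk table: negative at-risk count in interval ", i)
    }
    n.hat[upper[i] + 1]
  }

  for (i in seq_len(I)) {
    n_enter <- as.integer(n.hat[lower[i]])
    if (i < I) {
      guess <- if (S[lower[i]] > 0)
        as.integer(round(nrisk[i] * S[lower[i + 1]] / S[lower[i]]) - nrisk[i + 1])
      else 0L
      guess <- min(max(guess, 0L), n_enter)
      for (iter in 1:100) {
        est <- pass(i, guess)
        if (est == nrisk[i + 1]) break
        nxt <- guess + (est - nrisk[i + 1])
        nxt <- min(max(nxt, 0L), n_enter)
        if (nxt == guess) break
        guess <- as.integer(nxt)
      }
      ncen[i] <- guess
      # unresolvable residue: adopt the implied count (risk tables are rounded)
      if (n.hat[lower[i + 1]] != nrisk[i + 1])
        nrisk[i + 1] <- n.hat[lower[i + 1]]
    } else {
      if (is.null(curve$total_events)) {
        ncen[i] <- 0L
        pass(i, 0L)
      } else {
        guess <- 0L
        for (iter in 1:200) {
          pass(i, guess)
          tot <- sum(d)
          if (tot == curve$total_events) break
          nxt <- guess + (tot - curve$total_events)
          nxt <- min(max(nxt, 0L), n_enter)
          if (nxt == guess) break
          guess <- as.integer(nxt)
        }
        ncen[i] <- guess
      }
    }
  }

  times <- rep(t, d)
  events <- rep(1L, length(times))
  for (i in seq_len(I)) {
    ct <- cen_times(i, ncen[i])
    times <- c(times, ct)
    events <- c(events, rep(0L, length(ct)))
  }
  tail_n <- as.integer(round(n.hat[K + 1]))
  if (tail_n > 0) {
    times <- c(times, rep(t[K], tail_n))
    events <- c(events, rep(0L, tail_n))
  }
  o <- order(times, -events)
  pseudo_ipd(data.frame(time = times[o], event = events[o]),
             label = curve$label)
}

#' Pseudo individual-patient data
#'
#' @param data data.frame with columns `time` (months, > 0) and `event`
#'   (1 event, 0 censored).
#' @param label character identifier.
#' @return object of class `pseudo_ipd`.
#' @export
pseudo_ipd <- function(data, label = "ipd") {
  stopifnot(is.data.frame(data), all(c("time", "event") %in% names(data)))
  if (nrow(data) == 0) stop("pseudo-IPD must contain at least one record")
  if (any(data$time < 0)) stop("negative event/censoring time")
  if (!all(data$event %in% c(0L, 1L))) stop("event must be 0 or 1")
  structure(list(label = label,
                 data = data.frame(time = as.numeric(data$time),
                                   event = as.integer(data$event))),
            class = "pseudo_ipd")
}

#' @export
print.pseudo_ipd <- function(x, ...) {
  cat("Pseudo-IPD:", x$label, "-", nrow(x$data), "patients,",
      sum(x$data$event), "events\n")
  invisible(x)
}

#' @export
as.data.frame.pseudo_ipd <- function(x, ...) x$data

#' Kaplan-Meier survival of pseudo-IPD at given times
#'
#' Convenience wrapper around [survival::survfit()] used for round-trip
#' checks of the reconstruction.
#'
#' @param ipd a `pseudo_ipd`.
#' @param times numeric vector of evaluation times (months).
#' @return numeric vector of KM survival estimates at `times`.
#' @export
km_survival <- function(ipd, times) {
  d <- ipd$data
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  sf <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  sf(times)
}

#' Write pseudo-IPD records to CSV
#'
#' Columns `time_months`, `event`, `label`.
#' @param ipd a `pseudo_ipd`.
#' @param file output path.
#' @export
write_ipd <- function(ipd, file) {
  utils::write.csv(
    data.frame(time_months = ipd$data$time, event = ipd$data$event,
               label = ipd$label),
    file, row.names = FALSE)
  invisible(file)
}
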