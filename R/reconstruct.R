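#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Inverts published Kaplan-Meier step coordinates and the number-at-risk
#' table into approximate per-subject event/censoring times, following the
#' iterative algorithm of Guyot and colleagues: within each risk-table
#' interval, censoring is assumed uniform; the number censored is adjusted
#' until the reconstructed number at risk matches the table at the next
#' entry, and event counts are chosen so the reconstructed product-limit
#' estimate tracks the digitized curve. When the source reports a total
#' event count, the final (unconstrained) interval's censoring is chosen to
#' reproduce it; otherwise no censoring is assumed there.
#'
#' @param km A [km_digitized()] object.
#' @param total_events Optional override of `km$total_events`; set to `NA`
#'   to ignore a stored count.
#' @return A `data.frame` with columns `time` (> 0, months) and `event`
#'   (1 = event, 0 = censored), one row per initially at-risk subject.
#'   Attributes `intervals` (per-interval events/censorings and residual
#'   risk-table mismatch) and `rounding_ties` document the integer rounding.
#' @export
#' @examples
#' ipd0 <- simulate_ipd(80, "log-normal", c(meanlog = 2.7, sdlog = 1.1),
#'                      censoring = "exponential", cens_rate = 0.02, seed = 7)
#' km <- km_digitize(ipd0, interval = 3)
#' ipd <- reconstruct_ipd(km)
#' nrow(ipd)   # 80
reconstruct_ipd <- function(km, total_events = NULL) {
  if (!inherits(km, "km_digitized")) stop("km must be a km_digitized object")
  if (length(km$risk_times) < 2) stop("need at least 2 risk-table entries")
  if (is.null(total_events)) total_events <- km$total_events
  if (length(total_events) && is.na(total_events)) total_events <- NULL

  Tt <- km$risk_times
  n_tab <- km$n_at_risk
  J <- length(Tt)
  t_max <- max(km$times, Tt)

  n_run <- n_tab[1]
  s_run <- 1
  rec_t <- numeric(0)
  rec_e <- integer(0)
  ties <- 0L
  meta <- vector("list", J)

  # process one interval [lo, up) given n/S on entry and n_cens censorings;
  # returns records and exit state
  pass <- function(lo, up, idx, n0, s0, n_cens) {
    cens_t <- if (n_cens > 0) lo + seq_len(n_cens) * (up - lo) / (n_cens + 1) else numeric(0)
    n <- n0; s <- s0
    tt <- numeric(0); ee <- integer(0)
    used <- 0L; ev <- 0L
    for (k in idx) {
      tk <- km$times[k]
      in_before <- which(cens_t <= tk)
      if (length(in_before) > used) {
        new <- setdiff(in_before, seq_len(used))
        tt <- c(tt, cens_t[new]); ee <- c(ee, rep(0L, length(new)))
        n <- n - length(new); used <- used + length(new)
      }
      if (n <= 0 || s <= 0) next
      raw <- n * (1 - km$survival[k] / s)
      d <- round_half_up(raw)
      if (abs(raw - floor(raw) - 0.5) < 1e-9) ties <<- ties + 1L
      d <- max(0L, min(d, n))
      if (d > 0) {
        s <- s * (1 - d / n)
        tt <- c(tt, rep(tk, d)); ee <- c(ee, rep(1L, d))
        n <- n - d; ev <- ev + d
      }
    }
    if (used < n_cens) {
      rest <- seq.int(used + 1L, n_cens)
      take <- min(length(rest), n)
      if (take > 0) {
        tt <- c(tt, cens_t[rest[seq_len(take)]]); ee <- c(ee, rep(0L, take))
        n <- n - take
      }
    }
    list(t = tt, e = ee, n_end = n, s_end = s, events = ev)
  }

  for (j in seq_len(J)) {
    lo <- Tt[j]
    last <- j == J
    up <- if (last) max(t_max, lo) else Tt[j + 1]
    idx <- if (last) which(km$times >= lo) else which(km$times >= lo & km$times < up)
    idx <- idx[km$times[idx] > 0]          # the (0,1) anchor carries no events

    if (!last) {
      target <- n_tab[j + 1]
      cj <- 0L
      seen <- integer(0)
      best <- NULL
      for (it in 1:60) {
        res <- pass(lo, up, idx, n_run, s_run, cj)
        diff <- res$n_end - target
        if (is.null(best) || abs(diff) < abs(best$diff)) {
          best <- list(res = res, diff = diff, cj = cj)
        }
        if (diff == 0) break
        if (cj %in% seen) break
        seen <- c(seen, cj)
        cj <- max(0L, min(n_run, cj + diff))
      }
      if (best$diff < 0 && best$cj == 0L) {
        stop("risk table inconsistent with curve in interval ", j,
             " [", lo, ", ", up, "): curve implies ", -best$diff,
             " fewer subjects at t = ", up, " than the risk table reports")
      }
      res <- best$res
      meta[[j]] <- data.frame(interval = j, lower = lo, upper = up,
                              events = res$events,
                              censored = best$cj, mismatch = best$diff)
    } else {
      cj <- 0L
      if (!is.null(total_events)) {
        # rescaling step: pick final-interval censoring reproducing the
        # reported total event count (event count is non-increasing in cj)
        ev_so_far <- sum(rec_e)
        best <- NULL
        for (cand in 0:n_run) {
          res_c <- pass(lo, up, idx, n_run, s_run, cand)
          gap <- abs(ev_so_far + res_c$events - total_events)
          if (is.null(best) || gap < best$gap) best <- list(cj = cand, gap = gap)
          if (gap == 0) break
        }
        cj <- best$cj
      }
      res <- pass(lo, up, idx, n_run, s_run, cj)
      meta[[j]] <- data.frame(interval = j, lower = lo, upper = up,
                              events = res$events, censored = cj, mismatch = 0)
    }
    rec_t <- c(rec_t, res$t); rec_e <- c(rec_e, res$e)
    n_run <- res$n_end; s_run <- res$s_end
  }

  if (n_run > 0) {   # still at risk at the end of follow-up
    rec_t <- c(rec_t, rep(t_max, n_run))
    rec_e <- c(rec_e, rep(0L, n_run))
  }
  ord <- order(rec_t, -rec_e)
  out <- data.frame(time = pmax(rec_t[ord], .Machine$double.eps),
                    event = rec_e[ord])
  attr(out, "intervals") <- do.call(rbind, meta)
  attr(out, "rounding_ties") <- ties
  out
}

#' Read digitized KM coordinates and a risk table from delimited text
#'
#' @param curve_file CSV/TSV with columns `time`, `survival`.
#' @param risk_file CSV/TSV with columns `time`, `n_risk`.
#' @param total_events Optional reported total event count.
#' @param ... Passed to [km_digitized()] (e.g. `tol`).
#' @return A [km_digitized()] object.
#' @export
read_km_csv <- function(curve_file, risk_file, total_events = NULL, ...) {
  sep <- function(f) if (grepl("\\.tsv$", f, ignore.case = TRUE)) "\t" else ","
  cu <- read.csv(curve_file, sep = sep(curve_file))
  ri <- read.csv(risk_file, sep = sep(risk_file))
  if (!all(c("time", "survival") %in% names(cu))) {
    stop("curve file must have columns time, survival")
  }
  if (!all(c("time", "n_risk") %in% names(ri))) {
    stop("risk file must have columns time, n_risk")
  }
  km_digitized(cu$time, cu$survival, ri$time, ri$n_risk,
               total_events = total_events, ...)
}

#' Write reconstructed pseudo-IPD as CSV (columns time, event)
#' @param ipd `data.frame` with `time` and `event`.
#' @param path Output file.
#' @export
write_ipd_csv <- function(ipd, path) {
  write.csv(ipd[, c("time", "event")], path, row.names = FALSE)
  invisible(path)
}

#' Read pseudo-IPD from CSV (columns time, event)
#' @param path Input file.
#' @export
read_ipd_csv <- function(path) {
  x <- read.csv(path)
  if (!all(c("time", "event") %in% names(x))) {
    stop("IPD file must have columns time, event")
  }
  x[, c("time", "event")]
}
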