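check_ipd <- function(ipd) {
  if (!is.data.frame(ipd) || !all(c("time_months", "event") %in% names(ipd))) {
    abort("IPD must be a data frame with columns time_months, event",
          class = "psmcea_invalid_input")
  }
  if (nrow(ipd) == 0) abort("IPD is empty", class = "psmcea_empty_input")
  if (any(!is.finite(ipd$time_months)) || any(ipd$time_months <= 0)) {
    abort("all IPD times must be positive and finite", class = "psmcea_invalid_input")
  }
  if (!all(ipd$event %in% c(0, 1))) {
    abort("event must be 0 or 1", class = "psmcea_invalid_input")
  }
  invisible(ipd)
}

#' Product-limit (Kaplan-Meier) estimate of a survival curve
#'
#' Thin wrapper around [survival::survfit()] returning a tidy step-function
#' table. At tied times events precede censorings, the standard
#' product-limit convention.
#'
#' @param ipd Tibble with columns `time_months` and `event` (1 = event,
#'   0 = censored).
#' @return A tibble with columns `time_months`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, one row per distinct observed time. Survival
#'   before the first row is 1.
#' @export
km_estimate <- function(ipd) {
  check_ipd(ipd)
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1,
                           data = ipd, conf.type = "none")
  tibble(time_months = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         n_censor = fit$n.censor, survival = fit$surv)
}

# step function S(t) for a km_estimate / digitized curve table
km_step_fun <- function(curve) {
  stats::stepfun(curve$time_months, c(1, curve$survival), right = FALSE)
}

validate_curve_risk <- function(curve, risk, repair_tol = 0.005) {
  if (!is.data.frame(curve) || !all(c("time_months", "survival") %in% names(curve)) ||
      nrow(curve) == 0) {
    abort("curve must be a non-empty data frame with time_months, survival",
          class = "psmcea_invalid_input")
  }
  if (!is.data.frame(risk) || !all(c("time_months", "n_at_risk") %in% names(risk)) ||
      nrow(risk) < 2) {
    abort("risk table needs columns time_months, n_at_risk and >= 2 rows",
          class = "psmcea_invalid_input")
  }
  if (is.unsorted(curve$time_months, strictly = TRUE)) {
    abort("curve times must be strictly increasing", class = "psmcea_invalid_input")
  }
  if (any(curve$survival < 0 | curve$survival > 1)) {
    abort("survival must lie in [0, 1]", class = "psmcea_invalid_input")
  }
  rises <- diff(curve$survival)
  bad <- which(rises > repair_tol)
  if (length(bad)) {
    abort(sprintf("survival increases by more than %g at curve rows: %s",
                  repair_tol, paste(bad + 1, collapse = ", ")),
          class = "psmcea_invalid_input")
  }
  inc <- which(diff(risk$n_at_risk) > 0)
  if (length(inc)) {
    abort(sprintf("n_at_risk increases at risk-table rows: %s",
                  paste(inc + 1, collapse = ", ")),
          class = "psmcea_invalid_input")
  }
  if (risk$n_at_risk[1] <= 0) {
    abort("initial n_at_risk must be positive", class = "psmcea_invalid_input")
  }
  # monotonicity repair of digitization pixel noise: clamp to running minimum
  curve$survival <- cummin(curve$survival)
  curve
}

#' Reconstruct pseudo individual-patient data from a digitized curve
#'
#' Deterministic implementation of the standard algorithm for recovering
#' pseudo-IPD from digitized Kaplan-Meier coordinates plus a number-at-risk
#' table: within each risk-table interval the number of censorings is
#' solved iteratively so that the at-risk count implied by the curve's
#' survival drops matches the published count entering the next interval;
#' censoring times are spread evenly within the interval (interval midpoint
#' when a single censoring is placed). Small digitization noise (survival
#' rises up to 0.005) is clamped to the running minimum; larger rises are
#' treated as input errors.
#'
#' @param curve Tibble `time_months`, `survival` — the digitized curve,
#'   step-function convention.
#' @param risk Tibble `time_months`, `n_at_risk` — the number-at-risk table.
#' @param total_events Optional total event count; when given, a final
#'   adjustment pass converts trailing censorings/events after the last
#'   risk-table boundary so the reconstructed total matches.
#' @return A tibble with columns `time_months`, `event`; one row per
#'   reconstructed subject (sample size = initial at-risk count).
#' @references The procedure follows the published iterative KM-inversion
#'   algorithm used throughout health-economic survival reanalysis.
#' @export
reconstruct_ipd <- function(curve, risk, total_events = NULL) {
  curve <- validate_curve_risk(curve, risk)
  # ensure the curve starts at t = 0, S = 1
  if (curve$time_months[1] > 0) {
    curve <- bind_rows(tibble(time_months = 0, survival = 1), curve)
  }
  t_s <- curve$time_months
  s <- curve$survival
  k <- length(t_s)
  t_risk <- risk$time_months
  n_risk <- risk$n_at_risk
  j_max <- length(t_risk)

  # index of first digitized point at/after each risk boundary
  lower <- findInterval(t_risk, t_s, left.open = TRUE) + 1L
  lower[1] <- 1L
  upper <- c(lower[-1] - 1L, k)
  if (any(lower > k)) {
    abort("curve does not cover all risk-table boundaries", class = "psmcea_invalid_input")
  }

  n_hat <- numeric(k + 1L)       # at-risk entering each digitized point
  d <- integer(k)                # events at each digitized point
  cen <- integer(k)              # censorings in [t_s[i], t_s[i+1])
  km_hat <- numeric(k)           # reconstructed KM value at each point
  n_hat[1] <- n_risk[1]
  last_event <- 0L               # index of last point with an event (0 = none)
  km_last <- 1

  place_interval <- function(jlo, jhi, n_cen_j, t_lo, t_hi, n_enter, km_in, last_in) {
    # distribute n_cen_j censor times evenly over (t_lo, t_hi), then walk the
    # digitized points computing event counts from the KM drops
    cen_i <- integer(jhi - jlo + 1L)
    if (n_cen_j > 0) {
      ct <- t_lo + seq_len(n_cen_j) * (t_hi - t_lo) / (n_cen_j + 1)
      cen_i <- vapply(seq(jlo, jhi), function(i) {
        hi <- if (i < k) t_s[i + 1L] else Inf
        sum(ct >= t_s[i] & ct < hi)
      }, integer(1))
      # censor times before the first digitized point of the interval attach to it
      cen_i[1] <- cen_i[1] + sum(ct < t_s[jlo])
    }
    d_i <- integer(jhi - jlo + 1L)
    km_i <- numeric(jhi - jlo + 1L)
    n_cur <- n_enter
    km_cur <- km_in
    last <- last_in
    n_out <- n_enter
    for (ii in seq(jlo, jhi)) {
      idx <- ii - jlo + 1L
      if (ii == 1L) {
        d_i[idx] <- 0L
        km_i[idx] <- 1
      } else {
        d_i[idx] <- if (n_cur > 0) max(0L, round(n_cur * (1 - s[ii] / km_cur))) else 0L
        d_i[idx] <- min(d_i[idx], n_cur)
        km_i[idx] <- if (n_cur > 0) km_cur * (1 - d_i[idx] / n_cur) else km_cur
      }
      if (d_i[idx] > 0) {
        km_cur <- km_i[idx]
        last <- ii
      }
      n_cur <- n_cur - d_i[idx] - cen_i[idx]
      if (n_cur < 0) n_cur <- 0
    }
    list(d = d_i, cen = cen_i, km = km_i, n_exit = n_cur,
         km_last = km_cur, last = last)
  }

  for (j in seq_len(j_max - 1L)) {
    jlo <- lower[j]; jhi <- upper[j]
    if (jhi < jlo) next
    n_enter <- n_hat[jlo]
    # initial censoring guess from the survival ratio across the interval
    s_lo <- s[jlo]
    s_next <- s[min(lower[j + 1L], k)]
    guess <- if (s_lo > 0) round(n_enter * s_next / s_lo - n_risk[j + 1L]) else 0
    n_cen_j <- max(0L, as.integer(guess))
    for (iter in 1:40) {
      res <- place_interval(jlo, jhi, n_cen_j, t_risk[j], t_risk[j + 1L],
                            n_enter, km_last, last_event)
      diff_n <- res$n_exit - n_risk[j + 1L]
      if (diff_n == 0L || (n_cen_j == 0L && diff_n < 0L)) break
      n_cen_j <- max(0L, n_cen_j + diff_n)
    }
    d[jlo:jhi] <- res$d
    cen[jlo:jhi] <- res$cen
    km_hat[jlo:jhi] <- res$km
    n_hat[jhi + 1L] <- res$n_exit
    km_last <- res$km_last
    last_event <- res$last
  }

  # final interval: beyond the last risk boundary assume no interior
  # censoring; events follow the KM drops, survivors are censored at the end
  jlo <- lower[j_max]
  if (jlo <= k) {
    res <- place_interval(jlo, k, 0L, t_risk[j_max], t_s[k],
                          n_hat[jlo], km_last, last_event)
    d[jlo:k] <- res$d
    cen[jlo:k] <- res$cen
    km_hat[jlo:k] <- res$km
    n_hat[k + 1L] <- res$n_exit
  }

  # optional rescaling to a known total event count: convert tail events
  # to censorings (or vice versa) at the latest event times
  if (!is.null(total_events)) {
    excess <- sum(d) - as.integer(total_events)
    i <- k
    while (excess > 0 && i >= 1) {
      take <- min(d[i], excess)
      d[i] <- d[i] - take
      cen[i] <- cen[i] + take
      excess <- excess - take
      i <- i - 1L
    }
    i <- k
    while (excess < 0 && i >= 1) {
      take <- min(cen[i], -excess)
      cen[i] <- cen[i] - take
      d[i] <- d[i] + take
      excess <- excess + take
      i <- i - 1L
    }
  }

  times <- c(rep(t_s, d), cen_times(t_s, cen, t_risk), rep(max(t_s), n_hat[k + 1L]))
  events <- c(rep(1L, sum(d)), rep(0L, sum(cen) + n_hat[k + 1L]))
  out <- tibble(time_months = pmax(times, 1e-9), event = events) |>
    arrange(.data$time_months, desc(.data$event))
  if (nrow(out) != n_risk[1]) {
    abort("reconstruction lost subjects: events+censorings do not conserve n",
          class = "psmcea_internal")
  }
  out
}

# deterministic censoring times: midpoints of [t_i, t_{i+1}) for each
# censoring attributed to digitized point i
cen_times <- function(t_s, cen, t_risk) {
  k <- length(t_s)
  unlist(lapply(seq_len(k), function(i) {
    if (cen[i] == 0L) return(numeric(0))
    hi <- if (i < k) t_s[i + 1L] else max(t_s[k], t_risk[length(t_risk)])
    if (cen[i] == 1L) (t_s[i] + hi) / 2
    else t_s[i] + seq_len(cen[i]) * (hi - t_s[i]) / (cen[i] + 1L)
  }))
}
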