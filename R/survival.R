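#' Kaplan-Meier product-limit estimate
#'
#' Fits the product-limit survival estimate with Greenwood variance and
#' log-log 95% confidence limits. Individuals censored at an event time
#' remain at risk for the events at that time. The estimate steps only at
#' event times.
#'
#' @param data Tibble with columns `time` (> 0, days) and `event`
#'   (1 = death, 0 = censored).
#' @return A `km_fit` object; `tidy()` gives the step table (`time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, `std_err`, `lower`, `upper`),
#'   `glance()` the sample summary including the interpolated median.
#' @examples
#' km_fit(tibble::tibble(time = 1:4, event = 1))
#' @export
km_fit <- function(data) {
  stopifnot(is.data.frame(data), all(c("time", "event") %in% names(data)))
  time <- data$time; event <- data$event
  if (any(time <= 0)) abort("survival times must be positive.")
  if (!all(event %in% c(0, 1))) abort("`event` must be 0 or 1.")
  if (sum(event) == 0) {
    warn("no events observed; survival stays at 1 and the median is undefined.")
  }
  ev_times <- sort(unique(time[event == 1]))
  n_risk <- vapply(ev_times, function(t) sum(time >= t), double(1))
  n_event <- vapply(ev_times, function(t) sum(time == t & event == 1),
                    double(1))
  n_censor <- vapply(ev_times, function(t) sum(time == t & event == 0),
                     double(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw <- cumsum(n_event / (n_risk * pmax(n_risk - n_event, 1e-300)))
  std_err <- surv * sqrt(gw)
  # log-log confidence limits, undefined where S is 0 or 1
  z <- stats::qnorm(0.975)
  se_ll <- ifelse(surv > 0 & surv < 1, sqrt(gw) / abs(log(surv)), NA_real_)
  lower <- ifelse(is.na(se_ll), ifelse(surv == 0, 0, NA_real_),
                  surv^exp(z * se_ll))
  upper <- ifelse(is.na(se_ll), ifelse(surv == 0, 0, NA_real_),
                  surv^exp(-z * se_ll))
  steps <- tibble(time = ev_times, n_risk = n_risk, n_event = n_event,
                  n_censor = n_censor, surv = surv, std_err = std_err,
                  lower = lower, upper = upper)
  med <- interpolated_median(steps)
  structure(list(steps = steps, n = length(time), n_events = sum(event),
                 median = med),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> n = %d, events = %d, interpolated median = %s\n",
              x$n, x$n_events,
              if (is.na(x$median)) "undefined" else format(x$median)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.km_fit <- function(x, ...) x$steps

#' @exportS3Method generics::glance
glance.km_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, median = x$median,
         median_defined = !is.na(x$median))
}

#' Survival curve plot
#'
#' @param object A `km_fit`.
#' @param ... Unused.
#' @return A ggplot step curve with the 95% confidence band.
#' @exportS3Method ggplot2::autoplot
autoplot.km_fit <- function(object, ...) {
  df <- bind_rows(tibble(time = 0, surv = 1, lower = 1, upper = 1),
                  object$steps)
  ggplot(df, aes(x = .data$time, y = .data$surv)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper), stat = "identity",
                fill = "grey80", alpha = 0.5) +
    geom_step() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "time (days)", y = "survival") +
    theme_minimal()
}

#' Interpolated median survival
#'
#' The median is interpolated linearly between the two step points nearest
#' 50% survival, \eqn{(t_1, S_1)} with \eqn{S_1 > 0.5} and
#' \eqn{(t_2, S_2)} with \eqn{S_2 \le 0.5}:
#' \eqn{t_1 + (S_1 - 0.5)/(S_1 - S_2) (t_2 - t_1)}. If survival equals 0.5
#' exactly at a step, that step's time is returned; if it crosses 0.5
#' already at the first event there is no earlier step to interpolate from
#' and the first event time is returned. `NA` if survival never reaches
#' 0.5.
#'
#' @param est A `km_fit` or its step tibble (`time`, `surv`).
#' @return The median survival time, or `NA` when undefined.
#' @export
interpolated_median <- function(est) {
  steps <- if (inherits(est, "km_fit")) est$steps else est
  idx <- which(steps$surv <= 0.5)
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  if (i == 1) return(steps$time[1])
  steps$time[i - 1] +
    (steps$surv[i - 1] - 0.5) / (steps$surv[i - 1] - steps$surv[i]) *
      (steps$time[i] - steps$time[i - 1])
}

#' Bootstrap median survival
#'
#' The resampling procedure behind the reported lifespan medians:
#' individuals — `(time, event)` pairs — are resampled with replacement
#' `n_bootstrap` times (default 100); each replicate gets a Kaplan-Meier
#' fit and an interpolated median; the point estimate is the median of the
#' replicate medians and the standard error their standard deviation.
#' Replicates whose survival never crosses 0.5 are dropped and counted; an
#' error is raised if more than half are dropped.
#'
#' @param data Tibble with `time` and `event` columns.
#' @param n_bootstrap Number of bootstrap replicates (default 100).
#' @param seed Optional integer seed for reproducible resampling (applied
#'   locally; the global RNG state is untouched).
#' @return A `boot_median` object; `glance()` gives the one-row summary
#'   (`median`, `se`, `median_full`, `n_undefined`), `tidy()` the replicate
#'   medians.
#' @export
bootstrap_median <- function(data, n_bootstrap = 100, seed = NULL) {
  stopifnot(n_bootstrap >= 1)
  n <- nrow(data)
  if (n < 10) warn("fewer than 10 individuals; bootstrap medians will be unstable.")
  draw <- function() {
    replicate(n_bootstrap, {
      idx <- sample.int(n, n, replace = TRUE)
      # a no-event resample is a legitimate undefined-median replicate;
      # its per-fit warning would only be noise here
      interpolated_median(suppressWarnings(km_fit(data[idx, ,
                                                       drop = FALSE])))
    })
  }
  meds <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  n_undef <- sum(is.na(meds))
  if (n_undef > n_bootstrap / 2) {
    abort(sprintf("%d of %d bootstrap replicates had an undefined median.",
                  n_undef, n_bootstrap))
  }
  ok <- meds[!is.na(meds)]
  structure(list(estimate = median(ok), se = sd(ok),
                 median_full = interpolated_median(km_fit(data)),
                 replicates = meds, n_undefined = n_undef,
                 n_bootstrap = n_bootstrap, n = n),
            class = "boot_median")
}

#' @export
print.boot_median <- function(x, ...) {
  cat(sprintf("<boot_median> median = %.2f (SE %.3f), full-data median = %.2f\n",
              x$estimate, x$se, x$median_full))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.boot_median <- function(x, ...) {
  tibble(replicate = seq_along(x$replicates), median = x$replicates)
}

#' @exportS3Method generics::glance
glance.boot_median <- function(x, ...) {
  tibble(n = x$n, n_bootstrap = x$n_bootstrap, median = x$estimate,
         se = x$se, median_full = x$median_full, n_undefined = x$n_undefined)
}

#' Two-sided log-rank test
#'
#' Standard observed-minus-expected statistic over pooled event times with
#' hypergeometric variance; the p-value comes from the chi-square
#' distribution with one degree of freedom. Symmetric in group order.
#'
#' @param data Tibble with `time`, `event` and a two-level `group` column;
#'   alternatively pass the second group as `data_b`.
#' @param data_b Optional second-group tibble (`time`, `event`).
#' @return A one-row tibble: `statistic`, `p.value`, `n`, `n_events`.
#' @export
logrank_test <- function(data, data_b = NULL) {
  if (!is.null(data_b)) {
    data <- bind_rows(mutate(data[, c("time", "event")], group = "a"),
                      mutate(data_b[, c("time", "event")], group = "b"))
  }
  groups <- unique(data$group)
  if (length(groups) != 2) abort("log-rank test needs exactly two groups.")
  if (!all(table(data$group) > 0)) abort("a group is empty.")
  if (sum(data$event) == 0) abort("no events observed.")
  g1 <- data$group == groups[1]
  ev_times <- sort(unique(data$time[data$event == 1]))
  o <- e <- v <- 0
  for (t in ev_times) {
    at_risk <- data$time >= t
    nj <- sum(at_risk); n1j <- sum(at_risk & g1)
    dj <- sum(data$time == t & data$event == 1)
    d1j <- sum(data$time == t & data$event == 1 & g1)
    o <- o + d1j
    e <- e + dj * n1j / nj
    if (nj > 1) {
      v <- v + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
    }
  }
  chisq <- if (v > 0) (o - e)^2 / v else 0
  tibble(statistic = chisq,
         p.value = if (v > 0) pchisq(chisq, df = 1, lower.tail = FALSE) else 1,
         n = nrow(data), n_events = sum(data$event))
}

#' Percent change in median lifespan
#'
#' `100 * (treated - control) / control`, reported to one decimal — the
#' "change in median lifespan" figure-box convention.
#'
#' @param treated_median,control_median Median lifespans (days);
#'   `control_median` must be positive.
#' @return Percent change, rounded to one decimal.
#' @examples
#' percent_median_change(34, 17)  # +100.0
#' @export
percent_median_change <- function(treated_median, control_median) {
  stopifnot(control_median > 0)
  round(100 * (treated_median - control_median) / control_median, 1)
}

#' Suppression of a lifespan-shortening effect
#'
#' How much of a reference lifespan reduction a second condition abolishes:
#' `100 * (reduction_ref - reduction_mut) / reduction_ref`, rounded to the
#' nearest integer. For example, a knockdown shortening lifespan by 47.7%
#' in the reference but only 21% in a mutant is suppressed by 56%.
#' Reductions of opposite sign return the value with a warning.
#'
#' @param reduction_ref,reduction_mut Percent lifespan reductions in the
#'   reference and the modified condition; `reduction_ref` must be nonzero.
#' @return Suppression percent, rounded to the nearest integer.
#' @export
suppression_percent <- function(reduction_ref, reduction_mut) {
  stopifnot(reduction_ref != 0)
  if (sign(reduction_ref) != sign(reduction_mut) && reduction_mut != 0) {
    warn("reductions have opposite signs; suppression percent exceeds 100.")
  }
  round(100 * (reduction_ref - reduction_mut) / reduction_ref)
}

#' Per-group lifespan summary table
#'
#' Bootstrap median, standard error, percent change versus a named control
#' group, and the two-sided log-rank p against that control, for every
#' group in a lifespan table.
#'
#' @param data Tibble with `time`, `event`, `group`.
#' @param control Name of the control group.
#' @param n_bootstrap Bootstrap replicates per group (default 100).
#' @param seed Optional integer seed.
#' @return A tibble with one row per group: `group`, `n`, `n_events`,
#'   `median`, `se`, `median_full`, `pct_change`, `logrank_p`.
#' @export
lifespan_summary <- function(data, control, n_bootstrap = 100, seed = NULL) {
  if (!control %in% data$group) abort("`control` is not a group in `data`.")
  groups <- unique(data$group)
  ctrl <- data[data$group == control, , drop = FALSE]
  res <- purrr::imap_dfr(setNames(groups, groups), function(g, nm) {
    sub <- data[data$group == g, , drop = FALSE]
    bm <- bootstrap_median(sub, n_bootstrap = n_bootstrap,
                           seed = if (is.null(seed)) NULL
                                  else seed + match(g, groups))
    tibble(group = g, n = nrow(sub), n_events = sum(sub$event),
           median = bm$estimate, se = bm$se, median_full = bm$median_full)
  })
  ctrl_median <- res$median[res$group == control]
  res |>
    mutate(
      pct_change = ifelse(.data$group == control, 0,
                          purrr::map_dbl(.data$median,
                                         percent_median_change,
                                         control_median = ctrl_median)),
      logrank_p = purrr::map_dbl(.data$group, function(g) {
        if (g == control) return(NA_real_)
        logrank_test(data[data$group == g, , drop = FALSE], ctrl)$p.value
      }))
}

#' Survival curves per group
#'
#' @param data Tibble with `time`, `event`, `group`.
#' @return A ggplot with one Kaplan-Meier step curve per group.
#' @export
plot_survival <- function(data) {
  df <- purrr::map_dfr(split(data, data$group), function(sub) {
    fit <- km_fit(sub)
    bind_rows(tibble(time = 0, surv = 1),
              fit$steps[, c("time", "surv")]) |>
      mutate(group = sub$group[1])
  })
  ggplot(df, aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    geom_step() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "time (days)", y = "survival", colour = NULL) +
    theme_minimal()
}
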