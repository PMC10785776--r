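# First-order decay fits on turnover profiles
#
# The heavy ratio of a protein under steady-state turnover is
# R(t) = exp(-k t) with R(0) = 1 by construction, so the rate is fitted by
# least squares of ln R(t) = -k t through the origin — closed form, no
# initialization:  k_hat = sum(t * (-ln R)) / sum(t^2).

#' Fit a first-order decay rate to one turnover profile
#'
#' @param ratios Named or paired input: either a numeric vector of heavy
#'   ratios with chase times (days) supplied in `times`, or a
#'   [turnover_profiles()] subset for a single protein x genotype (columns
#'   `chase_time`, `ratio`).
#' @param times Chase times in days (ignored when `ratios` is a profile
#'   tibble).
#' @return List of class `decay_fit`: `k_hat` (1/day), `half_life` (days,
#'   `log(2) / k_hat`), `n_points` (ratio points + the enforced anchor),
#'   `rss` (residual sum of squares of ln R).
#' @export
#' @examples
#' fit_decay(0.5, times = 1)$half_life  # 1 day
fit_decay <- function(ratios, times = NULL) {
  if (is.data.frame(ratios)) {
    times <- ratios$chase_time
    ratios <- ratios$ratio
  }
  if (length(ratios) != length(times)) {
    stop_config("ratios and times must have equal length")
  }
  keep <- times > 0
  ratios <- ratios[keep]; times <- times[keep]
  if (length(ratios) < 1) {
    stop_insufficient("need at least one ratio at chase_time > 0")
  }
  if (any(ratios <= 0)) {
    stop_silac("ratios must be positive for the log-linear fit", "silac_domain_error")
  }
  lr <- log(ratios)
  k_hat <- sum(times * (-lr)) / sum(times^2)
  structure(
    list(
      k_hat = k_hat, half_life = log(2) / k_hat,
      n_points = length(ratios) + 1L,
      rss = sum((lr + k_hat * times)^2)
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("First-order decay fit: k = %.4g /day, half-life = %.4g days (%d points)\n",
              x$k_hat, x$half_life, x$n_points))
  invisible(x)
}

#' Fit decay rates for every protein x genotype in a profile table
#'
#' @param profiles A [turnover_profiles()] tibble.
#' @return Tibble: `protein`, `genotype`, `k_hat`, `half_life`,
#'   `n_points`, `rss`.
#' @export
fit_decay_all <- function(profiles) {
  groups <- split(
    as_tibble(profiles),
    paste(profiles$protein, profiles$genotype, sep = "\r")
  )
  dplyr::bind_rows(lapply(groups, function(d) {
    fit <- fit_decay(d)
    tibble(
      protein = d$protein[1], genotype = d$genotype[1],
      k_hat = fit$k_hat, half_life = fit$half_life,
      n_points = fit$n_points, rss = fit$rss
    )
  }))
}
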