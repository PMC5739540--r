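#' Construct an actinomycin-D chase decay course
#'
#' A decay course holds relative mRNA abundance measurements over time after
#' transcriptional arrest, per replicate. Validation enforces strictly
#' positive abundances, a t = 0 measurement for every replicate and at
#' least two distinct timepoints per replicate.
#'
#' @param time_hr numeric vector of times in hours (>= 0).
#' @param abundance numeric vector of relative abundances (> 0).
#' @param replicate replicate identifiers (parallel to `time_hr`).
#' @param condition a single condition label.
#' @return data.frame of class `decay_course` with columns `condition`,
#'   `replicate`, `time_hr`, `abundance`.
#' @export
decay_course <- function(time_hr, abundance, replicate = 1L,
                         condition = "sample") {
  df <- data.frame(condition = as.character(condition),
                   replicate = as.character(replicate),
                   time_hr = as.numeric(time_hr),
                   abundance = as.numeric(abundance),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$abundance)) || any(df$abundance <= 0)) {
    stop("abundances must be strictly positive and finite")
  }
  if (any(df$time_hr < 0)) stop("times must be >= 0")
  for (r in unique(df$replicate)) {
    tt <- df$time_hr[df$replicate == r]
    if (!any(tt == 0)) stop("replicate '", r, "' has no t = 0 measurement")
    if (length(unique(tt)) < 2L) {
      stop("replicate '", r, "' has fewer than 2 distinct timepoints")
    }
  }
  class(df) <- c("decay_course", "data.frame")
  df
}

# Divide each replicate's abundances by its t = 0 level (geometric mean of
# t = 0 measurements, robust to replicated t0 wells).
normalize_t0 <- function(course) {
  for (r in unique(course$replicate)) {
    sel <- course$replicate == r
    t0 <- exp(mean(log(course$abundance[sel & course$time_hr == 0])))
    course$abundance[sel] <- course$abundance[sel] / t0
  }
  course
}

#' Convert qPCR Ct values to t0-normalised relative abundances
#'
#' Standard delta-delta-Ct preprocessing: the target Ct is first normalised
#' against a reference (housekeeping) gene measured on the same wells,
#' `rel = 2^-(ct_target - ct_reference)`, then each replicate's course is
#' scaled so its t = 0 value is 1.
#'
#' @param ct_target Ct values of the transcript of interest.
#' @param ct_reference Ct values of the normaliser gene, paired with
#'   `ct_target` (same replicate and time for each element).
#' @inheritParams decay_course
#' @return a [decay_course].
#' @export
ct_to_relative <- function(ct_target, ct_reference, time_hr, replicate = 1L,
                           condition = "sample") {
  if (length(ct_target) != length(ct_reference)) {
    stop("ct_target and ct_reference must be paired (equal length)")
  }
  rel <- 2^(-(ct_target - ct_reference))
  replicate <- rep_len(as.character(replicate), length(rel))
  missing_t0 <- setdiff(unique(replicate),
                        unique(replicate[time_hr == 0]))
  if (length(missing_t0)) {
    stop("missing t = 0 pair for replicate(s): ",
         paste(missing_t0, collapse = ", "))
  }
  normalize_t0(decay_course(time_hr, rel, replicate, condition))
}

#' Estimate an mRNA half-life from a decay course
#'
#' Fits first-order decay `A(t) = A0 * exp(-k t)` by ordinary least squares
#' of `ln(abundance)` on time. Abundances are first normalised per replicate
#' to their t = 0 level, but the intercept is still estimated (not pinned at
#' zero), so a noisy t0 well does not bias the slope. The half-life is
#' `t1/2 = ln(2) / k`.
#'
#' @param course a [decay_course] (or data.frame with columns `replicate`,
#'   `time_hr`, `abundance`).
#' @param method `"pooled"` fits one regression over all replicate points;
#'   `"per_replicate_mean"` fits each replicate separately and reports the
#'   mean half-life with its standard error.
#' @return object of class `half_life_estimate` with elements `k` (per
#'   hour), `t_half_hr`, `se_k`, `ci95_t_half` (hours), `r_squared`,
#'   `n_points`, `method`, `condition` and `t_half_reps` (per-replicate
#'   half-lives, when each replicate can be fitted on its own).
#' @examples
#' course <- decay_course(c(0, 2, 4), c(1, 0.5, 0.25))
#' fit_half_life(course)$t_half_hr  # exactly 2
#' @export
fit_half_life <- function(course, method = c("pooled", "per_replicate_mean")) {
  method <- match.arg(method)
  if (!inherits(course, "decay_course")) {
    course <- decay_course(course$time_hr, course$abundance,
                           course$replicate,
                           if (!is.null(course$condition)) course$condition[1] else "sample")
  }
  course <- normalize_t0(course)
  if (length(unique(course$time_hr)) < 2L) {
    stop("fewer than 2 distinct timepoints")
  }

  fit_one <- function(df) {
    fit <- stats::lm(log(abundance) ~ time_hr, data = df)
    # noiseless data triggers a spurious perfect-fit warning in summary.lm
    sm <- suppressWarnings(summary(fit))
    slope <- unname(stats::coef(fit)["time_hr"])
    list(slope = slope,
         se = sm$coefficients["time_hr", "Std. Error"],
         df = fit$df.residual,
         r2 = if (is.null(sm$r.squared)) NA_real_ else sm$r.squared)
  }

  reps <- unique(course$replicate)
  t_half_reps <- vapply(reps, function(r) {
    f <- fit_one(course[course$replicate == r, ])
    if (f$slope >= 0) NA_real_ else log(2) / (-f$slope)
  }, numeric(1))
  names(t_half_reps) <- reps

  if (method == "pooled") {
    f <- fit_one(course)
    if (f$slope >= 0) stop("non-decaying course: fitted slope >= 0")
    k <- -f$slope
    se_k <- f$se
    tcrit <- stats::qt(0.975, f$df)
    k_lo <- k - tcrit * se_k
    k_hi <- k + tcrit * se_k
    ci <- c(log(2) / k_hi, if (k_lo > 0) log(2) / k_lo else Inf)
    est <- list(k = k, t_half_hr = log(2) / k, se_k = se_k,
                ci95_t_half = ci, r_squared = f$r2,
                n_points = nrow(course), method = method)
  } else {
    if (any(is.na(t_half_reps))) {
      stop("non-decaying course in replicate(s): ",
           paste(reps[is.na(t_half_reps)], collapse = ", "))
    }
    m <- mean(t_half_reps)
    se <- if (length(t_half_reps) > 1L) {
      stats::sd(t_half_reps) / sqrt(length(t_half_reps))
    } else NA_real_
    ci <- if (is.na(se)) c(NA_real_, NA_real_) else {
      m + c(-1, 1) * stats::qt(0.975, length(t_half_reps) - 1L) * se
    }
    r2s <- vapply(reps, function(r) fit_one(course[course$replicate == r, ])$r2,
                  numeric(1))
    k <- log(2) / m
    est <- list(k = k, t_half_hr = m,
                se_k = NA_real_, ci95_t_half = ci,
                r_squared = mean(r2s), n_points = nrow(course),
                method = method)
  }
  est$condition <- course$condition[1]
  est$t_half_reps <- t_half_reps
  structure(est, class = "half_life_estimate")
}

#' @export
print.half_life_estimate <- function(x, ...) {
  cat(sprintf("Half-life estimate (%s, %s): t1/2 = %.3g h (k = %.3g /h)\n",
              x$condition, x$method, x$t_half_hr, x$k))
  if (all(is.finite(x$ci95_t_half))) {
    cat(sprintf("  95%% CI [%.3g, %.3g] h; R^2 = %.3f; n = %d points\n",
                x$ci95_t_half[1], x$ci95_t_half[2], x$r_squared, x$n_points))
  }
  invisible(x)
}

#' Half-life by 50%-crossing linear interpolation
#'
#' Reads the half-life off the decay plot: the replicate-averaged,
#' t0-normalised abundance is interpolated linearly between the two
#' timepoints bracketing 0.5. Provided for comparison with the regression
#' estimator of [fit_half_life()], which uses all points.
#'
#' @inheritParams fit_half_life
#' @return half-life in hours (NA if the course never falls below 0.5).
#' @export
half_life_interp <- function(course) {
  course <- normalize_t0(course)
  means <- tapply(course$abundance, course$time_hr, mean)
  tt <- as.numeric(names(means))
  o <- order(tt)
  tt <- tt[o]; means <- as.numeric(means)[o]
  below <- which(means <= 0.5)
  if (length(below) == 0L) return(NA_real_)
  i <- below[1]
  if (means[i] == 0.5 || i == 1L) return(tt[i])
  frac <- (means[i - 1] - 0.5) / (means[i - 1] - means[i])
  tt[i - 1] + frac * (tt[i] - tt[i - 1])
}

#' Compare two half-life estimates
#'
#' Computes the ratio of point estimates and a two-sided two-sample t-test
#' on log-scale per-replicate half-lives.
#'
#' @param a,b [fit_half_life()] estimates, or numeric vectors of
#'   replicate-level half-lives.
#' @return list with `ratio` (t1/2 of `a` over t1/2 of `b`), `p_value`
#'   (NA when either side has fewer than 2 replicate-level estimates) and
#'   the replicate values used.
#' @export
compare_half_lives <- function(a, b) {
  reps_of <- function(x) {
    if (inherits(x, "half_life_estimate")) x$t_half_reps else as.numeric(x)
  }
  point_of <- function(x) {
    if (inherits(x, "half_life_estimate")) x$t_half_hr else mean(as.numeric(x))
  }
  ra <- reps_of(a); rb <- reps_of(b)
  ratio <- point_of(a) / point_of(b)
  p <- if (sum(is.finite(ra)) >= 2L && sum(is.finite(rb)) >= 2L) {
    # zero within-group variance (noiseless data) breaks the t statistic:
    # equal means are then indistinguishable (p = 1), unequal means are
    # separated with certainty (p -> 0)
    tryCatch(stats::t.test(log(ra), log(rb))$p.value,
             error = function(e) {
               if (isTRUE(all.equal(mean(log(ra)), mean(log(rb))))) 1 else 0
             })
  } else NA_real_
  list(ratio = ratio, p_value = p, reps_a = ra, reps_b = rb)
}
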