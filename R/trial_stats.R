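# z_{0.8} + z_{0.975} entering the two-arm sample-size formula; kept as the
# literal constants of the 80%-power, 5% two-sided design.
power_constant <- function() (0.841 + 1.96)^2

#' Per-group annualized PBVC statistics
#'
#' @param label group name (e.g. `"AD"`, `"controls"`).
#' @param values optional per-subject annualized PBVC values (%/yr).
#' @param n subject count (derived from `values` when present).
#' @param mean_pbvc,sd_pbvc group mean and SD (%/yr; derived from `values`
#'   when present, and checked against them when both are supplied).
#' @return A `group_stats` object.
#' @export
group_stats <- function(label, values = NULL, n = NULL, mean_pbvc = NULL,
                        sd_pbvc = NULL) {
  if (!is.null(values)) {
    values <- as.numeric(values)
    if (length(values) < 2L)
      stop("at least 2 per-subject values required")
    if (is.null(n)) n <- length(values)
    if (n != length(values))
      stop("n (", n, ") does not match length(values) (", length(values), ")")
    m <- mean(values); s <- stats::sd(values)
    tol <- 1e-6 * max(1, abs(m), s)
    if (!is.null(mean_pbvc) && abs(mean_pbvc - m) > tol)
      stop("supplied mean_pbvc does not match values")
    if (!is.null(sd_pbvc) && abs(sd_pbvc - s) > tol)
      stop("supplied sd_pbvc does not match values")
    mean_pbvc <- m; sd_pbvc <- s
  }
  if (is.null(mean_pbvc) || is.null(sd_pbvc))
    stop("either values or both mean_pbvc and sd_pbvc must be given")
  if (sd_pbvc < 0) stop("sd_pbvc must be >= 0")
  structure(list(label = label, n = n, mean_pbvc = mean_pbvc,
                 sd_pbvc = sd_pbvc, values = values),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat("<group_stats> ", x$label,
      if (!is.null(x$n)) paste0(" (n = ", x$n, ")"),
      ": mean ", signif(x$mean_pbvc, 4), ", SD ", signif(x$sd_pbvc, 4),
      " %/yr\n", sep = "")
  invisible(x)
}

#' Two-arm sample size for a given effect and dispersion
#'
#' `(0.841 + 1.96)^2 * 2 * sigma^2 / delta^2`: subjects per arm for 80%
#' power at the 5% two-sided significance level to detect a difference
#' `delta` in mean annualized PBVC between arms with common SD `sigma`.
#'
#' @param sigma common SD of annualized PBVC in the treatment and placebo
#'   arms (%/yr, > 0).
#' @param delta treatment effect on the mean annualized PBVC (%/yr, != 0).
#' @return A list: `raw` (unrounded) and `n_per_arm` (nearest integer).
#' @export
sample_size <- function(sigma, delta) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (!is.finite(delta) || delta == 0)
    stop("undefined effect: delta must be nonzero")
  raw <- power_constant() * 2 * sigma^2 / delta^2
  list(raw = raw, n_per_arm = as.integer(round(raw)))
}

#' Effect size and dispersion for a disease-modification trial
#'
#' The trial detects a `reduction` (default 25%) of disease progression.
#' Without controls, progression is the AD group's mean atrophy rate; when
#' controlling for normal aging, it is the AD-minus-control excess rate. In
#' both cases both arms consist of AD patients, so `sigma` is the AD group's
#' SD; the controls only shift the effect size.
#'
#' @param ad `group_stats` of the patient group.
#' @param controls optional `group_stats` of the control group.
#' @param reduction fraction of progression the treatment removes, in (0, 1).
#' @return A list with `delta` and `sigma` (%/yr).
#' @export
effect_size <- function(ad, controls = NULL, reduction = 0.25) {
  stopifnot(inherits(ad, "group_stats"))
  if (reduction <= 0 || reduction >= 1)
    stop("reduction must be in (0, 1)")
  if (is.null(controls)) {
    delta <- reduction * ad$mean_pbvc
  } else {
    stopifnot(inherits(controls, "group_stats"))
    if (ad$mean_pbvc <= controls$mean_pbvc)
      stop("non-positive effect: AD mean (", signif(ad$mean_pbvc, 4),
           ") does not exceed control mean (",
           signif(controls$mean_pbvc, 4), ")")
    delta <- reduction * (ad$mean_pbvc - controls$mean_pbvc)
  }
  list(delta = delta, sigma = ad$sd_pbvc)
}

#' Sample size from group statistics
#'
#' Convenience wrapper combining [effect_size()] and [sample_size()].
#'
#' @inheritParams effect_size
#' @return A `sample_size_result`: `n_per_arm`, `raw`, `delta`, `sigma`,
#'   `controlled_for_aging`, and (when [bootstrap_ci()] has been attached)
#'   `ci_low`/`ci_high`.
#' @export
estimate_sample_size <- function(ad, controls = NULL, reduction = 0.25) {
  es <- effect_size(ad, controls, reduction)
  ss <- sample_size(es$sigma, es$delta)
  structure(list(n_per_arm = ss$n_per_arm, raw = ss$raw,
                 delta = es$delta, sigma = es$sigma,
                 controlled_for_aging = !is.null(controls),
                 ci_low = NA_real_, ci_high = NA_real_),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat("<sample_size_result> n per arm = ", x$n_per_arm,
      " (raw ", signif(x$raw, 6), ")",
      if (x$controlled_for_aging) ", controlling for normal aging",
      "\n  delta = ", signif(x$delta, 5), " %/yr, sigma = ",
      signif(x$sigma, 5), " %/yr\n", sep = "")
  if (is.finite(x$ci_low))
    cat("  95% BC bootstrap CI: (", round(x$ci_low), "-", round(x$ci_high),
        ")\n", sep = "")
  invisible(x)
}

#' Bias-corrected bootstrap CI for an estimated sample size
#'
#' Resamples subjects with replacement within each group, recomputes the
#' sample size per replicate, and returns the 95% bias-corrected (BC)
#' percentile interval: with `z0 = qnorm(fraction of replicates below the
#' point estimate)`, the interval endpoints are the `pnorm(2*z0 -+ 1.96)`
#' quantiles of the replicate distribution.
#'
#' @param ad_values per-subject annualized PBVC of the patient group
#'   (length >= 2).
#' @param control_values optional per-subject PBVC of the control group;
#'   when supplied the effect controls for normal aging and the control
#'   group is resampled too.
#' @param reduction treated fraction of progression, in (0, 1).
#' @param n_boot bootstrap replicates (default 10000, minimum 100).
#' @param seed RNG seed for the resampling.
#' @return A list: `ci_low`, `ci_high` (unrounded sample sizes), `point`
#'   (the unrounded point estimate), `z0`, and `replicates` (invisible
#'   workhorse output, the replicate raw sample sizes).
#' @export
bootstrap_ci <- function(ad_values, control_values = NULL, reduction = 0.25,
                         n_boot = 10000L, seed = 1L) {
  ad_values <- as.numeric(ad_values)
  if (length(ad_values) < 2L) stop("ad_values must have length >= 2")
  if (!is.null(control_values)) {
    control_values <- as.numeric(control_values)
    if (length(control_values) < 2L)
      stop("control_values must have length >= 2")
  }
  if (n_boot < 100L) stop("n_boot must be >= 100")
  point_delta <- if (is.null(control_values)) {
    reduction * mean(ad_values)
  } else {
    reduction * (mean(ad_values) - mean(control_values))
  }
  if (point_delta <= 0)
    stop("non-positive effect: point estimate of delta is ",
         signif(point_delta, 4))
  # zero-variance groups are tolerated here (sample size 0, interval
  # collapses); the strict sample_size() preconditions apply elsewhere
  point <- power_constant() * 2 * stats::var(ad_values) / point_delta^2

  set.seed(seed)
  n_ad <- length(ad_values)
  reps <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    av <- ad_values[sample.int(n_ad, n_ad, replace = TRUE)]
    m_ad <- mean(av); s_ad <- stats::sd(av)
    if (is.null(control_values)) {
      delta <- reduction * m_ad
    } else {
      cv <- control_values[sample.int(length(control_values),
                                      length(control_values),
                                      replace = TRUE)]
      delta <- reduction * (m_ad - mean(cv))
    }
    reps[b] <- if (delta <= 0) NA_real_ else
      power_constant() * 2 * s_ad^2 / delta^2
  }
  reps <- reps[is.finite(reps)]
  if (length(reps) < n_boot * 0.5)
    stop("bootstrap degenerate: fewer than half the replicates yield a ",
         "positive effect")
  if (max(reps) == min(reps)) {
    warning("degenerate bootstrap: all replicates identical; ",
            "interval collapses to the point estimate")
    return(list(ci_low = point, ci_high = point, point = point, z0 = 0,
                replicates = reps))
  }
  frac_below <- (sum(reps < point) + 0.5 * sum(reps == point)) / length(reps)
  frac_below <- min(max(frac_below, 1 / length(reps)),
                    1 - 1 / length(reps))
  z0 <- stats::qnorm(frac_below)
  probs <- stats::pnorm(c(2 * z0 - 1.96, 2 * z0 + 1.96))
  ci <- unname(stats::quantile(reps, probs))
  list(ci_low = ci[1], ci_high = ci[2], point = point, z0 = z0,
       replicates = reps)
}

#' Sample-size table across measurement methods
#'
#' Emits, per method, the sample size based on the patient atrophy rate
#' alone and (when a control group is available) the one controlling for
#' normal aging, with bias-corrected bootstrap CIs when per-subject values
#' are present.
#'
#' @param stats_by_method named list; each element is a list with `ad` (a
#'   [group_stats()]) and optionally `controls`.
#' @param reduction treated fraction of progression.
#' @param n_boot,seed bootstrap settings, used only when per-subject values
#'   are present.
#' @return A data.frame with one row per method: `method`, `n_alone`,
#'   `raw_alone`, `ci_alone_low/high`, `n_controlling`, `raw_controlling`,
#'   `ci_controlling_low/high` (NA where unavailable).
#' @export
sample_size_table <- function(stats_by_method, reduction = 0.25,
                              n_boot = 10000L, seed = 1L) {
  stopifnot(length(stats_by_method) >= 1L)
  if (is.null(names(stats_by_method)))
    names(stats_by_method) <- paste0("method", seq_along(stats_by_method))
  rows <- lapply(names(stats_by_method), function(nm) {
    entry <- stats_by_method[[nm]]
    ad <- entry$ad
    ctl <- entry$controls
    alone <- estimate_sample_size(ad, NULL, reduction)
    row <- data.frame(method = nm,
                      n_alone = alone$n_per_arm, raw_alone = alone$raw,
                      ci_alone_low = NA_real_, ci_alone_high = NA_real_,
                      n_controlling = NA_integer_,
                      raw_controlling = NA_real_,
                      ci_controlling_low = NA_real_,
                      ci_controlling_high = NA_real_)
    has_vals <- !is.null(ad$values)
    if (has_vals) {
      ci <- bootstrap_ci(ad$values, NULL, reduction, n_boot, seed)
      row$ci_alone_low <- ci$ci_low; row$ci_alone_high <- ci$ci_high
    }
    if (!is.null(ctl)) {
      ctrl <- estimate_sample_size(ad, ctl, reduction)
      row$n_controlling <- ctrl$n_per_arm
      row$raw_controlling <- ctrl$raw
      if (has_vals && !is.null(ctl$values)) {
        ci <- bootstrap_ci(ad$values, ctl$values, reduction, n_boot, seed)
        row$ci_controlling_low <- ci$ci_low
        row$ci_controlling_high <- ci$ci_high
      }
    }
    row
  })
  do.call(rbind, rows)
}

#' Read per-subject PBVC values from a delimited table
#'
#' Expects a header line with at least the columns `subject`, `group` and
#' `pbvc` (tab- or comma-delimited); an optional `interval` column is
#' carried through.
#'
#' @param path file path.
#' @return A data.frame with one row per subject.
#' @export
read_pbvc_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e)))
  need <- c("subject", "group", "pbvc")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parse error: missing column(s) ", paste(miss, collapse = ", "),
         " in ", path)
  if (any(!is.finite(df$pbvc)))
    stop("parse error: non-numeric pbvc value at line ",
         which(!is.finite(df$pbvc))[1] + 1L)
  df
}
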