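# Evaluation analyses: lnEM calibration, learning curves, covariate
# contrasts.

#' Per-stage lnEM calibration table
#'
#' For each malignant stage, summarizes the stacked-ensemble lnEM of
#' held-out samples (min/mean/max) and the absolute deviation from the
#' stage's supervising value (median and 90th percentile). All malignant
#' samples are scored through the ensemble directly, mirroring the
#' evaluation protocol in which every malignant example is fed to the
#' staging model.
#'
#' @param system A trained `"em_system"`.
#' @param newdata Labeled data frame (marker columns + `label`); defaults to
#'   the system's internal test split. Benign rows are ignored.
#' @return Data frame of class `"em_calibration"` with rows I-IV and columns
#'   `n`, `ln_em_min`, `ln_em_mean`, `ln_em_max`, `dev_p50`, `dev_p90`,
#'   `within_0.5` (fraction within 0.5 of the supervising value).
#' @export
em_calibration_table <- function(system, newdata = NULL) {
  if (is.null(newdata)) {
    newdata <- cbind(system$data[system$split$test, , drop = FALSE])
    newdata$label <- system$label[system$split$test]
  }
  lab <- as_stage(newdata$label)
  mal <- which(lab != "benign")
  if (!length(mal)) stop("no malignant samples to calibrate on")
  st <- factor(as.character(lab[mal]), levels = malignant_stages())
  if (any(table(st) == 0)) stop("a malignant stage is absent from the data")
  sc <- em_score(system, newdata[mal, , drop = FALSE])
  target <- as.numeric(system$config$supervising_values[as.character(st)])
  dev <- abs(sc$ln_em - target)
  rows <- lapply(malignant_stages(), function(s) {
    i <- which(st == s)
    data.frame(stage = s, n = length(i),
               ln_em_min = min(sc$ln_em[i]), ln_em_mean = mean(sc$ln_em[i]),
               ln_em_max = max(sc$ln_em[i]),
               dev_p50 = as.numeric(quantile(dev[i], 0.5)),
               dev_p90 = as.numeric(quantile(dev[i], 0.9)),
               within_0.5 = mean(dev[i] <= 0.5))
  })
  out <- do.call(rbind, rows)
  attr(out, "overall_dev_p90") <- as.numeric(quantile(dev, 0.9))
  attr(out, "overall_within_0.5") <- mean(dev <= 0.5)
  class(out) <- c("em_calibration", "data.frame")
  out
}

#' @export
print.em_calibration <- function(x, digits = 3, ...) {
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat(sprintf("overall: 90th-pct |lnEM - target| = %.3f; within 0.5: %.1f%%\n",
              attr(x, "overall_dev_p90"), 100 * attr(x, "overall_within_0.5")))
  invisible(x)
}

#' Learning curve of test accuracy versus cohort size
#'
#' For each total cohort size and each seed, simulates a fresh cohort (split
#' evenly over the five classes), trains a full system, and measures 5-class
#' accuracy on one fixed held-out pool. The expectation, matching the
#' behavior of the system on growing data, is that mean accuracy does not
#' decrease with size.
#'
#' @param sizes Strictly increasing total cohort sizes (each at least 25 so
#'   every class is represented).
#' @param seeds Integer seeds (one fit per size x seed).
#' @param spec Base [cohort_spec()] defining the data distribution.
#' @param config Base [em_config()].
#' @param pool_per_class Held-out evaluation pool size per class.
#' @return Data frame of class `"em_learning_curve"`: `size`, `mean_acc`,
#'   `sd_acc`, `n_seeds`, plus an `accuracies` attribute with every run.
#' @export
learning_curve <- function(sizes, seeds, spec = cohort_spec(), config = em_config(),
                           pool_per_class = 100) {
  stopifnot(length(sizes) >= 2 || length(unique(sizes)) >= 1, length(seeds) >= 1)
  sizes <- as.integer(sizes)
  if (any(sizes < 25)) stop("size too small to contain all five classes")
  pool_spec <- spec
  pool_spec$n_per_class <- setNames(rep(pool_per_class, 5), stage_levels())
  pool_spec$seed <- derive_seed(spec$seed, 999L)
  pool <- simulate_cohort(pool_spec)
  runs <- expand.grid(size = sizes, seed = as.integer(seeds))
  runs$accuracy <- NA_real_
  for (r in seq_len(nrow(runs))) {
    per <- max(5L, round(runs$size[r] / 5))
    sp <- spec
    sp$n_per_class <- setNames(rep(per, 5), stage_levels())
    sp$seed <- derive_seed(runs$seed[r], runs$size[r])
    cfg <- config
    cfg$seed <- derive_seed(runs$seed[r], runs$size[r] + 1L)
    fit <- em_system(simulate_cohort(sp), cfg)
    pred <- predict(fit, pool)
    runs$accuracy[r] <- mean(as.character(pred$verdict) == as.character(pool$label))
  }
  agg <- do.call(rbind, lapply(sort(unique(runs$size)), function(s) {
    a <- runs$accuracy[runs$size == s]
    data.frame(size = s, mean_acc = mean(a), sd_acc = sd(a), n_seeds = length(a))
  }))
  attr(agg, "accuracies") <- runs
  class(agg) <- c("em_learning_curve", "data.frame")
  agg
}

#' Covariate contrast of EM scores
#'
#' Compares mean EM (raw scale) between two patient groups defined by a
#' covariate column (e.g. `diet` or `family_history`), with bootstrap
#' confidence intervals for each group mean and for the difference. Every
#' patient is scored through the stacked ensemble. A direction is claimed
#' only when the bootstrap interval of the difference excludes zero.
#'
#' @param system A trained `"em_system"`.
#' @param cohort Data frame with marker columns and the grouping column.
#' @param group Name of the grouping column; its first level (sorted) is the
#'   reference group.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level.
#' @param seed Seed for the bootstrap.
#' @return List of class `"em_contrast"`: per-group `n`/`mean_em`/interval,
#'   `difference` (exposed minus reference) with interval, and `direction`
#'   (`"higher"`, `"lower"`, or `"none"`).
#' @export
covariate_contrast <- function(system, cohort, group = "diet", n_boot = 1000,
                               conf = 0.95, seed = 1L) {
  if (!group %in% names(cohort)) stop("grouping column not found: ", group)
  g <- as.factor(cohort[[group]])
  if (nlevels(g) != 2) stop("grouping must define exactly two groups")
  if (any(table(g) == 0)) stop("empty group")
  em <- em_score(system, cohort)$em
  lv <- levels(g)
  a <- em[g == lv[1]]; b <- em[g == lv[2]]
  with_seed(seed, {
    qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    boot_mean <- function(x) replicate(n_boot, mean(sample(x, replace = TRUE)))
    ba <- boot_mean(a); bb <- boot_mean(b)
    diff_ci <- as.numeric(quantile(bb - ba, qs))
    direction <- if (diff_ci[1] > 0) "higher" else if (diff_ci[2] < 0) "lower" else "none"
    structure(list(
      group = group,
      levels = lv,
      n = c(length(a), length(b)),
      mean_em = c(mean(a), mean(b)),
      ci = rbind(as.numeric(quantile(ba, qs)), as.numeric(quantile(bb, qs))),
      difference = mean(b) - mean(a),
      difference_ci = diff_ci,
      direction = direction,
      conf = conf
    ), class = "em_contrast")
  })
}

#' @export
print.em_contrast <- function(x, ...) {
  cat(sprintf("EM contrast by %s (%d%% bootstrap intervals)\n",
              x$group, round(100 * x$conf)))
  for (i in 1:2) {
    cat(sprintf("  %-14s n = %4d  mean EM %8.2f  [%.2f, %.2f]\n",
                x$levels[i], x$n[i], x$mean_em[i], x$ci[i, 1], x$ci[i, 2]))
  }
  cat(sprintf("  difference (%s - %s): %.2f [%.2f, %.2f] -> %s\n",
              x$levels[2], x$levels[1], x$difference,
              x$difference_ci[1], x$difference_ci[2],
              if (x$direction == "none") "no direction claimed"
              else paste(x$levels[2], x$direction)))
  invisible(x)
}
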