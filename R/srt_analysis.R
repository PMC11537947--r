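#' Species-specific saccade latency classes
#'
#' Latency boundaries used to partition saccades into anticipatory,
#' express and regular classes.  Anticipatory saccades (launched without
#' visual guidance, including pre-target crossings) fall below 50 ms;
#' express saccades occupy the window from 50 ms up to the regular floor,
#' which is 75 ms for marmosets and 100 ms for humans.
#'
#' @param species `"marmoset"` or `"human"`.
#' @return Named list with `anticipatory_max_ms` and `regular_min_ms`.
#' @export
srt_class_bounds <- function(species) {
  species <- match.arg(species, c("marmoset", "human"))
  list(anticipatory_max_ms = 50,
       regular_min_ms = if (species == "marmoset") 75 else 100)
}

#' Classify saccades by latency
#'
#' Partitions SRTs into `anticipatory` (< 50 ms, including negative,
#' pre-target latencies), `express` (from 50 ms up to the species'
#' regular floor) and `regular` (at or above the floor); missing SRTs
#' (no saccade) are labeled `no_saccade`.  Every trial receives exactly
#' one category.
#'
#' @param srt_ms numeric vector of SRTs (ms); `NA` marks no saccade.
#' @param species `"marmoset"` or `"human"`.
#' @param bounds optional override of [srt_class_bounds()].
#' @return Factor with levels `anticipatory`, `express`, `regular`,
#'   `no_saccade`.
#' @export
#' @examples
#' classify_saccades(c(40, 60, 80), "marmoset")
classify_saccades <- function(srt_ms, species, bounds = NULL) {
  if (is.null(bounds)) bounds <- srt_class_bounds(species)
  out <- ifelse(is.na(srt_ms), "no_saccade",
         ifelse(srt_ms < bounds$anticipatory_max_ms, "anticipatory",
         ifelse(srt_ms < bounds$regular_min_ms, "express", "regular")))
  factor(out, levels = c("anticipatory", "express", "regular", "no_saccade"))
}

#' Histogram binning specification
#'
#' @param bin_width_ms bin width (ms); the conventional width for SRT
#'   histograms here is 6 ms.
#' @param range_ms length-2 numeric bin range (ms); extended automatically
#'   when data fall outside it.
#' @return An object of class `histogram_spec`.
#' @export
histogram_spec <- function(bin_width_ms = 6, range_ms = c(0, 450)) {
  stopifnot(bin_width_ms > 0, length(range_ms) == 2,
            range_ms[2] > range_ms[1])
  structure(list(bin_width_ms = bin_width_ms, range_ms = range_ms),
            class = "histogram_spec")
}

# bin edges covering the spec range, extended to span the data
bin_edges <- function(values, spec) {
  w <- spec$bin_width_ms
  lo <- min(spec$range_ms[1], if (length(values)) floor(min(values) / w) * w)
  hi <- max(spec$range_ms[2], if (length(values)) ceiling(max(values) / w) * w)
  if (hi <= lo) hi <- lo + w
  seq(lo, hi + if ((hi - lo) %% w > 0) w else 0, by = w)
}

#' Binned SRT proportions
#'
#' Counts latencies into fixed-width bins (left-closed, right-open) and
#' normalizes to proportions, which sum to one.
#'
#' @param srt_ms numeric latencies (ms); `NA` dropped.
#' @param spec a [histogram_spec()].
#' @return Data frame with `bin_left`, `bin_right`, `mid`, `count`,
#'   `proportion`.
#' @export
histogram_proportions <- function(srt_ms, spec = histogram_spec()) {
  v <- srt_ms[!is.na(srt_ms)]
  if (length(v) == 0) stop("empty sample")
  edges <- bin_edges(v, spec)
  idx <- findInterval(v, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  data.frame(bin_left = edges[-length(edges)], bin_right = edges[-1],
             mid = (edges[-length(edges)] + edges[-1]) / 2,
             count = counts, proportion = counts / length(v))
}

#' Empirical cumulative distribution function of SRTs
#'
#' Thin wrapper over [stats::ecdf()] (right-continuous step function).
#'
#' @param srt_ms numeric latencies (ms); `NA` dropped.
#' @return An `ecdf` function.
#' @export
srt_cdf <- function(srt_ms) {
  v <- srt_ms[!is.na(srt_ms)]
  if (length(v) == 0) stop("empty sample")
  stats::ecdf(v)
}

#' Coefficient of determination between binned distributions
#'
#' `R^2 = 1 - sum((o - m)^2) / sum((o - mean(o))^2)` over matched bins,
#' with the observed proportions as reference.  Equals 1 only for
#' identical vectors and can be negative for fits worse than the
#' observed mean.
#'
#' @param observed,model numeric vectors of matched binned proportions.
#' @return Scalar R-squared.
#' @export
#' @examples
#' r_squared(c(0.2, 0.3, 0.5), c(0.25, 0.25, 0.5))  # 0.8929
r_squared <- function(observed, model) {
  stopifnot(length(observed) == length(model), length(observed) > 1)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed proportions are constant")
  1 - sum((observed - model)^2) / ss_tot
}

#' Mean squared error between binned distributions
#'
#' @param observed,model numeric vectors of matched binned proportions.
#' @return Scalar MSE (symmetric in its arguments).
#' @export
mse <- function(observed, model) {
  stopifnot(length(observed) == length(model), length(observed) > 0)
  mean((observed - model)^2)
}

#' First-order Wasserstein distance between two latency samples
#'
#' Earth Mover's distance on the line: the integral of the absolute
#' difference between the two empirical CDFs, in ms.  Sensitive to
#' overall shape differences between distributions; shifting a sample by
#' `c` ms moves the distance by exactly `c`.
#'
#' @param a,b numeric samples (ms); `NA` dropped.
#' @return Scalar distance (ms).
#' @export
wasserstein_1d <- function(a, b) {
  a <- sort(a[!is.na(a)]); b <- sort(b[!is.na(b)])
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  if (length(a) == length(b)) return(mean(abs(a - b)))
  # integrate |F_a - F_b| over the knots of the combined sample
  knots <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(knots); fb <- stats::ecdf(b)(knots)
  dt <- diff(knots)
  sum(abs(fa[-length(fa)] - fb[-length(fb)]) * dt)
}

#' Quantile table of a latency sample
#'
#' Linear interpolation between order statistics (the type-7 convention
#' of [stats::quantile()]).
#'
#' @param srt_ms numeric latencies (ms); `NA` dropped.
#' @param probs probabilities.
#' @return Named numeric vector of quantiles.
#' @export
quantile_table <- function(srt_ms, probs = c(0.1, 0.25, 0.5, 0.75, 0.9)) {
  v <- srt_ms[!is.na(srt_ms)]
  if (length(v) == 0) stop("empty sample")
  stats::quantile(v, probs = probs, type = 7)
}

#' Wilcoxon rank-sum test between two latency samples
#'
#' Two-sided rank-sum (Mann-Whitney) test.  For small groups (both sizes
#' at most `exact_max`) the null distribution of the rank sum is
#' enumerated exactly over all group splits, which also handles ties;
#' larger samples use the normal approximation with tie correction via
#' [stats::wilcox.test()].
#'
#' @param a,b numeric samples; `NA` dropped.
#' @param exact_max largest per-group size for exact enumeration.
#' @return List with `statistic` (rank sum of `a`), `p_value`, `method`.
#' @export
rank_sum_test <- function(a, b, exact_max = 10) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0 || n2 == 0) stop("empty sample")
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)])
  if (n1 <= exact_max && n2 <= exact_max) {
    splits <- utils::combn(n1 + n2, n1)
    w_all <- colSums(matrix(r[splits], nrow = n1))
    mu <- n1 * (n1 + n2 + 1) / 2
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
    list(statistic = w_obs, p_value = p, method = "exact enumeration")
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    list(statistic = w_obs, p_value = wt$p.value,
         method = "normal approximation with tie correction")
  }
}

#' Proportion of latencies beyond a cutoff
#'
#' @param srt_ms numeric latencies (ms); `NA` dropped.
#' @param cutoff_ms cutoff (strictly exceeded).
#' @return Scalar proportion.
#' @export
fraction_exceeding <- function(srt_ms, cutoff_ms) {
  v <- srt_ms[!is.na(srt_ms)]
  if (length(v) == 0) stop("empty sample")
  mean(v > cutoff_ms)
}

#' Estimate the anticipatory latency boundary from landing points
#'
#' Anticipatory saccades are launched before visual guidance is
#' available, so at short latencies errant saccades (landing opposite
#' the target) are as or more frequent than correct ones.  Binning
#' latencies of correct and errant saccades and scanning from short to
#' long, the boundary is the left edge of the first bin in which correct
#' saccades outnumber errant ones and keep doing so for `run_length`
#' consecutive bins.
#'
#' @param srt_ms numeric latencies (ms).
#' @param correct logical vector, `TRUE` for correct (target-directed)
#'   saccades, aligned with `srt_ms`.
#' @param spec a [histogram_spec()].
#' @param run_length number of consecutive correct-dominated bins
#'   required.
#' @return List with `boundary_ms` and `flag` (`"ok"` or `"no_errant"`;
#'   with no errant saccades the boundary is the sample minimum's bin
#'   edge).
#' @export
estimate_anticipatory_boundary <- function(srt_ms, correct,
                                           spec = histogram_spec(),
                                           run_length = 3) {
  keep <- !is.na(srt_ms) & !is.na(correct)
  srt_ms <- srt_ms[keep]; correct <- as.logical(correct[keep])
  if (length(srt_ms) == 0) stop("empty sample")
  w <- spec$bin_width_ms
  if (!any(!correct)) {
    return(list(boundary_ms = floor(min(srt_ms) / w) * w,
                flag = "no_errant"))
  }
  edges <- bin_edges(srt_ms, spec)
  idx <- findInterval(srt_ms, edges, rightmost.closed = FALSE)
  nb <- length(edges) - 1
  n_corr <- tabulate(idx[correct], nbins = nb)
  n_err <- tabulate(idx[!correct], nbins = nb)
  dominated <- n_corr > n_err
  run <- 0
  for (i in seq_len(nb)) {
    run <- if (dominated[i]) run + 1 else 0
    if (run >= run_length) {
      return(list(boundary_ms = edges[i - run_length + 1], flag = "ok"))
    }
  }
  # correct saccades never dominate for a full run: no boundary found
  list(boundary_ms = edges[nb + 1], flag = "no_boundary")
}

#' Compare an observed and a simulated SRT distribution
#'
#' Computes the full distribution-comparison report for a pair of
#' latency samples on a common binning: binned proportions and CDFs,
#' R-squared and mean squared error of the binned proportions,
#' first-order Wasserstein distance, quantile table, and a two-sided
#' rank-sum test.
#'
#' @param observed,model numeric latency samples (ms).
#' @param spec a [histogram_spec()].
#' @param probs quantile probabilities.
#' @return An object of class `comparison_report`: list with `bins`
#'   (data frame of per-bin observed/model proportions and CDFs),
#'   `r_squared`, `mse`, `wasserstein_ms`, `quantiles` (matrix),
#'   `rank_sum`, `n_observed`, `n_model`.
#' @export
compare_srt_distributions <- function(observed, model,
                                      spec = histogram_spec(),
                                      probs = c(0.1, 0.25, 0.5, 0.75, 0.9)) {
  obs <- observed[!is.na(observed)]; mod <- model[!is.na(model)]
  if (length(obs) == 0 || length(mod) == 0) stop("empty sample")
  # common binning spanning both samples
  joint <- histogram_spec(spec$bin_width_ms,
                          range(spec$range_ms, obs, mod))
  ho <- histogram_proportions(obs, joint)
  hm <- histogram_proportions(mod, joint)
  bins <- data.frame(bin_left = ho$bin_left, bin_right = ho$bin_right,
                     mid = ho$mid,
                     observed = ho$proportion, model = hm$proportion,
                     observed_cdf = cumsum(ho$proportion),
                     model_cdf = cumsum(hm$proportion))
  qt <- rbind(observed = quantile_table(obs, probs),
              model = quantile_table(mod, probs))
  structure(list(
    bins = bins,
    r_squared = r_squared(bins$observed, bins$model),
    mse = mse(bins$observed, bins$model),
    wasserstein_ms = wasserstein_1d(obs, mod),
    quantiles = qt,
    rank_sum = rank_sum_test(obs, mod),
    n_observed = length(obs), n_model = length(mod)
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("SRT distribution comparison\n")
  cat(sprintf("  n (observed/model): %d / %d over %d bins\n",
              x$n_observed, x$n_model, nrow(x$bins)))
  cat(sprintf("  R^2 = %.4f   MSE = %.6f   Wasserstein = %.2f ms\n",
              x$r_squared, x$mse, x$wasserstein_ms))
  cat(sprintf("  rank-sum p = %.3g (%s)\n",
              x$rank_sum$p_value, x$rank_sum$method))
  cat("  quantiles:\n")
  print(round(x$quantiles, 1))
  invisible(x)
}

#' Write a comparison report to delimited files
#'
#' Writes the per-bin table as CSV and the scalar summary (R-squared,
#' MSE, Wasserstein distance, quantiles, rank-sum p) as a flat
#' key-value file.
#'
#' @param report a [compare_srt_distributions()] result.
#' @param bins_path CSV path for the per-bin table.
#' @param summary_path key-value path for the scalar summary.
#' @return `summary_path`, invisibly.
#' @export
write_comparison_report <- function(report, bins_path, summary_path) {
  stopifnot(inherits(report, "comparison_report"))
  utils::write.csv(report$bins, bins_path, row.names = FALSE, quote = FALSE)
  qt <- report$quantiles
  summ <- c(
    list(r_squared = report$r_squared, mse = report$mse,
         wasserstein_ms = report$wasserstein_ms,
         rank_sum_p = report$rank_sum$p_value,
         n_observed = report$n_observed, n_model = report$n_model),
    stats::setNames(as.list(qt["observed", ]),
                    paste0("observed_q", gsub("%", "", colnames(qt)))),
    stats::setNames(as.list(qt["model", ]),
                    paste0("model_q", gsub("%", "", colnames(qt))))
  )
  write_config(summ, summary_path)
}
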