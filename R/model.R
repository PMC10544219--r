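#' Zero-truncated Poisson upper-tail p-value
#'
#' Probability of observing at least `k` edits in a window given that at
#' least one is observed, under a Poisson background with mean `lambda`:
#' `P(X >= k | X >= 1) = (1 - F(k - 1; lambda)) / (1 - exp(-lambda))`.
#' The zero-truncation reflects that only windows containing an edit are
#' ever examined, so a window with a single edit is never significant
#' (`k = 1` returns exactly 1).
#'
#' @param k Integer vector of observed edit counts, all `>= 1`.
#' @param lambda Positive numeric vector of background means (recycled).
#' @return Numeric vector of p-values in (0, 1]. Computed in log space so
#'   tiny `lambda` and large `k` do not underflow prematurely.
#' @examples
#' ztp_pvalue(1, 0.3)        # exactly 1
#' ztp_pvalue(2, 1)          # 0.41802...
#' @export
ztp_pvalue <- function(k, lambda) {
  if (length(k) == 0L) return(numeric(0))
  if (any(k < 1 | k != floor(k)))
    stop("k must be integer >= 1 (zero-truncation: windows without edits ",
         "are never tested)")
  if (any(lambda <= 0)) stop("lambda must be > 0")
  n <- max(length(k), length(lambda))
  k <- rep_len(k, n); lambda <- rep_len(lambda, n)
  log_num <- ppois(k - 1, lambda, lower.tail = FALSE, log.p = TRUE)
  log_den <- log(-expm1(-lambda))
  p <- exp(log_num - log_den)
  p[k == 1] <- 1
  pmin(p, 1)
}

#' Benjamini-Hochberg adjustment of window p-values
#'
#' Standard step-up FDR adjustment (delegates to [stats::p.adjust()]),
#' with input validation appropriate for window tests.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

depth_bin <- function(depth, thresholds) {
  ## smallest threshold strictly greater than the depth; depth >= max -> Inf
  n_below <- rowSums(outer(depth, thresholds, FUN = ">="))
  c(thresholds, Inf)[n_below + 1L]
}

#' Fit the stratified zero-truncated Poisson background model
#'
#' Estimates the expected background editing rate (edits per substrate
#' instance) separately for exonic and intronic windows, and within each
#' class for a ladder of read-depth strata: a window of depth `d` is
#' assigned the smallest threshold `t` with `d < t` (depth at or above the
#' largest threshold uses the top stratum). The rate for stratum `t` is the
#' mean edit fraction of all qualifying windows of that class with depth
#' `< t`; the top stratum uses windows with depth at or above the largest
#' threshold. This makes the bar for significance at poorly covered
#' windows — where a single edited read already inflates the edit
#' fraction — correspondingly higher.
#'
#' @param stats Window statistics from [aggregate_windows()].
#' @param thresholds Strictly increasing depth thresholds; default
#'   `c(10, 20, 30, 40, 50)`.
#' @param include_zero_windows If `FALSE` (default), rates are estimated
#'   from windows carrying at least one edit — the windows the model will
#'   actually test. If `TRUE`, zero-edit windows with substrate enter the
#'   means as well.
#' @param stratify_depth If `FALSE`, a single stratum per region class is
#'   used (the depth ladder collapses); exposed chiefly to demonstrate why
#'   stratification is needed.
#' @return An object of class `ztp_bg` with components `rates` (data.frame
#'   of `region_class`, `bin_upper` (`Inf` = top stratum), `rate`,
#'   `n_windows`, `fallback`), `thresholds`, `include_zero_windows`,
#'   `stratify_depth`, `stats` (the training windows) and `call`. Empty
#'   strata inherit the nearest higher-threshold stratum's rate; a
#'   stratum whose mean is zero is substituted with the smallest positive
#'   rate across strata (with a warning) so the truncation term stays
#'   defined.
#' @seealso [test_windows()], [simulate.ztp_bg()], [residuals.ztp_bg()]
#' @export
fit_background <- function(stats, thresholds = c(10L, 20L, 30L, 40L, 50L),
                           include_zero_windows = FALSE,
                           stratify_depth = TRUE) {
  if (!is.data.frame(stats) || nrow(stats) == 0L)
    stop("stats must be a non-empty window statistics data.frame")
  if (any(stats$substrate_instances <= 0))
    stop("all windows must carry at least one substrate instance")
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L || is.unsorted(thresholds, strictly = TRUE) ||
      any(thresholds < 1))
    stop("thresholds must be strictly increasing and >= 1")

  pool <- if (include_zero_windows) stats else
    stats[stats$edit_instances >= 1L, , drop = FALSE]
  classes <- sort(unique(stats$region_class))
  uppers <- if (stratify_depth) c(thresholds, Inf) else Inf
  rows <- list()
  for (cl in classes) {
    sub <- pool[pool$region_class == cl, , drop = FALSE]
    for (u in uppers) {
      qual <- if (is.infinite(u)) {
        if (stratify_depth) sub$read_depth >= max(thresholds) else
          rep(TRUE, nrow(sub))
      } else sub$read_depth < u
      rows[[length(rows) + 1L]] <- data.frame(
        region_class = cl, bin_upper = u,
        rate = if (any(qual)) mean(sub$edit_fraction[qual]) else NA_real_,
        n_windows = sum(qual), stringsAsFactors = FALSE)
    }
  }
  rates <- do.call(rbind, rows)
  rates$fallback <- FALSE
  ## empty strata inherit the nearest higher-threshold stratum, top-down
  for (cl in classes) {
    idx <- which(rates$region_class == cl)   # ordered low -> top
    for (i in rev(seq_along(idx))) {
      if (is.na(rates$rate[idx[i]])) {
        donors <- idx[-seq_len(i)]
        donor <- donors[!is.na(rates$rate[donors])][1]
        if (is.na(donor)) donor <- idx[!is.na(rates$rate[idx])][1]
        if (is.na(donor))
          stop("no windows available to estimate rates for class '", cl, "'")
        rates$rate[idx[i]] <- rates$rate[donor]
        rates$fallback[idx[i]] <- TRUE
      }
    }
  }
  if (any(rates$rate == 0)) {
    posmin <- suppressWarnings(min(rates$rate[rates$rate > 0]))
    if (!is.finite(posmin))
      stop("all background rates are zero; cannot form a Poisson model")
    warning("strata with zero background rate substituted with the ",
            "smallest positive rate across strata (",
            signif(posmin, 4), ")")
    rates$fallback[rates$rate == 0] <- TRUE
    rates$rate[rates$rate == 0] <- posmin
  }
  structure(list(rates = rates, thresholds = thresholds,
                 include_zero_windows = include_zero_windows,
                 stratify_depth = stratify_depth,
                 stats = stats, call = match.call()),
            class = "ztp_bg")
}

lookup_rate <- function(object, region_class, read_depth) {
  uppers <- if (object$stratify_depth)
    depth_bin(read_depth, object$thresholds) else rep(Inf, length(read_depth))
  key <- paste(region_class, uppers)
  tab <- setNames(object$rates$rate,
                  paste(object$rates$region_class, object$rates$bin_upper))
  r <- unname(tab[key])
  if (anyNA(r))
    stop("no background rate for region class '",
         region_class[is.na(r)][1],
         "'; the class was absent from the training windows")
  r
}

#' @export
print.ztp_bg <- function(x, ...) {
  cat("Stratified zero-truncated Poisson background model\n")
  cat("  region classes:", paste(unique(x$rates$region_class),
                                 collapse = ", "), "\n")
  cat("  depth strata:  ",
      if (x$stratify_depth)
        paste0("< ", paste(x$thresholds, collapse = ", < "), ", top")
      else "none (single stratum)", "\n")
  cat("  rate estimation:",
      if (x$include_zero_windows) "all windows" else "edited windows only",
      "\n")
  cat("  training windows:", nrow(x$stats), "(",
      sum(x$stats$edit_instances >= 1), "edited )\n")
  invisible(x)
}

#' @export
summary.ztp_bg <- function(object, ...) {
  print(object)
  cat("\nPer-stratum background rates (edits per substrate instance):\n")
  print(object$rates, row.names = FALSE)
  invisible(object$rates)
}

#' @export
coef.ztp_bg <- function(object, ...) {
  setNames(object$rates$rate,
           paste0(object$rates$region_class, ":<", object$rates$bin_upper))
}

#' Test windows against a fitted background model
#'
#' Computes, for every window carrying at least one edit, the window mean
#' `lambda = rate(class, depth stratum) * substrate_instances`, the
#' zero-truncated Poisson upper-tail p-value of its edit count, and a
#' Benjamini-Hochberg adjusted p-value.
#'
#' @param stats Window statistics (defaults to the model's training set).
#' @param object A `ztp_bg` fit from [fit_background()].
#' @param adjust `"global"` (one FDR across all tested windows, default) or
#'   `"by_class"` (exons and introns adjusted separately).
#' @return `stats` restricted to tested windows, extended with columns
#'   `lambda`, `p_raw`, `p_adj`.
#' @export
test_windows <- function(stats, object, adjust = c("global", "by_class")) {
  stopifnot(inherits(object, "ztp_bg"))
  adjust <- match.arg(adjust)
  tested <- stats[stats$edit_instances >= 1L, , drop = FALSE]
  if (nrow(tested) == 0L) {
    tested$lambda <- numeric(0); tested$p_raw <- numeric(0)
    tested$p_adj <- numeric(0)
    return(tested)
  }
  rate <- lookup_rate(object, tested$region_class, tested$read_depth)
  lambda <- rate * tested$substrate_instances
  if (any(lambda <= 0)) {
    warning("windows with zero background mean assigned the smallest ",
            "representable positive p-value")
  }
  p_raw <- rep(.Machine$double.xmin, nrow(tested))
  ok <- lambda > 0
  p_raw[ok] <- ztp_pvalue(tested$edit_instances[ok], lambda[ok])
  tested$lambda <- lambda
  tested$p_raw <- p_raw
  tested$p_adj <- if (adjust == "global") bh_adjust(p_raw) else
    stats::ave(p_raw, tested$region_class, FUN = bh_adjust)
  rownames(tested) <- NULL
  tested
}

#' @describeIn fit_background `predict` returns the per-window background
#'   mean `lambda` (and the tested-window table when `type = "test"`).
#' @param object,... S3 method arguments.
#' @param newdata Window statistics to predict for; defaults to the
#'   training windows.
#' @param type `"lambda"` for background means of all windows, `"test"`
#'   for the tested-window table of [test_windows()].
#' @export
predict.ztp_bg <- function(object, newdata = NULL,
                           type = c("lambda", "test"), ...) {
  type <- match.arg(type)
  stats <- if (is.null(newdata)) object$stats else newdata
  if (type == "test") return(test_windows(stats, object))
  rate <- lookup_rate(object, stats$region_class, stats$read_depth)
  setNames(rate * stats$substrate_instances, stats$window_id)
}

#' Simulate edit counts from a fitted background model
#'
#' Draws one zero-truncated Poisson count per tested window at its fitted
#' `lambda`, by inverse-CDF on the truncated distribution. Used to check
#' that simulated edit-count distributions match observed ones.
#'
#' @param object A `ztp_bg` fit.
#' @param nsim Number of replicate simulations; default 1.
#' @param seed Optional integer seed; the caller's RNG state is restored
#'   afterwards.
#' @param stats Window statistics to simulate for (default: the model's
#'   tested training windows).
#' @param ... Unused.
#' @return An integer matrix with one row per tested window and `nsim`
#'   columns, with the window ids as row names.
#' @export
simulate.ztp_bg <- function(object, nsim = 1, seed = NULL, stats = NULL,
                            ...) {
  if (is.null(stats)) stats <- object$stats
  tested <- stats[stats$edit_instances >= 1L, , drop = FALSE]
  lambda <- lookup_rate(object, tested$region_class, tested$read_depth) *
    tested$substrate_instances
  lambda <- pmax(lambda, .Machine$double.xmin)
  n <- nrow(tested)
  draws <- with_seed(seed, {
    m <- matrix(0L, nrow = n, ncol = nsim)
    for (j in seq_len(nsim)) {
      u <- runif(n)
      p0 <- ppois(0, lambda)
      m[, j] <- qpois(p0 + u * (1 - p0), lambda)
    }
    m
  })
  ## guard: truncation can be lost to rounding when lambda ~ 0
  draws[!is.finite(draws) | draws < 1] <- 1L
  storage.mode(draws) <- "integer"
  rownames(draws) <- tested$window_id
  draws
}

#' Pearson residuals of observed edit counts under the fitted model
#'
#' Residuals `(k - mu) / sigma` for each tested window, where `mu` and
#' `sigma` are the zero-truncated Poisson mean `lambda / (1 - exp(-lambda))`
#' and standard deviation at the window's fitted `lambda`.
#'
#' @param object A `ztp_bg` fit.
#' @param ... Unused.
#' @return Named numeric vector of residuals for tested windows.
#' @export
residuals.ztp_bg <- function(object, ...) {
  tested <- object$stats[object$stats$edit_instances >= 1L, , drop = FALSE]
  lambda <- lookup_rate(object, tested$region_class, tested$read_depth) *
    tested$substrate_instances
  lambda <- pmax(lambda, .Machine$double.xmin)
  denom <- -expm1(-lambda)
  mu <- lambda / denom
  v <- mu * (1 + lambda - mu)
  setNames((tested$edit_instances - mu) / sqrt(pmax(v, 1e-12)),
           tested$window_id)
}

#' Compare observed and simulated edit-count distributions
#'
#' Plots the empirical distribution of observed per-window edit counts
#' against counts simulated from the fitted model, the standard visual
#' check that the zero-truncated Poisson background is adequate.
#'
#' @param x A `ztp_bg` fit.
#' @param nsim Simulated replicates pooled into the comparison; default 20.
#' @param seed Seed for the simulation; default 1.
#' @param max_k Right edge of the count axis; default the observed maximum.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the matrix of observed and simulated frequencies.
#' @importFrom graphics barplot legend
#' @export
plot.ztp_bg <- function(x, nsim = 20, seed = 1, max_k = NULL, ...) {
  tested <- x$stats[x$stats$edit_instances >= 1L, , drop = FALSE]
  sim <- simulate(x, nsim = nsim, seed = seed)
  if (is.null(max_k)) max_k <- max(tested$edit_instances)
  ks <- seq_len(max_k)
  obs <- tabulate(pmin(tested$edit_instances, max_k), nbins = max_k) /
    nrow(tested)
  simf <- tabulate(pmin(as.vector(sim), max_k), nbins = max_k) / length(sim)
  m <- rbind(observed = obs, simulated = simf)
  colnames(m) <- ks
  barplot(m, beside = TRUE, legend.text = rownames(m),
          xlab = "edits per window", ylab = "fraction of windows", ...)
  invisible(m)
}
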