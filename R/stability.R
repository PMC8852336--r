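# The stability engine: split-half ICC(A,1) between averages of the first
# and last m epochs of a permuted epoch order, swept over m and summarized
# across permutations, regions, thresholds and sample sizes.

# --- ICC(A,1) core -----------------------------------------------------

# Vectorized ICC(A,1) with 95% CI from per-cell sufficient statistics of
# paired measurements (a_i, b_i), i = 1..n: Sa = sum a, Sb = sum b,
# Saa = sum a^2, Sbb = sum b^2, Sab = sum a*b. k = 2 throughout.
icc_from_sums <- function(Sa, Sb, Saa, Sbb, Sab, n, conf_level = 0.95, ci = TRUE) {
  k <- 2
  g <- (Sa + Sb) / (k * n)
  ssr <- pmax(k * ((Saa + 2 * Sab + Sbb) / 4 - n * g^2), 0)
  msr <- ssr / (n - 1)
  msc <- n * (Sa / n - Sb / n)^2 / 2
  sst <- Saa + Sbb - k * n * g^2
  sse <- pmax(sst - ssr - msc, 0)
  mse <- sse / (n - 1)
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- ifelse(denom > 0, (msr - mse) / denom, 1)
  degen <- denom <= .Machine$double.eps
  if (!ci) {
    return(list(icc = icc, ci_low = NULL, ci_high = NULL,
                msr = msr, msc = msc, mse = mse, degenerate = degen))
  }

  alpha <- 1 - conf_level
  one_m <- pmax(1 - icc, .Machine$double.eps)
  a <- (k * icc) / (n * one_m)
  b <- 1 + (k * icc * (n - 1)) / (n * one_m)
  vnum <- (a * msc + b * mse)^2
  vden <- (a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1))
  v <- ifelse(vden > 0, vnum / vden, 1)
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - fl * mse) / (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fu * msr)
  lo[degen] <- 1; hi[degen] <- 1
  lo <- pmin(lo, icc); hi <- pmax(hi, icc)
  list(icc = icc, ci_low = lo, ci_high = hi, msr = msr, msc = msc, mse = mse,
       degenerate = degen)
}

#' Intraclass correlation ICC(A,1): single rater, two-way model, absolute agreement
#'
#' Computes ICC(A,1) between two measurement columns across participants
#' from the two-way ANOVA mean squares: with rows = participants and
#' columns = measurements (k = 2),
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' Absolute agreement penalizes systematic offsets between the columns
#' (the column mean square enters the denominator), unlike consistency
#' ICC. The 95% confidence interval uses the standard F-based
#' (McGraw-Wong) construction with Satterthwaite degrees of freedom.
#'
#' @param mat numeric matrix `participants x 2` of paired measurements.
#' @param conf_level confidence level (default 0.95).
#' @return a list of class `icc_result`: `icc`, `ci_low`, `ci_high`, `n`,
#'   `k = 2`, and `degenerate` (TRUE when total variance is zero, in which
#'   case ICC is defined as 1 with a degenerate CI).
#' @examples
#' icc_a1(cbind(c(1, 3, 5), c(2, 4, 6)))$icc  # 8/9
#' @export
icc_a1 <- function(mat, conf_level = 0.95) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 2L) stop("`mat` must have exactly 2 measurement columns", call. = FALSE)
  n <- nrow(mat)
  if (n < 3L) stop("ICC requires at least 3 participants", call. = FALSE)
  if (any(!is.finite(mat))) stop("measurements must be finite", call. = FALSE)
  a <- mat[, 1]; b <- mat[, 2]
  r <- icc_from_sums(sum(a), sum(b), sum(a^2), sum(b^2), sum(a * b), n, conf_level)
  if (r$degenerate) {
    warning("zero total variance: ICC defined as 1 with degenerate CI", call. = FALSE)
  }
  structure(list(icc = r$icc, ci_low = r$ci_low, ci_high = r$ci_high,
                 n = n, k = 2L, degenerate = r$degenerate),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.4f  [%.4f, %.4f]  (n = %d, k = %d)\n",
              x$icc, x$ci_low, x$ci_high, x$n, x$k))
  invisible(x)
}

# --- permutation schedule ----------------------------------------------

#' Epoch-order permutation schedule
#'
#' Pre-draws the epoch-order randomizations used by the stability engine:
#' `n_permutations` independent permutations of `1..n_epochs`, generated
#' from a single root seed so results are reproducible.
#'
#' @param n_epochs number of epochs in the array.
#' @param n_permutations number of randomizations (default 1000).
#' @param seed integer root seed.
#' @return an object of class `perm_schedule` with an
#'   `n_permutations x n_epochs` integer matrix `orders`.
#' @export
permutation_schedule <- function(n_epochs, n_permutations = 1000L, seed = 1L) {
  stopifnot_scalar_count(n_epochs, "n_epochs", min = 2L)
  stopifnot_scalar_count(n_permutations, "n_permutations")
  orders <- with_seed(seed, {
    t(vapply(seq_len(n_permutations), function(i) sample.int(n_epochs),
             integer(n_epochs)))
  })
  structure(list(n_epochs = as.integer(n_epochs),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), orders = orders),
            class = "perm_schedule")
}

#' @export
print.perm_schedule <- function(x, ...) {
  cat(sprintf("<perm_schedule> %d permutations of %d epochs (seed %d)\n",
              x$n_permutations, x$n_epochs, x$seed))
  invisible(x)
}

# --- split-half bin machinery ------------------------------------------

# For a (cells x epochs) matrix under one epoch order, return per-bin-size
# means: A[, m] = mean over first m epochs, B[, m] = mean over last m.
split_half_means <- function(X, ord, M) {
  E <- length(ord)
  # running-mean operator: column m averages epochs 1..m (upper triangle / m)
  W <- matrix(0, M, M)
  W[upper.tri(W, diag = TRUE)] <- 1
  W <- sweep(W, 2L, seq_len(M), "/")
  list(A = X[, ord[1:M], drop = FALSE] %*% W,
       B = X[, ord[E:(E - M + 1L)], drop = FALSE] %*% W)
}

# Sufficient statistics over participants for every (region*band, m) cell.
# A, B are (RF*S x M); rows ordered region-band fastest, participants slowest.
sums_over_participants <- function(A, B, RF, S, M) {
  sum_s <- function(x) {
    dim(x) <- c(RF, S, M)
    colSums(aperm(x, c(2, 1, 3)))  # -> RF x M
  }
  list(Sa = sum_s(A), Sb = sum_s(B), Saa = sum_s(A^2), Sbb = sum_s(B^2),
       Sab = sum_s(A * B))
}

# --- stability curves ---------------------------------------------------

#' Permutation-based split-half ICC stability curves
#'
#' The core analysis: for each permutation of the epoch order and each bin
#' size m = 1..n_epochs/2, the per-participant feature averaged over the
#' first m permuted epochs (bin A) is compared with the average over the
#' last m permuted epochs (bin B) via ICC(A,1) across participants,
#' separately for every region and band. The median ICC (and median CI
#' bounds) across permutations, as a function of data duration
#' m * epoch_length, is the stability curve. Across-region summaries
#' (median, median absolute deviation, range, median CI bounds) are also
#' computed per band and duration.
#'
#' @param x a [band_power_array()] (or any 4-D array
#'   `regions x bands x participants x epochs`).
#' @param schedule a [permutation_schedule()] whose `n_epochs` matches the
#'   array. For odd epoch counts the largest bin size is
#'   `floor(n_epochs/2)` and the middle epoch is never used (warning).
#' @param conf_level confidence level for the per-permutation ICC CIs.
#' @return an object of class `stability_curve`: `durations_s`; arrays
#'   `icc`, `ci_low`, `ci_high` (regions x bands x durations; medians
#'   across permutations); data.frame `region_summary` (per band x
#'   duration: across-region median, MAD, min, max, median CI bounds);
#'   plus region/band labels and the epoch length.
#' @export
stability_curves <- function(x, schedule, conf_level = 0.95) {
  bp <- as_band_power(x)
  d <- dim(bp$values)  # R, F, S, E
  R <- d[1]; F_ <- d[2]; S <- d[3]; E <- d[4]
  if (!inherits(schedule, "perm_schedule")) stop("`schedule` must be a perm_schedule", call. = FALSE)
  if (schedule$n_epochs != E) stop("schedule epoch count does not match the array", call. = FALSE)
  if (S < 3L) stop("at least 3 participants are required for ICC", call. = FALSE)
  if (E %% 2L != 0L) warning("odd epoch count: largest bin size is floor(n_epochs/2)")
  M <- E %/% 2L
  RF <- R * F_
  P <- schedule$n_permutations

  # rows of X: region fastest, then band, then participant
  X <- matrix(bp$values, nrow = RF * S, ncol = E)
  icc_p <- array(NA_real_, dim = c(P, RF, M))
  lo_p <- array(NA_real_, dim = c(P, RF, M))
  hi_p <- array(NA_real_, dim = c(P, RF, M))
  for (p in seq_len(P)) {
    ab <- split_half_means(X, schedule$orders[p, ], M)
    ss <- sums_over_participants(ab$A, ab$B, RF, S, M)
    r <- icc_from_sums(ss$Sa, ss$Sb, ss$Saa, ss$Sbb, ss$Sab, S, conf_level)
    icc_p[p, , ] <- r$icc
    lo_p[p, , ] <- r$ci_low
    hi_p[p, , ] <- r$ci_high
  }

  med_over_p <- function(a) apply(a, c(2, 3), stats::median)  # RF x M
  icc_med <- med_over_p(icc_p)
  lo_med <- med_over_p(lo_p)
  hi_med <- med_over_p(hi_p)
  durations <- seq_len(M) * bp$epoch_length_s

  to_rfm <- function(m2) array(m2, dim = c(R, F_, M))
  icc_arr <- to_rfm(icc_med); lo_arr <- to_rfm(lo_med); hi_arr <- to_rfm(hi_med)
  dimnames(icc_arr) <- dimnames(lo_arr) <- dimnames(hi_arr) <-
    list(bp$regions, bp$bands, NULL)

  rs <- do.call(rbind, lapply(seq_len(F_), function(f) {
    data.frame(
      band = bp$bands[f],
      duration_s = durations,
      median_icc = apply(icc_arr[, f, , drop = FALSE], 3, stats::median),
      mad_icc = apply(icc_arr[, f, , drop = FALSE], 3, stats::mad),
      min_icc = apply(icc_arr[, f, , drop = FALSE], 3, min),
      max_icc = apply(icc_arr[, f, , drop = FALSE], 3, max),
      median_ci_low = apply(lo_arr[, f, , drop = FALSE], 3, stats::median),
      median_ci_high = apply(hi_arr[, f, , drop = FALSE], 3, stats::median),
      stringsAsFactors = FALSE
    )
  }))
  structure(
    list(durations_s = durations, icc = icc_arr, ci_low = lo_arr, ci_high = hi_arr,
         region_summary = rs, regions = bp$regions, bands = bp$bands,
         epoch_length_s = bp$epoch_length_s, n_permutations = P,
         n_participants = S),
    class = "stability_curve"
  )
}

as_band_power <- function(x) {
  if (inherits(x, "band_power_array")) return(x)
  if (is.array(x) && length(dim(x)) == 4L) return(band_power_array(x))
  stop("expected a band_power_array or a 4-D array", call. = FALSE)
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf("<stability_curve> %d regions x %d bands, durations %g-%g s (%d permutations, n = %d)\n",
              length(x$regions), length(x$bands), min(x$durations_s),
              max(x$durations_s), x$n_permutations, x$n_participants))
  invisible(x)
}

# --- threshold durations ------------------------------------------------

#' Minimal data durations to reach ICC reliability thresholds
#'
#' For every region, band and threshold (moderate ICC > 0.50, good
#' ICC > 0.75, excellent ICC > 0.90 by default), extracts the smallest
#' data duration whose median ICC strictly exceeds the threshold. The
#' first-crossing rule is used even if the curve later dips; cells whose
#' curve never exceeds the threshold are coded DNS ("did not stabilize",
#' `NA` duration). Aggregates across regions (median/min/max per band and
#' threshold, with DNS ordered above every finite duration) and the
#' most/least stable region per band (highest/lowest mean of the median
#' ICC curve across all durations) are attached.
#'
#' @param curve a [stability_curve()].
#' @param thresholds numeric thresholds (default `c(0.50, 0.75, 0.90)`).
#' @return an object of class `threshold_table`: data.frame `durations`
#'   (region, band, threshold, duration_s with NA = DNS), data.frame
#'   `aggregates` (band, threshold, median/min/max duration as character
#'   with `"DNS"` coding, most/least stable region), `epoch_length_s`.
#' @export
threshold_durations <- function(curve, thresholds = c(0.50, 0.75, 0.90)) {
  if (!inherits(curve, "stability_curve")) stop("`curve` must be a stability_curve", call. = FALSE)
  thresholds <- sort(thresholds)
  R <- length(curve$regions); F_ <- length(curve$bands)
  rows <- vector("list", R * F_ * length(thresholds))
  i <- 0L
  for (f in seq_len(F_)) for (r in seq_len(R)) for (th in thresholds) {
    cross <- which(curve$icc[r, f, ] > th)
    i <- i + 1L
    rows[[i]] <- data.frame(
      region = curve$regions[r], band = curve$bands[f], threshold = th,
      duration_s = if (length(cross)) curve$durations_s[cross[1L]] else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  durations <- do.call(rbind, rows)

  fmt <- function(v) if (is.finite(v)) format(v, trim = TRUE) else "DNS"
  agg <- do.call(rbind, lapply(seq_len(F_), function(f) {
    overall <- apply(curve$icc[, f, , drop = FALSE], 1, mean)
    do.call(rbind, lapply(thresholds, function(th) {
      dur <- durations$duration_s[durations$band == curve$bands[f] &
                                  durations$threshold == th]
      dinf <- ifelse(is.na(dur), Inf, dur)  # DNS sorts above any finite duration
      data.frame(
        band = curve$bands[f], threshold = th,
        median = fmt(stats::median(dinf)), min = fmt(min(dinf)), max = fmt(max(dinf)),
        most_stable_region = curve$regions[which.max(overall)],
        least_stable_region = curve$regions[which.min(overall)],
        stringsAsFactors = FALSE
      )
    }))
  }))
  structure(list(durations = durations, aggregates = agg,
                 thresholds = thresholds, epoch_length_s = curve$epoch_length_s),
            class = "threshold_table")
}

#' @export
print.threshold_table <- function(x, ...) {
  cat("<threshold_table>\n")
  print(x$aggregates, row.names = FALSE)
  invisible(x)
}

# --- CI overlap between two stability summaries -------------------------

#' Compare two stability curves via median confidence-interval overlap
#'
#' For each band and shared duration, checks whether the across-region
#' median 95% CI intervals of two stability analyses intersect. Used to
#' compare stability across datasets, source-imaging methods or
#' parameterizations: non-divergent stability means the intervals overlap
#' at every band and duration.
#'
#' @param a,b [stability_curve()] objects; their duration grids are
#'   intersected and must share at least one duration.
#' @return a data.frame (band, duration_s, overlap logical, the four CI
#'   bounds), with attribute `divergent` listing non-overlapping cells.
#' @export
ci_overlap <- function(a, b) {
  if (!inherits(a, "stability_curve") || !inherits(b, "stability_curve")) {
    stop("both arguments must be stability_curve objects", call. = FALSE)
  }
  shared <- intersect(a$durations_s, b$durations_s)
  if (length(shared) == 0L) stop("the duration grids of the two curves are disjoint", call. = FALSE)
  bands <- intersect(a$bands, b$bands)
  if (length(bands) == 0L) stop("the band sets of the two curves are disjoint", call. = FALSE)
  sa <- a$region_summary; sb <- b$region_summary
  out <- do.call(rbind, lapply(bands, function(f) {
    ia <- sa[sa$band == f & sa$duration_s %in% shared, ]
    ib <- sb[sb$band == f & sb$duration_s %in% shared, ]
    ia <- ia[order(ia$duration_s), ]; ib <- ib[order(ib$duration_s), ]
    data.frame(
      band = f, duration_s = ia$duration_s,
      overlap = ia$median_ci_low <= ib$median_ci_high &
                ib$median_ci_low <= ia$median_ci_high,
      a_ci_low = ia$median_ci_low, a_ci_high = ia$median_ci_high,
      b_ci_low = ib$median_ci_low, b_ci_high = ib$median_ci_high,
      stringsAsFactors = FALSE
    )
  }))
  attr(out, "divergent") <- out[!out$overlap, c("band", "duration_s")]
  out
}

# --- sample-size subsampling --------------------------------------------

#' Stability as a function of sample size
#'
#' Randomly subsamples participants (without replacement) at each
#' requested size, recomputes the stability curves of the global-region
#' array for every draw, and summarizes the median and median absolute
#' deviation of the median-ICC curves across draws. Used to determine the
#' sample size at which the time-by-ICC estimate itself stabilizes.
#'
#' @param x a [band_power_array()]; collapsed with [region_mean()] first
#'   if it has more than one region.
#' @param sizes participant sample sizes (default
#'   `c(5, 10, 20, 40, 60, 80, 100)`); sizes exceeding the available
#'   participants are skipped with a warning.
#' @param n_subsamples randomizations of the participant subset per size
#'   (default 100).
#' @param schedule a [permutation_schedule()] shared by all draws.
#' @param seed seed for the participant draws.
#' @return a data.frame (size, band, duration_s, median_icc, mad_icc)
#'   across subsamples, of class `subsample_stability`.
#' @export
subsample_stability <- function(x, sizes = c(5, 10, 20, 40, 60, 80, 100),
                                n_subsamples = 100L, schedule, seed = 1L) {
  bp <- as_band_power(x)
  if (dim(bp$values)[1] > 1L) bp <- region_mean(bp)
  S <- dim(bp$values)[3]
  keep <- sizes[sizes <= S]
  if (length(keep) < length(sizes)) {
    warning(sprintf("skipping sizes larger than the %d available participants: %s",
                    S, paste(setdiff(sizes, keep), collapse = ", ")))
  }
  if (!length(keep)) stop("no requested size is feasible", call. = FALSE)
  out <- list()
  for (sz in keep) {
    draws <- with_seed(child_seed(seed, sz), {
      lapply(seq_len(n_subsamples), function(i) sample.int(S, sz))
    })
    if (sz == S) draws <- draws[1L]  # only one possible subset
    curves <- lapply(draws, function(idx) {
      sub <- bp
      sub$values <- bp$values[, , idx, , drop = FALSE]
      stability_curves(sub, schedule)$icc[1, , , drop = FALSE]  # F x M (dims 1,F,M)
    })
    arr <- simplify2array(curves)  # 1 x F x M x draws
    med <- apply(arr, c(2, 3), stats::median)
    madv <- apply(arr, c(2, 3), stats::mad)
    if (length(draws) == 1L) madv[] <- 0
    for (f in seq_along(bp$bands)) {
      out[[length(out) + 1L]] <- data.frame(
        size = sz, band = bp$bands[f],
        duration_s = seq_len(dim(arr)[3]) * bp$epoch_length_s,
        median_icc = med[f, ], mad_icc = madv[f, ],
        n_subsamples = length(draws), stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("subsample_stability", class(res))
  res
}
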