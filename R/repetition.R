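#' Project component scores onto classifier boundary weights
#'
#' Superimposes a region's three component time courses with the boundary
#' coefficients of the classification analysis, yielding a single equivalent
#' time course that best expresses the category-specific activity.
#'
#' @param scores `3 x time` matrix (one trial/evoked) or `3 x time x n`
#'   array.
#' @param weights Unit-norm 3-vector of boundary coefficients.
#' @return A time vector (or `time x n` matrix).
#' @export
project_boundary_timecourse <- function(scores, weights) {
  if (length(weights) != 3) stop_invalid("`weights` must be a 3-vector")
  dm <- dim(scores)
  if (is.null(dm) || !dm[1] == 3) stop_invalid("`scores` must be 3 x time [x n]")
  if (length(dm) == 2) {
    as.numeric(crossprod(scores, weights))
  } else {
    apply(scores, 3, function(m) as.numeric(crossprod(m, weights)))
  }
}

#' Boundary weights of a category's pattern
#'
#' Extracts a single unit 3-vector of boundary coefficients per region for a
#' category: the mean of the unit-normalized discriminant normals over all of
#' that category's exemplar-versus-nonsense pairwise classifiers and over the
#' time bins of the category-specific window, renormalized. These are exactly
#' the classifiers that define the category-specific pattern the repetition
#' analysis projects onto.
#'
#' @param decoding A `decoding_result` containing the category-vs-nonsense
#'   pairs.
#' @param region Region index.
#' @param category `"face"` or `"tool"`.
#' @param window_ms Category-specific time window `c(start, end)` in ms.
#' @param section Optional: restrict to entry pairs within one section.
#' @return Unit-norm 3-vector.
#' @export
category_boundary_weights <- function(decoding, region, category, window_ms,
                                      section = NULL) {
  stopifnot(inherits(decoding, "decoding_result"))
  ri <- match(region, decoding$regions)
  if (is.na(ri)) stop("region not present in decoding result", call. = FALSE)
  ent <- rsa_entries()
  is_cat <- ent$group == category
  is_non <- ent$group == "nonsense"
  if (!is.null(section)) {
    is_cat <- is_cat & ent$section == section
    is_non <- is_non & ent$section == section
  }
  pr <- decoding$pairs
  sel <- (is_cat[pr$a] & is_non[pr$b]) | (is_non[pr$a] & is_cat[pr$b])
  if (!any(sel)) stop_invalid("no %s-vs-nonsense pairs in this decoding result",
                              category)
  bins <- which(decoding$time_ms >= window_ms[1] & decoding$time_ms <= window_ms[2])
  if (!length(bins)) stop_invalid("window [%g, %g] contains no time bins",
                                  window_ms[1], window_ms[2])
  # orient each normal so it points from nonsense towards the category
  w <- c(0, 0, 0)
  for (pi in which(sel)) {
    flip <- if (is_non[pr$a[pi]]) -1 else 1
    for (t in bins) {
      wt <- decoding$weights[ri, t, pi, ]
      if (all(is.finite(wt))) w <- w + flip * wt
    }
  }
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop_invalid("boundary weights are degenerate (all zero)")
  w / nw
}

#' Average trials into sequential presentation-order segments
#'
#' Unlike pseudo-trial averaging, trials are taken in series: the condition's
#' trials are ordered by presentation order within the section and split into
#' `n_segments` contiguous near-equal blocks (5-8 trials for 50-80 trials),
#' so the first segment is the beginning of the section and the last its end.
#' Conditions with fewer than `min_trials` trials are excluded (returns
#' `NULL` with a warning).
#'
#' @param components A `region_components`.
#' @param stimulus Stimulus index (1..6).
#' @param section Section (default 1, the first section).
#' @param n_segments Number of segments (default 10).
#' @param min_trials Exclusion threshold (default 50).
#' @return A `regions x 3 x time x n_segments` array of segment-mean
#'   component scores, with the block sizes as attribute `"segment_sizes"`;
#'   or `NULL` when the condition is excluded.
#' @export
sequential_segment_average <- function(components, stimulus, section = 1,
                                       n_segments = 10L, min_trials = 50L) {
  stopifnot(inherits(components, "region_components"))
  lab <- components$labels
  idx <- which(lab$stimulus == stimulus & lab$section == section)
  n <- length(idx)
  if (n < max(min_trials, n_segments)) {
    warn(sprintf("stimulus %d section %d excluded: %d trials < %d",
                 stimulus, section, n, min_trials))
    return(NULL)
  }
  idx <- idx[order(lab$presentation_order[idx])]
  sizes <- balanced_block_sizes(n, n_segments)
  seg <- rep(seq_len(n_segments), times = sizes)
  nt <- length(components$time_ms)
  nc <- components$n_components
  nr <- components$n_regions
  out <- array(NA_real_, dim = c(nr, nc, nt, n_segments))
  for (r in seq_len(nr)) {
    flat <- matrix(components$scores[[r]][, , idx, drop = FALSE], nrow = nc * nt)
    gm <- t(rowsum(t(flat), seg) / as.numeric(sizes))
    out[r, , , ] <- array(gm, dim = c(nc, nt, n_segments))
  }
  attr(out, "segment_sizes") <- sizes
  out
}

#' Segment amplitudes of the projected category pattern
#'
#' For each sequential segment: the projected evoked time course is averaged
#' over the category-specific window bins, then across the category's
#' exemplars, and the absolute value of the result is taken (in that order).
#'
#' @param projected List (one element per exemplar) of `time x n_segments`
#'   matrices of projected evoked responses.
#' @param time_ms Time axis matching the rows.
#' @param window_ms Category-specific window `c(start, end)` in ms.
#' @return Numeric vector of `n_segments` non-negative amplitudes.
#' @export
repetition_amplitudes <- function(projected, time_ms, window_ms) {
  bins <- which(time_ms >= window_ms[1] & time_ms <= window_ms[2])
  if (!length(bins)) stop_invalid("window [%g, %g] contains no time bins",
                                  window_ms[1], window_ms[2])
  per_ex <- vapply(projected, function(m) {
    colMeans(m[bins, , drop = FALSE])
  }, numeric(ncol(projected[[1]])))
  abs(rowMeans(as.matrix(per_ex)))
}

#' Per-subject repetition amplitude series
#'
#' Runs the full repetition procedure for one subject: boundary weights from
#' the category's exemplar-vs-nonsense classifiers in the given window,
#' sequential segment averaging of the first section's trials, projection
#' onto the weights, and window/exemplar averaging with the final absolute
#' value.
#'
#' @param components The subject's `region_components`.
#' @param decoding The subject's `decoding_result` (source of the boundary
#'   weights).
#' @param region Region index.
#' @param category `"face"` or `"tool"`.
#' @param window_ms Category-specific window, e.g. `c(140, 170)` for faces,
#'   `c(210, 220)` for tools.
#' @param section Section analyzed (default 1, the first section).
#' @param n_segments Number of sequential segments (default 10).
#' @param min_trials Exclusion threshold (default 50).
#' @return Tibble with `segment` and `amplitude`, or `NULL` if every exemplar
#'   condition is excluded.
#' @export
repetition_series <- function(components, decoding, region, category,
                              window_ms, section = 1, n_segments = 10L,
                              min_trials = 50L) {
  weights <- category_boundary_weights(decoding, region, category, window_ms)
  stims <- category_stimuli(category)
  ri <- match(region, seq_len(components$n_regions))
  if (is.na(ri)) stop("region out of range", call. = FALSE)
  projected <- list()
  for (s in stims) {
    segs <- sequential_segment_average(components, s, section = section,
                                       n_segments = n_segments,
                                       min_trials = min_trials)
    if (is.null(segs)) next
    sc <- array(segs[region, , , ], dim = dim(segs)[2:4])
    projected[[length(projected) + 1]] <- project_boundary_timecourse(sc, weights)
  }
  if (!length(projected)) return(NULL)
  amp <- repetition_amplitudes(projected, components$time_ms, window_ms)
  tibble(segment = seq_len(n_segments), amplitude = amp)
}

#' Pooled regression of repetition amplitudes on segment index
#'
#' Simple linear regression of amplitude on segment index (1..n_segments)
#' pooled over all subject-segment points (not per-subject slopes), so with
#' `n` subjects and 10 segments the slope F-test has `(1, 10 n - 2)` degrees
#' of freedom. A perfectly linear input gives residual 0 and `F = Inf`
#' (reported as `p = 0`).
#'
#' @param amplitudes Tibble with columns `subject`, `segment`, `amplitude`.
#' @return A `repetition_fit`: `k` (slope, amplitude units per segment),
#'   `intercept`, `F`, `df` (`c(1, n_points - 2)`), `p_value`, `n_points`.
#' @export
repetition_regression <- function(amplitudes) {
  need <- c("subject", "segment", "amplitude")
  if (!all(need %in% names(amplitudes))) {
    stop_invalid("`amplitudes` needs columns subject, segment, amplitude")
  }
  if (length(unique(amplitudes$subject)) < 2) {
    stop_invalid("need at least 2 subjects")
  }
  x <- amplitudes$segment
  y <- amplitudes$amplitude
  n <- length(x)
  k <- stats::cov(x, y) / stats::var(x)
  a <- mean(y) - k * mean(x)
  fit <- a + k * x
  ssr <- sum((fit - mean(y))^2)
  sse <- sum((y - fit)^2)
  Fstat <- if (sse == 0) Inf else (ssr / 1) / (sse / (n - 2))
  p <- if (is.infinite(Fstat)) 0 else stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  structure(
    list(k = k, intercept = a, F = Fstat, df = c(1L, n - 2L), p_value = p,
         n_points = n),
    class = "repetition_fit"
  )
}

#' @export
print.repetition_fit <- function(x, ...) {
  cat(sprintf("repetition regression: k = %.3f, F(%d, %d) = %.3g, p = %.3g\n",
              x$k, x$df[1], x$df[2], x$F, x$p_value))
  invisible(x)
}

#' @rdname repetition_regression
#' @param x A `repetition_fit`.
#' @param ... Unused.
#' @export
tidy.repetition_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "segment"),
         estimate = c(x$intercept, x$k))
}

#' @rdname repetition_regression
#' @export
glance.repetition_fit <- function(x, ...) {
  tibble(k = x$k, statistic = x$F, df1 = x$df[1], df2 = x$df[2],
         p_value = x$p_value, n_points = x$n_points)
}
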