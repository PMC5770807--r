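#' One-sample t-test at every region-time cell
#'
#' Mass-univariate ("SPM-style") testing: an independent one-sample t-test of
#' the subject-level Fisher-z values against 0 at each region-time cell
#' (separately per model when a `model` column is present). Missing subject
#' values (masked cells) are skipped. Cells with zero variance across
#' subjects get `p = 0` when the mean is nonzero and `p = 1` otherwise, and
#' are flagged in the `degenerate` column.
#'
#' @param z_maps Tibble with columns `subject`, `region`, `time_ms`, `z` and
#'   optionally `model`.
#' @param one_sided If `TRUE`, the p-value tests the positive direction
#'   (`mean z > 0`); default two-sided.
#' @return A tibble with `region`, `time_ms` (and `model`), `n`, `mean_z`,
#'   `t`, `p`, `degenerate`.
#' @export
region_time_ttest <- function(z_maps, one_sided = FALSE) {
  grp <- intersect(c("model", "region", "time_ms"), names(z_maps))
  out <- dplyr::summarise(
    dplyr::group_by(z_maps, dplyr::across(dplyr::all_of(grp))),
    n = sum(!is.na(.data$z)),
    mean_z = mean(.data$z, na.rm = TRUE),
    sd_z = stats::sd(.data$z, na.rm = TRUE),
    .groups = "drop"
  )
  out$degenerate <- !is.na(out$sd_z) & out$sd_z == 0
  out$t <- ifelse(out$n >= 2 & out$sd_z > 0,
                  out$mean_z / (out$sd_z / sqrt(out$n)), NA_real_)
  out$p <- if (one_sided) {
    stats::pt(out$t, df = out$n - 1, lower.tail = FALSE)
  } else {
    2 * stats::pt(abs(out$t), df = out$n - 1, lower.tail = FALSE)
  }
  deg <- out$degenerate
  out$t[deg] <- ifelse(out$mean_z[deg] == 0, 0, sign(out$mean_z[deg]) * Inf)
  out$p[deg] <- ifelse(out$mean_z[deg] == 0, 1, 0)
  if (any(deg)) warn(sprintf("%d cell(s) had zero variance across subjects", sum(deg)))
  dplyr::select(out, -"sd_z")
}

#' Benjamini-Hochberg FDR mask over the region-time grid
#'
#' Step-up FDR control pooled across all testable cells jointly (the full
#' regions x time-bins grid per model, matching the mass-univariate design).
#' When a `model` column is present, `q` may be a single level or a named
#' vector per model; the package convention is q = 0.01 for the stimulus
#' recognizer and category-vs-nonsense models and q = 0.05 for the
#' one-vs-rest models (see [model_fdr_level()]).
#'
#' @param ttest Tibble from [region_time_ttest()] (needs a `p` column).
#' @param q FDR level(s): `NULL` (default) applies the per-model convention,
#'   a single number applies everywhere, a named vector overrides per model.
#' @return The input with `p_adj`, `q` and logical `significant` added.
#' @export
fdr_mask <- function(ttest, q = NULL) {
  apply_one <- function(d, qlev) {
    d$p_adj <- stats::p.adjust(d$p, method = "BH")
    d$q <- qlev
    d$significant <- !is.na(d$p_adj) & d$p_adj <= qlev
    d
  }
  if ("model" %in% names(ttest)) {
    parts <- split(ttest, ttest$model)
    out <- lapply(names(parts), function(m) {
      qlev <- if (is.null(q)) {
        model_fdr_level(m)
      } else if (!is.null(names(q))) {
        if (m %in% names(q)) q[[m]] else model_fdr_level(m)
      } else {
        q
      }
      apply_one(parts[[m]], qlev)
    })
    dplyr::bind_rows(out)
  } else {
    apply_one(ttest, q %||% 0.05)
  }
}

#' Significance onset times per region
#'
#' The onset is the first significant time bin strictly after stimulus onset
#' (time 0); pre-stimulus significance is ignored. Optionally a minimum run
#' length of consecutive significant bins can be required (default 1, i.e.
#' a single significant bin suffices).
#'
#' @param sig Tibble from [fdr_mask()] (needs `region`, `time_ms`,
#'   `significant`, optionally `model`).
#' @param min_run Minimum number of consecutive significant bins (default 1).
#' @return A tibble with `region` (and `model`) and `onset_ms` (`NA` when the
#'   region never reaches significance post-stimulus).
#' @export
onset_table <- function(sig, min_run = 1L) {
  grp <- intersect(c("model", "region"), names(sig))
  one <- function(d) {
    d <- d[order(d$time_ms), ]
    post <- d$time_ms > 0
    s <- d$significant & post
    if (min_run > 1) {
      r <- rle(s)
      keep <- r$values & r$lengths >= min_run
      if (!any(keep)) return(NA_real_)
      first <- cumsum(c(1, r$lengths))[which(keep)[1]]
      return(d$time_ms[first])
    }
    if (!any(s)) return(NA_real_)
    d$time_ms[which(s)[1]]
  }
  dplyr::summarise(dplyr::group_by(sig, dplyr::across(dplyr::all_of(grp))),
                   onset_ms = one(dplyr::pick(dplyr::everything())),
                   .groups = "drop")
}

#' Onset time for one region
#'
#' @inheritParams onset_table
#' @param region Region index.
#' @return Onset in ms, or `NA` if the region never becomes significant
#'   after stimulus onset.
#' @export
onset_time <- function(sig, region, min_run = 1L) {
  d <- sig[sig$region == region, ]
  if (!nrow(d)) return(NA_real_)
  onset_table(d, min_run = min_run)$onset_ms[1]
}

#' Bootstrap test of a decodability characteristic
#'
#' Resamples participants with replacement (1000 draws by default), forming
#' the bootstrap distribution of the across-subject mean of a performance
#' characteristic (onset, peak latency, peak or mean accuracy, or a
#' difference of two of them). The percentile 95% interval gives the test:
#' reject (p < 0.05) when the interval excludes 0.
#'
#' @param values Numeric vector, one value per subject.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return A one-row tibble: `estimate`, `ci_low`, `ci_high`, `n_boot`,
#'   `reject`.
#' @export
bootstrap_characteristic <- function(values, n_boot = 1000, conf = 0.95,
                                     seed = 1L) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop_invalid("need at least 2 subjects")
  n_boot <- check_count(n_boot, "n_boot")
  means <- with_seed(derive_seed(seed, "bootstrap"), {
    vapply(seq_len(n_boot), function(i) {
      mean(values[sample.int(length(values), replace = TRUE)])
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(means, c(alpha, 1 - alpha), type = 7))
  tibble(estimate = mean(values), ci_low = ci[1], ci_high = ci[2],
         n_boot = n_boot, reject = ci[1] > 0 | ci[2] < 0)
}

#' Decodability characteristics of a region-time accuracy map
#'
#' Summarizes a group-average accuracy (or z) time course per region the way
#' decoding studies tabulate performance: significance onset, peak latency,
#' peak value, and the mean over an analysis window.
#'
#' @param map Tibble with `region`, `time_ms`, `value` and logical
#'   `significant` (optionally `model`).
#' @param window_ms Window for the mean (default `c(50, 700)`).
#' @return A tibble with `region` (and `model`), `onset_ms`, `peak_ms`,
#'   `peak`, `mean_value`.
#' @export
decodability_characteristics <- function(map, window_ms = c(50, 700)) {
  grp <- intersect(c("model", "region"), names(map))
  dplyr::summarise(
    dplyr::group_by(map, dplyr::across(dplyr::all_of(grp))),
    onset_ms = {
      s <- .data$significant & .data$time_ms > 0
      if (any(s)) min(.data$time_ms[s]) else NA_real_
    },
    peak_ms = {
      post <- .data$time_ms > 0
      .data$time_ms[post][which.max(.data$value[post])]
    },
    peak = max(.data$value[.data$time_ms > 0], na.rm = TRUE),
    mean_value = mean(.data$value[.data$time_ms >= window_ms[1] &
                                    .data$time_ms <= window_ms[2]], na.rm = TRUE),
    .groups = "drop"
  )
}

#' Average homologous regions across hemispheres
#'
#' Collapses the 82-region maps to 41 bilateral areas by averaging the left
#' and right instance of every alias, as done before the model-specificity
#' MANOVA.
#'
#' @param maps Tibble with a `region` column (indices into `region_table`)
#'   and one or more value columns.
#' @param region_table Region table from [load_region_table()].
#' @param value Name of the value column (default `"z"`).
#' @return A tibble where `region` is replaced by `area` (the alias), values
#'   averaged across hemispheres.
#' @export
average_hemispheres <- function(maps, region_table = load_region_table(),
                                value = "z") {
  maps$area <- region_table$alias[maps$region]
  grp <- setdiff(names(maps), c("region", value))
  dplyr::summarise(dplyr::group_by(maps, dplyr::across(dplyr::all_of(grp))),
                   "{value}" := mean(.data[[value]], na.rm = TRUE),
                   .groups = "drop")
}

#' MANOVA test of model-specific spatial structure
#'
#' Tests whether the spatial maps of correlation with different model RDMs
#' genuinely differ in structure, not just in overall level. Observations are
#' the per-subject, per-model area vectors (z values averaged over a time
#' window and across hemispheres); models define the groups of a one-way
#' MANOVA. Bartlett's sequential dimensionality test then asks whether the
#' group means span more than a `d`-dimensional subspace: at `d = 1` (the
#' default) rejection means the three model means do not lie on one line,
#' i.e. each model picks out a distinct spatial distribution. The statistic
#' is `chi2 = (n - 1 - (p + g)/2) * sum(log(1 + lambda_j))` over the
#' discriminant eigenvalues beyond the first `d`, with
#' `df = (p - d) * (g - d - 1)`.
#'
#' The groups are treated as independent samples even though they come from
#' the same subjects; the result carries a note to that effect.
#'
#' @param z_maps Tibble with columns `subject`, `area` (or `region`),
#'   `model`, `z` — one value per subject-area-model (already time-averaged).
#' @param d Dimensionality under the null (default 1).
#' @return A `manova_specificity` object with `chi2`, `df`, `p_value`,
#'   `n_obs`, `n_areas`, `n_groups`, `rank_deficient`.
#' @export
manova_model_specificity <- function(z_maps, d = 1L) {
  area_col <- if ("area" %in% names(z_maps)) "area" else "region"
  wide <- tidyr::pivot_wider(
    z_maps[c("subject", area_col, "model", "z")],
    names_from = dplyr::all_of(area_col), values_from = "z")
  X <- as.matrix(wide[, setdiff(names(wide), c("subject", "model"))])
  groups <- factor(wide$model)
  g <- nlevels(groups)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= g) stop_invalid("need more observations than groups")
  gm <- colMeans(X)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (lev in levels(groups)) {
    Xi <- X[groups == lev, , drop = FALSE]
    mi <- colMeans(Xi)
    Xc <- sweep(Xi, 2, mi)
    W <- W + crossprod(Xc)
    B <- B + nrow(Xi) * tcrossprod(mi - gm)
  }
  eW <- eigen(W, symmetric = TRUE)
  tol <- max(eW$values) * p * .Machine$double.eps
  keep <- eW$values > tol
  rank_deficient <- sum(keep) < p
  p_eff <- sum(keep)
  # whiten by W^{-1/2} (pseudo-inverse on the retained subspace), then
  # eigenvalues of the whitened between-group scatter are those of W^-1 B
  Wih <- eW$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eW$values[keep]), p_eff) %*% t(eW$vectors[, keep, drop = FALSE])
  lambda <- eigen(Wih %*% B %*% Wih, symmetric = TRUE, only.values = TRUE)$values
  s <- min(p_eff, g - 1)
  lambda <- pmax(lambda[seq_len(s)], 0)
  if (d >= s) stop_invalid("d must be smaller than min(p, g - 1)")
  chi2 <- (n - 1 - (p_eff + g) / 2) * sum(log(1 + lambda[(d + 1):s]))
  df <- (p_eff - d) * (g - d - 1)
  if (rank_deficient) {
    warn(sprintf("within-group scatter is rank deficient (rank %d < %d areas); %s",
                 p_eff, p, "pseudo-inverse used and df based on the rank"))
  }
  structure(
    list(chi2 = chi2, df = df, p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
         d = d, eigenvalues = lambda, n_obs = n, n_areas = p, n_groups = g,
         rank_deficient = rank_deficient,
         note = paste("model groups treated as independent samples;",
                      "observations from the same subjects are correlated")),
    class = "manova_specificity"
  )
}

#' @export
print.manova_specificity <- function(x, ...) {
  cat(sprintf("Bartlett dimensionality test (means span > %d dimension%s)\n",
              x$d, if (x$d == 1) "" else "s"))
  cat(sprintf("  chi2(%d) = %.2f, p = %.4g  [%d obs, %d areas, %d groups]\n",
              x$df, x$chi2, x$p_value, x$n_obs, x$n_areas, x$n_groups))
  cat(" ", x$note, "\n")
  invisible(x)
}

#' @rdname manova_model_specificity
#' @param x A `manova_specificity` object.
#' @param ... Unused.
#' @export
glance.manova_specificity <- function(x, ...) {
  tibble(chi2 = x$chi2, df = x$df, p_value = x$p_value,
         n_obs = x$n_obs, n_areas = x$n_areas, n_groups = x$n_groups,
         rank_deficient = x$rank_deficient)
}

#' @rdname manova_model_specificity
#' @export
tidy.manova_specificity <- function(x, ...) {
  tibble(term = paste0("dimension>", x$d), statistic = x$chi2,
         df = x$df, p_value = x$p_value)
}
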