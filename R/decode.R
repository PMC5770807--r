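#' The 12 RSA condition entries
#'
#' Canonical entry order for all pairwise decoding and RDM work: the 6
#' stimuli (face1, face2, tool1, tool2, nonsense1, nonsense2) of section 1,
#' then the same stimuli of section 2 — 12 entries (6 images x 2 sections).
#'
#' @return A tibble with columns `entry` (1..12), `stimulus` (1..6),
#'   `section` (1..2), `group` and `label`.
#' @export
#' @examples
#' rsa_entries()
rsa_entries <- function() {
  g <- stimulus_groups()
  ex <- c(1, 2, 1, 2, 1, 2)  # exemplar number within group
  tibble(
    entry = 1:12,
    stimulus = rep(1:6, times = 2),
    section = rep(1:2, each = 6),
    group = rep(g, times = 2),
    label = paste0(rep(paste0(g, ex), times = 2), ".s", rep(1:2, each = 6))
  )
}

#' All unordered entry pairs
#'
#' @param entries Entry tibble from [rsa_entries()].
#' @return A tibble with `pair` (1..66), `a`, `b` (entry indices, `a < b`).
#' @export
entry_pairs <- function(entries = rsa_entries()) {
  cmb <- utils::combn(entries$entry, 2)
  tibble(pair = seq_len(ncol(cmb)), a = cmb[1, ], b = cmb[2, ])
}

#' Decode one condition pair over time in one region
#'
#' The core cross-validated classifier: per randomization, each condition's
#' raw trials are re-permuted and averaged into `n_pseudo` pseudo-trials; one
#' pseudo-trial per class is held out, a pooled-covariance linear discriminant
#' (ridge-regularized, `S + ridge * tr(S)/3 * I`) is fit on the remaining
#' `2 * (n_pseudo - 1)` training pseudo-trials (18 for the default 10), and
#' the 2 held-out pseudo-trials are classified. Accuracy is the fraction of
#' correct test classifications over all randomizations; the boundary weight
#' is the mean unit-normalized discriminant normal, renormalized.
#'
#' @param scores_a,scores_b `3 x time x trials` arrays of component scores
#'   for the two conditions (same time axis).
#' @param n_randomizations Number of pseudo-trial redraws (default 100).
#' @param n_pseudo Pseudo-trials per condition (default 10).
#' @param ridge Ridge fraction for the within-class covariance (default 1e-3).
#' @param seed Integer seed.
#' @return List with `accuracy` (time vector in `[0, 1]`), `weights`
#'   (`3 x time`, unit columns), `n_train` and `n_test`.
#' @export
decode_pair_timecourse <- function(scores_a, scores_b, n_randomizations = 100,
                                   n_pseudo = 10, ridge = 1e-3, seed = 1L) {
  stopifnot(length(dim(scores_a)) == 3, length(dim(scores_b)) == 3)
  n_randomizations <- check_count(n_randomizations, "n_randomizations")
  nA <- dim(scores_a)[3]; nB <- dim(scores_b)[3]
  draws <- with_seed(derive_seed(seed, "decode_pair"), {
    list(permA = vapply(seq_len(n_randomizations), function(i) sample(nA), integer(nA)),
         permB = vapply(seq_len(n_randomizations), function(i) sample(nB), integer(nB)),
         testA = sample(n_pseudo, n_randomizations, replace = TRUE),
         testB = sample(n_pseudo, n_randomizations, replace = TRUE))
  })
  lda_decode_pair(scores_a, scores_b, draws$permA, draws$permB,
                  draws$testA, draws$testB, as.integer(n_pseudo), ridge)
}

#' Time-resolved pairwise decoding across regions
#'
#' Runs [decode_pair_timecourse()] for every unordered pair of retained
#' condition entries in every region. A condition entry is retained when it
#' has at least `min_trials` trials; pairs involving excluded entries carry
#' `NA` accuracy. Each unordered pair is computed once (the result is
#' symmetric by construction).
#'
#' @param components A `region_components`.
#' @param n_randomizations Pseudo-trial redraws per pair (default 100).
#' @param min_trials Exclusion threshold (default 50).
#' @param regions Integer region indices to decode (default: all).
#' @param pairs Optional tibble/matrix of entry-index pairs (columns `a`,
#'   `b`) to restrict the computation; default all 66.
#' @param n_pseudo Pseudo-trials per condition (default 10).
#' @param ridge Covariance ridge fraction (default 1e-3).
#' @param seed Integer seed.
#' @return A `decoding_result`: `accuracy` (`regions x time x pairs`),
#'   `weights` (`regions x time x pairs x 3`), `pairs`, `entries` (with
#'   `n_trials` and `retained`), `regions`, `time_ms`, `n_randomizations`,
#'   `n_train`, `n_test`.
#' @export
decode_conditions <- function(components, n_randomizations = 100,
                              min_trials = 50L, regions = NULL, pairs = NULL,
                              n_pseudo = 10, ridge = 1e-3, seed = 1L) {
  stopifnot(inherits(components, "region_components"))
  lab <- components$labels
  entries <- rsa_entries()
  entries$n_trials <- vapply(seq_len(12), function(i) {
    sum(lab$stimulus == entries$stimulus[i] & lab$section == entries$section[i])
  }, integer(1))
  entries$retained <- entries$n_trials >= max(min_trials, n_pseudo)
  if (is.null(regions)) regions <- seq_len(components$n_regions)
  pr <- if (is.null(pairs)) entry_pairs(entries) else {
    p <- as.data.frame(pairs)
    tibble(pair = seq_len(nrow(p)), a = as.integer(p$a), b = as.integer(p$b))
  }
  nt <- length(components$time_ms)
  nreg <- length(regions)
  npair <- nrow(pr)
  acc <- array(NA_real_, dim = c(nreg, nt, npair))
  wts <- array(NA_real_, dim = c(nreg, nt, npair, 3))
  trial_idx <- lapply(seq_len(12), function(i) {
    which(lab$stimulus == entries$stimulus[i] & lab$section == entries$section[i])
  })
  for (ri in seq_along(regions)) {
    r <- regions[ri]
    for (pi in seq_len(npair)) {
      ea <- pr$a[pi]; eb <- pr$b[pi]
      if (!entries$retained[ea] || !entries$retained[eb]) next
      res <- decode_pair_timecourse(
        components$scores[[r]][, , trial_idx[[ea]], drop = FALSE],
        components$scores[[r]][, , trial_idx[[eb]], drop = FALSE],
        n_randomizations = n_randomizations, n_pseudo = n_pseudo,
        ridge = ridge, seed = derive_seed(seed, "region", r, "pair", ea, eb))
      acc[ri, , pi] <- res$accuracy
      wts[ri, , pi, ] <- t(res$weights)
    }
  }
  structure(
    list(accuracy = acc, weights = wts, pairs = pr, entries = entries,
         regions = as.integer(regions), time_ms = components$time_ms,
         n_randomizations = n_randomizations,
         n_train = 2L * (as.integer(n_pseudo) - 1L), n_test = 2L),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(paste0("<decoding_result> %d regions x %d time bins x %d pairs ",
                     "(%d randomizations, %d/%d train/test)\n"),
              length(x$regions), length(x$time_ms), nrow(x$pairs),
              x$n_randomizations, x$n_train, x$n_test))
  ex <- sum(!x$entries$retained)
  if (ex > 0) cat(sprintf("  %d condition entr%s excluded (< min trials)\n",
                          ex, if (ex == 1) "y" else "ies"))
  invisible(x)
}

#' @rdname decode_conditions
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @export
tidy.decoding_result <- function(x, ...) {
  ent <- x$entries
  # array is regions x time x pairs (region varies fastest, column-major)
  long <- tidyr::expand_grid(pair = x$pairs$pair, time_ms = x$time_ms,
                             region = x$regions)
  long$accuracy <- as.vector(x$accuracy)
  long <- dplyr::left_join(long, x$pairs, by = "pair")
  long$entry_a <- ent$label[long$a]
  long$entry_b <- ent$label[long$b]
  dplyr::select(dplyr::arrange(long, .data$region, .data$time_ms, .data$pair),
                "region", "time_ms", "pair", "entry_a", "entry_b", "accuracy")
}

#' Null decoding distribution by label permutation
#'
#' Estimates the chance-level accuracy distribution by randomly reassigning
#' class labels to the pooled raw trials of the two conditions before
#' pseudo-trial averaging, then running the decoder unchanged. With
#' `shuffle = FALSE` the original assignment is kept, which reproduces the
#' observed decoding (a self-check).
#'
#' @inheritParams decode_pair_timecourse
#' @param n_permutations Number of label reshuffles.
#' @param shuffle If `FALSE`, keep the true labels (identity permutation).
#' @return A tibble with `perm`, `time_bin`, `accuracy`.
#' @export
permutation_chance <- function(scores_a, scores_b, n_permutations = 100,
                               n_randomizations = 20, n_pseudo = 10,
                               ridge = 1e-3, seed = 1L, shuffle = TRUE) {
  nA <- dim(scores_a)[3]; nB <- dim(scores_b)[3]
  pool <- array(c(scores_a, scores_b), dim = c(3, dim(scores_a)[2], nA + nB))
  out <- vector("list", n_permutations)
  for (p in seq_len(n_permutations)) {
    idx <- if (shuffle) {
      with_seed(derive_seed(seed, "labelperm", p), sample(nA + nB))
    } else {
      seq_len(nA + nB)
    }
    res <- decode_pair_timecourse(
      pool[, , idx[seq_len(nA)], drop = FALSE],
      pool[, , idx[nA + seq_len(nB)], drop = FALSE],
      n_randomizations = n_randomizations, n_pseudo = n_pseudo,
      ridge = ridge, seed = derive_seed(seed, "permdecode", p))
    out[[p]] <- tibble(perm = p, time_bin = seq_len(dim(scores_a)[2]),
                       accuracy = res$accuracy)
  }
  dplyr::bind_rows(out)
}
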