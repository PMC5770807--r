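#' Resample epochs to the analysis grid
#'
#' Crops epochs to the analysis window and reduces the sampling rate by
#' non-overlapping block means (10:1 for 1 kHz recordings, giving 81 bins of
#' 10 ms across -100..700 ms). Input already on the target grid is cropped
#' and passed through unchanged.
#'
#' @param epochs A `source_epochs`.
#' @param window_ms Analysis window `c(start, end)` in ms; must lie within
#'   the input span.
#' @param target_step_ms Output bin width in ms (default 10).
#' @return A `source_epochs` on the target grid; its time axis is
#'   `seq(window_ms[1], window_ms[2], by = target_step_ms)`, each output bin
#'   the mean of the input samples it covers.
#' @export
resample_epochs <- function(epochs, window_ms = c(-100, 700), target_step_ms = 10) {
  stopifnot(inherits(epochs, "source_epochs"))
  t_in <- epochs$time_ms
  if (window_ms[1] < min(t_in) || window_ms[2] > max(t_in)) {
    stop_invalid("window [%g, %g] outside input span [%g, %g]",
                 window_ms[1], window_ms[2], min(t_in), max(t_in))
  }
  step_in <- stats::median(diff(t_in))
  t_out <- seq(window_ms[1], window_ms[2], by = target_step_ms)
  if (isTRUE(all.equal(step_in, target_step_ms))) {
    keep <- which(t_in >= window_ms[1] - 1e-9 & t_in <= window_ms[2] + 1e-9)
    return(new_source_epochs(epochs$data[, keep, , drop = FALSE],
                             t_in[keep], epochs$labels))
  }
  d <- dim(epochs$data)
  out <- array(NA_real_, dim = c(d[1], length(t_out), d[3]))
  for (i in seq_along(t_out)) {
    block <- which(t_in >= t_out[i] - 1e-9 & t_in < t_out[i] + target_step_ms - 1e-9)
    if (!length(block)) stop_invalid("no input samples in bin starting %g ms", t_out[i])
    out[, i, ] <- if (length(block) == 1L) {
      epochs$data[, block, ]
    } else {
      colMeans(aperm(epochs$data[, block, , drop = FALSE], c(2, 1, 3)))
    }
  }
  new_source_epochs(out, t_out, epochs$labels)
}

#' Reduce each region to three spatial principal components
#'
#' For each region, the vertex x (time * trials) data matrix is vertex-mean
#' centred and decomposed into spatial principal components; the top three
#' orthonormal loading vectors are kept and every trial is projected onto
#' them, giving three component time courses per trial per region. Loadings
#' are fitted once on all trials of all conditions jointly, so the
#' classifier's feature space is identical across conditions; each loading's
#' sign is fixed so its largest-magnitude vertex weight is positive.
#'
#' @param epochs A `source_epochs` (typically resampled to the analysis grid).
#' @param parcellation The matching `parcellation`; every region needs at
#'   least 3 vertices.
#' @param n_components Number of spatial components to keep (default 3).
#' @return A `region_components` object: `scores` (list per region of
#'   `n_components x time x trials` arrays), `loadings` (list of
#'   `vertices x n_components` orthonormal matrices), `explained_variance`
#'   (`n_components x regions`, non-increasing fractions), plus the time axis
#'   and trial labels.
#' @export
extract_region_components <- function(epochs, parcellation, n_components = 3L) {
  stopifnot(inherits(epochs, "source_epochs"), inherits(parcellation, "parcellation"))
  n_components <- check_count(n_components, "n_components")
  d <- dim(epochs$data)
  if (d[1] != parcellation$n_vertices) {
    stop_invalid("parcellation has %d vertices but data has %d",
                 parcellation$n_vertices, d[1])
  }
  nr <- parcellation$n_regions
  small <- which(parcellation$region_sizes < n_components)
  if (length(small)) {
    stop_invalid("region %d has %d vertices; need >= %d for the component reduction",
                 small[1], parcellation$region_sizes[small[1]], n_components)
  }
  scores <- vector("list", nr)
  loadings <- vector("list", nr)
  ev <- matrix(NA_real_, n_components, nr)
  for (r in seq_len(nr)) {
    v <- region_vertices(parcellation, r)
    X <- matrix(epochs$data[v, , ], nrow = length(v))   # vertices x (time*trials)
    X <- X - rowMeans(X)
    C <- tcrossprod(X) / (ncol(X) - 1)
    eg <- eigen(C, symmetric = TRUE)
    vals <- pmax(eg$values, 0)
    L <- eg$vectors[, seq_len(n_components), drop = FALSE]
    # sign convention: largest-magnitude vertex loading positive
    for (k in seq_len(n_components)) {
      j <- which.max(abs(L[, k]))
      if (L[j, k] < 0) L[, k] <- -L[, k]
    }
    sc <- crossprod(L, X)                               # n_comp x (time*trials)
    scores[[r]] <- array(sc, dim = c(n_components, d[2], d[3]))
    loadings[[r]] <- L
    tot <- sum(vals)
    ev[, r] <- if (tot > 0) vals[seq_len(n_components)] / tot else 0
  }
  structure(
    list(scores = scores, loadings = loadings, explained_variance = ev,
         time_ms = epochs$time_ms, labels = epochs$labels,
         n_regions = nr, n_components = n_components),
    class = "region_components"
  )
}

#' @export
print.region_components <- function(x, ...) {
  cat(sprintf("<region_components> %d regions x %d components x %d time bins x %d trials\n",
              x$n_regions, x$n_components, length(x$time_ms), nrow(x$labels)))
  invisible(x)
}

#' Average raw trials into pseudo-trials
#'
#' Each (stimulus, section) condition's trials are randomly permuted and split
#' into 10 near-equal groups (sizes `floor(n/10)` or `ceiling(n/10)`, larger
#' groups first), and each group is averaged into one pseudo-trial, raising
#' SNR before classification. Conditions with fewer than `min_trials` trials
#' are excluded (reported in the result, not an error).
#'
#' @param components A `region_components`.
#' @param min_trials Minimum trial count for a condition to be retained
#'   (default 50).
#' @param n_pseudo Number of pseudo-trials per condition (default 10).
#' @param seed Integer seed for the random permutations.
#' @return A `pseudo_trials` object: `conditions` (tibble with `stimulus`,
#'   `section`, `n_trials`, `retained`, `group_sizes` list-column) and
#'   `pseudo` (list per retained condition of
#'   `regions x components x time x n_pseudo` arrays).
#' @export
make_pseudo_trials <- function(components, min_trials = 50L, n_pseudo = 10L,
                               seed = 1L) {
  stopifnot(inherits(components, "region_components"))
  min_trials <- check_count(min_trials, "min_trials", min = 0L)
  n_pseudo <- check_count(n_pseudo, "n_pseudo")
  lab <- components$labels
  conds <- tidyr::expand_grid(stimulus = 1:6, section = 1:2)
  nt <- length(components$time_ms)
  nc <- components$n_components
  nr <- components$n_regions
  pseudo <- list()
  info <- vector("list", nrow(conds))
  set.seed(derive_seed(seed, "pseudo"))
  for (i in seq_len(nrow(conds))) {
    idx <- which(lab$stimulus == conds$stimulus[i] & lab$section == conds$section[i])
    n <- length(idx)
    retained <- n >= min_trials && n >= n_pseudo
    sizes <- if (retained) balanced_block_sizes(n, n_pseudo) else integer(0)
    info[[i]] <- tibble(stimulus = conds$stimulus[i], section = conds$section[i],
                        n_trials = n, retained = retained,
                        group_sizes = list(sizes))
    if (!retained) next
    perm <- idx[sample(n)]
    groups <- rep(seq_len(n_pseudo), times = sizes)
    arr <- array(NA_real_, dim = c(nr, nc, nt, n_pseudo))
    for (r in seq_len(nr)) {
      sc <- components$scores[[r]][, , perm, drop = FALSE]
      flat <- matrix(sc, nrow = nc * nt)                 # (comp*time) x n
      gm <- t(rowsum(t(flat), groups) / as.numeric(sizes))
      arr[r, , , ] <- array(gm, dim = c(nc, nt, n_pseudo))
    }
    pseudo[[paste0("s", conds$stimulus[i], ".sec", conds$section[i])]] <- arr
  }
  structure(
    list(conditions = dplyr::bind_rows(info), pseudo = pseudo,
         time_ms = components$time_ms, n_pseudo = n_pseudo),
    class = "pseudo_trials"
  )
}
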