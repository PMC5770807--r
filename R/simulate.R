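#' Specify an injected effect for the simulator
#'
#' Effects are additive spatiotemporal templates: a region-confined spatial
#' loading times a raised-cosine temporal envelope times condition and
#' repetition multipliers. Four kinds mirror the structure the analysis is
#' designed to detect:
#'
#' * `stimulus_specific`: each of the 6 stimuli gets its own random spatial
#'   loading, identical across sections — the structure the "stimulus
#'   recognizer" model picks up (early sensory activity).
#' * `category_binding`: all exemplars of one category share a loading (plus
#'   small exemplar-specific jitter); other conditions get nothing — creates
#'   within-category similarity / across-category dissimilarity.
#' * `supra_categorical`: one shared loading for the whole target group
#'   (default `"meaningful"` = faces + tools), emulating late
#'   category-independent meaning-related activity.
#' * `repetition_trend`: like `category_binding` but the per-trial amplitude
#'   grows linearly with the presentation-order segment (10 segments per
#'   section): amplitude for a trial in segment `g` is
#'   `amplitude + trend_slope * (g - 1)`, so segment-mean amplitudes are
#'   exactly linear in `g` with slope `trend_slope` before noise.
#'
#' @param kind One of `"stimulus_specific"`, `"category_binding"`,
#'   `"supra_categorical"`, `"repetition_trend"`.
#' @param target_regions Integer region indices carrying the effect.
#' @param window_ms Length-2 numeric `c(start, end)` in ms, inside the epoch.
#' @param amplitude Peak signal amplitude (arbitrary signal units).
#' @param category Which stimuli carry the effect: `"face"`, `"tool"`,
#'   `"nonsense"`, `"meaningful"` (faces + tools) or `"all"`.
#' @param trend_slope Amplitude change per segment (repetition_trend only).
#' @param exemplar_jitter Relative magnitude of exemplar-specific loading
#'   jitter for category-level effects.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(kind, target_regions, window_ms, amplitude,
                        category = c("all", "face", "tool", "nonsense", "meaningful"),
                        trend_slope = 0, exemplar_jitter = 0.25) {
  kind <- match.arg(kind, c("stimulus_specific", "category_binding",
                            "supra_categorical", "repetition_trend"))
  category <- match.arg(category)
  if (length(window_ms) != 2L || !all(is.finite(window_ms)) ||
      window_ms[1] > window_ms[2]) {
    stop_invalid("`window_ms` must be c(start, end) with start <= end")
  }
  check_scalar_number(amplitude, "amplitude")
  check_scalar_number(trend_slope, "trend_slope")
  structure(
    list(kind = kind, target_regions = as.integer(target_regions),
         window_ms = as.numeric(window_ms), amplitude = amplitude,
         category = category, trend_slope = trend_slope,
         exemplar_jitter = exemplar_jitter),
    class = "effect_spec"
  )
}

#' Simulation configuration
#'
#' Defaults emulate the study design the analysis targets: 22 subjects, 6
#' stimuli (2 faces, 2 tools, 2 nonsense) x 2 sections x 80 trials per
#' condition, 82 atlas regions, epochs from -100 to 700 ms at 10 ms
#' resolution, i.i.d. Gaussian vertex noise.
#'
#' @param n_subjects Number of simulated subjects.
#' @param n_regions Number of atlas regions.
#' @param vertices_per_region Count (>= 3) or range `c(min, max)`.
#' @param n_trials_per_condition Trials per (stimulus, section): a single
#'   count, or a 6 x 2 matrix for unbalanced designs (e.g. to emulate
#'   artifact-rejection losses and the < 50 exclusion rule).
#' @param epoch_ms Epoch window `c(start, end)` in ms.
#' @param step_ms Time-bin width in ms (> 0).
#' @param noise_sd Standard deviation of i.i.d. Gaussian vertex noise.
#' @param noise_autocorr If `TRUE`, noise is smoothed along time with a short
#'   raised-cosine kernel (then rescaled to `noise_sd`), emulating low-pass
#'   filtered recordings.
#' @param leakage_width Spatial leakage width in regions (0 = none); see
#'   [apply_spatial_leakage()].
#' @param effects List of [effect_spec()] objects.
#' @param seed Master seed; all subject/stage randomness is derived from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 22, n_regions = 82,
                              vertices_per_region = 10,
                              n_trials_per_condition = 80,
                              epoch_ms = c(-100, 700), step_ms = 10,
                              noise_sd = 1, noise_autocorr = FALSE,
                              leakage_width = 0, effects = list(),
                              seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  n_regions <- check_count(n_regions, "n_regions")
  check_scalar_number(step_ms, "step_ms", min = 0, allow_zero = FALSE)
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  check_scalar_number(leakage_width, "leakage_width", min = 0)
  if (length(epoch_ms) != 2L || epoch_ms[1] >= epoch_ms[2]) {
    stop_invalid("`epoch_ms` must be c(start, end) with start < end")
  }
  trials <- n_trials_per_condition
  if (is.matrix(trials)) {
    if (!all(dim(trials) == c(6L, 2L))) {
      stop_invalid("`n_trials_per_condition` matrix must be 6 stimuli x 2 sections")
    }
  } else {
    trials <- matrix(check_count(trials, "n_trials_per_condition"), 6L, 2L)
  }
  if (any(trials < 1)) stop_invalid("`n_trials_per_condition` must be >= 1")
  time_ms <- seq(epoch_ms[1], epoch_ms[2], by = step_ms)
  for (ef in effects) {
    if (!inherits(ef, "effect_spec")) stop_invalid("effects must be effect_spec objects")
    if (ef$window_ms[1] < epoch_ms[1] || ef$window_ms[2] > epoch_ms[2]) {
      stop_invalid("effect window [%g, %g] lies outside the epoch [%g, %g]",
                   ef$window_ms[1], ef$window_ms[2], epoch_ms[1], epoch_ms[2])
    }
    if (any(ef$target_regions < 1 | ef$target_regions > n_regions)) {
      stop_invalid("effect target regions out of range 1..%d", n_regions)
    }
  }
  structure(
    list(n_subjects = n_subjects, n_regions = n_regions,
         vertices_per_region = vertices_per_region,
         n_trials_per_condition = trials,
         epoch_ms = as.numeric(epoch_ms), step_ms = step_ms,
         time_ms = time_ms, noise_sd = noise_sd,
         noise_autocorr = isTRUE(noise_autocorr),
         leakage_width = leakage_width,
         effects = effects, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# stimulus -> category map used throughout: 1,2 face; 3,4 tool; 5,6 nonsense
stimulus_groups <- function() {
  c("face", "face", "tool", "tool", "nonsense", "nonsense")
}

category_stimuli <- function(category) {
  g <- stimulus_groups()
  switch(category,
         all = 1:6,
         meaningful = which(g %in% c("face", "tool")),
         which(g == category))
}

# Hann taper sampled at bin centres: keeps energy in windows only 1-2 bins wide
window_envelope <- function(time_ms, window_ms) {
  idx <- which(time_ms >= window_ms[1] & time_ms <= window_ms[2])
  n <- length(idx)
  env <- numeric(length(time_ms))
  if (n > 0) env[idx] <- sin(pi * (seq_len(n) - 0.5) / n)^2
  env
}

random_unit <- function(n) {
  v <- stats::rnorm(n)
  v / sqrt(sum(v^2))
}

# trial labels for one subject; presentation_order is a seeded permutation
# within each (stimulus, section)
make_labels <- function(trials_mat, seed) {
  stim <- rep(rep(1:6, times = 2), times = as.vector(trials_mat))
  sect <- rep(rep(1:2, each = 6), times = as.vector(trials_mat))
  ord <- integer(length(stim))
  with_seed(derive_seed(seed, "order"), {
    for (s in 1:6) for (sec in 1:2) {
      i <- which(stim == s & sect == sec)
      ord[i] <- sample(length(i))
    }
  })
  tibble(trial = seq_along(stim), stimulus = stim,
         group = stimulus_groups()[stim], section = sect,
         presentation_order = ord)
}

# map presentation order to one of 10 sequential segments (larger blocks first)
segment_of_order <- function(ord, n_in_condition, n_segments = 10L) {
  sizes <- balanced_block_sizes(n_in_condition, n_segments)
  rep(seq_len(n_segments), times = sizes)[ord]
}

new_source_epochs <- function(data, time_ms, labels) {
  stopifnot(dim(data)[2] == length(time_ms), dim(data)[3] == nrow(labels))
  structure(list(data = data, time_ms = as.numeric(time_ms), labels = labels),
            class = "source_epochs")
}

#' @export
print.source_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<source_epochs> %d vertices x %d time bins (%g..%g ms) x %d trials\n",
              d[1], d[2], min(x$time_ms), max(x$time_ms), d[3]))
  invisible(x)
}

#' Simulate one subject's source-space epochs
#'
#' @param config A [simulation_config()].
#' @param subject Subject index in `1..n_subjects`.
#' @param parcellation A `parcellation`; built from the config if omitted.
#' @return A list with `epochs` (a `source_epochs`) and `ground_truth`
#'   (per-effect realized regions, time bins, condition loadings and per-trial
#'   amplitude multipliers).
#' @export
simulate_subject <- function(config, subject, parcellation = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  subject <- check_count(subject, "subject")
  if (is.null(parcellation)) {
    parcellation <- build_synthetic_parcellation(
      config$n_regions, config$vertices_per_region, seed = config$seed)
  }
  nv <- parcellation$n_vertices
  time_ms <- config$time_ms
  nt <- length(time_ms)
  labels <- make_labels(config$n_trials_per_condition,
                        derive_seed(config$seed, "labels", subject))
  ntr <- nrow(labels)

  data <- with_seed(derive_seed(config$seed, "noise", subject), {
    array(stats::rnorm(nv * nt * ntr, sd = config$noise_sd), dim = c(nv, nt, ntr))
  })
  if (config$noise_autocorr && nt >= 3) {
    k <- sin(pi * (1:3 - 0.5) / 3)^2
    k <- k / sqrt(sum(k^2))   # unit energy: keeps marginal sd at noise_sd
    for (v in seq_len(nv)) {
      sm <- apply(data[v, , , drop = FALSE], 3, function(m) {
        stats::filter(as.numeric(m), k, sides = 2)
      })
      sm[is.na(sm)] <- 0
      data[v, , ] <- sm
    }
  }

  gt <- vector("list", length(config$effects))
  for (e in seq_along(config$effects)) {
    ef <- config$effects[[e]]
    env <- window_envelope(time_ms, ef$window_ms)
    bins <- which(env > 0)
    verts <- which(parcellation$assignment %in% ef$target_regions)
    stim_set <- if (ef$kind == "stimulus_specific") 1:6 else category_stimuli(ef$category)

    loadings <- with_seed(derive_seed(config$seed, "effect", e, subject), {
      base <- random_unit(length(verts))
      lapply(1:6, function(s) {
        if (!s %in% stim_set) return(NULL)
        if (ef$kind == "stimulus_specific") {
          random_unit(length(verts))
        } else {
          w <- base + ef$exemplar_jitter * random_unit(length(verts))
          w / sqrt(sum(w^2))
        }
      })
    })

    trial_amp <- numeric(ntr)
    for (s in stim_set) for (sec in 1:2) {
      i <- which(labels$stimulus == s & labels$section == sec)
      if (!length(i)) next
      if (ef$kind == "repetition_trend") {
        seg <- segment_of_order(labels$presentation_order[i], length(i))
        trial_amp[i] <- ef$amplitude + ef$trend_slope * (seg - 1)
      } else {
        trial_amp[i] <- ef$amplitude
      }
    }
    active <- which(trial_amp != 0)
    for (i in active) {
      w <- loadings[[labels$stimulus[i]]]
      data[verts, bins, i] <- data[verts, bins, i] +
        trial_amp[i] * tcrossprod(w, env[bins])
    }
    gt[[e]] <- list(kind = ef$kind, regions = ef$target_regions,
                    time_bins = bins, time_ms = time_ms[bins],
                    stimuli = stim_set, trial_amplitude = trial_amp)
  }

  epochs <- new_source_epochs(data, time_ms, labels)
  if (config$leakage_width > 0) {
    epochs <- apply_spatial_leakage(epochs, parcellation, config$leakage_width)
  }
  list(epochs = epochs, ground_truth = gt)
}

#' Simulate a full multi-subject dataset
#'
#' Materializes every subject's epochs in memory; for large configurations
#' prefer iterating [simulate_subject()] (as [run_pipeline()] does).
#'
#' @inheritParams simulate_subject
#' @return A list with `subjects` (list of `source_epochs`), `parcellation`,
#'   `ground_truth` (per subject) and the `config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_subjects = 2, n_regions = 4,
#'                          vertices_per_region = 5,
#'                          n_trials_per_condition = 5, seed = 7)
#' ds <- simulate_dataset(cfg)
#' dim(ds$subjects[[1]]$data)  # 20 x 81 x 60
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  parc <- build_synthetic_parcellation(config$n_regions,
                                       config$vertices_per_region,
                                       seed = config$seed)
  subs <- vector("list", config$n_subjects)
  gts <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    r <- simulate_subject(config, i, parc)
    subs[[i]] <- r$epochs
    gts[[i]] <- r$ground_truth
  }
  list(subjects = subs, parcellation = parc, ground_truth = gts,
       config = config)
}

#' Mix vertex signals across neighbouring regions (leakage stand-in)
#'
#' Emulates the spatial blur of a linear inverse solution at the region level:
#' each vertex's signal becomes a normalized mixture of its own signal and the
#' mean signals of regions up to `width` indices away (triangular kernel
#' `(width + 1 - d) / (width + 1)`). Region adjacency is the index chain of
#' the synthetic parcellation. `width = 0` is the identity, and a spatially
#' constant signal passes through unchanged.
#'
#' @param epochs A `source_epochs`.
#' @param parcellation The matching `parcellation`.
#' @param width Non-negative leakage width, in regions.
#' @return A new `source_epochs` with mixed signals.
#' @export
apply_spatial_leakage <- function(epochs, parcellation, width) {
  stopifnot(inherits(epochs, "source_epochs"), inherits(parcellation, "parcellation"))
  check_scalar_number(width, "width", min = 0)
  if (width == 0) return(epochs)
  nv <- parcellation$n_vertices
  if (dim(epochs$data)[1] != nv) {
    stop_invalid("parcellation has %d vertices but data has %d",
                 nv, dim(epochs$data)[1])
  }
  nr <- parcellation$n_regions
  nt <- dim(epochs$data)[2]; ntr <- dim(epochs$data)[3]
  flat <- matrix(epochs$data, nrow = nv)  # vertices x (time*trials)
  # region means
  M <- rowsum(flat, parcellation$assignment) / as.numeric(parcellation$region_sizes)
  out <- flat
  for (r in seq_len(nr)) {
    d <- abs(seq_len(nr) - r)
    nb <- which(d >= 1 & d <= width)
    if (!length(nb)) next
    wts <- (width + 1 - d[nb]) / (width + 1)
    mix <- crossprod(matrix(wts, nrow = length(nb)), M[nb, , drop = FALSE])
    v <- which(parcellation$assignment == r)
    out[v, ] <- (flat[v, , drop = FALSE] +
                   rep(1, length(v)) %o% as.numeric(mix)) / (1 + sum(wts))
  }
  new_source_epochs(array(out, dim = c(nv, nt, ntr)), epochs$time_ms, epochs$labels)
}
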