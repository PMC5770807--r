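#' Write / read a simulated dataset container
#'
#' Serializes the dataset list (`subjects`, `parcellation`, `ground_truth`,
#' `config`) to a single-file container with a schema version, and validates
#' the schema on read, naming any missing field.
#'
#' @param dataset A dataset list as returned by [simulate_dataset()].
#' @param path File path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   the dataset list.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(is.list(dataset))
  payload <- list(schema = "megrsa-dataset", version = 1L, dataset = dataset)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path, call. = FALSE)
  payload <- readRDS(path)
  if (!identical(payload$schema, "megrsa-dataset")) {
    abort("not a megrsa dataset container", class = "megrsa_schema_error")
  }
  ds <- payload$dataset
  for (field in c("subjects", "parcellation")) {
    if (is.null(ds[[field]])) {
      abort(sprintf("dataset is missing field '%s'", field),
            class = "megrsa_schema_error")
    }
  }
  for (i in seq_along(ds$subjects)) {
    ep <- ds$subjects[[i]]
    for (field in c("data", "time_ms", "labels")) {
      if (is.null(ep[[field]])) {
        abort(sprintf("subject %d is missing field '%s'", i, field),
              class = "megrsa_schema_error")
      }
    }
    for (lcol in c("stimulus", "group", "section", "presentation_order")) {
      if (is.null(ep$labels[[lcol]])) {
        abort(sprintf("subject %d labels are missing '%s'", i, lcol),
              class = "megrsa_schema_error")
      }
    }
  }
  ds
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  # strip the RDS header (carries version info) before hashing
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline on simulated or loaded data
#'
#' Executes the stages in order — simulate (or ingest) -> resample ->
#' region-component reduction -> pairwise decoding -> RSA model maps ->
#' group statistics (t-maps, FDR, onsets, MANOVA) -> repetition analysis —
#' streaming one subject at a time so only component-level data stays in
#' memory. Identical config and seed give identical outputs.
#'
#' @param config A [simulation_config()] describing the dataset, or a dataset
#'   list from [simulate_dataset()] / [read_dataset()].
#' @param models Model names for [model_rdm_set()].
#' @param window_ms Analysis window passed to [resample_epochs()]
#'   (default `c(-100, 700)`, clipped to the data span).
#' @param n_randomizations Decoder randomizations per pair.
#' @param min_trials Condition exclusion threshold.
#' @param q FDR level(s); default per-model convention (0.01 types 1/2,
#'   0.05 type 3).
#' @param one_sided Sidedness of the region-time t-tests.
#' @param manova_window_ms Time window averaged before the MANOVA
#'   (default `c(50, 400)`).
#' @param repetition List of repetition analyses, each a list with `region`,
#'   `category`, `window_ms` (optional `section`).
#' @param seed Master seed for every stage (defaults to the config's).
#' @param cache_dir Optional directory; per-subject decoding results are
#'   cached there keyed by a config hash and reused on reruns.
#' @return A `pipeline_result` list: `z_maps` (subject-level tibble),
#'   `ttest`, `significance`, `onsets`, `accuracy_maps` (group-mean pairwise
#'   accuracy), `manova`, `repetition` (per-analysis amplitudes + fit),
#'   `entries`, `manifest`.
#' @export
run_pipeline <- function(config,
                         models = c("recognizer", "face_vs_nonsense",
                                    "tool_vs_nonsense", "face_specific",
                                    "tool_specific", "meaningful"),
                         window_ms = c(-100, 700),
                         n_randomizations = 100, min_trials = 50L,
                         q = NULL, one_sided = FALSE,
                         manova_window_ms = c(50, 400),
                         repetition = list(), seed = NULL,
                         cache_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  from_config <- inherits(config, "simulation_config")
  if (from_config) {
    parc <- build_synthetic_parcellation(config$n_regions,
                                         config$vertices_per_region,
                                         seed = config$seed)
    n_subjects <- config$n_subjects
    if (is.null(seed)) seed <- config$seed
  } else {
    parc <- config$parcellation
    n_subjects <- length(config$subjects)
    if (is.null(seed)) seed <- 1L
  }
  model_set <- model_rdm_set(models)
  stage_time <- c()
  mark <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    stage_time[[name]] <<- t1 - t0
    t0 <<- t1
  }
  hash <- config_hash(list(config = if (from_config) config else "external",
                           n_randomizations = n_randomizations,
                           min_trials = min_trials, seed = seed))

  z_list <- vector("list", n_subjects)
  acc_list <- vector("list", n_subjects)
  rep_list <- list()
  entries <- NULL
  for (i in seq_len(n_subjects)) {
    epochs <- if (from_config) {
      simulate_subject(config, i, parc)$epochs
    } else {
      config$subjects[[i]]
    }
    span <- range(epochs$time_ms)
    epochs <- resample_epochs(epochs, window_ms = c(max(window_ms[1], span[1]),
                                                    min(window_ms[2], span[2])))
    comp <- extract_region_components(epochs, parc)
    cache_file <- if (!is.null(cache_dir)) {
      file.path(cache_dir, sprintf("decode_%s_sub%02d.rds", hash, i))
    }
    dec <- if (!is.null(cache_file) && file.exists(cache_file)) {
      readRDS(cache_file)
    } else {
      d <- decode_conditions(comp, n_randomizations = n_randomizations,
                             min_trials = min_trials,
                             seed = derive_seed(seed, "decode", i))
      if (!is.null(cache_file)) {
        dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(d, cache_file)
      }
      d
    }
    entries <- dec$entries
    zi <- rsa_model_maps(dec, model_set)
    zi$subject <- i
    z_list[[i]] <- zi
    ai <- tidy(dec)
    ai$subject <- i
    acc_list[[i]] <- ai
    for (rs in repetition) {
      series <- repetition_series(comp, dec, rs$region, rs$category,
                                  rs$window_ms,
                                  section = rs$section %||% 1,
                                  min_trials = min_trials)
      if (is.null(series)) next
      series$subject <- i
      series$analysis <- paste0(rs$category, "_r", rs$region)
      rep_list[[length(rep_list) + 1]] <- series
    }
  }
  mark("subjects")

  z_maps <- dplyr::bind_rows(z_list)
  tt <- region_time_ttest(z_maps, one_sided = one_sided)
  sig <- fdr_mask(tt, q = q)
  onsets <- onset_table(sig)
  acc_maps <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(acc_list),
                    .data$region, .data$time_ms, .data$pair),
    accuracy = mean(.data$accuracy, na.rm = TRUE), .groups = "drop")
  mark("group_stats")

  man <- NULL
  if (length(models) >= 3 && n_subjects >= 2) {
    zw <- dplyr::filter(z_maps, .data$time_ms >= manova_window_ms[1],
                        .data$time_ms <= manova_window_ms[2])
    zw <- dplyr::summarise(
      dplyr::group_by(zw, .data$subject, .data$region, .data$model),
      z = mean(.data$z, na.rm = TRUE), .groups = "drop")
    zw$area <- zw$region
    man <- tryCatch(manova_model_specificity(zw),
                    error = function(e) NULL)
  }
  mark("manova")

  rep_out <- NULL
  if (length(rep_list)) {
    amp <- dplyr::bind_rows(rep_list)
    rep_out <- lapply(split(amp, amp$analysis), function(d) {
      list(amplitudes = as_tibble(d), fit = repetition_regression(d))
    })
  }
  mark("repetition")

  structure(
    list(z_maps = z_maps, ttest = tt, significance = sig, onsets = onsets,
         accuracy_maps = acc_maps, manova = man, repetition = rep_out,
         entries = entries,
         manifest = list(
           config_hash = hash, seed = seed, n_subjects = n_subjects,
           models = models, n_randomizations = n_randomizations,
           min_trials = min_trials,
           package_version = as.character(utils::packageVersion("megrsa")),
           r_version = R.version.string,
           stage_seconds = unlist(stage_time),
           output_digest = config_hash(list(z = z_maps, o = onsets)))),
    class = "pipeline_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects, %d models, %d regions x %d time bins\n",
              x$manifest$n_subjects, length(x$manifest$models),
              length(unique(x$ttest$region)), length(unique(x$ttest$time_ms))))
  sig_n <- sum(x$significance$significant)
  cat(sprintf("  %d significant region-time cells; %d region onsets found\n",
              sig_n, sum(!is.na(x$onsets$onset_ms))))
  if (!is.null(x$manova)) {
    cat(sprintf("  model specificity: chi2(%d) = %.2f, p = %.3g\n",
                x$manova$df, x$manova$chi2, x$manova$p_value))
  }
  invisible(x)
}
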