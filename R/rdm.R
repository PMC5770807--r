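#' Construct an RDM container
#'
#' A 12 x 12 symmetric dissimilarity matrix over the (stimulus, section)
#' entries, with a validity mask (the diagonal is always invalid). Used for
#' both empirical matrices (decoding accuracies) and binary model matrices.
#'
#' @param values 12 x 12 symmetric numeric matrix.
#' @param mask 12 x 12 symmetric logical matrix of valid cells.
#' @return An `rdm` object.
#' @export
new_rdm <- function(values, mask) {
  stopifnot(is.matrix(values), all(dim(values) == c(12, 12)),
            is.matrix(mask), all(dim(mask) == c(12, 12)))
  diag(mask) <- FALSE
  if (!isTRUE(all.equal(values[mask], t(values)[mask])) ||
      !identical(mask, t(mask))) {
    stop_invalid("RDM values and mask must be symmetric")
  }
  structure(list(values = values, mask = mask,
                 entries = rsa_entries()), class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> 12 x 12, %d valid upper-triangle cells\n",
              sum(x$mask[upper.tri(x$mask)])))
  invisible(x)
}

#' Empirical RDM from pairwise decoding accuracies
#'
#' Cell (a, b) holds the decoding accuracy for entry pair \{a, b\} at one
#' region and time bin — accuracy is the dissimilarity measure. Cells
#' involving excluded conditions (and the diagonal) are masked invalid.
#'
#' @param decoding A `decoding_result`.
#' @param region Region index (must be among `decoding$regions`).
#' @param time_bin Time-bin index into `decoding$time_ms`.
#' @return An `rdm`.
#' @export
build_empirical_rdm <- function(decoding, region, time_bin) {
  stopifnot(inherits(decoding, "decoding_result"))
  ri <- match(region, decoding$regions)
  if (is.na(ri)) stop("region not present in decoding result", call. = FALSE)
  if (time_bin < 1 || time_bin > length(decoding$time_ms)) {
    stop("time_bin out of range", call. = FALSE)
  }
  vals <- matrix(0, 12, 12)
  mask <- matrix(FALSE, 12, 12)
  pr <- decoding$pairs
  accs <- decoding$accuracy[ri, time_bin, ]
  for (i in seq_len(nrow(pr))) {
    a <- pr$a[i]; b <- pr$b[i]
    if (is.na(accs[i])) next
    vals[a, b] <- vals[b, a] <- accs[i]
    mask[a, b] <- mask[b, a] <- TRUE
  }
  new_rdm(vals, mask)
}

#' Model RDMs: stimulus recognizer, category-vs-nonsense, one-vs-rest
#'
#' Three binary model types (values 0 = low, 1 = high dissimilarity):
#'
#' * `"stimulus_recognizer"` (type 1): every between-stimulus pair is
#'   dissimilar (1) except the 6 same-stimulus cross-section pairs (0); all
#'   off-diagonal cells valid.
#' * `"category_vs_nonsense"` (type 2, `target` `"face"` or `"tool"`): only
#'   the 8 entries of the target category and the nonsense group take part;
#'   cross-group cells are 1, within-group cells 0, and the 4 same-stimulus
#'   cross-section cells among them are masked.
#' * `"one_vs_rest"` (type 3, `target` `"face"`, `"tool"` or `"meaningful"`):
#'   all 12 entries; cells between the target group and everything else are
#'   1, cells within the target group and within the rest are 0, and all 6
#'   same-stimulus cross-section cells are masked. `"meaningful"` treats
#'   faces + tools as one group versus nonsense.
#'
#' @param type Model type (see above).
#' @param target Target category; required for types 2 and 3.
#' @return An `rdm` with binary values on valid cells.
#' @export
#' @examples
#' m <- build_model_rdm("one_vs_rest", "face")
#' sum(m$mask[upper.tri(m$mask)])  # 60 valid cells
build_model_rdm <- function(type = c("stimulus_recognizer", "category_vs_nonsense",
                                     "one_vs_rest"),
                            target = NULL) {
  type <- match.arg(type)
  ent <- rsa_entries()
  vals <- matrix(0, 12, 12)
  mask <- matrix(FALSE, 12, 12)
  same_stim <- outer(ent$stimulus, ent$stimulus, "==") &
    outer(ent$section, ent$section, "!=")

  if (type == "stimulus_recognizer") {
    if (!is.null(target)) stop_invalid("type 1 takes no target")
    mask[] <- TRUE
    vals[] <- 1
    vals[same_stim] <- 0
  } else if (type == "category_vs_nonsense") {
    if (is.null(target) || !target %in% c("face", "tool")) {
      stop_invalid("type 2 target must be 'face' or 'tool'")
    }
    keep <- ent$group %in% c(target, "nonsense")
    mask[keep, keep] <- TRUE
    vals[outer(keep, keep, "&") & outer(ent$group, ent$group, "!=")] <- 1
    mask[same_stim] <- FALSE
  } else {
    if (is.null(target) || !target %in% c("face", "tool", "meaningful")) {
      stop_invalid("type 3 target must be 'face', 'tool' or 'meaningful'")
    }
    in_target <- if (target == "meaningful") {
      ent$group %in% c("face", "tool")
    } else {
      ent$group == target
    }
    mask[] <- TRUE
    vals[outer(in_target, !in_target, "&") | outer(!in_target, in_target, "&")] <- 1
    mask[same_stim] <- FALSE
  }
  diag(mask) <- FALSE
  new_rdm(vals, mask)
}

#' Named model set used by the pipeline
#'
#' @param models Character vector of model names among `"recognizer"`,
#'   `"face_vs_nonsense"`, `"tool_vs_nonsense"`, `"face_specific"`,
#'   `"tool_specific"`, `"meaningful"`.
#' @return Named list of `rdm` objects.
#' @export
model_rdm_set <- function(models = c("recognizer", "face_vs_nonsense",
                                     "tool_vs_nonsense", "face_specific",
                                     "tool_specific", "meaningful")) {
  defs <- list(
    recognizer = list("stimulus_recognizer", NULL),
    face_vs_nonsense = list("category_vs_nonsense", "face"),
    tool_vs_nonsense = list("category_vs_nonsense", "tool"),
    face_specific = list("one_vs_rest", "face"),
    tool_specific = list("one_vs_rest", "tool"),
    meaningful = list("one_vs_rest", "meaningful")
  )
  bad <- setdiff(models, names(defs))
  if (length(bad)) stop_invalid("unknown model(s): %s", paste(bad, collapse = ", "))
  setNames(lapply(models, function(m) {
    build_model_rdm(defs[[m]][[1]], defs[[m]][[2]])
  }), models)
}

#' Default FDR level per model
#'
#' Convention used by the group statistics: q = 0.01 for the stimulus
#' recognizer and category-vs-nonsense models, q = 0.05 for the one-vs-rest
#' (type 3) models.
#'
#' @param model Character vector of model names (see [model_rdm_set()]).
#' @return Numeric vector of FDR levels.
#' @export
model_fdr_level <- function(model) {
  ifelse(model %in% c("face_specific", "tool_specific", "meaningful"), 0.05, 0.01)
}

#' Spearman correlation between an empirical and a model RDM
#'
#' Rank correlation (average ranks for ties) over the upper-triangle cells
#' valid in both matrices. Undefined results — fewer than 3 joint cells, or a
#' constant model or empirical vector — propagate as `NA`, not zero.
#'
#' @param empirical,model `rdm` objects.
#' @return Spearman's rho in `[-1, 1]`, or `NA` when undefined.
#' @export
correlate_rdms <- function(empirical, model) {
  stopifnot(inherits(empirical, "rdm"), inherits(model, "rdm"))
  up <- upper.tri(empirical$values)
  joint <- up & empirical$mask & model$mask
  if (sum(joint) < 3) return(NA_real_)
  x <- empirical$values[joint]
  y <- model$values[joint]
  if (length(unique(y)) < 2 || length(unique(x)) < 2) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Fisher variance-stabilizing transform
#'
#' `z = atanh(rho)`; correlations at exactly +/-1 are clipped to
#' `1 - 1e-6` in magnitude so the transform stays finite.
#'
#' @param rho Correlation(s) in `[-1, 1]` (NA passes through).
#' @return Fisher z value(s).
#' @export
fisher_z <- function(rho) {
  clipped <- pmin(pmax(rho, -1 + 1e-6), 1 - 1e-6)
  atanh(clipped)
}

#' Fisher-z model correlation maps across regions and time
#'
#' For every region and time bin of a decoding result, builds the empirical
#' RDM and correlates it with each model RDM, returning Fisher-transformed
#' Spearman coefficients — one subject's contribution to the group maps.
#'
#' @param decoding A `decoding_result`.
#' @param models Named list of model `rdm`s (default [model_rdm_set()]).
#' @return A tibble with `region`, `time_ms`, `model`, `rho`, `z`.
#' @export
rsa_model_maps <- function(decoding, models = model_rdm_set()) {
  stopifnot(inherits(decoding, "decoding_result"))
  up <- upper.tri(matrix(0, 12, 12))
  pr <- decoding$pairs
  # precompute, per model, which pairs are valid and the model values
  prep <- lapply(models, function(m) {
    valid <- m$mask[cbind(pr$a, pr$b)]
    list(idx = which(valid), y = m$values[cbind(pr$a, pr$b)][valid])
  })
  nt <- length(decoding$time_ms)
  out <- vector("list", length(decoding$regions))
  for (ri in seq_along(decoding$regions)) {
    rows <- vector("list", length(models))
    for (mi in seq_along(models)) {
      p <- prep[[mi]]
      rho <- vapply(seq_len(nt), function(t) {
        x <- decoding$accuracy[ri, t, p$idx]
        ok <- !is.na(x)
        if (sum(ok) < 3) return(NA_real_)
        y <- p$y[ok]
        if (length(unique(y)) < 2 || length(unique(x[ok])) < 2) return(NA_real_)
        stats::cor(x[ok], y, method = "spearman")
      }, numeric(1))
      rows[[mi]] <- tibble(region = decoding$regions[ri],
                           time_ms = decoding$time_ms,
                           model = names(models)[mi],
                           rho = rho, z = fisher_z(rho))
    }
    out[[ri]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out)
}
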