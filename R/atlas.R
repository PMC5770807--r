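#' The 82-region cortical atlas table
#'
#' Loads the packaged parcellation scheme: 41 gyral/sulcal areas of a modified
#' Destrieux scheme, each present in both hemispheres, giving 82 regions. Rows
#' follow the canonical order used by every region-indexed result in the
#' package: printed area order, left hemisphere before right. MNI seed
#' coordinates are given for the right hemisphere; left-hemisphere seeds mirror
#' the x coordinate.
#'
#' @param path Optional path to a user-supplied TSV with columns
#'   `name`, `alias`, `hemisphere`, `mni_x`, `mni_y`, `mni_z`. Defaults to the
#'   packaged table. User tables may extend the scheme but must satisfy the
#'   same invariants (two hemispheres per alias, finite seeds).
#' @return A tibble with one row per region and columns `region` (integer
#'   index), `name`, `alias`, `hemisphere` (`"left"`/`"right"`), `label`
#'   (e.g. `"leIPS"`, `"rFG"`), `mni_x`, `mni_y`, `mni_z`.
#' @export
#' @examples
#' atlas <- load_region_table()
#' nrow(atlas)                       # 82
#' dplyr::filter(atlas, alias == "IPS", hemisphere == "right")
load_region_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "atlas_regions_82.tsv", package = "megrsa")
  }
  if (!nzchar(path) || !file.exists(path)) {
    abort("region table resource not found; package installation is corrupt",
          class = "megrsa_config_error")
  }
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = TRUE)
  needed <- c("name", "alias", "hemisphere", "mni_x", "mni_y", "mni_z")
  if (!all(needed %in% names(raw))) {
    abort(sprintf("region table is missing columns: %s",
                  paste(setdiff(needed, names(raw)), collapse = ", ")),
          class = "megrsa_config_error")
  }
  tbl <- as_tibble(raw[needed])
  validate_region_table(tbl)
  tbl$label <- paste0(ifelse(tbl$hemisphere == "left", "le", "r"), tbl$alias)
  tibble(region = seq_len(nrow(tbl)), tbl)
}

validate_region_table <- function(tbl) {
  if (!all(tbl$hemisphere %in% c("left", "right"))) {
    abort("hemisphere must be 'left' or 'right'", class = "megrsa_config_error")
  }
  if (anyDuplicated(paste(tbl$alias, tbl$hemisphere))) {
    abort("alias + hemisphere must be unique", class = "megrsa_config_error")
  }
  per_alias <- table(tbl$alias)
  if (any(per_alias != 2L)) {
    abort("every alias must appear in exactly two hemispheres",
          class = "megrsa_config_error")
  }
  seeds <- as.matrix(tbl[c("mni_x", "mni_y", "mni_z")])
  if (!all(is.finite(seeds))) {
    abort("MNI seeds must be finite", class = "megrsa_config_error")
  }
  invisible(tbl)
}

#' Build a synthetic vertex-to-region parcellation
#'
#' Assigns vertices to regions as disjoint contiguous blocks, standing in for a
#' FreeSurfer labeling when working with simulated data. Block sizes are either
#' fixed or drawn uniformly from a range (seeded, so reproducible).
#'
#' @param n_regions Number of regions (>= 1).
#' @param vertices_per_region A single count (>= 3) or a length-2 range
#'   `c(min, max)` with `min >= 3`; regions need at least 3 vertices for the
#'   three-component reduction.
#' @param seed Integer seed controlling the drawn block sizes.
#' @return A `parcellation` object: list with `n_vertices`, `assignment`
#'   (integer vector, vertex -> region index) and `n_regions`.
#' @export
#' @examples
#' p <- build_synthetic_parcellation(82, 10, seed = 1)
#' p$n_vertices  # 820
build_synthetic_parcellation <- function(n_regions, vertices_per_region, seed = 1L) {
  n_regions <- check_count(n_regions, "n_regions")
  if (!is.numeric(vertices_per_region) ||
      !length(vertices_per_region) %in% c(1L, 2L) ||
      any(vertices_per_region != round(vertices_per_region))) {
    stop_invalid("`vertices_per_region` must be one count or a range c(min, max)")
  }
  if (any(vertices_per_region < 3)) {
    stop_invalid("`vertices_per_region` must be >= 3 (three components per region)")
  }
  sizes <- if (length(vertices_per_region) == 1L) {
    rep(as.integer(vertices_per_region), n_regions)
  } else {
    with_seed(derive_seed(seed, "parcellation"), {
      sample(seq(vertices_per_region[1], vertices_per_region[2]),
             n_regions, replace = TRUE)
    })
  }
  assignment <- rep(seq_len(n_regions), times = sizes)
  structure(
    list(n_vertices = length(assignment),
         n_regions = n_regions,
         assignment = as.integer(assignment),
         region_sizes = as.integer(sizes)),
    class = "parcellation"
  )
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d vertices in %d regions (sizes %d-%d)\n",
              x$n_vertices, x$n_regions,
              min(x$region_sizes), max(x$region_sizes)))
  invisible(x)
}

region_vertices <- function(parcellation, region) {
  which(parcellation$assignment == region)
}
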