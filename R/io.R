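# Plain-text interchange: cohorts as per-subject CSV matrices plus a
# manifest, realization stacks as per-realization CSVs plus a JSON
# manifest, distance matrices as square CSVs.

#' Write a cohort to disk
#'
#' Each subject becomes one CSV matrix (rows = components, columns = time
#' points, row names in the first column) plus a manifest CSV with columns
#' `subject_id`, `group`, `path`.
#'
#' @param cohort Cohort tibble (see [generate_cohort()]).
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_len(nrow(cohort)), function(i) {
    p <- file.path(dir, paste0(cohort$subject_id[i], ".csv"))
    utils::write.csv(cohort$timecourses[[i]], p, row.names = TRUE)
    p
  }, character(1))
  manifest <- data.frame(
    subject_id = cohort$subject_id,
    group = as.character(cohort$group),
    path = basename(paths)
  )
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a cohort manifest back into a cohort tibble
#'
#' @param manifest Path to a manifest CSV (columns `subject_id`, `group`,
#'   `path`; paths resolved relative to the manifest's directory).
#' @return A cohort tibble with the `timecourses` list-column.
#' @export
read_cohort <- function(manifest) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  base <- dirname(manifest)
  tcs <- lapply(man$path, function(p) {
    full <- if (file.exists(p)) p else file.path(base, p)
    df <- utils::read.csv(full, row.names = 1L, check.names = FALSE)
    as.matrix(df)
  })
  tibble::tibble(
    subject_id = man$subject_id,
    group = factor(man$group),
    timecourses = tcs
  )
}

#' Write an ICA realization stack to disk
#'
#' One CSV per realization's spatial maps (and per mixing matrix when
#' present) plus a JSON manifest recording shapes and file names.
#'
#' @param stack An `"ica_stack"`.
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_realization_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  map_files <- vapply(seq_len(stack$K), function(k) {
    f <- sprintf("maps_%02d.csv", k)
    utils::write.csv(stack$spatial_maps[[k]], file.path(dir, f), row.names = FALSE)
    f
  }, character(1))
  mix_files <- NULL
  if (!is.null(stack$mixing)) {
    mix_files <- vapply(seq_len(stack$K), function(k) {
      f <- sprintf("mixing_%02d.csv", k)
      utils::write.csv(stack$mixing[[k]], file.path(dir, f), row.names = FALSE)
      f
    }, character(1))
  }
  manifest <- list(
    K = stack$K, M = stack$M, n_voxels = stack$n_voxels,
    spatial_maps = map_files, mixing = mix_files
  )
  mp <- file.path(dir, "stack.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, null = "null")
  invisible(mp)
}

#' Read an ICA realization stack from a JSON manifest
#'
#' @param manifest Path to a `stack.json` written by
#'   [write_realization_stack()].
#' @return An `"ica_stack"` (without ground-truth annotations).
#' @export
read_realization_stack <- function(manifest) {
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  base <- dirname(manifest)
  maps <- lapply(man$spatial_maps, function(f) {
    as.matrix(utils::read.csv(file.path(base, f), check.names = FALSE))
  })
  mixing <- NULL
  if (!is.null(man$mixing) && length(man$mixing) > 0L) {
    mixing <- lapply(man$mixing, function(f) {
      as.matrix(utils::read.csv(file.path(base, f), check.names = FALSE))
    })
  }
  structure(list(
    spatial_maps = maps, mixing = mixing,
    K = length(maps), M = nrow(maps[[1L]]), n_voxels = ncol(maps[[1L]]),
    truth = NULL
  ), class = "ica_stack")
}

#' Write / read a distance matrix as a square CSV
#'
#' @param D Distance matrix.
#' @param path CSV path.
#' @return `write_distance_matrix()` returns `path` invisibly;
#'   `read_distance_matrix()` returns the matrix with its metric tag.
#' @export
write_distance_matrix <- function(D, path) {
  df <- as.data.frame(D)
  utils::write.csv(cbind(metric = metric_tag(D), df), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  tag <- as.character(df$metric[1L])
  D <- as.matrix(df[, setdiff(colnames(df), "metric"), drop = FALSE])
  attr(D, "metric") <- tag
  D
}
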