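# Plain-text readers/writers for the pipeline's interchange formats:
# tab-delimited feature/confound tables (first column = subject id, empty
# cell = missing), one whitespace-delimited square count matrix per subject,
# two-column label maps, JSON truth records.

#' Write / read a feature or confound table
#'
#' Tab-delimited text with a header row, subject ids in the first column and
#' empty cells for missing values.
#'
#' @param data Tibble (first column subject id).
#' @param path File path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a tibble.
#' @export
write_feature_table <- function(data, path) {
  readr::write_tsv(data, path, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_tsv(path, na = "", show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_double(),
                                          subject_id = readr::col_character()))
}

#' Write / read a connectome stack
#'
#' Each subject's streamline-count matrix goes to
#' `<dir>/connectome_<subject>.txt` as a whitespace-delimited square integer
#' matrix; per-parcel voxel counts go to `<dir>/voxel_counts.tsv`.
#'
#' @param stack A [connectome_stack()].
#' @param dir Output directory (created if needed).
#' @return `write_connectomes()` returns `dir` invisibly;
#'   `read_connectomes()` returns a [connectome_stack()].
#' @export
write_connectomes <- function(stack, dir) {
  stopifnot(inherits(stack, "connectome_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack$counts)) {
    utils::write.table(
      stack$counts[[i]],
      file.path(dir, paste0("connectome_", stack$subject_id[i], ".txt")),
      row.names = FALSE, col.names = FALSE)
  }
  readr::write_tsv(
    tibble::tibble(node = stack$node_ids,
                   voxel_count = stack$voxel_counts),
    file.path(dir, "voxel_counts.tsv"))
  invisible(dir)
}

#' @rdname write_connectomes
#' @export
read_connectomes <- function(dir) {
  vox <- readr::read_tsv(file.path(dir, "voxel_counts.tsv"),
                         show_col_types = FALSE)
  files <- sort(list.files(dir, pattern = "^connectome_.*\\.txt$",
                           full.names = TRUE))
  if (length(files) == 0) abort("no connectome matrix files found")
  subject_id <- sub("^connectome_(.*)\\.txt$", "\\1", basename(files))
  counts <- lapply(files, function(f) {
    m <- as.matrix(utils::read.table(f))
    dimnames(m) <- NULL
    storage.mode(m) <- "integer"
    m
  })
  connectome_stack(counts, vox$voxel_count, vox$node, subject_id)
}

#' Write / read a two-column label map
#'
#' @param map Tibble with two columns (item id, label).
#' @param path File path.
#' @return The path (write) or a tibble (read).
#' @export
write_label_map <- function(map, path) {
  readr::write_tsv(map, path)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a synthetic cohort to disk in the interchange formats
#'
#' Behavior and confound tables as TSV, ages as a two-column TSV,
#' connectomes as per-subject matrix files plus a voxel-count table, label
#' maps as two-column TSVs, and the truth record as JSON.
#'
#' @param cohort A `syn_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "syn_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(cohort$behavior, file.path(dir, "behavior.tsv"))
  write_feature_table(cohort$confounds, file.path(dir, "confounds.tsv"))
  readr::write_tsv(tibble::tibble(subject_id = cohort$subject_id,
                                  age = cohort$ages),
                   file.path(dir, "ages.tsv"))
  write_connectomes(cohort$connectomes, file.path(dir, "connectomes"))
  write_label_map(cohort$node_modules, file.path(dir, "node_modules.tsv"))
  write_label_map(cohort$behavior_domains,
                  file.path(dir, "behavior_domains.tsv"))
  truth <- cohort$truth
  truth$latent_fun <- NULL
  truth$missing_mask <- which(truth$missing_mask)  # compact: linear indices
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

# Write a square labeled matrix as TSV with a leading label column.
write_matrix_tsv <- function(m, path) {
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  lab <- rownames(m) %||% as.character(seq_len(nrow(m)))
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(id = lab), df), path)
  invisible(path)
}
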