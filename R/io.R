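# TSV interchange for count tables, design metadata and environment.

#' Read and write genus x sample count tables
#'
#' Count tables travel as TSV with genera in rows (first column `genus_id`)
#' and samples in columns. Reading validates that every entry is a
#' non-negative integer and reports the offending cell otherwise.
#'
#' @param path File path.
#' @return `read_count_table()`: an integer matrix with dimnames.
#' @export
read_count_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(df)[1] != "genus_id") {
    abort("Count table must have `genus_id` as its first column.",
          class = "seasonmix_format_error")
  }
  m <- as.matrix(df[, -1])
  rownames(m) <- df$genus_id
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("Non-integer or negative count at genus '%s', sample '%s'.",
                  rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]),
          class = "seasonmix_format_error")
  }
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_count_table
#' @param counts Genus x sample integer matrix.
#' @export
write_count_table <- function(counts, path) {
  validate_counts(counts)
  df <- bind_cols(tibble(genus_id = rownames(counts)), as_tibble(counts))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a sample design table
#'
#' Expects TSV with columns `sample_id`, `site_id`, `elevation_m`,
#' `collection_date` (ISO-8601) and either `depth_layer` (labels like
#' "0-5", "0–5 cm") or `depth_mid_cm` (2.5/7.5/15/25); the missing one of
#' the two is derived.
#'
#' @param path File path.
#' @return Design tibble as produced by [design_grid()].
#' @export
read_design_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("sample_id", "site_id", "elevation_m", "collection_date")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort(paste0("Design table missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "seasonmix_format_error")
  }
  df$collection_date <- as_date_strict(df$collection_date, "collection_date")
  if (!"depth_mid_cm" %in% names(df)) {
    if (!"depth_layer" %in% names(df)) {
      abort("Design table needs `depth_layer` or `depth_mid_cm`.",
            class = "seasonmix_format_error")
    }
    df$depth_mid_cm <- depth_midpoint(df$depth_layer)
  }
  if (!"depth_layer" %in% names(df)) {
    inv <- setNames(names(.depth_map), .depth_map)
    df$depth_layer <- unname(inv[as.character(df$depth_mid_cm)])
  }
  if (anyDuplicated(df[, c("site_id", "collection_date", "depth_layer")])) {
    abort("Duplicate (site, date, depth) combinations in design table.",
          class = "seasonmix_format_error")
  }
  as_tibble(df)[, c("sample_id", "site_id", "elevation_m", "collection_date",
                    "depth_layer", "depth_mid_cm")]
}

#' @rdname read_design_table
#' @param design Design tibble.
#' @export
write_design_table <- function(design, path) {
  readr::write_tsv(as_tibble(design), path)
  invisible(path)
}

#' Read an environmental table keyed by sample_id
#'
#' @param path File path.
#' @return Tibble with `sample_id` plus numeric environmental columns.
#' @export
read_env_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(df)) {
    abort("Environment table needs a `sample_id` column.",
          class = "seasonmix_format_error")
  }
  as_tibble(df)
}

#' Read and cross-validate a full input bundle
#'
#' Loads the count, design, and optional environment tables and enforces
#' sample alignment, naming any offending id.
#'
#' @param counts_path,design_path,env_path File paths (`env_path` optional).
#' @return List: `counts`, `design`, `env` (NULL when not supplied).
#' @export
read_inputs <- function(counts_path, design_path, env_path = NULL) {
  counts <- read_count_table(counts_path)
  design <- read_design_table(design_path)
  missing_meta <- setdiff(colnames(counts), design$sample_id)
  if (length(missing_meta)) {
    abort(paste0("Sample(s) in counts but not in design metadata: ",
                 paste(head(missing_meta, 5), collapse = ", ")),
          class = "seasonmix_alignment_error")
  }
  design <- design |> filter(.data$sample_id %in% colnames(counts))
  env <- NULL
  if (!is.null(env_path)) {
    env <- read_env_table(env_path)
    missing_env <- setdiff(colnames(counts), env$sample_id)
    if (length(missing_env)) {
      abort(paste0("Sample(s) in counts but not in environment table: ",
                   paste(head(missing_env, 5), collapse = ", ")),
            class = "seasonmix_alignment_error")
    }
  }
  list(counts = counts, design = design, env = env)
}
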