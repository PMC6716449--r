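#' Validate a genus x sample count matrix
#'
#' @param counts Integer matrix, genera in rows, samples in columns, with
#'   dimnames.
#' @return The matrix, invisibly, after validation.
#' @keywords internal
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix (genera x samples).",
          class = "seasonmix_input_error")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)[1, ]
    abort(sprintf("Counts must be non-negative integers (first offence at row %d, column %d).",
                  bad[1], bad[2]),
          class = "seasonmix_format_error")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` needs genus rownames and sample colnames.",
          class = "seasonmix_input_error")
  }
  invisible(counts)
}

#' Rarefy a count table to a fixed depth
#'
#' Subsamples each sample's reads without replacement down to `depth`
#' (column sums of the result equal `depth` exactly). Samples whose total
#' is below `depth` are dropped with a warning. The conventional depths for
#' the motivating study design are 21,307 reads for fungal tables and
#' 19,998 for bacterial tables (the minimum observed sample depths).
#'
#' @param counts Genus x sample integer matrix.
#' @param depth Target depth (reads per sample), default 21307.
#' @param seed Optional integer seed; recorded in the `seed` attribute.
#' @return Rarefied matrix with attribute `seed`.
#' @export
rarefy_counts <- function(counts, depth = 21307, seed = NULL) {
  validate_counts(counts)
  if (length(depth) != 1 || depth < 1) {
    abort("`depth` must be a single integer >= 1.", class = "seasonmix_input_error")
  }
  totals <- colSums(counts)
  keep <- totals >= depth
  if (!all(keep)) {
    warn(sprintf("Dropping %d sample(s) with fewer than %d reads: %s",
                 sum(!keep), depth,
                 paste(colnames(counts)[!keep], collapse = ", ")))
  }
  kept <- counts[, keep, drop = FALSE]
  out <- with_seed_opt(seed, {
    # vegan expects samples in rows; silence its smallest-count heuristic
    # warning, which misfires on dense simulated tables
    t(suppressWarnings(vegan::rrarefy(t(kept), sample = depth)))
  })
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(kept)
  attr(out, "seed") <- seed
  out
}

#' Per-sample genus richness
#'
#' Number of genera with nonzero reads in each sample. Richness is
#' monotone non-increasing under rarefaction.
#'
#' @param counts Genus x sample integer matrix.
#' @return Tibble with `sample_id` and `richness`.
#' @export
genus_richness <- function(counts) {
  validate_counts(counts)
  tibble(sample_id = colnames(counts),
         richness = as.integer(colSums(counts > 0)))
}

#' Genus rank abundance and per-cluster rank ranges
#'
#' Ranks genera by total reads (rank 1 = most abundant; ties broken by
#' genus id, lexicographically) and summarises the range of ranks spanned
#' by each cluster — the standard view of whether a cluster collects
#' dominant or rare genera.
#'
#' @param counts Genus x sample integer matrix.
#' @param labels Named integer vector (or tibble with `genus_id`,
#'   `cluster`) assigning every genus to a cluster.
#' @return A list with `genus` (tibble: genus_id, total, rank, cluster) and
#'   `cluster` (tibble: cluster, n_genera, min_rank, max_rank).
#' @export
rank_abundance <- function(counts, labels) {
  validate_counts(counts)
  if (is.data.frame(labels)) {
    labels <- setNames(labels$cluster, labels$genus_id)
  }
  if (!setequal(names(labels), rownames(counts))) {
    abort("`labels` must cover exactly the genera of `counts`.",
          class = "seasonmix_input_error")
  }
  totals <- rowSums(counts)
  ord <- order(-totals, rownames(counts))
  genus <- tibble(
    genus_id = rownames(counts)[ord],
    total = totals[ord],
    rank = seq_along(ord),
    cluster = unname(labels[rownames(counts)[ord]])
  )
  cluster <- genus |>
    group_by(.data$cluster) |>
    summarise(n_genera = n(),
              min_rank = min(.data$rank),
              max_rank = max(.data$rank),
              .groups = "drop")
  list(genus = genus, cluster = cluster)
}
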