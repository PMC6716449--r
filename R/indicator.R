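# Compositional indicator-genus analysis.
#
# Each genus is represented by its relative-abundance profile across
# samples (counts normalized to sum 1 over samples), so the statistic is
# invariant to overall genus abundance. The indicator value of a genus
# within its cluster is the mean proportional similarity between its
# profile and each other member's profile; the permutation p-value
# compares that value to the same statistic computed on randomly drawn
# genus sets of the same size. Note this follows the mean-similarity
# statistic described for genus clusters — not the Dufrene-Legendre
# indicator value for sample groups, which addresses a different design.

genus_profiles <- function(counts) {
  validate_counts(counts)
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    abort(paste0("All-zero genus profile(s): ",
                 paste(head(rownames(counts)[tot == 0], 5), collapse = ", ")),
          class = "seasonmix_degenerate_error")
  }
  counts / tot
}

# proportional similarity between profile p and every row of P
prop_sim_to <- function(p, P) {
  rowSums(pmin(matrix(p, nrow(P), length(p), byrow = TRUE), P))
}

# full genus x genus proportional-similarity matrix
similarity_matrix <- function(counts) {
  P <- genus_profiles(counts)
  G <- nrow(P)
  S <- matrix(0, G, G, dimnames = list(rownames(P), rownames(P)))
  for (g in seq_len(G)) S[g, ] <- prop_sim_to(P[g, ], P)
  S
}

#' Indicator value of a genus within a cluster
#'
#' Mean proportional similarity (`sum_s min(p_s, q_s)` on sample-normalized
#' profiles, bounded in \[0, 1\]) between the focal genus and every other
#' member of its cluster; the focal genus is excluded from the comparison
#' set.
#'
#' @param counts Genus x sample integer matrix.
#' @param focal Focal genus id (rowname).
#' @param members Character vector of the cluster's member genus ids
#'   (may include the focal genus; it is dropped).
#' @return Scalar in \[0, 1\].
#' @export
indicator_value <- function(counts, focal, members) {
  P <- genus_profiles(counts)
  members <- setdiff(members, focal)
  if (!focal %in% rownames(P) || !all(members %in% rownames(P))) {
    abort("Unknown genus id(s).", class = "seasonmix_input_error")
  }
  if (length(members) < 1) {
    abort("Cluster needs at least one member besides the focal genus.",
          class = "seasonmix_input_error")
  }
  mean(prop_sim_to(P[focal, ], P[members, , drop = FALSE]))
}

#' Permutation p-value for an indicator value
#'
#' Draws `n_permutations` random genus sets of size `cluster_size` from the
#' full genus pool, computes the same mean-similarity statistic (a random
#' focal member against the rest of its set), and reports the add-one
#' estimator `p = (1 + #\{null >= observed\}) / (1 + n_permutations)`. With
#' the default 99 permutations the smallest attainable p is 0.01.
#'
#' @param observed Observed indicator value.
#' @param cluster_size Size of the cluster (focal genus included).
#' @param counts Genus x sample integer matrix (the genus pool).
#' @param n_permutations Number of random sets (default 99).
#' @param seed Optional integer seed.
#' @param sim Optional precomputed similarity matrix (see internals); when
#'   supplied, `counts` may be missing.
#' @return Scalar p-value in `[1/(n_permutations + 1), 1]`.
#' @export
permutation_pvalue <- function(observed, cluster_size, counts = NULL,
                               n_permutations = 99, seed = NULL, sim = NULL) {
  if (n_permutations < 1) {
    abort("`n_permutations` must be >= 1.", class = "seasonmix_input_error")
  }
  if (is.null(sim)) sim <- similarity_matrix(counts)
  G <- nrow(sim)
  if (cluster_size > G) {
    abort("Cluster size exceeds the genus pool.", class = "seasonmix_input_error")
  }
  if (cluster_size < 2) {
    abort("Cluster size must be >= 2.", class = "seasonmix_input_error")
  }
  null_stats <- with_seed_opt(seed, {
    vapply(seq_len(n_permutations), function(i) {
      idx <- sample.int(G, cluster_size)
      mean(sim[idx[1], idx[-1]])
    }, numeric(1))
  })
  (1 + sum(null_stats >= observed)) / (1 + n_permutations)
}

#' Indicator table for all genera of a clustering
#'
#' Scores every genus against its own cluster and attaches permutation
#' p-values (one null distribution per cluster size). The genus with the
#' highest indicator value in each cluster is flagged as the cluster's
#' most reliable indicator. Singleton clusters get `NA` values with a
#' warning.
#'
#' @param counts Genus x sample integer matrix.
#' @param clusters Tibble with `genus_id` and `cluster` (e.g. from
#'   [assign_clusters()]), covering all genera.
#' @param n_permutations Permutations per null distribution (default 99).
#' @param seed Optional integer seed.
#' @return Object of class `smx_indicator`: a tibble with `cluster`,
#'   `genus_id`, `indicator_value`, `p.value`, `n_permutations`,
#'   `top_indicator` (logical).
#' @export
indicator_table <- function(counts, clusters, n_permutations = 99, seed = NULL) {
  validate_counts(counts)
  if (!setequal(clusters$genus_id, rownames(counts))) {
    abort("`clusters` must cover exactly the genera of `counts`.",
          class = "seasonmix_input_error")
  }
  sim <- similarity_matrix(counts)
  cl_ids <- sort(unique(clusters$cluster))
  rows <- map(cl_ids, function(cl) {
    members <- clusters$genus_id[clusters$cluster == cl]
    m <- length(members)
    if (m < 2) {
      warn(sprintf("Cluster %s is a singleton; indicator value undefined.", cl))
      return(tibble(cluster = cl, genus_id = members,
                    indicator_value = NA_real_, p.value = NA_real_,
                    n_permutations = n_permutations))
    }
    vals <- vapply(members, function(g) {
      mean(sim[g, setdiff(members, g)])
    }, numeric(1))
    null_stats <- with_seed_opt(derive_seed(seed, match(cl, cl_ids)) %||% NULL, {
      vapply(seq_len(n_permutations), function(i) {
        idx <- sample.int(nrow(sim), m)
        mean(sim[idx[1], idx[-1]])
      }, numeric(1))
    })
    pvals <- vapply(vals, function(v) {
      (1 + sum(null_stats >= v)) / (1 + n_permutations)
    }, numeric(1))
    tibble(cluster = cl, genus_id = members, indicator_value = unname(vals),
           p.value = unname(pvals), n_permutations = n_permutations)
  })
  out <- list_rbind(rows) |>
    group_by(.data$cluster) |>
    mutate(top_indicator = !is.na(.data$indicator_value) &
             .data$indicator_value == max(.data$indicator_value)) |>
    ungroup()
  class(out) <- c("smx_indicator", class(out))
  out
}
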