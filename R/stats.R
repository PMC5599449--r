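#' Shannon diversity index
#'
#' `H' = -sum p_i log(p_i)` over taxa with non-zero counts. Natural
#' logarithm by default (the H' convention); pass `base = 2` for the
#' historical QIIME convention.
#'
#' @param counts non-negative numeric vector (counts or relative
#'   abundances) with positive sum.
#' @param base logarithm base.
#' @return The Shannon index.
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(counts < 0)) abort("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) abort("cannot compute Shannon index of an all-zero vector")
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = base))
}

#' Per-sample diversity summaries
#'
#' @param counts a long count tibble.
#' @param base logarithm base for [shannon()].
#' @return A tibble `sample_id`, `n_reads`, `richness`, `shannon`.
#' @export
sample_diversity <- function(counts, base = exp(1)) {
  counts |>
    group_by(.data$sample_id) |>
    summarise(n_reads = sum(.data$count),
              richness = sum(.data$count > 0),
              shannon = shannon(.data$count, base = base),
              .groups = "drop")
}

#' Rarefaction by repeated subsampling
#'
#' Observed OTU richness from subsampling the count vector without
#' replacement at each depth, repeated `n_reps` times. The subsampling mean
#' converges on the hypergeometric closed form
#' `E[S_d] = sum_i (1 - choose(N - N_i, d) / choose(N, d))`
#' (as computed by `vegan::rarefy`), which is used as the oracle in the
#' package's tests.
#'
#' @param counts non-negative integer vector.
#' @param depths subsampling depths (each at most `sum(counts)`).
#' @param n_reps repetitions per depth.
#' @param seed integer seed.
#' @return A tibble of class `cs_rarefaction`: `depth`, `mean_otus`,
#'   `sd_otus`, `n_reps`.
#' @export
rarefaction_curve <- function(counts, depths, n_reps = 10L, seed = 1L) {
  counts <- as.integer(counts)
  total <- sum(counts)
  if (any(depths > total)) {
    abort(paste0("depth exceeds total count (", total, ")"))
  }
  taxa <- rep.int(seq_along(counts), counts)
  with_seed(seed, {
    res <- map(depths, function(d) {
      obs <- vapply(seq_len(n_reps), function(r) {
        length(unique(taxa[sample.int(total, d)]))
      }, integer(1))
      tibble(depth = d, mean_otus = mean(obs), sd_otus = stats::sd(obs),
             n_reps = n_reps)
    })
    structure(bind_rows(res), class = c("cs_rarefaction", "tbl_df", "tbl",
                                        "data.frame"))
  })
}

#' Bray-Curtis dissimilarity between two profiles
#'
#' `sum |x_i - y_i| / sum (x_i + y_i)`, in \[0, 1\] for non-negative data.
#'
#' @param x,y equal-length non-negative numeric vectors.
#' @return The dissimilarity.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (any(x < 0) || any(y < 0)) abort("abundances must be non-negative")
  denom <- sum(x + y)
  if (denom == 0) abort("Bray-Curtis undefined for two all-zero profiles")
  sum(abs(x - y)) / denom
}

#' Pairwise Bray-Curtis distance matrix
#'
#' Computed with `vegan::vegdist` on the samples-by-OTU matrix implied by a
#' long count (or relative-abundance) tibble.
#'
#' @param counts a long tibble with `sample_id`, `otu_id` and a value
#'   column.
#' @param value which column to use (`"count"` or `"rel_abundance"`).
#' @return A `dist` object labelled by sample id.
#' @export
bray_curtis_matrix <- function(counts, value = "count") {
  m <- counts_matrix(counts, value)
  vegan::vegdist(m, method = "bray")
}

counts_matrix <- function(counts, value = "count") {
  wide <- counts |>
    select("sample_id", "otu_id", value = all_of(value)) |>
    tidyr::pivot_wider(names_from = "otu_id", values_from = "value",
                       values_fill = 0) |>
    arrange(.data$sample_id)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}

#' UPGMA (average-linkage) hierarchical clustering
#'
#' @param d a `dist` object (e.g. from [bray_curtis_matrix()]).
#' @return An `hclust` object.
#' @export
hclust_upgma <- function(d) {
  if (attr(d, "Size") < 2L) abort("clustering needs at least two samples")
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Tidy merge list of a dendrogram
#'
#' @param h an `hclust` object.
#' @return A tibble `step`, `a`, `b`, `height` where leaves are labelled by
#'   name and internal nodes by `node<step>`.
#' @export
dendrogram_merges <- function(h) {
  lab <- function(i) {
    if (i < 0) h$labels[-i] else paste0("node", i)
  }
  tibble(
    step = seq_len(nrow(h$merge)),
    a = map_chr(h$merge[, 1], lab),
    b = map_chr(h$merge[, 2], lab),
    height = h$height
  )
}

#' Write a dendrogram as Newick
#'
#' @param h an `hclust` object.
#' @param path output path.
#' @export
write_newick <- function(h, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("write_newick() requires the ape package")
  }
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}

#' SIMPER: per-OTU contributions to between-group dissimilarity
#'
#' For every cross-group sample pair (j, k), the Bray-Curtis dissimilarity
#' on (by default square-root transformed) relative abundances decomposes
#' additively over OTUs as `d_i(j,k) = |y_ij - y_ik| / sum_m (y_mj + y_mk)`.
#' The SIMPER contribution of OTU i is the mean of `d_i(j,k)` over all
#' cross-group pairs, so the contributions sum exactly to the average
#' between-group dissimilarity. The square-root transform follows standard
#' SIMPER practice of damping the influence of dominant taxa.
#'
#' @param rel a relative-abundance tibble ([relative_abundances()]).
#' @param group_a,group_b disjoint character vectors of sample ids.
#' @param sqrt_transform apply a square-root transform first (default TRUE).
#' @return A tibble of class `cs_simper`, ordered by descending
#'   contribution: `otu_id`, `average` (contribution to the average
#'   dissimilarity), `contribution_pct`, `cumulative_pct`, `mean_a`,
#'   `mean_b` (group means of the transformed abundances). The overall
#'   average dissimilarity and pair count are attached as attributes
#'   `overall` and `n_pairs`.
#' @export
simper <- function(rel, group_a, group_b, sqrt_transform = TRUE) {
  if (length(intersect(group_a, group_b)) > 0) {
    abort("`group_a` and `group_b` must be disjoint")
  }
  if (length(group_a) < 1L || length(group_b) < 1L) {
    abort("each group needs at least one sample")
  }
  m <- counts_matrix(rel |> filter(.data$sample_id %in% c(group_a, group_b)),
                     value = "rel_abundance")
  missing <- setdiff(c(group_a, group_b), rownames(m))
  if (length(missing) > 0) {
    abort(paste0("sample(s) not in table: ", paste(missing, collapse = ", ")))
  }
  y <- if (sqrt_transform) sqrt(m) else m
  otus <- colnames(y)
  contrib <- numeric(ncol(y))
  n_pairs <- 0L
  for (j in group_a) {
    for (k in group_b) {
      denom <- sum(y[j, ] + y[k, ])
      if (denom == 0) abort("a cross-group pair has two all-zero profiles")
      contrib <- contrib + abs(y[j, ] - y[k, ]) / denom
      n_pairs <- n_pairs + 1L
    }
  }
  contrib <- contrib / n_pairs
  overall <- sum(contrib)
  out <- tibble(
    otu_id = otus,
    average = unname(contrib),
    mean_a = unname(colMeans(y[group_a, , drop = FALSE])),
    mean_b = unname(colMeans(y[group_b, , drop = FALSE]))
  ) |>
    arrange(desc(.data$average), .data$otu_id) |>
    mutate(
      contribution_pct = if (overall > 0) 100 * .data$average / overall
      else 0,
      cumulative_pct = cumsum(.data$contribution_pct)
    ) |>
    select("otu_id", "average", "contribution_pct", "cumulative_pct",
           "mean_a", "mean_b")
  structure(out, class = c("cs_simper", class(tibble())),
            overall = overall, n_pairs = n_pairs)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.cs_simper <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.cs_simper <- function(x, ...) {
  tibble(overall_dissimilarity = attr(x, "overall"),
         n_pairs = attr(x, "n_pairs"),
         n_otus = nrow(x))
}
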