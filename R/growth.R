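#' Per-sample relative abundances
#'
#' @param counts a long count tibble (`sample_id`, `otu_id`, `count`).
#' @return The tibble with a `rel_abundance` column; samples whose counts
#'   sum to zero are dropped with a warning.
#' @export
relative_abundances <- function(counts) {
  totals <- counts |>
    group_by(.data$sample_id) |>
    summarise(total = sum(.data$count), .groups = "drop")
  empty <- totals$sample_id[totals$total == 0]
  if (length(empty) > 0) {
    warn(paste0("dropping zero-count sample(s): ",
                paste(empty, collapse = ", ")))
  }
  counts |>
    left_join(totals, by = "sample_id") |>
    filter(.data$total > 0) |>
    mutate(rel_abundance = .data$count / .data$total) |>
    select(-"total")
}

#' Growth-detection parameters
#'
#' The three criteria for concluding that an OTU actually grew on a plate
#' (rather than being carried over from the inoculum): (I) its relative
#' abundance must have increased compared to the inoculum, (II) its relative
#' abundance in the scraped community must be at least 0.2%, and (III) the
#' scraped community must comprise at least 20 visible colonies.
#'
#' @param min_rel_abundance criterion II threshold (fraction, inclusive).
#' @param min_visible_colonies criterion III threshold (inclusive).
#' @param require_increase apply criterion I (strict increase; an OTU absent
#'   from the inoculum trivially increased from a zero baseline).
#' @return A list of class `cs_growth_params`.
#' @export
growth_params <- function(min_rel_abundance = 0.002,
                          min_visible_colonies = 20L,
                          require_increase = TRUE) {
  if (min_rel_abundance < 0 || min_visible_colonies < 0) {
    abort("growth thresholds must be non-negative")
  }
  structure(list(min_rel_abundance = min_rel_abundance,
                 min_visible_colonies = as.integer(min_visible_colonies),
                 require_increase = isTRUE(require_increase)),
            class = "cs_growth_params")
}

#' Call growth for one scraped community against its inoculum
#'
#' Every OTU detected in the scraped sample receives a call with the three
#' criterion flags; `grew` is their conjunction. OTUs absent from the
#' scraped sample are not called.
#'
#' @param rel a relative-abundance tibble from [relative_abundances()].
#' @param samples sample metadata tibble with at least `sample_id` and
#'   `colonies` (visible colony count) for the scraped sample.
#' @param scraped_id,inoculum_id sample ids.
#' @param params a [growth_params()] object.
#' @return A tibble `otu_id`, `sample_id`, `rel_scraped`, `rel_inoculum`,
#'   `visible_colonies`, `c1_increase`, `c2_abundance`, `c3_colonies`,
#'   `grew`.
#' @export
call_growth <- function(rel, samples, scraped_id, inoculum_id,
                        params = growth_params()) {
  meta <- samples[samples$sample_id == scraped_id, ]
  if (nrow(meta) != 1L || is.na(meta$colonies)) {
    abort(paste0("missing visible colony count for sample ", scraped_id))
  }
  n_col <- meta$colonies
  scraped <- rel |> filter(.data$sample_id == scraped_id)
  inoc <- rel |>
    filter(.data$sample_id == inoculum_id) |>
    select("otu_id", rel_inoculum = "rel_abundance")
  scraped |>
    select("otu_id", rel_scraped = "rel_abundance") |>
    left_join(inoc, by = "otu_id") |>
    mutate(
      rel_inoculum = coalesce(.data$rel_inoculum, 0),
      sample_id = scraped_id,
      visible_colonies = n_col,
      c1_increase = if (params$require_increase) {
        .data$rel_scraped > .data$rel_inoculum
      } else TRUE,
      c2_abundance = .data$rel_scraped >= params$min_rel_abundance,
      c3_colonies = n_col >= params$min_visible_colonies,
      grew = .data$c1_increase & .data$c2_abundance & .data$c3_colonies
    ) |>
    select("otu_id", "sample_id", "rel_scraped", "rel_inoculum",
           "visible_colonies", "c1_increase", "c2_abundance", "c3_colonies",
           "grew")
}

#' Call growth for every scraped sample in a run
#'
#' Pairs each `role == "scraped"` sample with the inoculum sample of the
#' same sponge and row-binds the per-sample calls.
#'
#' @inheritParams call_growth
#' @return Row-bound growth calls.
#' @export
call_growth_all <- function(rel, samples, params = growth_params()) {
  scraped <- samples |> filter(.data$role == "scraped")
  inocula <- samples |> filter(.data$role == "inoculum")
  out <- list()
  for (i in seq_len(nrow(scraped))) {
    inoc <- inocula$sample_id[inocula$sponge == scraped$sponge[i]]
    if (length(inoc) != 1L) {
      abort(paste0("no unique inoculum for sponge ", scraped$sponge[i]))
    }
    if (!scraped$sample_id[i] %in% rel$sample_id) next
    out[[i]] <- call_growth(rel, samples, scraped$sample_id[i], inoc, params)
  }
  bind_rows(out)
}

#' Classify taxonomic novelty against type strains
#'
#' An OTU is novel when its representative's best identity to any type
#' strain is at most `novel_max` percent (inclusive: 95.0 counts as novel),
#' and order-level novel when that identity is strictly below `order_max`.
#'
#' @param otus an OTU tibble.
#' @param refdb the type-strain refdb tibble.
#' @param novel_max inclusive novelty threshold (default 95).
#' @param order_max exclusive order-level threshold (default 89).
#' @param scoring an [align_scoring()] object.
#' @return A tibble `otu_id`, `closest_type_strain`, `identity`, `is_novel`,
#'   `order_level_novel`.
#' @export
classify_novelty <- function(otus, refdb, novel_max = 95, order_max = 89,
                             scoring = align_scoring()) {
  if (nrow(refdb) == 0L) abort("empty type-strain database")
  res <- map(otus$representative, function(s) {
    ids <- percent_identity_many(s, refdb$v1v2, scoring)
    best <- order(-ids, refdb$id)[1L]
    list(ref = refdb$id[best], ident = ids[best])
  })
  tibble(
    otu_id = otus$otu_id,
    closest_type_strain = map_chr(res, "ref"),
    identity = map_dbl(res, "ident")
  ) |>
    mutate(is_novel = .data$identity <= novel_max,
           order_level_novel = .data$identity < order_max)
}

#' Venn-region counts of OTU detection across groups
#'
#' An OTU is detected in a group when its pooled count over the group's
#' samples reaches `presence_min` (default 1 read: detection by even a
#' single read counts). Counts are reported for all `2^k - 1` non-empty
#' regions of the k groups.
#'
#' @param counts a long count tibble.
#' @param groups named list mapping group name to a character vector of
#'   sample ids.
#' @param presence_min pooled-count detection threshold.
#' @return A tibble `region` (group names joined by `&`), `degree`,
#'   `n_otus`, whose `n_otus` sum over regions equals the number of distinct
#'   OTUs detected in any group.
#' @export
overlap_sets <- function(counts, groups, presence_min = 1L) {
  k <- length(groups)
  if (k < 1L) abort("need at least one group")
  if (k > 5L) abort("more than 5 groups does not make a readable Venn")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    abort("`groups` must be a named list")
  }
  detected <- map(groups, function(ids) {
    counts |>
      filter(.data$sample_id %in% ids) |>
      group_by(.data$otu_id) |>
      summarise(pooled = sum(.data$count), .groups = "drop") |>
      filter(.data$pooled >= presence_min) |>
      pull(.data$otu_id)
  })
  all_otus <- unique(unlist(detected))
  membership <- vapply(detected, function(s) all_otus %in% s,
                       logical(length(all_otus)))
  if (length(all_otus) == 1L) membership <- matrix(membership, nrow = 1L)
  subsets <- tidyr::expand_grid(
    !!!setNames(rep(list(c(TRUE, FALSE)), k), names(groups))
  ) |>
    filter(rowSums(across(everything())) > 0)
  n_otus <- map_int(seq_len(nrow(subsets)), function(i) {
    sig <- unlist(subsets[i, ])
    if (length(all_otus) == 0L) return(0L)
    sum(apply(membership, 1L, function(m) all(m == sig)))
  })
  tibble(
    region = map_chr(seq_len(nrow(subsets)), function(i) {
      paste(names(groups)[unlist(subsets[i, ])], collapse = "&")
    }),
    degree = as.integer(rowSums(subsets)),
    n_otus = n_otus
  ) |>
    arrange(.data$degree, .data$region)
}

#' Report novel OTUs that met the growth criteria
#'
#' One row per novel OTU that grew in at least one scraped community: the
#' closest type strain and identity, the number of qualifying samples, the
#' maximum relative abundance over those samples, and the source sponges
#' and media.
#'
#' @param growth_calls output of [call_growth_all()].
#' @param novelty output of [classify_novelty()].
#' @param samples sample metadata tibble (`sample_id`, `sponge`, `medium`).
#' @param min_rel_for_report extra floor on the qualifying relative
#'   abundance (default 0: the growth criteria alone decide).
#' @return A tibble sorted by ascending identity (most novel first).
#' @export
summarize_novel_growth <- function(growth_calls, novelty, samples,
                                   min_rel_for_report = 0) {
  qualifying <- growth_calls |>
    filter(.data$grew, .data$rel_scraped >= min_rel_for_report) |>
    inner_join(novelty |> filter(.data$is_novel), by = "otu_id") |>
    left_join(samples[, c("sample_id", "sponge", "medium")], by = "sample_id")
  if (nrow(qualifying) == 0L) {
    return(tibble(otu_id = character(), closest_type_strain = character(),
                  identity = numeric(), n_samples = integer(),
                  max_rel_abundance = numeric(), sponges = character(),
                  media = character()))
  }
  qualifying |>
    group_by(.data$otu_id, .data$closest_type_strain, .data$identity) |>
    summarise(
      n_samples = n_distinct(.data$sample_id),
      max_rel_abundance = max(.data$rel_scraped),
      sponges = paste(sort(unique(.data$sponge)), collapse = ","),
      media = paste(sort(unique(.data$medium)), collapse = ","),
      .groups = "drop"
    ) |>
    arrange(.data$identity)
}
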