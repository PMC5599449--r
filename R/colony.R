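#' Majority-rule colony-to-OTU assignment
#'
#' A colony is assigned the modal OTU among its reads if and only if that
#' OTU accounts for strictly more than half of the colony's reads; a 50/50
#' split leaves the colony unassigned. By default the denominator is all
#' reads obtained for the colony, including reads that received no OTU label
#' (`NA`), which is the conservative reading of "reads obtained for that
#' colony"; set `count_unlabelled = FALSE` to restrict the denominator to
#' OTU-labelled reads.
#'
#' @param labels tibble with columns `colony_id`, `read_id`, `otu_id`
#'   (`NA` for unclustered reads).
#' @param count_unlabelled include unlabelled reads in the denominator.
#' @param all_colonies optional character vector of colony ids; colonies
#'   with zero retained reads are reported with `total_reads = 0` and no
#'   assignment rather than dropped.
#' @return A tibble `colony_id`, `total_reads`, `top_otu`,
#'   `majority_fraction`, `assigned` (logical), `assigned_otu` (`NA` when
#'   unassigned). Ties for the modal OTU are broken by lexicographic OTU id,
#'   which cannot affect assignment (a tied mode never exceeds 0.5 unless it
#'   is unique... it can when two OTUs tie below the majority line, in which
#'   case neither is assigned anyway).
#' @export
assign_colonies <- function(labels, count_unlabelled = TRUE,
                            all_colonies = NULL) {
  counted <- labels |>
    group_by(.data$colony_id) |>
    summarise(
      total_reads = if (count_unlabelled) n() else sum(!is.na(.data$otu_id)),
      .groups = "drop"
    )
  top <- labels |>
    filter(!is.na(.data$otu_id)) |>
    count(.data$colony_id, .data$otu_id) |>
    group_by(.data$colony_id) |>
    arrange(desc(.data$n), .data$otu_id, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    rename(top_otu = "otu_id", top_n = "n")
  out <- counted |>
    left_join(top, by = "colony_id") |>
    mutate(
      majority_fraction = ifelse(.data$total_reads > 0,
                                 coalesce(.data$top_n, 0L) / .data$total_reads,
                                 0),
      assigned = .data$majority_fraction > 0.5,
      assigned_otu = ifelse(.data$assigned, .data$top_otu, NA_character_)
    ) |>
    select("colony_id", "total_reads", "top_otu", "majority_fraction",
           "assigned", "assigned_otu")
  if (!is.null(all_colonies)) {
    missing <- setdiff(all_colonies, out$colony_id)
    if (length(missing) > 0) {
      out <- bind_rows(out, tibble(
        colony_id = missing, total_reads = 0L, top_otu = NA_character_,
        majority_fraction = 0, assigned = FALSE,
        assigned_otu = NA_character_
      ))
    }
    out <- out[match(all_colonies, out$colony_id), ]
  }
  out
}

#' OTUs selected for regrowth
#'
#' An OTU qualifies if it was assigned (by strict majority) to at least one
#' colony.
#'
#' @param assignments output of [assign_colonies()].
#' @return Sorted character vector of OTU ids.
#' @export
select_otus_for_regrowth <- function(assignments) {
  sort(unique(stats::na.omit(assignments$assigned_otu)))
}

#' Confirm isolates against OTU representatives
#'
#' A Sanger read confirms an isolate as belonging to its target OTU when it
#' is strictly more than `threshold` percent identical to the OTU's
#' representative over the overlapping (V1-V2) region; identity exactly at
#' the threshold does not confirm. Multiple isolates mapping to one OTU from
#' different source samples stay distinct rows (same-OTU isolates from
#' different sponges may be different strains).
#'
#' @param pairs tibble `isolate_id`, `target_otu`, `sanger_bases`.
#' @param otus an OTU tibble (for the representatives).
#' @param threshold confirmation threshold in percent (exclusive).
#' @param scoring an [align_scoring()] object.
#' @return `pairs` with columns `sanger_identity` and `confirmed`.
#' @export
confirm_isolates <- function(pairs, otus, threshold = 97,
                             scoring = align_scoring()) {
  reps <- setNames(otus$representative, otus$otu_id)
  missing <- setdiff(pairs$target_otu, names(reps))
  if (length(missing) > 0) {
    abort(paste0("unknown target OTU(s): ", paste(missing, collapse = ", ")))
  }
  pairs |>
    mutate(
      sanger_identity = map2_dbl(.data$sanger_bases, .data$target_otu,
                                 function(s, o) {
                                   percent_identity(s, reps[[o]], scoring)
                                 }),
      confirmed = .data$sanger_identity > threshold
    )
}

#' @importFrom purrr map2_dbl
NULL
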