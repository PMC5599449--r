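#' Open-reference OTU picking at 97% identity
#'
#' Two-stage greedy clustering with centroid representatives. Stage 1
#' (closed reference): every dereplicated read sequence is assigned to the
#' best reference whose V1-V2 window it matches at or above the identity
#' threshold (ties broken by lexicographic reference id). Stage 2 (de novo):
#' the remaining sequences are sorted by descending duplicate count, then
#' descending length, then lexicographic first-read id - the standard
#' abundance-sorted ordering for greedy centroid clustering - and each joins
#' the first existing centroid it matches at or above the threshold, or
#' founds a new OTU (`denovo1`, `denovo2`, ...) with itself as centroid.
#' Centroids are never recomputed as members join.
#'
#' @param reads a tibble with columns `id` and `bases` (primer- and
#'   barcode-trimmed).
#' @param refdb a refdb tibble (see [generate_reference_db()]).
#' @param threshold identity threshold in percent (default 97).
#' @param scoring an [align_scoring()] object.
#' @return A tibble of OTUs: `otu_id`, `origin` (`closed`/`denovo`),
#'   `representative` (centroid sequence), `members` (list-column of read
#'   ids), `n_reads`, `chimera_flag` (all `FALSE`; see [flag_bimeras()]).
#' @export
pick_otus_open_reference <- function(reads, refdb, threshold = 97,
                                     scoring = align_scoring()) {
  if (nrow(reads) == 0L) {
    return(tibble(otu_id = character(), origin = character(),
                  representative = character(), members = list(),
                  n_reads = integer(), chimera_flag = logical()))
  }
  derep <- reads |>
    group_by(bases = .data$bases) |>
    summarise(member_ids = list(sort(.data$id)), n = n(), .groups = "drop") |>
    mutate(first_id = map_chr(.data$member_ids, 1L))

  ref_seqs <- refdb$v1v2
  closed_assign <- map_chr(derep$bases, function(s) {
    ids <- percent_identity_many(s, ref_seqs, scoring)
    ok <- which(ids >= threshold)
    if (length(ok) == 0L) return(NA_character_)
    best <- ok[order(-ids[ok], refdb$id[ok])][1L]
    refdb$id[best]
  })

  otus <- list()
  # closed-reference OTUs: representative is the reference window itself
  for (rid in sort(unique(stats::na.omit(closed_assign)))) {
    rows <- which(!is.na(closed_assign) & closed_assign == rid)
    otus[[rid]] <- tibble(
      otu_id = rid, origin = "closed",
      representative = refdb$v1v2[refdb$id == rid],
      members = list(sort(unlist(derep$member_ids[rows]))),
      n_reads = sum(derep$n[rows])
    )
  }

  denovo <- derep[is.na(closed_assign), ]
  if (nrow(denovo) > 0) {
    denovo <- denovo[order(-denovo$n, -nchar(denovo$bases),
                           denovo$first_id), ]
    centroids <- character(0)
    cent_members <- list()
    cent_counts <- integer(0)
    for (i in seq_len(nrow(denovo))) {
      s <- denovo$bases[i]
      joined <- FALSE
      if (length(centroids) > 0) {
        ids <- percent_identity_many(s, centroids, scoring)
        hit <- which(ids >= threshold)
        if (length(hit) > 0) {
          j <- hit[1L]  # first (oldest) matching centroid
          cent_members[[j]] <- c(cent_members[[j]], denovo$member_ids[[i]])
          cent_counts[j] <- cent_counts[j] + denovo$n[i]
          joined <- TRUE
        }
      }
      if (!joined) {
        centroids <- c(centroids, s)
        cent_members <- c(cent_members, list(denovo$member_ids[[i]]))
        cent_counts <- c(cent_counts, denovo$n[i])
      }
    }
    for (j in seq_along(centroids)) {
      oid <- sprintf("denovo%d", j)
      otus[[oid]] <- tibble(
        otu_id = oid, origin = "denovo", representative = centroids[j],
        members = list(sort(cent_members[[j]])), n_reads = cent_counts[j]
      )
    }
  }
  bind_rows(otus) |> mutate(chimera_flag = FALSE)
}

#' Taxonomy truncation bands
#'
#' Identity of a de novo representative to its best reference determines how
#' deep the transferred lineage may go: >=97 keeps the full (species-level)
#' lineage, >=95 genus, >=90 family, >=85 order, >=80 class and phylum,
#' below 80 the OTU is `Unassigned`. The 95 and 89-ish anchors correspond to
#' the conventional genus- and order-level novelty bands for 16S fragments.
#'
#' @param species,genus,family,order,class identity lower bounds.
#' @return Named numeric vector of band bounds.
#' @export
taxonomy_bands <- function(species = 97, genus = 95, family = 90,
                           order = 85, class = 80) {
  c(species = species, genus = genus, family = family, order = order,
    class = class)
}

truncate_lineage <- function(lineage, identity, bands) {
  # lineage has 6 ranks: phylum;class;order;family;genus;species
  n_keep <- if (identity >= bands[["species"]]) 6L
  else if (identity >= bands[["genus"]]) 5L
  else if (identity >= bands[["family"]]) 4L
  else if (identity >= bands[["order"]]) 3L
  else if (identity >= bands[["class"]]) 2L
  else 0L
  if (n_keep == 0L) return("Unassigned")
  paste(head(strsplit(lineage, ";")[[1]], n_keep), collapse = ";")
}

#' Assign taxonomy to OTUs
#'
#' Closed-reference OTUs inherit the full lineage of their reference; de
#' novo OTUs take the lineage of their best reference hit truncated to the
#' rank supported by the identity (see [taxonomy_bands()]), or `Unassigned`.
#'
#' @param otus an OTU tibble from [pick_otus_open_reference()].
#' @param refdb a refdb tibble.
#' @param bands a [taxonomy_bands()] vector.
#' @param scoring an [align_scoring()] object.
#' @return `otus` with columns `taxonomy`, `closest_ref`, `ref_identity`.
#' @export
assign_taxonomy <- function(otus, refdb, bands = taxonomy_bands(),
                            scoring = align_scoring()) {
  if (nrow(otus) == 0L) {
    return(otus |> mutate(taxonomy = character(0),
                          closest_ref = character(0),
                          ref_identity = numeric(0)))
  }
  res <- map(seq_len(nrow(otus)), function(i) {
    if (otus$origin[i] == "closed") {
      ref <- refdb[refdb$id == otus$otu_id[i], ]
      return(list(tax = ref$lineage, ref = ref$id, ident = 100))
    }
    ids <- percent_identity_many(otus$representative[i], refdb$v1v2, scoring)
    best <- order(-ids, refdb$id)[1L]
    list(tax = truncate_lineage(refdb$lineage[best], ids[best], bands),
         ref = refdb$id[best], ident = ids[best])
  })
  otus |>
    mutate(taxonomy = map_chr(res, "tax"),
           closest_ref = map_chr(res, "ref"),
           ref_identity = map_dbl(res, "ident"))
}

#' Parameters for the simplified bimera screen
#'
#' @param segment_identity minimum identity of each segment to its parent.
#' @param margin how much (percentage points) the two-parent model must beat
#'   the best single-parent identity.
#' @param min_segment minimum segment length considered.
#' @param step crossover-point step size in bases.
#' @return A list of class `cs_bimera_params`.
#' @export
bimera_params <- function(segment_identity = 99, margin = 2,
                          min_segment = 40L, step = 10L) {
  structure(list(segment_identity = segment_identity, margin = margin,
                 min_segment = as.integer(min_segment),
                 step = as.integer(step)),
            class = "cs_bimera_params")
}

#' Flag likely two-parent chimeras (simplified screen, off by default)
#'
#' A deliberately simple single-crossover bimera test: an OTU representative
#' is flagged if some split point yields a prefix and a suffix that each
#' match a (different) parent at `segment_identity` or better, and the
#' length-weighted combined identity beats the best single-parent identity
#' by at least `margin` points. This is a documented simplification of
#' profile-based chimera detection tools and ships disabled; results are
#' invariant to the order in which parents are supplied.
#'
#' @param otus an OTU tibble.
#' @param refdb optional refdb whose V1-V2 windows join the parent pool.
#' @param params a [bimera_params()] object.
#' @param scoring an [align_scoring()] object.
#' @return `otus` with `chimera_flag` updated.
#' @export
flag_bimeras <- function(otus, refdb = NULL, params = bimera_params(),
                         scoring = align_scoring()) {
  parents <- tibble(id = otus$otu_id, seq = otus$representative)
  if (!is.null(refdb)) {
    parents <- bind_rows(parents, tibble(id = refdb$id, seq = refdb$v1v2))
  }
  parents <- parents |> distinct(.data$id, .keep_all = TRUE)
  if (nrow(parents) < 2L) return(otus)
  out <- otus
  for (i in seq_len(nrow(otus))) {
    q <- otus$representative[i]
    pool <- parents |> filter(.data$seq != q)
    if (nrow(pool) < 2L) next
    full_ids <- percent_identity_many(q, pool$seq, scoring)
    best_single <- max(full_ids)
    if (best_single >= 100) next
    len <- nchar(q)
    splits <- seq(params$min_segment, len - params$min_segment,
                  by = params$step)
    flagged <- FALSE
    for (x in splits) {
      pre <- substr(q, 1L, x)
      suf <- substr(q, x + 1L, len)
      pre_ids <- percent_identity_many(pre, pool$seq, scoring)
      suf_ids <- percent_identity_many(suf, pool$seq, scoring)
      bp <- which.max(pre_ids)
      bs <- which.max(suf_ids)
      if (bp == bs) {
        # best parents coincide: take the better cross combination
        alt_p <- order(-pre_ids)[2L]
        alt_s <- order(-suf_ids)[2L]
        comb1 <- c(pre_ids[bp], suf_ids[alt_s])
        comb2 <- c(pre_ids[alt_p], suf_ids[bs])
        seg <- if (min(comb1) >= min(comb2)) comb1 else comb2
      } else {
        seg <- c(pre_ids[bp], suf_ids[bs])
      }
      combined <- (x * seg[1L] + (len - x) * seg[2L]) / len
      if (all(seg >= params$segment_identity) &&
          combined >= best_single + params$margin) {
        flagged <- TRUE
        break
      }
    }
    out$chimera_flag[i] <- flagged
  }
  out
}

#' Build the samples-by-OTU count table
#'
#' @param otus an OTU tibble.
#' @param read_map tibble `read_id`, `sample_id` mapping every member read
#'   to its sample (e.g. the clean reads from [filter_library()]).
#' @param drop_flagged drop OTUs with `chimera_flag` (default `TRUE`).
#' @return A long count tibble `sample_id`, `otu_id`, `count` (only
#'   non-zero cells, so no all-zero OTU columns exist).
#' @export
build_otu_table <- function(otus, read_map, drop_flagged = TRUE) {
  kept <- if (drop_flagged) otus |> filter(!.data$chimera_flag) else otus
  if (nrow(kept) == 0L) {
    return(tibble(sample_id = character(), otu_id = character(),
                  count = integer()))
  }
  membership <- kept |>
    select("otu_id", "members") |>
    tidyr::unnest_longer("members", values_to = "read_id")
  unmapped <- setdiff(membership$read_id, read_map$read_id)
  if (length(unmapped) > 0) {
    abort(paste0("member read(s) not in read_map: ",
                 paste(head(unmapped, 5L), collapse = ", "),
                 if (length(unmapped) > 5L) " ..."))
  }
  membership |>
    left_join(read_map[, c("read_id", "sample_id")], by = "read_id") |>
    count(.data$sample_id, .data$otu_id, name = "count") |>
    arrange(.data$sample_id, .data$otu_id)
}

#' Write an OTU table as wide TSV
#'
#' @param counts a long count tibble from [build_otu_table()].
#' @param path output TSV (samples in rows, OTUs in columns).
#' @export
write_otu_table <- function(counts, path) {
  wide <- counts |>
    tidyr::pivot_wider(names_from = "otu_id", values_from = "count",
                       values_fill = 0L) |>
    arrange(.data$sample_id)
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read a wide-TSV OTU table back to long form
#' @param path TSV written by [write_otu_table()].
#' @return A long count tibble.
#' @export
read_otu_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", .default = "i"
  )) |>
    tidyr::pivot_longer(-"sample_id", names_to = "otu_id",
                        values_to = "count") |>
    filter(.data$count > 0) |>
    arrange(.data$sample_id, .data$otu_id)
}

#' Export an OTU table as BIOM
#'
#' Uses the biomformat package when available.
#'
#' @param counts a long count tibble.
#' @param path output `.biom` path.
#' @export
write_otu_biom <- function(counts, path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("write_otu_biom() requires the biomformat package")
  }
  mat <- counts |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                       values_fill = 0L)
  m <- as.matrix(mat[, -1, drop = FALSE])
  rownames(m) <- mat$otu_id
  biomformat::write_biom(biomformat::make_biom(m), path)
  invisible(path)
}
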