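MANIFEST_COLS <- c("sample_id", "fwd_barcode", "rev_barcode", "fwd_primer",
                   "rev_primer", "sponge", "medium", "surface", "day",
                   "colonies", "role", "plate_group")

check_manifest <- function(manifest) {
  missing <- setdiff(MANIFEST_COLS, names(manifest))
  if (length(missing) > 0) {
    abort(paste0("manifest lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(manifest$sample_id)) {
    abort("manifest sample ids must be unique")
  }
  if (length(unique(nchar(manifest$fwd_barcode))) > 1L) {
    abort("forward barcodes must have a single fixed length")
  }
  # a forward barcode identifies exactly one demultiplexing group
  bad <- manifest |>
    distinct(.data$fwd_barcode, .data$plate_group) |>
    count(.data$fwd_barcode) |>
    filter(.data$n > 1L)
  if (nrow(bad) > 0) {
    abort(paste0("forward barcode maps to multiple plate groups: ",
                 paste(bad$fwd_barcode, collapse = ", ")))
  }
  pairs <- paste(manifest$fwd_barcode, manifest$rev_barcode)
  dup <- duplicated(pairs) & !is.na(manifest$rev_barcode)
  if (any(dup)) {
    abort(paste0("duplicate forward/reverse barcode pair for: ",
                 paste(manifest$sample_id[dup], collapse = ", ")))
  }
  invisible(manifest)
}

#' Read / write a sample-and-colony manifest
#'
#' The manifest is a TSV with one row per sample or picked colony:
#' `sample_id`, `fwd_barcode`, `rev_barcode` (empty for single-barcoded
#' samples), `fwd_primer`, `rev_primer`, `sponge`, `medium`,
#' `surface` (`agar` or `filter`), `day`, `colonies` (visible colony count,
#' empty where not applicable), `role` (`inoculum`, `scraped` or `colony`)
#' and `plate_group` (the forward-barcode-level demultiplexing group; equal
#' to `sample_id` for single-barcoded samples).
#'
#' @param path TSV path.
#' @return A manifest tibble.
#' @export
read_manifest <- function(path) {
  man <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", fwd_barcode = "c", rev_barcode = "c", fwd_primer = "c",
    rev_primer = "c", sponge = "c", medium = "c", surface = "c", day = "i",
    colonies = "i", role = "c", plate_group = "c"
  ))
  check_manifest(man)
}

#' @rdname read_manifest
#' @param manifest a manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  check_manifest(manifest)
  readr::write_tsv(manifest, path)
  invisible(path)
}

#' Quality-filter parameters
#'
#' Defaults are the retention rules of the assay: reads are kept only if the
#' average Phred quality is strictly greater than 25, no homopolymer run
#' exceeds 6 bases, the post-trim length is at least 200 bp, and the 5'
#' primer carries zero mismatches.
#'
#' @param min_mean_quality exclusive lower bound on mean Phred score.
#' @param max_homopolymer maximum allowed single-base run length.
#' @param min_length minimum post-trim read length (inclusive).
#' @param max_primer_mismatches maximum allowed 5'-primer mismatches.
#' @return A list of class `cs_filter_params`.
#' @export
filter_params <- function(min_mean_quality = 25, max_homopolymer = 6L,
                          min_length = 200L, max_primer_mismatches = 0L) {
  if (min_mean_quality < 0 || max_homopolymer < 0 || min_length < 0 ||
      max_primer_mismatches < 0) {
    abort("filter parameters must be non-negative")
  }
  structure(list(min_mean_quality = min_mean_quality,
                 max_homopolymer = as.integer(max_homopolymer),
                 min_length = as.integer(min_length),
                 max_primer_mismatches = as.integer(max_primer_mismatches)),
            class = "cs_filter_params")
}

#' Demultiplex reads by forward barcode
#'
#' Matches the barcode field exactly at its expected offset (immediately
#' after the adaptor); there is no error correction, so a read with any
#' substitution inside the barcode goes to the unassigned bin. Adaptor and
#' barcode are trimmed from assigned reads.
#'
#' @param reads a sequence tibble.
#' @param manifest a manifest tibble.
#' @param adaptor the 5' adaptor preceding the barcode.
#' @return The reads tibble with barcode/adaptor trimmed for assigned reads
#'   and a `plate_group` column (`NA` = unassigned).
#' @export
demultiplex_forward <- function(reads, manifest, adaptor = DEFAULT_ADAPTOR) {
  check_manifest(manifest)
  if (nrow(reads) == 0L) {
    reads$plate_group <- character(0)
    return(reads)
  }
  bc_len <- nchar(manifest$fwd_barcode[1L])
  off <- nchar(adaptor)
  lookup <- manifest |>
    distinct(.data$fwd_barcode, .data$plate_group)
  observed <- substr(reads$bases, off + 1L, off + bc_len)
  idx <- match(observed, lookup$fwd_barcode)
  group <- lookup$plate_group[idx]
  assigned <- !is.na(group)
  out <- reads
  out$plate_group <- group
  out$bases[assigned] <- substr(out$bases[assigned], off + bc_len + 1L,
                                nchar(out$bases[assigned]))
  if (!is.null(out$quality)) {
    out$quality[assigned] <- map(out$quality[assigned],
                                 function(q) q[-seq_len(off + bc_len)])
  }
  out
}

#' Demultiplex colony reads by reverse barcode
#'
#' For double-barcoded (colony) plate groups, reads that run through the
#' reverse primer end in the reverse complement of the reverse barcode. The
#' barcode is matched exactly at the 3' end and trimmed; reads whose
#' terminal bases match no reverse barcode of their plate group stay
#' unassigned.
#'
#' @param reads a forward-demultiplexed sequence tibble (with `plate_group`).
#' @param manifest a manifest tibble.
#' @return The reads tibble with a `sample_id` column (`NA` = unassigned;
#'   single-barcoded groups keep their plate-group sample id) and reverse
#'   barcodes trimmed.
#' @export
demultiplex_reverse <- function(reads, manifest) {
  check_manifest(manifest)
  out <- reads
  out$sample_id <- NA_character_
  if (nrow(out) == 0L) return(out)
  for (grp in unique(stats::na.omit(reads$plate_group))) {
    rows <- which(reads$plate_group == grp)
    man <- manifest[manifest$plate_group == grp, ]
    if (all(is.na(man$rev_barcode) | !nzchar(man$rev_barcode))) {
      # single-barcoded group: the plate group is the sample
      out$sample_id[rows] <- man$sample_id[1L]
      next
    }
    bc_len <- nchar(man$rev_barcode[1L])
    tail_obs <- substr(out$bases[rows],
                       nchar(out$bases[rows]) - bc_len + 1L,
                       nchar(out$bases[rows]))
    idx <- match(tail_obs, revcomp(man$rev_barcode))
    hit <- !is.na(idx)
    out$sample_id[rows[hit]] <- man$sample_id[idx[hit]]
    trim_rows <- rows[hit]
    out$bases[trim_rows] <- substr(out$bases[trim_rows], 1L,
                                   nchar(out$bases[trim_rows]) - bc_len)
    if (!is.null(out$quality)) {
      out$quality[trim_rows] <- map(out$quality[trim_rows],
                                    function(q) q[seq_len(length(q) - bc_len)])
    }
  }
  out
}

max_homopolymer_run <- function(bases) {
  # longest single-base run, N runs included
  vapply(bases, function(b) {
    if (!nzchar(b)) return(0L)
    max(rle(strsplit(b, "")[[1]])$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

#' Apply the read-retention rules
#'
#' Each read (already barcode-trimmed) is checked against the four retention
#' rules in a fixed order - mean quality, homopolymer, length, primer - and
#' the first failing rule is reported as the failure reason. The mean Phred
#' score is computed over the post-trim biological sequence (primer removed,
#' and the reverse primer trimmed from the 3' end when present); the
#' homopolymer rule also applies to the post-trim sequence.
#'
#' @param reads a sequence tibble with qualities.
#' @param params a [filter_params()] object.
#' @param primer the forward primer (may contain IUPAC codes).
#' @param rev_primer optional reverse primer; if its reverse complement is
#'   found at the 3' end it is trimmed before the rules are evaluated.
#' @return The reads tibble, trimmed, with columns `pass` (logical),
#'   `reason` (`NA`, `"quality"`, `"homopolymer"`, `"length"` or
#'   `"primer"`), `mean_quality` and `primer_mismatches`.
#' @export
quality_filter <- function(reads, params = filter_params(), primer,
                           rev_primer = NULL) {
  if (nrow(reads) > 0 && !"quality" %in% names(reads)) {
    abort("quality_filter() requires per-base qualities")
  }
  p_len <- nchar(primer)
  out <- reads
  n <- nrow(out)
  if (n == 0L) {
    out$pass <- logical(0)
    out$reason <- character(0)
    out$mean_quality <- numeric(0)
    out$primer_mismatches <- integer(0)
    return(out)
  }
  prefix <- substr(out$bases, 1L, p_len)
  mism <- map_int(prefix, function(w) {
    if (nchar(w) < p_len) return(p_len)  # read too short to contain primer
    iupac_mismatches(primer, w)
  })
  # trim forward primer
  if (p_len > 0L) {
    out$bases <- substr(out$bases, p_len + 1L, nchar(out$bases))
    out$quality <- map(out$quality, function(q) {
      q[-seq_len(min(p_len, length(q)))]
    })
  }
  # trim reverse primer (reverse complement) from the 3' end when present
  if (!is.null(rev_primer) && nzchar(rev_primer)) {
    rc <- revcomp(rev_primer)
    r_len <- nchar(rc)
    tail_obs <- substr(out$bases, pmax(nchar(out$bases) - r_len + 1L, 1L),
                       nchar(out$bases))
    has_rev <- nchar(out$bases) >= r_len &
      map_int(tail_obs, function(w) {
        if (nchar(w) < r_len) return(1L)
        iupac_mismatches(rev_primer, revcomp(w))
      }) == 0L
    out$bases[has_rev] <- substr(out$bases[has_rev], 1L,
                                 nchar(out$bases[has_rev]) - r_len)
    out$quality[has_rev] <- map(out$quality[has_rev], function(q) {
      q[seq_len(length(q) - r_len)]
    })
  }
  mean_q <- map_dbl(out$quality, function(q) {
    if (length(q) == 0L) return(0)
    mean(q)
  })
  run_len <- max_homopolymer_run(out$bases)
  len <- nchar(out$bases)
  reason <- rep(NA_character_, n)
  reason[is.na(reason) & !(mean_q > params$min_mean_quality)] <- "quality"
  reason[is.na(reason) & run_len > params$max_homopolymer] <- "homopolymer"
  reason[is.na(reason) & len < params$min_length] <- "length"
  reason[is.na(reason) & mism > params$max_primer_mismatches] <- "primer"
  out$pass <- is.na(reason)
  out$reason <- reason
  out$mean_quality <- mean_q
  out$primer_mismatches <- mism
  out
}

#' Demultiplex and filter a whole library
#'
#' Composes [demultiplex_forward()], [demultiplex_reverse()] and
#' [quality_filter()] (using each sample's own primers) into one
#' deterministic pass. Reads failing to demultiplex are reported with reason
#' `"barcode_unknown"`.
#'
#' @param reads a sequence tibble of raw reads.
#' @param manifest a manifest tibble.
#' @param params a [filter_params()] object.
#' @param adaptor the 5' adaptor.
#' @return A list of class `cs_filter_result`: `reads` (clean, trimmed reads
#'   with `sample_id`), `report` (per-read tibble `read_id`, `sample_id`,
#'   `retained`, `reason`) and `per_sample` (retained/failed counts).
#' @export
filter_library <- function(reads, manifest, params = filter_params(),
                           adaptor = DEFAULT_ADAPTOR) {
  fwd <- demultiplex_forward(reads, manifest, adaptor)
  both <- demultiplex_reverse(fwd, manifest)
  assigned <- both |> filter(!is.na(.data$sample_id))
  unassigned <- both |> filter(is.na(.data$sample_id))
  pieces <- list()
  for (s in unique(assigned$sample_id)) {
    man <- manifest[manifest$sample_id == s, ]
    sub <- assigned |> filter(.data$sample_id == s)
    pieces[[s]] <- quality_filter(sub, params, man$fwd_primer,
                                  man$rev_primer)
  }
  filtered <- bind_rows(pieces)
  report <- bind_rows(
    if (nrow(filtered) > 0) {
      filtered |>
        transmute(read_id = .data$id, sample_id = .data$sample_id,
                  retained = .data$pass, reason = .data$reason)
    },
    if (nrow(unassigned) > 0) {
      unassigned |>
        transmute(read_id = .data$id, sample_id = NA_character_,
                  retained = FALSE, reason = "barcode_unknown")
    }
  )
  clean <- filtered |>
    filter(.data$pass) |>
    select("id", "bases", "quality", "sample_id")
  per_sample <- report |>
    group_by(sample_id = ifelse(is.na(.data$sample_id), "<unassigned>",
                                .data$sample_id)) |>
    summarise(input = n(), n_retained = sum(.data$retained),
              n_failed = .data$input - .data$n_retained, .groups = "drop")
  structure(list(reads = clean, report = report, per_sample = per_sample),
            class = "cs_filter_result")
}

#' @export
print.cs_filter_result <- function(x, ...) {
  cat(sprintf("<cs_filter_result> %d reads in, %d retained (%.1f%%)\n",
              nrow(x$report), nrow(x$reads),
              if (nrow(x$report) > 0) 100 * nrow(x$reads) / nrow(x$report)
              else 0))
  print(x$per_sample, n = 10)
  invisible(x)
}
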