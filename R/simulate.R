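#' Generate a synthetic type-strain reference database
#'
#' Produces full-length (~1500 bp) 16S-like reference sequences with a
#' designated ~311 bp V1-V2 window and a fabricated six-rank taxonomy. The
#' sequences are random with constrained composition (45-55% GC) rather than
#' real 16S genes, which keeps the package free of downloads; any function
#' that takes a `refdb` also accepts one built from a real reference FASTA
#' plus taxonomy table via [refdb_from_files()]. Generated type strains are
#' mutually < 90% identical in the V1-V2 window so that distinct taxa cannot
#' collapse into one 97% OTU.
#'
#' @param n_types number of type strains (>= 1).
#' @param seed integer seed; the output is byte-reproducible given the seed.
#' @param full_length total reference length.
#' @param v_start,v_len 0-based start and length of the V1-V2 window.
#' @param max_window_identity upper bound (exclusive) on pairwise V1-V2
#'   identity between type strains.
#' @return A tibble with columns `id`, `bases` (full length), `v1v2` (the
#'   window) and `lineage` (six semicolon-separated ranks).
#' @export
generate_reference_db <- function(n_types, seed, full_length = 1500L,
                                  v_start = 28L, v_len = 311L,
                                  max_window_identity = 90) {
  if (n_types < 1L) abort("`n_types` must be >= 1")
  with_seed(seed, {
    ids <- sprintf("TS%04d", seq_len(n_types))
    seqs <- character(n_types)
    windows <- character(n_types)
    for (i in seq_len(n_types)) {
      for (attempt in 1:50) {
        gc <- stats::runif(1, 0.45, 0.55)
        s <- random_dna(full_length, gc)
        w <- substr(s, v_start + 1L, v_start + v_len)
        if (max_homopolymer_run(w) <= 6L &&
            (i == 1L ||
             all(percent_identity_many(w, windows[seq_len(i - 1L)]) <
                 max_window_identity))) {
          seqs[i] <- s
          windows[i] <- w
          break
        }
      }
      if (!nzchar(seqs[i])) {
        abort("could not generate mutually divergent reference sequences")
      }
    }
    n_phyla <- max(2L, ceiling(n_types / 5))
    phylum <- sprintf("Phylum%02d", 1L + (seq_len(n_types) - 1L) %% n_phyla)
    lineage <- paste(
      phylum,
      sprintf("Class%02d", 1L + (seq_len(n_types) - 1L) %% (n_phyla * 2L)),
      sprintf("Order%03d", 1L + (seq_len(n_types) - 1L) %/% 3L),
      sprintf("Family%03d", 1L + (seq_len(n_types) - 1L) %/% 2L),
      sprintf("Genus%04d", seq_len(n_types)),
      sprintf("Genus%04d species%d", seq_len(n_types), seq_len(n_types)),
      sep = ";"
    )
    tibble(id = ids, bases = seqs, v1v2 = windows, lineage = lineage)
  })
}

#' Build a reference database from files
#'
#' Hook for using a real type-strain reference instead of the synthetic one:
#' a FASTA of (near) full-length 16S sequences and a two-column TSV
#' (`id`, `lineage`) of six-rank taxonomies.
#'
#' @param fasta_path reference FASTA.
#' @param taxonomy_path TSV with columns `id` and `lineage`.
#' @param v_start,v_len 0-based start and length of the amplified window.
#' @return A refdb tibble as from [generate_reference_db()].
#' @export
refdb_from_files <- function(fasta_path, taxonomy_path, v_start = 28L,
                             v_len = 311L) {
  seqs <- read_fasta(fasta_path)
  tax <- readr::read_tsv(taxonomy_path, col_types = "cc")
  missing <- setdiff(seqs$id, tax$id)
  if (length(missing) > 0) {
    abort(paste0("no taxonomy entry for: ", paste(missing, collapse = ", ")))
  }
  seqs |>
    mutate(v1v2 = substr(.data$bases, v_start + 1L, v_start + .env$v_len)) |>
    left_join(tax, by = "id")
}

#' Write the reference database to FASTA + taxonomy TSV
#' @param refdb a refdb tibble.
#' @param fasta_path,taxonomy_path output paths.
#' @export
write_refdb <- function(refdb, fasta_path, taxonomy_path) {
  write_fasta(refdb, fasta_path)
  readr::write_tsv(refdb[, c("id", "lineage")], taxonomy_path)
  invisible(fasta_path)
}

#' Mutate a sequence to a target percent divergence
#'
#' Plants substitutions (no indels) in the V1-V2 window until the measured
#' [percent_identity()] to the parent is within +/- 0.5 percentage points of
#' `100 - target_percent`. Used to create "novel" community members whose
#' distance to the closest type strain is known by construction, e.g. an
#' 18-point divergence emulating a deeply novel actinobacterium at ~82%
#' identity.
#'
#' @param parent a single-row refdb/sequence tibble (columns `id`, `bases`,
#'   optionally `v1v2`).
#' @param target_percent target divergence in \[0, 25\] percentage points.
#' @param seed integer seed.
#' @param tolerance acceptance half-width in percentage points.
#' @return A single-row tibble like `parent` with mutated `bases`/`v1v2` and
#'   id `<parent>_dNN`.
#' @export
mutate_to_divergence <- function(parent, target_percent, seed,
                                 tolerance = 0.5) {
  if (target_percent < 0 || target_percent > 25) {
    abort("`target_percent` must be in [0, 25]")
  }
  has_window <- !is.null(parent$v1v2)
  window <- if (has_window) parent$v1v2 else parent$bases
  len <- nchar(window)
  child_id <- sprintf("%s_d%02d", parent$id, round(target_percent))
  if (target_percent == 0) {
    out <- parent
    out$id <- child_id
    return(out)
  }
  with_seed(seed, {
    chars <- strsplit(window, "")[[1]]
    n_sub <- round(target_percent / 100 * len)
    if (n_sub >= len) abort("target divergence unreachable at this length")
    pos_order <- sample(len)
    mutated <- chars
    used <- 0L
    apply_subs <- function(k) {
      m <- chars
      for (p in pos_order[seq_len(k)]) {
        m[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
      }
      m
    }
    mutated <- apply_subs(n_sub)
    ident <- percent_identity(paste(mutated, collapse = ""), window)
    # the optimal alignment can recover slightly more identity than the
    # substitution count implies; top up deterministically if needed
    k <- n_sub
    while (ident > 100 - target_percent + tolerance && k < len - 1L) {
      k <- k + 1L
      mutated <- apply_subs(k)
      ident <- percent_identity(paste(mutated, collapse = ""), window)
    }
    while (ident < 100 - target_percent - tolerance && k > 1L) {
      k <- k - 1L
      mutated <- apply_subs(k)
      ident <- percent_identity(paste(mutated, collapse = ""), window)
    }
    if (abs(ident - (100 - target_percent)) > tolerance) {
      abort(sprintf("could not reach %.1f%% divergence (achieved %.2f%%)",
                    target_percent, 100 - ident))
    }
    new_window <- paste(mutated, collapse = "")
    # substitutions must not create a filter-violating homopolymer run
    if (max_homopolymer_run(new_window) > 6L) {
      return(mutate_to_divergence(parent, target_percent,
                                  seed = derive_seed(seed, 777L),
                                  tolerance = tolerance))
    }
    out <- parent
    out$id <- child_id
    if (has_window) {
      out$v1v2 <- new_window
      out$bases <- sub(window, new_window, parent$bases, fixed = TRUE)
    } else {
      out$bases <- new_window
    }
    out
  })
}

#' Simulate a community profile
#'
#' Draws log-normal relative abundances over a subset of reference taxa and
#' optionally plants novel members at controlled divergence from designated
#' parent type strains (via [mutate_to_divergence()]). Log-normal abundance
#' distributions are the standard model for rank-abundance structure in
#' microbial communities.
#'
#' @param refdb a refdb tibble.
#' @param n_taxa number of reference taxa to include.
#' @param meanlog,sdlog log-normal parameters for abundance draws.
#' @param novel_spec optional tibble with columns `parent_id` and
#'   `target_percent`: one planted novel member per row.
#' @param novel_prefix prefix for planted-member ids, so that novel taxa
#'   planted independently in several communities (possibly from the same
#'   parent, at the same divergence, but with different realized sequences)
#'   stay distinct.
#' @param seed integer seed.
#' @return A community profile tibble: `taxon_id`, `abundance` (sums to 1),
#'   `template` (V1-V2 sequence), `is_novel`, `parent_id`, `divergence`.
#' @export
simulate_community <- function(refdb, n_taxa, meanlog = 0, sdlog = 1,
                               novel_spec = NULL, novel_prefix = "",
                               seed = 1L) {
  if (n_taxa > nrow(refdb)) abort("`n_taxa` exceeds available taxa")
  with_seed(seed, {
    picked <- refdb[sort(sample(nrow(refdb), n_taxa)), ]
    prof <- tibble(
      taxon_id = picked$id,
      template = picked$v1v2,
      is_novel = FALSE,
      parent_id = NA_character_,
      divergence = 0
    )
    if (!is.null(novel_spec) && nrow(novel_spec) > 0) {
      for (i in seq_len(nrow(novel_spec))) {
        parent <- refdb[refdb$id == novel_spec$parent_id[i], ]
        if (nrow(parent) != 1L) {
          abort(paste0("unknown novel parent: ", novel_spec$parent_id[i]))
        }
        child <- mutate_to_divergence(parent, novel_spec$target_percent[i],
                                      seed = derive_seed(seed, i))
        prof <- bind_rows(prof, tibble(
          taxon_id = paste0(novel_prefix, child$id), template = child$v1v2,
          is_novel = TRUE,
          parent_id = parent$id, divergence = novel_spec$target_percent[i]
        ))
      }
    }
    ab <- rlnorm(nrow(prof), meanlog, sdlog)
    prof$abundance <- ab / sum(ab)
    prof[, c("taxon_id", "abundance", "template", "is_novel", "parent_id",
             "divergence")]
  })
}

#' Plating scenario parameters
#'
#' Describes what happens when an inoculum community is plated: per-taxon
#' colony-forming probabilities, overgrowth by one designated fast grower
#' (the "Pseudovibrio-like" behaviour: a taxon that may be undetectable in
#' the inoculum yet dominates plates), carry-over of non-growing inoculum
#' cells into the scraped biomass, and the visible colony count.
#'
#' @param growth_prob named numeric vector: probability that a cell of each
#'   taxon forms a colony (taxa missing from the vector default to
#'   `default_growth_prob`).
#' @param default_growth_prob fallback colony-forming probability.
#' @param dominant_taxon optional id of the designated fast grower.
#' @param dominance_factor multiplier (>= 1) on the fast grower's colony
#'   weight.
#' @param spike optional tibble (`taxon_id`, `template`, `colony_weight`)
#'   of taxa absent from the inoculum but growing on plates.
#' @param carryover_reads_fraction fraction of scraped-sample reads drawn
#'   from the inoculum profile rather than from colonies, in \[0, 1\].
#' @param n_visible_colonies visible colony count of the scraped community.
#' @param pick_cap per-plate cap on picked colonies of one taxon (the field
#'   convention of picking at most a few colonies of the same morphology).
#' @return A list of class `cs_plating_scenario`.
#' @export
plating_scenario <- function(growth_prob = numeric(), default_growth_prob = 1,
                             dominant_taxon = NULL, dominance_factor = 1,
                             spike = NULL, carryover_reads_fraction = 0,
                             n_visible_colonies = 100L, pick_cap = 3L) {
  if (any(growth_prob < 0 | growth_prob > 1)) {
    abort("growth probabilities must be in [0, 1]")
  }
  if (carryover_reads_fraction < 0 || carryover_reads_fraction > 1) {
    abort("`carryover_reads_fraction` must be in [0, 1]")
  }
  structure(
    list(growth_prob = growth_prob,
         default_growth_prob = default_growth_prob,
         dominant_taxon = dominant_taxon,
         dominance_factor = dominance_factor,
         spike = spike,
         carryover_reads_fraction = carryover_reads_fraction,
         n_visible_colonies = as.integer(n_visible_colonies),
         pick_cap = as.integer(pick_cap)),
    class = "cs_plating_scenario"
  )
}

scenario_growth_prob <- function(scenario, taxa) {
  p <- rep(scenario$default_growth_prob, length(taxa))
  names(p) <- taxa
  known <- intersect(taxa, names(scenario$growth_prob))
  p[known] <- scenario$growth_prob[known]
  p
}

colony_weights <- function(profile, scenario) {
  p <- scenario_growth_prob(scenario, profile$taxon_id)
  w <- profile$abundance * p
  if (!is.null(scenario$dominant_taxon)) {
    idx <- profile$taxon_id == scenario$dominant_taxon
    w[idx] <- w[idx] * scenario$dominance_factor
  }
  out <- tibble(taxon_id = profile$taxon_id, template = profile$template,
                weight = w)
  if (!is.null(scenario$spike) && nrow(scenario$spike) > 0) {
    out <- bind_rows(out, tibble(taxon_id = scenario$spike$taxon_id,
                                 template = scenario$spike$template,
                                 weight = scenario$spike$colony_weight))
  }
  out
}

#' Simulate plate scraping
#'
#' The scraped community is a mixture: `(1 - carryover)` parts colony-derived
#' biomass (inoculum abundance weighted by colony-forming probability and
#' dominance) plus `carryover` parts unmodified inoculum (cells that never
#' grew but are still physically present on the plate). Taxa with zero
#' growth probability therefore appear in the scraped profile only through
#' carry-over, and are recorded as not-grown in the ground truth - exactly
#' the artefact the downstream growth criteria exist to reject.
#'
#' @param profile an inoculum community profile ([simulate_community()]).
#' @param scenario a [plating_scenario()].
#' @return A list with `scraped` (a community profile tibble) and `truth`
#'   (a tibble `taxon_id`, `grew`, `carryover_only`).
#' @export
simulate_plating <- function(profile, scenario) {
  cw <- colony_weights(profile, scenario)
  carry <- scenario$carryover_reads_fraction
  if (sum(cw$weight) > 0) {
    colony_mix <- cw$weight / sum(cw$weight)
  } else {
    if (carry == 0) abort("no taxon grows and carry-over is zero")
    colony_mix <- rep(0, nrow(cw))
  }
  inoc <- setNames(profile$abundance, profile$taxon_id)
  scraped_ab <- as.numeric((1 - carry) * colony_mix +
                             carry * (inoc[cw$taxon_id] %|0|% 0))
  scraped <- tibble(
    taxon_id = cw$taxon_id,
    abundance = scraped_ab / sum(scraped_ab),
    template = cw$template
  ) |> filter(.data$abundance > 0)
  truth <- tibble(
    taxon_id = cw$taxon_id,
    grew = cw$weight > 0,
    carryover_only = cw$weight == 0 & cw$taxon_id %in% profile$taxon_id
  )
  list(scraped = scraped, truth = truth)
}

`%|0|%` <- function(x, fill) {
  x[is.na(x)] <- fill
  x
}

#' Simulate colony picking
#'
#' Colonies are drawn one at a time with probability proportional to
#' growth-weighted abundance; on each plate at most `scenario$pick_cap`
#' colonies of the same taxon are picked (capped taxa are skipped, mirroring
#' the practice of not re-picking the same morphology).
#'
#' @inheritParams simulate_plating
#' @param n_colonies total number of colonies to pick.
#' @param n_plates number of plates the picks are spread over.
#' @param seed integer seed.
#' @return A tibble `colony_id`, `plate`, `taxon_id`, `template`.
#' @export
simulate_colony_pick <- function(profile, scenario, n_colonies,
                                 n_plates = 1L, seed = 1L) {
  if (n_colonies == 0L) {
    return(tibble(colony_id = character(), plate = integer(),
                  taxon_id = character(), template = character()))
  }
  cw <- colony_weights(profile, scenario)
  cw <- cw[cw$weight > 0, ]
  if (nrow(cw) == 0L) abort("no taxon can form colonies in this scenario")
  with_seed(seed, {
    per_plate <- diff(round(seq(0, n_colonies, length.out = n_plates + 1L)))
    out <- list()
    cid <- 0L
    for (pl in seq_len(n_plates)) {
      picked <- integer(nrow(cw))
      for (k in seq_len(per_plate[pl])) {
        open <- which(picked < scenario$pick_cap)
        if (length(open) == 0L) break
        i <- open[sample.int(length(open), 1L,
                             prob = cw$weight[open] / sum(cw$weight[open]))]
        picked[i] <- picked[i] + 1L
        cid <- cid + 1L
        out[[cid]] <- tibble(colony_id = sprintf("C%04d", cid),
                             plate = pl, taxon_id = cw$taxon_id[i],
                             template = cw$template[i])
      }
    }
    bind_rows(out)
  })
}

#' 454-like error model parameters
#'
#' Substitutions are uniform over the three alternative bases; homopolymer
#' runs of length >= 2 gain or lose one base with probability proportional
#' to run length (the characteristic pyrosequencing failure mode); per-base
#' qualities come from a two-state good/bad profile. The paper-scale error
#' rates of real 454 runs are not published for this assay; the defaults are
#' order-of-magnitude pyrosequencing values and are explicitly assumptions.
#'
#' @param sub_rate per-base substitution probability.
#' @param homopolymer_rate per-run per-length unit probability of a +/-1
#'   length error.
#' @param bad_frac fraction of bases drawn from the bad quality state.
#' @param q_good,q_bad central Phred values of the two states.
#' @return A list of class `cs_error_model`.
#' @export
error_model <- function(sub_rate = 0.004, homopolymer_rate = 0.002,
                        bad_frac = 0.03, q_good = 38L, q_bad = 12L) {
  structure(list(sub_rate = sub_rate, homopolymer_rate = homopolymer_rate,
                 bad_frac = bad_frac, q_good = as.integer(q_good),
                 q_bad = as.integer(q_bad)),
            class = "cs_error_model")
}

DEFAULT_ADAPTOR <- "CGTATCGCCTCCCTCGCGCCATCAG"

# realize a degenerate (IUPAC) primer into the concrete bases one synthesized
# primer molecule carries
realize_iupac <- function(s) {
  chars <- strsplit(toupper(s), "")[[1]]
  out <- vapply(chars, function(c) {
    allowed <- IUPAC_SETS[[c]]
    if (is.null(allowed)) abort(paste0("unknown IUPAC code: ", c))
    if (length(allowed) == 1L) allowed else sample(allowed, 1L)
  }, character(1))
  paste(out, collapse = "")
}

apply_substitutions <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  for (p in hit) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  list(chars = chars, n = length(hit))
}

apply_homopolymer_errors <- function(chars, rate) {
  r <- rle(chars)
  n_indels <- 0L
  if (rate > 0) {
    eligible <- which(r$lengths >= 2L)
    for (i in eligible) {
      if (stats::runif(1) < rate * r$lengths[i]) {
        r$lengths[i] <- r$lengths[i] + sample(c(-1L, 1L), 1L)
        n_indels <- n_indels + 1L
      }
    }
  }
  list(chars = inverse.rle(r), n = n_indels)
}

#' Simulate barcoded amplicon reads
#'
#' Each read is assembled as
#' `adaptor + forward barcode + forward primer + template` and, when the
#' manifest entry carries a reverse barcode (colony samples), the read runs
#' through into `revcomp(reverse primer) + revcomp(reverse barcode)`.
#' Substitution and homopolymer errors are applied to the assembled read,
#' and Phred qualities are drawn from the two-state profile. Per-read
#' provenance (sample, template taxon, error counts) is returned as ground
#' truth.
#'
#' @param templates tibble `sample_id`, `taxon_id`, `template`, `weight`:
#'   the template mixture per sample.
#' @param manifest a sample/colony manifest (see [read_manifest()]).
#' @param error_model an [error_model()].
#' @param n_reads reads per sample: a scalar or a vector named by sample id.
#' @param seed integer seed.
#' @param adaptor 5' sequencing adaptor included in raw reads.
#' @return A list with `reads` (sequence tibble with qualities) and
#'   `provenance` (tibble `read_id`, `sample_id`, `taxon_id`, `template`,
#'   `n_subs`, `n_indels`).
#' @export
simulate_reads <- function(templates, manifest,
                           error_model = culturoscope::error_model(),
                           n_reads = 100L, seed = 1L,
                           adaptor = DEFAULT_ADAPTOR) {
  check_manifest(manifest)
  samples <- unique(templates$sample_id)
  missing <- setdiff(samples, manifest$sample_id)
  if (length(missing) > 0) {
    abort(paste0("templates reference samples absent from manifest: ",
                 paste(missing, collapse = ", ")))
  }
  if (is.null(names(n_reads))) {
    n_reads <- setNames(rep(n_reads[1L], length(samples)), samples)
  }
  with_seed(seed, {
    reads <- list()
    prov <- list()
    for (s in samples) {
      man <- manifest[manifest$sample_id == s, ]
      tpl <- templates[templates$sample_id == s, ]
      n <- n_reads[[s]]
      if (n == 0L || nrow(tpl) == 0L) next
      draw <- sample.int(nrow(tpl), n, replace = TRUE,
                         prob = tpl$weight / sum(tpl$weight))
      has_rev <- !is.na(man$rev_barcode) && nzchar(man$rev_barcode)
      ids <- sprintf("%s_r%05d", s, seq_len(n))
      bases <- character(n)
      quals <- vector("list", n)
      nsub <- integer(n)
      nind <- integer(n)
      for (k in seq_len(n)) {
        tail_part <- if (has_rev) {
          paste0(revcomp(realize_iupac(man$rev_primer)),
                 revcomp(man$rev_barcode))
        } else ""
        raw <- paste0(adaptor, man$fwd_barcode,
                      realize_iupac(man$fwd_primer),
                      tpl$template[draw[k]], tail_part)
        chars <- strsplit(raw, "")[[1]]
        sub <- apply_substitutions(chars, error_model$sub_rate)
        hp <- apply_homopolymer_errors(sub$chars,
                                       error_model$homopolymer_rate)
        bases[k] <- paste(hp$chars, collapse = "")
        L <- length(hp$chars)
        bad <- stats::runif(L) < error_model$bad_frac
        q <- ifelse(bad,
                    error_model$q_bad + sample(-3:3, L, replace = TRUE),
                    error_model$q_good + sample(-2:2, L, replace = TRUE))
        quals[[k]] <- as.integer(pmin(pmax(q, 2L), 40L))
        nsub[k] <- sub$n
        nind[k] <- hp$n
      }
      reads[[s]] <- seq_tbl(ids, bases, quals)
      prov[[s]] <- tibble(read_id = ids, sample_id = s,
                          taxon_id = tpl$taxon_id[draw],
                          template = tpl$template[draw],
                          n_subs = nsub, n_indels = nind)
    }
    list(reads = bind_rows(reads), provenance = bind_rows(prov))
  })
}

#' Generate a set of distinct barcodes
#'
#' @param n number of barcodes.
#' @param length barcode length.
#' @param min_dist minimum pairwise Hamming distance.
#' @param seed integer seed.
#' @return Character vector of `n` barcodes.
#' @export
generate_barcodes <- function(n, length = 8L, min_dist = 3L, seed = 1L) {
  with_seed(seed, {
    out <- character(0)
    hamming <- function(a, b) {
      sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }
    tries <- 0L
    while (length(out) < n) {
      cand <- random_dna(length)
      tries <- tries + 1L
      if (tries > 5000L * n) abort("cannot generate enough distinct barcodes")
      if (all(vapply(out, hamming, integer(1), b = cand) >= min_dist)) {
        out <- c(out, cand)
      }
    }
    out
  })
}
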