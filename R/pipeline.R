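DEFAULT_FWD_PRIMER <- "GTTYGATYMTGGCTCAG"
DEFAULT_REV_PRIMER <- "TGCTGCCTCCCGTAGGAGT"

#' Pipeline run configuration
#'
#' One object holds every threshold the pipeline applies (all defaulting to
#' the assay's published rules) plus the synthetic-scenario shape. The
#' default shape is a scaled-down version of the cultivation experiment the
#' simulator emulates - three sponge inocula, plate-scraped communities on
#' several media and surfaces, and double-barcoded picked colonies - sized
#' so a full run completes in minutes on one CPU.
#'
#' @param seed integer master seed; every stage derives its own stream.
#' @param out_dir run output directory.
#' @param n_types type strains in the synthetic reference database (the last
#'   one is reserved as the fast-growing, plate-dominating taxon absent from
#'   the inocula).
#' @param n_taxa_per_community reference taxa per sponge community.
#' @param sponges,media,surfaces,days factors of the scraping design.
#' @param n_plate_groups,colonies_per_group picked-colony design per sponge.
#' @param reads_per_inoculum,reads_per_scraped,reads_per_colony sequencing
#'   depth per sample type.
#' @param novel_divergences percent divergences of planted novel members
#'   (per sponge community).
#' @param growth_frac probability that a community taxon can form colonies.
#' @param carryover fraction of scraped reads carried over from the
#'   inoculum.
#' @param dominance_factor colony-weight multiplier of the dominant taxon on
#'   agar surfaces.
#' @param dominance_filter multiplier on filter membranes (default 1: the
#'   fast grower spreads over agar but is confined on filters, so
#'   filter-grown communities retain recoverable signal from slower taxa).
#' @param colony_contamination fraction of a picked colony's reads drawn
#'   from the surrounding plate community instead of the colony taxon.
#' @param filter [filter_params()]; `clustering_threshold` percent identity
#'   for OTU picking; `growth` [growth_params()]; `novelty_max`/`order_max`
#'   novelty thresholds; `sanger_threshold` isolate confirmation threshold;
#'   `error` [error_model()]; `chimera_screen` logical.
#' @param clustering_threshold,growth,novelty_max,order_max see above.
#' @param sanger_threshold,error,chimera_screen see above.
#' @param verbose print stage messages.
#' @return A list of class `cs_run_config`.
#' @export
run_config <- function(seed = 1L,
                       out_dir = tempfile("culturoscope_run_"),
                       n_types = 10L,
                       n_taxa_per_community = 7L,
                       sponges = c("AA", "PF", "CC"),
                       media = c("MA", "MH"),
                       surfaces = c("agar", "filter"),
                       days = 15L,
                       n_plate_groups = 2L,
                       colonies_per_group = 6L,
                       reads_per_inoculum = 300L,
                       reads_per_scraped = 150L,
                       reads_per_colony = 16L,
                       novel_divergences = c(8, 18),
                       growth_frac = 0.6,
                       carryover = 0.03,
                       dominance_factor = 25,
                       dominance_filter = 1,
                       colony_contamination = 0.08,
                       filter = filter_params(),
                       clustering_threshold = 97,
                       growth = growth_params(),
                       novelty_max = 95,
                       order_max = 89,
                       sanger_threshold = 97,
                       error = error_model(),
                       chimera_screen = FALSE,
                       verbose = FALSE) {
  structure(as.list(environment()), class = "cs_run_config")
}

config_to_yaml <- function(config, path) {
  flat <- config
  flat$filter <- unclass(flat$filter)
  flat$growth <- unclass(flat$growth)
  flat$error <- unclass(flat$error)
  yaml::write_yaml(lapply(unclass(flat), function(x) {
    if (is.function(x)) NULL else x
  }), path)
}

log_line <- function(con, ..., verbose = FALSE) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
  writeLines(msg, con)
  if (verbose) message(msg)
}

# --- scenario assembly ------------------------------------------------------

build_scenario <- function(config, refdb) {
  seed <- config$seed
  community_pool <- refdb[seq_len(nrow(refdb) - 1L), ]
  dominant <- refdb[nrow(refdb), ]
  sponges <- config$sponges
  communities <- list()
  scenarios <- list()
  for (i in seq_along(sponges)) {
    sp <- sponges[i]
    novel_spec <- NULL
    if (length(config$novel_divergences) > 0) {
      parents <- with_seed(derive_seed(seed, 50L + i), {
        sample(community_pool$id, length(config$novel_divergences))
      })
      novel_spec <- tibble(parent_id = parents,
                           target_percent = config$novel_divergences)
    }
    comm <- simulate_community(
      community_pool, config$n_taxa_per_community,
      meanlog = 0, sdlog = 1.2, novel_spec = novel_spec,
      novel_prefix = paste0(sp, "_"),
      seed = derive_seed(seed, 100L + i)
    )
    gp <- with_seed(derive_seed(seed, 150L + i), {
      p <- ifelse(stats::runif(nrow(comm)) < config$growth_frac,
                  stats::runif(nrow(comm), 0.3, 1), 0)
      # planted novel members must be able to grow, or there is nothing for
      # the novelty report to find
      p[comm$is_novel] <- stats::runif(sum(comm$is_novel), 0.7, 1)
      setNames(p, comm$taxon_id)
    })
    scenarios[[sp]] <- plating_scenario(
      growth_prob = gp,
      dominant_taxon = dominant$id,
      dominance_factor = config$dominance_factor,
      spike = tibble(taxon_id = dominant$id, template = dominant$v1v2,
                     colony_weight = config$dominance_factor *
                       mean(comm$abundance)),
      carryover_reads_fraction = config$carryover
    )
    communities[[sp]] <- comm
  }
  list(communities = communities, scenarios = scenarios,
       dominant = dominant)
}

build_manifest_and_templates <- function(config, scenario_set) {
  sponges <- config$sponges
  rows <- list()
  templates <- list()
  colony_truth <- list()
  visible <- list()
  # inocula
  for (sp in sponges) {
    sid <- paste0(sp, "_inoc")
    rows[[sid]] <- tibble(sample_id = sid, sponge = sp, medium = "none",
                          surface = "none", day = 0L, colonies = NA_integer_,
                          role = "inoculum", plate_group = sid)
    comm <- scenario_set$communities[[sp]]
    templates[[sid]] <- tibble(sample_id = sid, taxon_id = comm$taxon_id,
                               template = comm$template,
                               weight = comm$abundance)
  }
  # scraped communities
  combos <- tidyr::expand_grid(sponge = sponges, medium = config$media,
                               surface = config$surfaces, day = config$days)
  for (i in seq_len(nrow(combos))) {
    sp <- combos$sponge[i]
    sid <- sprintf("%s_%s_%s_d%02d", sp, combos$medium[i],
                   combos$surface[i], combos$day[i])
    scen <- scenario_set$scenarios[[sp]]
    if (combos$surface[i] == "filter") {
      scen$dominance_factor <- config$dominance_filter
      scen$spike$colony_weight <- config$dominance_filter *
        mean(scenario_set$communities[[sp]]$abundance)
    }
    plated <- simulate_plating(scenario_set$communities[[sp]], scen)
    n_vis <- with_seed(derive_seed(config$seed, 200L + i), {
      if (stats::runif(1) < 0.15) sample(2:15, 1L) else sample(20:250, 1L)
    })
    rows[[sid]] <- tibble(sample_id = sid, sponge = sp,
                          medium = combos$medium[i],
                          surface = combos$surface[i], day = combos$day[i],
                          colonies = n_vis, role = "scraped",
                          plate_group = sid)
    templates[[sid]] <- plated$scraped |>
      transmute(sample_id = sid, taxon_id = .data$taxon_id,
                template = .data$template, weight = .data$abundance)
    visible[[sid]] <- plated$truth |> mutate(sponge = sp, sample_id = sid)
  }
  # picked colonies (double-barcoded)
  for (i in seq_along(sponges)) {
    sp <- sponges[i]
    comm <- scenario_set$communities[[sp]]
    scen <- scenario_set$scenarios[[sp]]
    plate_mix <- colony_weights(comm, scen)
    plate_mix <- plate_mix[plate_mix$weight > 0, ]
    for (g in seq_len(config$n_plate_groups)) {
      grp <- sprintf("%s_pg%d", sp, g)
      picks <- simulate_colony_pick(
        comm, scen, config$colonies_per_group, n_plates = 1L,
        seed = derive_seed(config$seed, 300L + 10L * i + g)
      )
      for (ci in seq_len(nrow(picks))) {
        sid <- sprintf("%s_%s", grp, picks$colony_id[ci])
        rows[[sid]] <- tibble(sample_id = sid, sponge = sp,
                              medium = config$media[1L + (g - 1L) %%
                                                      length(config$media)],
                              surface = "agar", day = 30L,
                              colonies = NA_integer_, role = "colony",
                              plate_group = grp)
        own <- tibble(sample_id = sid, taxon_id = picks$taxon_id[ci],
                      template = picks$template[ci],
                      weight = 1 - config$colony_contamination)
        contam <- plate_mix |>
          filter(.data$taxon_id != picks$taxon_id[ci]) |>
          transmute(sample_id = sid, taxon_id = .data$taxon_id,
                    template = .data$template,
                    weight = config$colony_contamination * .data$weight /
                      sum(.data$weight))
        templates[[sid]] <- bind_rows(own, contam)
        colony_truth[[sid]] <- tibble(sample_id = sid, sponge = sp,
                                      plate_group = grp,
                                      true_taxon = picks$taxon_id[ci])
      }
    }
  }
  meta <- bind_rows(rows)
  # barcodes: forward per plate group, reverse per colony within group
  groups <- unique(meta$plate_group)
  fwd_bc <- setNames(
    generate_barcodes(length(groups), seed = derive_seed(config$seed, 400L)),
    groups
  )
  meta$fwd_barcode <- fwd_bc[meta$plate_group]
  meta$rev_barcode <- NA_character_
  for (grp in groups) {
    idx <- which(meta$plate_group == grp & meta$role == "colony")
    if (length(idx) > 0) {
      meta$rev_barcode[idx] <- generate_barcodes(
        length(idx), seed = derive_seed(config$seed, 500L +
                                          match(grp, groups))
      )
    }
  }
  meta$fwd_primer <- DEFAULT_FWD_PRIMER
  meta$rev_primer <- DEFAULT_REV_PRIMER
  manifest <- meta[, MANIFEST_COLS]
  list(manifest = manifest,
       templates = bind_rows(templates),
       colony_truth = bind_rows(colony_truth),
       plating_truth = bind_rows(visible))
}

# --- the pipeline -----------------------------------------------------------

#' Run the full pipeline on a synthetic experiment
#'
#' Simulates the cultivation experiment (reference database, sponge
#' communities, plating, colony picking, error-bearing barcoded reads),
#' then runs demultiplexing, quality filtering, open-reference OTU picking,
#' colony identification, growth calling, novelty classification, overlap
#' analysis and community statistics, writing every intermediate as TSV plus
#' a consolidated `report.md` into the run directory. Deterministic given
#' `config$seed`.
#'
#' @param config a [run_config()] object.
#' @return Invisibly, a list of class `cs_run` with the run directory and
#'   all major result tibbles.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  logcon <- file(out("run.log"), open = "wt")
  on.exit(close(logcon))
  lg <- function(...) log_line(logcon, ..., verbose = config$verbose)
  config_to_yaml(config, out("config.yaml"))

  # -- simulate --------------------------------------------------------------
  lg("simulate: reference database (n_types=", config$n_types, ")")
  refdb <- generate_reference_db(config$n_types,
                                 seed = derive_seed(config$seed, 1L))
  scenario_set <- build_scenario(config, refdb)
  built <- build_manifest_and_templates(config, scenario_set)
  manifest <- built$manifest
  n_reads <- setNames(
    ifelse(manifest$role == "inoculum", config$reads_per_inoculum,
           ifelse(manifest$role == "scraped", config$reads_per_scraped,
                  config$reads_per_colony)),
    manifest$sample_id
  )
  lg("simulate: ", nrow(manifest), " samples, ", sum(n_reads), " reads")
  sim <- simulate_reads(built$templates, manifest, config$error,
                        n_reads = n_reads,
                        seed = derive_seed(config$seed, 2L))
  write_fastq(sim$reads, out("reads.fastq"))
  write_manifest(manifest, out("manifest.tsv"))
  write_refdb(refdb, out("reference.fasta"), out("taxonomy.tsv"))
  readr::write_tsv(sim$provenance, out("provenance.tsv"))

  truth <- list(
    taxa = scenario_set$communities |>
      bind_rows(.id = "sponge") |>
      distinct(.data$taxon_id, .keep_all = TRUE) |>
      select("taxon_id", "template", "is_novel", "parent_id", "divergence"),
    dominant_taxon = scenario_set$dominant$id,
    communities = lapply(scenario_set$communities, function(x) {
      setNames(as.list(x$abundance), x$taxon_id)
    }),
    grown = lapply(split(built$plating_truth,
                         built$plating_truth$sponge), function(x) {
      sort(unique(x$taxon_id[x$grew]))
    }),
    carryover_only = lapply(split(built$plating_truth,
                                  built$plating_truth$sponge), function(x) {
      sort(unique(x$taxon_id[x$carryover_only]))
    }),
    colonies = built$colony_truth
  )
  # the dominant spike taxon also has a template; include it in taxa
  if (!truth$dominant_taxon %in% truth$taxa$taxon_id) {
    truth$taxa <- bind_rows(truth$taxa, tibble(
      taxon_id = scenario_set$dominant$id,
      template = scenario_set$dominant$v1v2,
      is_novel = FALSE, parent_id = NA_character_, divergence = 0
    ))
  }
  jsonlite::write_json(truth, out("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)

  # -- demultiplex + filter --------------------------------------------------
  lg("demux/filter: mean quality > ", config$filter$min_mean_quality,
     ", homopolymer <= ", config$filter$max_homopolymer,
     ", length >= ", config$filter$min_length,
     ", primer mismatches <= ", config$filter$max_primer_mismatches)
  filt <- filter_library(sim$reads, manifest, config$filter)
  readr::write_tsv(filt$report, out("filter_report.tsv"))
  readr::write_tsv(filt$per_sample, out("per_sample_retention.tsv"))
  lg("demux/filter: ", nrow(filt$reads), "/", nrow(sim$reads),
     " reads retained")

  # -- OTU picking -----------------------------------------------------------
  lg("cluster: open-reference at ", config$clustering_threshold, "% identity")
  otus <- pick_otus_open_reference(filt$reads, refdb,
                                   threshold = config$clustering_threshold)
  if (config$chimera_screen) {
    otus <- flag_bimeras(otus, refdb)
    lg("cluster: bimera screen flagged ", sum(otus$chimera_flag), " OTUs")
  }
  otus <- assign_taxonomy(otus, refdb)
  counts <- build_otu_table(otus, filt$reads |>
                              transmute(read_id = .data$id,
                                        sample_id = .data$sample_id))
  lg("cluster: ", nrow(otus), " OTUs (",
     sum(otus$origin == "closed"), " closed, ",
     sum(otus$origin == "denovo"), " de novo)")
  readr::write_tsv(otus |> select(-"members"), out("otus.tsv"))
  write_fasta(seq_tbl(otus$otu_id, otus$representative),
              out("representatives.fasta"))
  write_otu_table(counts, out("otu_table.tsv"))

  # -- colony identification -------------------------------------------------
  membership <- otus |>
    select("otu_id", "members") |>
    tidyr::unnest_longer("members", values_to = "read_id")
  colony_samples <- manifest$sample_id[manifest$role == "colony"]
  colony_labels <- filt$reads |>
    filter(.data$sample_id %in% colony_samples) |>
    transmute(colony_id = .data$sample_id, read_id = .data$id) |>
    left_join(membership, by = "read_id")
  assignments <- assign_colonies(colony_labels,
                                 all_colonies = colony_samples)
  lg("colonies: ", sum(assignments$assigned), "/", nrow(assignments),
     " colonies assigned by the >50% majority rule")
  readr::write_tsv(assignments, out("colony_assignments.tsv"))
  regrow <- select_otus_for_regrowth(assignments)
  readr::write_tsv(tibble(otu_id = regrow), out("regrowth_otus.tsv"))

  # simulated Sanger confirmation: one isolate per regrown OTU, whose Sanger
  # read is the true template of the colony's taxon
  iso <- assignments |>
    filter(.data$assigned) |>
    inner_join(built$colony_truth,
               by = c(colony_id = "sample_id")) |>
    group_by(.data$assigned_otu) |>
    slice(1L) |>
    ungroup()
  confirmations <- tibble()
  if (nrow(iso) > 0) {
    taxa_templates <- setNames(truth$taxa$template, truth$taxa$taxon_id)
    confirmations <- confirm_isolates(
      tibble(isolate_id = paste0("iso_", iso$colony_id),
             target_otu = iso$assigned_otu,
             sanger_bases = unname(taxa_templates[iso$true_taxon])),
      otus, threshold = config$sanger_threshold
    )
    readr::write_tsv(confirmations, out("confirmations.tsv"))
    lg("colonies: ", sum(confirmations$confirmed), "/", nrow(confirmations),
       " isolates confirmed at >", config$sanger_threshold, "% identity")
  }

  # -- growth + novelty ------------------------------------------------------
  samples_meta <- manifest |>
    select("sample_id", "sponge", "medium", "surface", "day", "colonies",
           "role")
  rel <- relative_abundances(counts)
  growth_calls <- call_growth_all(rel, samples_meta, config$growth)
  lg("growth: criteria I (increase), II (>=",
     100 * config$growth$min_rel_abundance, "% rel. abundance), III (>=",
     config$growth$min_visible_colonies, " visible colonies)")
  readr::write_tsv(growth_calls, out("growth_calls.tsv"))
  novelty <- classify_novelty(otus, refdb, config$novelty_max,
                              config$order_max)
  readr::write_tsv(novelty, out("novelty.tsv"))
  table1 <- summarize_novel_growth(growth_calls, novelty, samples_meta)
  readr::write_tsv(table1, out("table1_style_report.tsv"))
  lg("growth: ", sum(growth_calls$grew), " growth calls; ",
     nrow(table1), " novel cultivable OTUs (identity <= ",
     config$novelty_max, "%)")

  # -- overlap (Venn) --------------------------------------------------------
  venns <- list()
  inoc_groups <- setNames(
    as.list(paste0(config$sponges, "_inoc")), config$sponges
  )
  venns[["sponges"]] <- overlap_sets(counts, inoc_groups)
  for (sp in config$sponges) {
    grp <- list(
      sponge = paste0(sp, "_inoc"),
      scraped = samples_meta$sample_id[samples_meta$role == "scraped" &
                                         samples_meta$sponge == sp],
      picked = samples_meta$sample_id[samples_meta$role == "colony" &
                                        samples_meta$sponge == sp]
    )
    venns[[sp]] <- overlap_sets(counts, grp)
  }
  venn_tbl <- bind_rows(venns, .id = "comparison")
  readr::write_tsv(venn_tbl, out("venn.tsv"))

  # -- community statistics --------------------------------------------------
  diversity <- sample_diversity(counts)
  readr::write_tsv(diversity, out("diversity.tsv"))
  inoc_ids <- paste0(config$sponges, "_inoc")
  rare_sample <- inoc_ids[1L]
  rare_counts <- counts |>
    filter(.data$sample_id == rare_sample) |>
    pull(.data$count)
  depths <- unique(pmax(1L, round(seq(0.1, 1, by = 0.3) * sum(rare_counts))))
  rare <- rarefaction_curve(rare_counts, depths, n_reps = 20L,
                            seed = derive_seed(config$seed, 600L))
  readr::write_tsv(rare |> mutate(sample_id = rare_sample),
                   out("rarefaction.tsv"))
  comm_ids <- samples_meta$sample_id[samples_meta$role %in%
                                       c("inoculum", "scraped")]
  dm <- bray_curtis_matrix(rel |> filter(.data$sample_id %in% comm_ids),
                           value = "rel_abundance")
  dm_tbl <- as.data.frame(as.matrix(dm))
  readr::write_tsv(cbind(tibble(sample_id = rownames(dm_tbl)), dm_tbl),
                   out("bray_curtis.tsv"))
  dend <- hclust_upgma(dm)
  write_newick(dend, out("dendrogram.nwk"))
  sponge_a <- samples_meta$sample_id[samples_meta$role == "scraped" &
                                       samples_meta$sponge ==
                                       config$sponges[1L]]
  sponge_b <- samples_meta$sample_id[samples_meta$role == "scraped" &
                                       samples_meta$sponge ==
                                       config$sponges[2L]]
  simp <- simper(rel, sponge_a, sponge_b, sqrt_transform = TRUE)
  readr::write_tsv(tidy(simp), out("simper.tsv"))
  lg("stats: Shannon range ",
     sprintf("%.2f-%.2f", min(diversity$shannon), max(diversity$shannon)),
     "; SIMPER overall dissimilarity ",
     sprintf("%.3f", attr(simp, "overall")))

  results <- list(
    dir = config$out_dir, config = config, refdb = refdb,
    manifest = manifest, filter = filt, otus = otus, counts = counts,
    assignments = assignments, confirmations = confirmations,
    growth_calls = growth_calls, novelty = novelty, table1 = table1,
    venn = venn_tbl, diversity = diversity, rarefaction = rare,
    dendrogram = dend, simper = simp, truth = truth,
    provenance = sim$provenance
  )
  write_report_md(results, out("report.md"))
  lg("done")
  invisible(structure(results, class = "cs_run"))
}

write_report_md <- function(res, path) {
  fmt_tbl <- function(df, n = 15L) {
    df <- head(df, n)
    if (nrow(df) == 0L) return("(none)")
    paste(utils::capture.output(print(as.data.frame(df), row.names = FALSE)),
          collapse = "\n")
  }
  lines <- c(
    "# Culturomics pipeline run report",
    "",
    sprintf("Master seed: %d.", res$config$seed),
    "",
    "## Read retention",
    "",
    fmt_tbl(res$filter$per_sample, 50L),
    "",
    sprintf("## OTUs (%d total: %d closed, %d de novo)", nrow(res$otus),
            sum(res$otus$origin == "closed"),
            sum(res$otus$origin == "denovo")),
    "",
    fmt_tbl(res$otus |> select("otu_id", "origin", "n_reads", "taxonomy")),
    "",
    sprintf("## Colony assignment (%d/%d assigned)",
            sum(res$assignments$assigned), nrow(res$assignments)),
    "",
    fmt_tbl(res$assignments),
    "",
    sprintf("## Growth calls (%d grew)", sum(res$growth_calls$grew)),
    "",
    fmt_tbl(res$growth_calls |> filter(.data$grew)),
    "",
    "## Novel cultivable OTUs",
    "",
    fmt_tbl(res$table1),
    "",
    "## OTU-set overlaps",
    "",
    fmt_tbl(res$venn, 40L),
    "",
    "## Diversity",
    "",
    fmt_tbl(res$diversity, 50L),
    "",
    "## SIMPER top contributors",
    "",
    fmt_tbl(tidy(res$simper), 10L)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.cs_run <- function(x, ...) {
  cat("<cs_run> ", x$dir, "\n",
      nrow(x$manifest), " samples, ", nrow(x$otus), " OTUs, ",
      sum(x$assignments$assigned), "/", nrow(x$assignments),
      " colonies assigned, ", sum(x$growth_calls$grew), " growth calls\n",
      sep = "")
  invisible(x)
}

# map each OTU representative to the ground-truth taxon it derives from
map_otus_to_taxa <- function(otus, taxa, threshold = 97,
                             scoring = align_scoring()) {
  map_chr(otus$representative, function(s) {
    ids <- percent_identity_many(s, taxa$template, scoring)
    best <- which.max(ids)
    if (ids[best] >= threshold) taxa$taxon_id[best] else NA_character_
  })
}

#' Score a run against its simulation ground truth
#'
#' Recomputes, from the run directory alone: colony-identification accuracy
#' (assigned colonies whose OTU maps back to the colony's true taxon),
#' growth-call precision and recall per sponge (against the taxa that truly
#' formed colonies; recall is measured over truly-grown taxa that were
#' detectable, i.e. reached the abundance criterion in at least one
#' qualifying scraped sample), and novelty-call accuracy over OTUs that map
#' to planted taxa.
#'
#' @param run_dir a directory produced by [run_pipeline()].
#' @return A tibble `metric`, `value`, `n` (denominator).
#' @export
validate_against_truth <- function(run_dir) {
  gt_path <- file.path(run_dir, "ground_truth.json")
  if (!file.exists(gt_path)) {
    abort(paste0("no ground_truth.json under ", run_dir,
                 " (was this run simulated?)"))
  }
  truth <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  taxa <- as_tibble(truth$taxa)
  otus <- read_fasta(file.path(run_dir, "representatives.fasta")) |>
    rename(otu_id = "id", representative = "bases")
  otu_taxon <- setNames(map_otus_to_taxa(otus, taxa), otus$otu_id)

  assignments <- readr::read_tsv(
    file.path(run_dir, "colony_assignments.tsv"),
    col_types = readr::cols(colony_id = "c", total_reads = "i",
                            top_otu = "c", majority_fraction = "d",
                            assigned = "l", assigned_otu = "c")
  )
  colonies <- as_tibble(truth$colonies)
  scored <- assignments |>
    filter(.data$assigned) |>
    inner_join(colonies, by = c(colony_id = "sample_id")) |>
    mutate(mapped = unname(otu_taxon[.data$assigned_otu]),
           # an assigned OTU that maps to no planted taxon is plainly wrong
           correct = !is.na(.data$mapped) & .data$mapped == .data$true_taxon)
  colony_acc <- if (nrow(scored) > 0) mean(scored$correct) else NA_real_

  growth_calls <- readr::read_tsv(
    file.path(run_dir, "growth_calls.tsv"),
    col_types = readr::cols(
      otu_id = "c", sample_id = "c", rel_scraped = "d", rel_inoculum = "d",
      visible_colonies = "i", c1_increase = "l", c2_abundance = "l",
      c3_colonies = "l", grew = "l"
    )
  )
  manifest <- read_manifest(file.path(run_dir, "manifest.tsv"))
  growth_calls <- growth_calls |>
    left_join(manifest[, c("sample_id", "sponge")], by = "sample_id")
  tp <- fp <- 0L
  eligible <- pred_n <- 0L
  recalled <- 0L
  for (sp in names(truth$grown)) {
    grown <- unlist(truth$grown[[sp]])
    calls_sp <- growth_calls |> filter(.data$sponge == sp)
    pred <- unique(stats::na.omit(
      otu_taxon[calls_sp$otu_id[calls_sp$grew]]
    ))
    pred_n <- pred_n + length(pred)
    tp <- tp + sum(pred %in% grown)
    fp <- fp + sum(!pred %in% grown)
    # detectable grown taxa: reached criterion II+III in some sample
    detectable <- unique(stats::na.omit(
      otu_taxon[calls_sp$otu_id[calls_sp$c2_abundance & calls_sp$c3_colonies]]
    ))
    det_grown <- intersect(grown, detectable)
    eligible <- eligible + length(det_grown)
    recalled <- recalled + sum(det_grown %in% pred)
  }
  precision <- if (pred_n > 0) tp / pred_n else NA_real_
  recall <- if (eligible > 0) recalled / eligible else NA_real_

  novelty <- readr::read_tsv(
    file.path(run_dir, "novelty.tsv"),
    col_types = readr::cols(otu_id = "c", closest_type_strain = "c",
                            identity = "d", is_novel = "l",
                            order_level_novel = "l")
  )
  nov <- novelty |>
    mutate(taxon = unname(otu_taxon[.data$otu_id])) |>
    filter(!is.na(.data$taxon)) |>
    left_join(taxa[, c("taxon_id", "divergence")],
              by = c(taxon = "taxon_id")) |>
    mutate(expected_novel = 100 - .data$divergence <= 95)
  novelty_acc <- if (nrow(nov) > 0) {
    mean(nov$is_novel == nov$expected_novel)
  } else NA_real_

  tibble(
    metric = c("colony_id_accuracy", "growth_precision", "growth_recall",
               "novelty_accuracy"),
    value = c(colony_acc, precision, recall, novelty_acc),
    n = c(nrow(scored), pred_n, eligible, nrow(nov))
  )
}
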