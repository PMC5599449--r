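test_that("reference database generation is seeded and divergent", {
  db1 <- generate_reference_db(3, seed = 1)
  db2 <- generate_reference_db(3, seed = 1)
  expect_identical(db1, db2)

  db <- generate_reference_db(4, seed = 2)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_lt(percent_identity(db$v1v2[i], db$v1v2[j]), 90)
  }
  expect_equal(nrow(generate_reference_db(1, seed = 3)), 1L)
  # windows never violate the homopolymer retention rule
  expect_true(all(culturoscope:::max_homopolymer_run(db$v1v2) <= 6))
})

test_that("mutate_to_divergence hits its target within half a point", {
  db <- tiny_refdb()
  parent <- db[1, ]
  expect_equal(mutate_to_divergence(parent, 0, seed = 1)$v1v2, parent$v1v2)
  for (target in c(5, 18)) {
    child <- mutate_to_divergence(parent, target, seed = 4)
    ident <- percent_identity(child$v1v2, parent$v1v2)
    expect_gte(ident, 100 - target - 0.5)
    expect_lte(ident, 100 - target + 0.5)
  }
  expect_error(mutate_to_divergence(parent, 30, seed = 1), "0, 25")
})

test_that("community profiles normalise and plant novel members", {
  db <- tiny_refdb()
  one <- simulate_community(db, 1, seed = 5)
  expect_equal(one$abundance, 1)
  for (s in 1:5) {
    p <- simulate_community(db, 3, seed = s)
    expect_equal(sum(p$abundance), 1, tolerance = 1e-9)
  }
  spec <- tibble::tibble(parent_id = db$id[1], target_percent = 5)
  p <- simulate_community(db, 2, novel_spec = spec, seed = 6)
  nov <- p[p$is_novel, ]
  expect_equal(nrow(nov), 1L)
  ident <- percent_identity(nov$template, db$v1v2[db$id == nov$parent_id])
  expect_lte(ident, 95.5)  # qualifies as novel under the <=95 rule (+/-0.5)
})

test_that("plating mixes colony growth with inoculum carry-over", {
  db <- tiny_refdb()
  prof <- simulate_community(db, 3, seed = 7)

  # only one taxon grows, no carry-over: scraped profile is that taxon
  only <- setNames(c(1, 0, 0), prof$taxon_id)
  sc <- plating_scenario(growth_prob = only, default_growth_prob = 0,
                         carryover_reads_fraction = 0)
  out <- simulate_plating(prof, sc)
  expect_equal(out$scraped$taxon_id, prof$taxon_id[1])
  expect_equal(out$scraped$abundance, 1)
  expect_true(out$truth$grew[1])
  expect_false(any(out$truth$grew[-1]))
  expect_true(all(out$truth$carryover_only[-1] == (prof$abundance[-1] > 0)))

  # full carry-over reproduces the inoculum exactly
  sc1 <- plating_scenario(carryover_reads_fraction = 1)
  out1 <- simulate_plating(prof, sc1)
  expect_equal(
    out1$scraped$abundance[match(prof$taxon_id, out1$scraped$taxon_id)],
    prof$abundance,
    tolerance = 1e-12
  )

  # dominance raises the fast grower above its inoculum share
  scd <- plating_scenario(dominant_taxon = prof$taxon_id[2],
                          dominance_factor = 50,
                          carryover_reads_fraction = 0.05)
  outd <- simulate_plating(prof, scd)
  expect_gt(outd$scraped$abundance[outd$scraped$taxon_id == prof$taxon_id[2]],
            prof$abundance[2])
})

test_that("colony picking respects the per-plate per-taxon cap", {
  db <- tiny_refdb()
  prof <- simulate_community(db, 2, seed = 8)
  expect_equal(nrow(simulate_colony_pick(prof, plating_scenario(), 0)), 0L)

  single <- prof[1, ]
  single$abundance <- 1
  picks <- simulate_colony_pick(single, plating_scenario(pick_cap = 3L),
                                n_colonies = 10, n_plates = 1L, seed = 9)
  expect_true(all(picks$taxon_id == single$taxon_id))
  expect_lte(nrow(picks), 3L)  # cap stops the plate at 3 same-taxon picks

  picks2 <- simulate_colony_pick(prof, plating_scenario(pick_cap = 2L),
                                 n_colonies = 8, n_plates = 2L, seed = 10)
  per <- dplyr::count(picks2, plate, taxon_id)
  expect_true(all(per$n <= 2L))
})

test_that("noise-free reads demultiplex perfectly and match their template", {
  db <- tiny_refdb()
  man <- tiny_manifest(db)
  templates <- dplyr::bind_rows(
    tibble::tibble(sample_id = "S1", taxon_id = db$id[1],
                   template = db$v1v2[1], weight = 1),
    tibble::tibble(sample_id = man$sample_id[3], taxon_id = db$id[2],
                   template = db$v1v2[2], weight = 1)
  )
  noise_free <- error_model(sub_rate = 0, homopolymer_rate = 0, bad_frac = 0)
  sim <- simulate_reads(templates, man, noise_free, n_reads = 10, seed = 12)
  expect_equal(nrow(sim$reads), 20L)

  filt <- filter_library(sim$reads, man)
  expect_equal(nrow(filt$reads), 20L)  # 100% retention in the noise-free limit
  joined <- dplyr::left_join(filt$reads, sim$provenance,
                             by = c(id = "read_id"))
  expect_true(all(joined$sample_id.x == joined$sample_id.y))
  expect_true(all(joined$bases == joined$template))
})

test_that("read simulation is byte-reproducible and checks barcodes", {
  db <- tiny_refdb()
  man <- tiny_manifest(db)
  templates <- tibble::tibble(sample_id = "S1", taxon_id = db$id[1],
                              template = db$v1v2[1], weight = 1)
  s1 <- simulate_reads(templates, man, n_reads = 5, seed = 3)
  s2 <- simulate_reads(templates, man, n_reads = 5, seed = 3)
  expect_identical(s1, s2)

  clash <- man
  clash$rev_barcode[3:4] <- clash$rev_barcode[3]
  expect_error(simulate_reads(templates, clash, n_reads = 2, seed = 1),
               "barcode pair")
})

test_that("homopolymer error model lengthens runs at the expected rate", {
  # a template with a 6-base run: +1 errors create 7-base runs that the
  # retention rules must reject
  template <- paste0(strrep("ACGT", 30), "AAAAAA", strrep("TGCA", 30))
  man <- tiny_manifest(tiny_refdb())[1, ]
  templates <- tibble::tibble(sample_id = "S1", taxon_id = "t",
                              template = template, weight = 1)
  rate <- 0.05
  em <- error_model(sub_rate = 0, homopolymer_rate = rate, bad_frac = 0)
  n <- 400L
  sim <- simulate_reads(templates, man, em, n_reads = n, seed = 44)
  runs <- culturoscope:::max_homopolymer_run(sim$reads$bases)
  frac7 <- mean(runs >= 7)
  # the 6-run gains a base with probability rate * 6 / 2; other (shorter)
  # runs can also stretch, so test a generous band around the analytic rate
  p <- rate * 6 / 2
  expect_gt(frac7, p - 3 * sqrt(p * (1 - p) / n))
  expect_lt(frac7, 4 * p)
})
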