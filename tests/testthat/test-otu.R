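test_that("closed-reference hits collapse onto their reference", {
  db <- tiny_refdb()
  reads <- tibble::tibble(id = c("r1", "r2", "r3"),
                          bases = db$v1v2[c(1, 1, 1)])
  otus <- pick_otus_open_reference(reads, db)
  expect_equal(nrow(otus), 1L)
  expect_equal(otus$otu_id, db$id[1])
  expect_equal(otus$origin, "closed")
  expect_equal(otus$representative, db$v1v2[1])
  expect_equal(sort(otus$members[[1]]), c("r1", "r2", "r3"))
})

test_that("sequences below threshold to everything found separate de novo OTUs", {
  db <- tiny_refdb()
  set.seed(5)
  a <- random_seq(300)
  # ~90% identical to a: below the 97% threshold, so two OTUs
  ac <- strsplit(a, "")[[1]]
  for (p in sample(300, 30)) ac[p] <- setdiff(c("A", "C", "G", "T"), ac[p])[1]
  b <- paste(ac, collapse = "")
  reads <- tibble::tibble(id = c("x", "y"), bases = c(a, b))
  otus <- pick_otus_open_reference(reads, db)
  expect_equal(nrow(otus), 2L)
  expect_true(all(otus$origin == "denovo"))
})

test_that("every de novo member is at least 97% identical to its centroid", {
  db <- tiny_refdb()
  parent <- mutate_to_divergence(db[1, ], 8, seed = 2)
  set.seed(6)
  variants <- vapply(1:6, function(i) {
    chars <- strsplit(parent$v1v2, "")[[1]]
    for (p in sample(311, 3)) {
      chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
    }
    paste(chars, collapse = "")
  }, character(1))
  reads <- tibble::tibble(id = paste0("v", 1:6), bases = variants)
  otus <- pick_otus_open_reference(reads, db)
  for (i in seq_len(nrow(otus))) {
    if (otus$origin[i] != "denovo") next
    members <- otus$members[[i]]
    for (m in members) {
      expect_gte(percent_identity(reads$bases[reads$id == m],
                                  otus$representative[i]), 97)
    }
  }
})

test_that("greedy clustering equals the naive oracle on random instances", {
  db <- generate_reference_db(3, seed = 77, full_length = 500L,
                              v_start = 10L, v_len = 200L)
  set.seed(42)
  for (inst in 1:15) {
    n <- sample(5:15, 1)
    reads <- tibble::tibble(
      id = sprintf("i%02d_r%02d", inst, seq_len(n)),
      bases = vapply(seq_len(n), function(k) {
        if (runif(1) < 0.5) {
          # reference-derived with a few substitutions
          chars <- strsplit(db$v1v2[sample(3, 1)], "")[[1]]
          nm <- sample(0:8, 1)
          for (p in sample(length(chars), nm)) {
            chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
          }
          paste(chars, collapse = "")
        } else {
          random_seq(sample(150:250, 1))
        }
      }, character(1))
    )
    got <- pick_otus_open_reference(reads, db)
    want <- oracle_greedy_otus(reads, db)
    got_list <- setNames(lapply(got$members, sort), got$otu_id)
    expect_equal(got_list[sort(names(got_list))],
                 want[sort(names(want))], info = paste("instance", inst))
  }
})

test_that("clustering is invariant to read input order", {
  db <- tiny_refdb()
  set.seed(9)
  reads <- tibble::tibble(
    id = paste0("r", 1:10),
    bases = c(db$v1v2[c(1, 1, 2)],
              vapply(1:7, function(i) random_seq(250), character(1)))
  )
  a <- pick_otus_open_reference(reads, db)
  b <- pick_otus_open_reference(reads[sample(10), ], db)
  expect_equal(a$otu_id, b$otu_id)
  expect_equal(lapply(a$members, sort), lapply(b$members, sort))
})

test_that("taxonomy transfer truncates by identity bands", {
  db <- tiny_refdb()
  reads <- tibble::tibble(id = "r1", bases = db$v1v2[1])
  closed <- assign_taxonomy(pick_otus_open_reference(reads, db), db)
  expect_equal(closed$taxonomy, db$lineage[1])

  # ~94% to the best reference: family-level truncation (4 of 6 ranks)
  child <- mutate_to_divergence(db[1, ], 6, seed = 3)
  denovo <- assign_taxonomy(
    pick_otus_open_reference(tibble::tibble(id = "n1", bases = child$v1v2),
                             db),
    db
  )
  expect_equal(denovo$origin, "denovo")
  expect_equal(denovo$taxonomy,
               paste(strsplit(db$lineage[1], ";")[[1]][1:4], collapse = ";"))

  # unrelated sequence: unassigned
  set.seed(10)
  far <- assign_taxonomy(
    pick_otus_open_reference(tibble::tibble(id = "f1",
                                            bases = random_seq(300)), db),
    db
  )
  expect_equal(far$taxonomy, "Unassigned")
})

test_that("bimera screen flags a perfect two-parent crossover only", {
  db <- generate_reference_db(4, seed = 21)
  crossover <- paste0(substr(db$v1v2[1], 1, 150),
                      substr(db$v1v2[2], 151, 311))
  reads <- tibble::tibble(id = c("c1", "g1"),
                          bases = c(crossover, db$v1v2[3]))
  otus <- pick_otus_open_reference(reads, db)
  flagged <- flag_bimeras(otus, db)
  expect_true(flagged$chimera_flag[flagged$origin == "denovo"])
  expect_false(any(flagged$chimera_flag[flagged$origin == "closed"]))

  # parent order invariance
  flagged2 <- flag_bimeras(otus, db[sample(4), ])
  expect_equal(flagged$chimera_flag, flagged2$chimera_flag)
})

test_that("OTU tables tally counts and conserve read totals", {
  db <- tiny_refdb()
  reads <- tibble::tibble(
    id = paste0("r", 1:5),
    bases = db$v1v2[c(1, 1, 1, 2, 2)]
  )
  read_map <- tibble::tibble(read_id = paste0("r", 1:5),
                             sample_id = c("A", "A", "A", "A", "B"))
  otus <- pick_otus_open_reference(reads, db)
  counts <- build_otu_table(otus, read_map)
  expect_equal(counts$count[counts$sample_id == "A" &
                              counts$otu_id == db$id[1]], 3L)
  totals <- dplyr::count(read_map, sample_id)
  sums <- dplyr::summarise(dplyr::group_by(counts, sample_id),
                           n = sum(count))
  expect_equal(sums$n, totals$n)

  # dropping a flagged OTU removes its column
  otus$chimera_flag[otus$otu_id == db$id[2]] <- TRUE
  dropped <- build_otu_table(otus, read_map)
  expect_false(db$id[2] %in% dropped$otu_id)

  otus$chimera_flag <- FALSE
  expect_error(build_otu_table(otus, read_map[1:3, ]), "not in read_map")
})

test_that("wide TSV round-trips the count table", {
  counts <- tibble::tibble(
    sample_id = c("A", "A", "B"),
    otu_id = c("o1", "o2", "o1"),
    count = c(3L, 1L, 2L)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(counts, path)
  expect_equal(read_otu_table(path), dplyr::arrange(counts, sample_id, otu_id))
})
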