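rel_from <- function(...) {
  relative_abundances(tibble::tibble(...))
}

test_that("relative abundances normalise per sample", {
  rel <- rel_from(sample_id = c("A", "A"), otu_id = c("o1", "o2"),
                  count = c(3L, 1L))
  expect_equal(rel$rel_abundance, c(0.75, 0.25))
  single <- rel_from(sample_id = "A", otu_id = "o1", count = 5L)
  expect_equal(single$rel_abundance, 1)
  expect_warning(
    rel_from(sample_id = c("A", "B"), otu_id = c("o1", "o1"),
             count = c(2L, 0L)),
    "zero-count"
  )
})

growth_fixture <- function(scraped_counts, inoc_counts, colonies = 25L) {
  counts <- dplyr::bind_rows(
    tibble::tibble(sample_id = "scr", otu_id = names(scraped_counts),
                   count = as.integer(scraped_counts)),
    tibble::tibble(sample_id = "inoc", otu_id = names(inoc_counts),
                   count = as.integer(inoc_counts))
  )
  samples <- tibble::tibble(sample_id = c("scr", "inoc"),
                            colonies = c(colonies, NA_integer_),
                            sponge = "AA", role = c("scraped", "inoculum"))
  list(rel = relative_abundances(counts), samples = samples)
}

test_that("the three growth criteria apply with their printed boundaries", {
  # 0.3% scraped vs 0.1% inoculum, 25 colonies: all criteria met
  f <- growth_fixture(c(big = 997L, x = 3L), c(big = 999L, x = 1L))
  call <- call_growth(f$rel, f$samples, "scr", "inoc")
  x <- call[call$otu_id == "x", ]
  expect_true(x$c1_increase && x$c2_abundance && x$c3_colonies && x$grew)

  # 0.15% scraped fails criterion II (>= 0.2%)
  f2 <- growth_fixture(c(big = 9985L, x = 15L), c(big = 9999L, x = 1L))
  x2 <- call_growth(f2$rel, f2$samples, "scr", "inoc")
  x2 <- x2[x2$otu_id == "x", ]
  expect_true(x2$c1_increase)
  expect_false(x2$c2_abundance)
  expect_false(x2$grew)
  # exactly 0.2% passes criterion II (inclusive)
  f2b <- growth_fixture(c(big = 998L, x = 2L), c(big = 999L, x = 1L))
  expect_true(call_growth(f2b$rel, f2b$samples, "scr",
                          "inoc")$c2_abundance[2])

  # a 10-colony community fails criterion III for every OTU
  f3 <- growth_fixture(c(big = 997L, x = 3L), c(big = 999L, x = 1L),
                       colonies = 10L)
  c3 <- call_growth(f3$rel, f3$samples, "scr", "inoc")
  expect_false(any(c3$grew))
  expect_false(any(c3$c3_colonies))
  # exactly 20 colonies passes criterion III (inclusive)
  f3b <- growth_fixture(c(big = 997L, x = 3L), c(big = 999L, x = 1L),
                        colonies = 20L)
  expect_true(all(call_growth(f3b$rel, f3b$samples, "scr",
                              "inoc")$c3_colonies))

  # criterion I is a strict increase; equal abundance fails
  f4 <- growth_fixture(c(big = 500L, x = 500L), c(big = 500L, x = 500L))
  expect_false(any(call_growth(f4$rel, f4$samples, "scr",
                               "inoc")$c1_increase))

  # an OTU absent from the inoculum trivially increased from zero
  f5 <- growth_fixture(c(big = 900L, newcomer = 100L), c(big = 1000L))
  n5 <- call_growth(f5$rel, f5$samples, "scr", "inoc")
  n5 <- n5[n5$otu_id == "newcomer", ]
  expect_equal(n5$rel_inoculum, 0)
  expect_true(n5$grew)

  # a missing colony count is an error naming the sample
  bad <- growth_fixture(c(x = 10L), c(x = 10L))
  bad$samples$colonies[1] <- NA_integer_
  expect_error(call_growth(bad$rel, bad$samples, "scr", "inoc"), "scr")
})

test_that("grew is monotone in scraped relative abundance", {
  inoc <- c(big = 950L, x = 50L)
  prev <- FALSE
  for (x_count in c(10L, 60L, 200L, 800L)) {
    f <- growth_fixture(c(big = 1000L - 0L, x = x_count), inoc)
    call <- call_growth(f$rel, f$samples, "scr", "inoc")
    grew <- call$grew[call$otu_id == "x"]
    expect_false(prev && !grew)  # never flips TRUE -> FALSE as rel rises
    prev <- grew
  }
})

test_that("novelty thresholds are <=95 inclusive and <89 exclusive", {
  set.seed(77)
  base <- random_seq(200)
  subst <- function(s, k) {
    # isolated, well-spaced substitutions so the optimal alignment stays
    # gap-free and identity is exactly 100 * (200 - k) / 200
    chars <- strsplit(s, "")[[1]]
    for (p in seq(3L, by = 5L, length.out = k)) {
      chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
    }
    paste(chars, collapse = "")
  }
  refdb <- tibble::tibble(id = "T1", v1v2 = base,
                          lineage = "p;c;o;f;g;s")
  otus <- tibble::tibble(
    otu_id = c("exact", "at95", "near96", "deep"),
    representative = c(base, subst(base, 10), subst(base, 9),
                       subst(base, 36))
  )
  nov <- classify_novelty(otus, refdb)
  expect_equal(nov$identity, c(100, 95, 95.5, 82))
  expect_equal(nov$is_novel, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(nov$order_level_novel, c(FALSE, FALSE, FALSE, TRUE))
  # order-level novelty implies novelty
  expect_true(all(!nov$order_level_novel | nov$is_novel))
  expect_error(classify_novelty(otus, refdb[0, ]), "empty")
})

test_that("Venn regions match brute-force set algebra", {
  counts <- tibble::tibble(
    sample_id = c("a1", "a2", "b1", "c1"),
    otu_id = c("o1", "o2", "o1", "o3"),
    count = c(1L, 2L, 1L, 5L)
  )
  same <- overlap_sets(counts, list(g1 = c("a1", "a2"), g2 = c("a1", "a2")))
  expect_equal(same$n_otus[same$region == "g1&g2"], 2L)
  expect_equal(sum(same$n_otus), 2L)

  disjoint <- overlap_sets(counts, list(g1 = "a1", g2 = "c1"))
  expect_equal(disjoint$n_otus[disjoint$region == "g1&g2"], 0L)

  set.seed(3)
  otu_pool <- paste0("o", 1:12)
  counts_r <- tibble::tibble(
    sample_id = sample(paste0("s", 1:6), 40, replace = TRUE),
    otu_id = sample(otu_pool, 40, replace = TRUE),
    count = sample(1:5, 40, replace = TRUE)
  ) |> dplyr::count(sample_id, otu_id, wt = count, name = "count")
  groups <- list(G1 = c("s1", "s2"), G2 = c("s3", "s4"), G3 = c("s5", "s6"))
  venn <- overlap_sets(counts_r, groups)
  sets <- lapply(groups, function(ids) {
    unique(counts_r$otu_id[counts_r$sample_id %in% ids])
  })
  for (i in seq_len(nrow(venn))) {
    members <- strsplit(venn$region[i], "&", fixed = TRUE)[[1]]
    expected <- Reduce(intersect, sets[members])
    for (out in setdiff(names(sets), members)) {
      expected <- setdiff(expected, sets[[out]])
    }
    expect_equal(venn$n_otus[i], length(expected), info = venn$region[i])
  }
  expect_equal(sum(venn$n_otus), length(unique(unlist(sets))))

  expect_error(overlap_sets(counts, setNames(as.list(letters[1:6]),
                                             letters[1:6])),
               "5 groups")
})

test_that("the novel-growth report aggregates qualifying samples", {
  growth_calls <- tibble::tibble(
    otu_id = c("n1", "n1", "n2", "k1"),
    sample_id = c("s1", "s2", "s1", "s1"),
    rel_scraped = c(0.01, 0.03, 0.004, 0.5),
    rel_inoculum = 0, visible_colonies = 30L,
    c1_increase = TRUE, c2_abundance = TRUE, c3_colonies = TRUE,
    grew = c(TRUE, TRUE, TRUE, TRUE)
  )
  novelty <- tibble::tibble(
    otu_id = c("n1", "n2", "k1"),
    closest_type_strain = c("T1", "T2", "T3"),
    identity = c(82, 94.5, 99),
    is_novel = c(TRUE, TRUE, FALSE),
    order_level_novel = c(TRUE, FALSE, FALSE)
  )
  samples <- tibble::tibble(sample_id = c("s1", "s2"),
                            sponge = c("AA", "PF"),
                            medium = c("MA", "MH"))
  rep <- summarize_novel_growth(growth_calls, novelty, samples)
  expect_equal(rep$otu_id, c("n1", "n2"))  # most novel first
  expect_equal(rep$n_samples, c(2L, 1L))
  expect_equal(rep$max_rel_abundance, c(0.03, 0.004))
  expect_equal(rep$sponges[1], "AA,PF")

  empty <- summarize_novel_growth(
    growth_calls[growth_calls$otu_id == "k1", ], novelty, samples
  )
  expect_equal(nrow(empty), 0L)
})
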