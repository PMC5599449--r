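test_that("Shannon index matches closed forms", {
  expect_equal(shannon(c(1, 1, 1, 1)), log(4))
  expect_equal(shannon(c(5, 0, 0)), 0)
  expect_equal(shannon(c(2, 1, 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_equal(shannon(c(1, 1, 1, 1), base = 2), 2)
  expect_error(shannon(c(0, 0)), "all-zero")
  # bounded by log richness, and agrees with vegan
  set.seed(4)
  for (i in 1:10) {
    x <- sample(0:50, 8, replace = TRUE)
    if (sum(x) == 0) next
    expect_lte(shannon(x), log(sum(x > 0)) + 1e-12)
    expect_equal(shannon(x), unname(vegan::diversity(x, index = "shannon")))
  }
})

test_that("rarefaction limits and hypergeometric oracle", {
  x <- c(10L, 5L, 1L, 0L, 30L)
  full <- rarefaction_curve(x, depths = sum(x), n_reps = 5, seed = 1)
  expect_equal(full$mean_otus, 4)  # every present OTU observed
  expect_equal(full$sd_otus, 0)
  one <- rarefaction_curve(x, depths = 1L, n_reps = 10, seed = 1)
  expect_equal(one$mean_otus, 1)
  expect_equal(one$sd_otus, 0)
  expect_error(rarefaction_curve(x, depths = sum(x) + 1L), "exceeds")

  set.seed(9)
  y <- sample(1:60, 12)
  n_reps <- 200L
  for (d in c(5L, 25L, 100L, sum(y) %/% 2L)) {
    got <- rarefaction_curve(y, depths = d, n_reps = n_reps, seed = 2)
    expected <- unname(suppressWarnings(vegan::rarefy(y, sample = d)))
    sem <- got$sd_otus / sqrt(n_reps)
    expect_lt(abs(got$mean_otus - expected), max(3 * sem, 1e-3))
  }
})

test_that("Bray-Curtis follows its formula and bounds", {
  expect_equal(bray_curtis(c(1, 2), c(1, 2)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 3)), 1)
  expect_equal(bray_curtis(c(0.75, 0.25), c(0.25, 0.75)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(11)
  for (i in 1:10) {
    x <- runif(6); y <- runif(6)
    d <- bray_curtis(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, bray_curtis(y, x))
    expect_equal(d, sum(abs(x - y)) / sum(x + y))
  }
})

test_that("distance matrices agree with vegan::vegdist", {
  set.seed(12)
  counts <- tidyr::expand_grid(sample_id = paste0("s", 1:4),
                               otu_id = paste0("o", 1:6)) |>
    dplyr::mutate(count = sample(0:20, 24, replace = TRUE))
  d <- bray_curtis_matrix(counts)
  m <- matrix(counts$count, nrow = 4, byrow = TRUE)
  expect_equal(as.numeric(d), as.numeric(vegan::vegdist(m, "bray")))
})

test_that("UPGMA reproduces hand-worked and oracle dendrograms", {
  dm <- matrix(c(0, 0.2, 0.6,
                 0.2, 0, 0.6,
                 0.6, 0.6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  h <- hclust_upgma(stats::as.dist(dm))
  merges <- dendrogram_merges(h)
  expect_equal(merges$height, c(0.2, 0.6))
  expect_setequal(c(merges$a[1], merges$b[1]), c("A", "B"))

  two <- matrix(0, 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  h2 <- hclust_upgma(stats::as.dist(two))
  expect_equal(h2$height, 0)
  expect_error(hclust_upgma(stats::dist(1)), "at least two")

  # random matrices vs the naive oracle, compared as cophenetic distances
  set.seed(13)
  for (n in 4:7) {
    for (rep in 1:3) {
      m <- matrix(0, n, n, dimnames = list(paste0("L", 1:n), paste0("L", 1:n)))
      vals <- runif(n * (n - 1) / 2, 0.05, 1)
      m[lower.tri(m)] <- vals
      m <- m + t(m)
      h <- hclust_upgma(stats::as.dist(m))
      got <- as.matrix(stats::cophenetic(h))
      want <- oracle_upgma_cophenetic(m)
      expect_equal(got[rownames(want), colnames(want)], want,
                   tolerance = 1e-9)
    }
  }
})

simper_fixture <- function(n_samples = 4, n_otus = 5, seed = 1) {
  set.seed(seed)
  tidyr::expand_grid(sample_id = paste0("s", seq_len(n_samples)),
                     otu_id = paste0("o", seq_len(n_otus))) |>
    dplyr::mutate(count = sample(0:30, n_samples * n_otus, replace = TRUE)) |>
    relative_abundances()
}

test_that("SIMPER decomposes the average Bray-Curtis dissimilarity", {
  # identical profiles: zero everywhere
  rel <- dplyr::bind_rows(
    tibble::tibble(sample_id = "a", otu_id = c("o1", "o2"),
                   rel_abundance = c(0.6, 0.4), count = c(6L, 4L)),
    tibble::tibble(sample_id = "b", otu_id = c("o1", "o2"),
                   rel_abundance = c(0.6, 0.4), count = c(6L, 4L))
  )
  s0 <- simper(rel, "a", "b")
  expect_equal(attr(s0, "overall"), 0)
  expect_true(all(s0$average == 0))

  # disjoint single-OTU profiles, no transform: each contributes 0.5
  rel2 <- dplyr::bind_rows(
    tibble::tibble(sample_id = "a", otu_id = c("o1", "o2"),
                   rel_abundance = c(1, 0)),
    tibble::tibble(sample_id = "b", otu_id = c("o1", "o2"),
                   rel_abundance = c(0, 1))
  )
  s1 <- simper(rel2, "a", "b", sqrt_transform = FALSE)
  expect_equal(attr(s1, "overall"), 1)
  expect_equal(sort(s1$average), c(0.5, 0.5))
  expect_equal(sum(s1$contribution_pct), 100)

  expect_error(simper(rel2, c("a", "b"), "b"), "disjoint")
})

test_that("SIMPER contributions sum to the mean cross-pair dissimilarity", {
  for (seed in 1:5) {
    rel <- simper_fixture(seed = seed)
    ga <- c("s1", "s2"); gb <- c("s3", "s4")
    s <- simper(rel, ga, gb, sqrt_transform = TRUE)
    m <- sqrt(culturoscope:::counts_matrix(rel, "rel_abundance"))
    pairs <- c()
    for (j in ga) for (k in gb) {
      pairs <- c(pairs, bray_curtis(m[j, ], m[k, ]))
    }
    expect_equal(sum(s$average), mean(pairs), tolerance = 1e-9)
    expect_equal(attr(s, "overall"), mean(pairs), tolerance = 1e-9)
  }
})

test_that("SIMPER agrees with vegan's implementation", {
  rel <- simper_fixture(seed = 42)
  ga <- c("s1", "s2"); gb <- c("s3", "s4")
  ours <- simper(rel, ga, gb, sqrt_transform = FALSE)
  m <- culturoscope:::counts_matrix(rel, "rel_abundance")
  grp <- ifelse(rownames(m) %in% ga, "A", "B")
  vs <- summary(vegan::simper(m, grp, permutations = 0),
                ordered = FALSE)[[1]]
  expect_equal(ours$average[match(rownames(vs), ours$otu_id)],
               unname(vs$average), tolerance = 1e-9)
})

test_that("tidy and glance expose the SIMPER result", {
  rel <- simper_fixture(seed = 2)
  s <- simper(rel, c("s1", "s2"), c("s3", "s4"))
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "cs_simper"))
  gl <- glance(s)
  expect_equal(gl$overall_dissimilarity, attr(s, "overall"))
  expect_equal(gl$n_otus, nrow(s))
})

test_that("result plots build without error", {
  rel <- simper_fixture(seed = 3)
  s <- simper(rel, c("s1", "s2"), c("s3", "s4"))
  expect_s3_class(ggplot2::autoplot(s), "ggplot")
  rc <- rarefaction_curve(c(20L, 10L, 3L), depths = c(5L, 15L), n_reps = 5)
  expect_s3_class(ggplot2::autoplot(rc), "ggplot")
  gc <- tibble::tibble(otu_id = "o", sample_id = "s", rel_scraped = 0.1,
                       rel_inoculum = 0.05, visible_colonies = 30L,
                       c1_increase = TRUE, c2_abundance = TRUE,
                       c3_colonies = TRUE, grew = TRUE)
  expect_s3_class(plot_growth_calls(gc), "ggplot")
})
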