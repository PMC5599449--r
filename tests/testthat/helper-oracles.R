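# Independent oracle implementations used across the suite. These are kept
# deliberately naive and separate from the package's code paths.

# plain-R Gotoh dynamic programme (scores only), same scoring convention as
# the package: gap of length L costs gap_open + L * gap_extend, free end
# gaps optional
oracle_nw_score <- function(a, b, match = 5, mismatch = -4, gap_open = -10,
                            gap_extend = -1, free_end_gaps = TRUE) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) {
    X[i, 1] <- if (free_end_gaps) 0 else gap_open + (i - 1) * gap_extend
  }
  for (j in 2:(m + 1)) {
    Y[1, j] <- if (free_end_gaps) 0 else gap_open + (j - 1) * gap_extend
  }
  sub <- function(x, y) if (x == y && x %in% c("A", "C", "G", "T")) match
  else mismatch
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
        sub(ac[i - 1], bc[j - 1])
      X[i, j] <- max(M[i - 1, j] + gap_open + gap_extend,
                     X[i - 1, j] + gap_extend,
                     Y[i - 1, j] + gap_open + gap_extend)
      Y[i, j] <- max(M[i, j - 1] + gap_open + gap_extend,
                     X[i, j - 1] + gap_open + gap_extend,
                     Y[i, j - 1] + gap_extend)
    }
  }
  H <- pmax(M, X, Y)
  if (free_end_gaps) {
    max(H[n + 1, ], H[, m + 1])
  } else {
    H[n + 1, m + 1]
  }
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# naive re-simulation of the open-reference greedy clustering rule
oracle_greedy_otus <- function(reads, refdb, threshold = 97) {
  derep <- split(reads$id, reads$bases)
  derep <- lapply(names(derep), function(b) {
    list(bases = b, ids = sort(derep[[b]]))
  })
  assign <- list()
  leftover <- list()
  for (d in derep) {
    idents <- vapply(refdb$v1v2, function(r) percent_identity(d$bases, r),
                     numeric(1))
    ok <- which(idents >= threshold)
    if (length(ok) > 0) {
      best <- ok[order(-idents[ok], refdb$id[ok])][1]
      rid <- refdb$id[best]
      assign[[rid]] <- sort(c(assign[[rid]], d$ids))
    } else {
      leftover[[length(leftover) + 1]] <- d
    }
  }
  if (length(leftover) > 0) {
    ns <- vapply(leftover, function(d) length(d$ids), integer(1))
    lens <- vapply(leftover, function(d) nchar(d$bases), integer(1))
    firsts <- vapply(leftover, function(d) d$ids[1], character(1))
    leftover <- leftover[order(-ns, -lens, firsts)]
    cents <- character(0)
    for (d in leftover) {
      placed <- FALSE
      for (k in seq_along(cents)) {
        if (percent_identity(d$bases, cents[k]) >= threshold) {
          oid <- sprintf("denovo%d", k)
          assign[[oid]] <- sort(c(assign[[oid]], d$ids))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        cents <- c(cents, d$bases)
        assign[[sprintf("denovo%d", length(cents))]] <- d$ids
      }
    }
  }
  assign
}

# strict-majority assignment oracle over a named count vector
oracle_majority <- function(counts, total = sum(counts)) {
  if (total == 0 || sum(counts) == 0) return(NA_character_)
  top <- names(counts)[which.max(counts)]
  if (max(counts) / total > 0.5) top else NA_character_
}

# naive UPGMA returning the cophenetic distance matrix
oracle_upgma_cophenetic <- function(dm) {
  labels <- rownames(dm)
  n <- length(labels)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, length(clusters))
  d <- dm
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  repeat {
    idx <- which(active)
    if (length(idx) < 2) break
    best <- c(NA, NA); bestd <- Inf
    for (i in idx) for (j in idx) {
      if (i < j && d[i, j] < bestd) { bestd <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    mi <- clusters[[i]]; mj <- clusters[[j]]
    for (a in mi) for (b in mj) {
      coph[a, b] <- coph[b, a] <- bestd
    }
    new <- c(mi, mj)
    # size-weighted average linkage update
    dnew <- rep(NA_real_, nrow(d))
    for (k in idx) {
      if (k == i || k == j) next
      dnew[k] <- (length(mi) * d[i, k] + length(mj) * d[j, k]) /
        (length(mi) + length(mj))
    }
    d <- rbind(cbind(d, dnew), c(dnew, NA))
    clusters[[length(clusters) + 1]] <- new
    active <- c(active, TRUE)
    active[c(i, j)] <- FALSE
  }
  coph
}

# tiny refdb + manifest builders shared by several files
tiny_refdb <- function(n = 3, seed = 11) {
  generate_reference_db(n, seed = seed)
}

tiny_manifest <- function(refdb, n_colonies = 2) {
  fwd <- generate_barcodes(3, seed = 5)
  rev <- generate_barcodes(n_colonies, seed = 6)
  dplyr::bind_rows(
    tibble::tibble(sample_id = "S1", fwd_barcode = fwd[1],
                   rev_barcode = NA_character_, plate_group = "S1",
                   role = "inoculum", colonies = NA_integer_),
    tibble::tibble(sample_id = "S2", fwd_barcode = fwd[2],
                   rev_barcode = NA_character_, plate_group = "S2",
                   role = "scraped", colonies = 40L),
    tibble::tibble(sample_id = sprintf("PG1_C%02d", seq_len(n_colonies)),
                   fwd_barcode = fwd[3], rev_barcode = rev,
                   plate_group = "PG1", role = "colony",
                   colonies = NA_integer_)
  ) |>
    dplyr::mutate(fwd_primer = "GTTYGATYMTGGCTCAG",
                  rev_primer = "TGCTGCCTCCCGTAGGAGT",
                  sponge = "AA", medium = "MA", surface = "agar", day = 15L) |>
    dplyr::select(dplyr::all_of(culturoscope:::MANIFEST_COLS))
}
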