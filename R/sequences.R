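#' Build a sequence tibble
#'
#' Sequence collections are plain tibbles with columns `id`, `bases` and an
#' optional `quality` list-column of per-base Phred integers; every function
#' in the package that consumes or produces sequences uses this shape so that
#' collections compose with dplyr verbs.
#'
#' @param id character vector of unique, non-empty record ids.
#' @param bases character vector of sequences over `A,C,G,T,N` (reference and
#'   primer sequences may additionally carry IUPAC ambiguity codes).
#' @param quality optional list of integer vectors, one per record, each the
#'   same length as its sequence.
#' @return A tibble with columns `id`, `bases` and (if supplied) `quality`.
#' @export
seq_tbl <- function(id, bases, quality = NULL) {
  id <- as.character(id)
  bases <- toupper(as.character(bases))
  if (length(id) != length(bases)) {
    abort("`id` and `bases` must have the same length")
  }
  if (anyNA(id) || any(!nzchar(id))) abort("sequence ids must be non-empty")
  if (anyDuplicated(id)) {
    abort(paste0("duplicate sequence id(s): ",
                 paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  if (any(!nzchar(bases))) {
    abort(paste0("empty sequence for id(s): ",
                 paste(id[!nzchar(bases)], collapse = ", ")))
  }
  out <- tibble(id = id, bases = bases)
  if (!is.null(quality)) {
    quality <- map(quality, as.integer)
    bad <- nchar(bases) != lengths(quality)
    if (any(bad)) {
      abort(paste0("quality length differs from sequence length for: ",
                   paste(id[bad], collapse = ", ")))
    }
    out$quality <- quality
  }
  out
}

#' Read a FASTA file into a sequence tibble
#'
#' @param path path to a FASTA file.
#' @return A tibble with columns `id` and `bases`; record order is preserved
#'   and whitespace inside sequences is removed. Duplicate ids or empty
#'   sequences raise an error.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (file.size(path) == 0L) return(seq_tbl(character(), character()))
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) abort(paste0("malformed FASTA in ", path, ": ",
                                     conditionMessage(e)))
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- gsub("\\s+", "", as.character(set))
  names(seqs) <- NULL
  seq_tbl(ids, seqs)
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs a sequence tibble (see [seq_tbl()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(setNames(seqs$bases, seqs$id))
  Biostrings::writeXStringSet(set, path, format = "fasta", width = 80L)
  invisible(path)
}

#' Read a FASTQ file (Phred+33) into a sequence tibble
#'
#' The file must be in four-line-per-record form. Quality strings are decoded
#' to integer Phred scores.
#'
#' @param path path to a FASTQ file.
#' @return A tibble with columns `id`, `bases` and `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (file.size(path) == 0L) {
    return(seq_tbl(character(), character(), list()))
  }
  validate_fastq_lines(path)
  set <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      # harmless notice about dropped metadata columns during coercion
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  quals <- map(as(Biostrings::quality(set), "IntegerList"), as.integer)
  names(quals) <- NULL
  seqs <- as.character(set)
  names(seqs) <- NULL
  seq_tbl(ids, seqs, quals)
}

# Biostrings silently normalises records whose quality string length differs
# from the sequence length, so the structural check is done on the raw lines.
validate_fastq_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    abort(paste0("malformed FASTQ in ", path,
                 ": number of lines is not a multiple of 4"))
  }
  heads <- lines[seq(1L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  bad_head <- !startsWith(heads, "@")
  if (any(bad_head)) {
    abort(paste0("malformed FASTQ header at line ",
                 (which(bad_head)[1L] - 1L) * 4L + 1L, " of ", path))
  }
  if (any(!startsWith(plus, "+"))) {
    abort(paste0("malformed FASTQ separator near line ",
                 (which(!startsWith(plus, "+"))[1L] - 1L) * 4L + 3L,
                 " of ", path))
  }
  bad_len <- nchar(seqs) != nchar(quals)
  if (any(bad_len)) {
    abort(paste0("sequence/quality length mismatch for record at line ",
                 (which(bad_len)[1L] - 1L) * 4L + 1L, " of ", path))
  }
  invisible(TRUE)
}

#' Write a sequence tibble to FASTQ (Phred+33)
#'
#' @inheritParams write_fasta
#' @export
write_fastq <- function(seqs, path) {
  if (is.null(seqs$quality)) abort("write_fastq() needs a `quality` column")
  qual_chr <- map_chr(seqs$quality, function(q) {
    rawToChar(as.raw(pmin(pmax(q, 0L), 93L) + 33L))
  })
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(seqs) > 0) {
    writeLines(paste0("@", seqs$id, "\n", seqs$bases, "\n+\n", qual_chr), con)
  }
  invisible(path)
}
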