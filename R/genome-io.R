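# Reading/writing standard formats, N-gap cataloguing, assembly statistics.
# Sequences travel as tibbles of (id, seq) with seq an uppercase string over
# {A,C,G,T,N}. Coordinates are 0-based half-open internally; GFF3 is written
# 1-based inclusive and BED 0-based half-open.

#' Read a FASTA file into a sequence tibble
#'
#' Reads a (multi-record) nucleotide FASTA. Sequences are uppercased and any
#' IUPAC ambiguity code other than A/C/G/T/N is replaced by `N`; the number of
#' substituted bases is reported via a message and attached as the
#' `iupac_substitutions` attribute.
#'
#' @param path path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `seq`, in file order, with attribute `iupac_substitutions`.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgt"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ", conditionMessage(e))
  )
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("malformed FASTA header (empty id) in ", path)
  seqs <- toupper(as.character(set))
  n_sub <- sum(vapply(seqs, function(s) {
    nchar(s) - sum(charcount_acgtn(s))
  }, numeric(1)))
  if (n_sub > 0) {
    seqs <- vapply(seqs, normalize_to_acgtn, character(1), USE.NAMES = FALSE)
    message(n_sub, " non-ACGTN base(s) replaced by N")
  }
  out <- tibble::tibble(id = ids, seq = unname(seqs))
  attr(out, "iupac_substitutions") <- as.integer(n_sub)
  out
}

# count of A/C/G/T/N characters in s (vector of length 1)
charcount_acgtn <- function(s) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  sum(v %in% c("A", "C", "G", "T", "N"))
}

normalize_to_acgtn <- function(s) {
  gsub("[^ACGTN]", "N", s)
}

#' Write a sequence tibble to FASTA
#'
#' @param records tibble with columns `id`, `seq`.
#' @param path output path.
#' @param width line width for sequence wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Catalogue N-gaps in a sequence
#'
#' Finds the maximal runs of `N` of length at least `min_len` in one sequence
#' record. Runs touching either end of the sequence are reported too (they are
#' genuine gaps; downstream closure refuses them for lack of a second flank).
#'
#' @param record one-row tibble (or list) with `id` and `seq`, e.g. one row of
#'   [read_fasta()].
#' @param min_len minimum run length to report (default 1).
#' @return tibble with columns `seq_id`, `start`, `end` (0-based half-open) and
#'   `length`, sorted by `start`.
#' @examples
#' scan_gaps(tibble::tibble(id = "s", seq = "ACGTNNNNACGT"))
#' @export
scan_gaps <- function(record, min_len = 1) {
  stopifnot(min_len >= 1)
  id <- record$id[[1]]
  seq <- record$seq[[1]]
  m <- gregexpr("N+", seq)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), length = integer()))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  keep <- len >= min_len
  tibble::tibble(seq_id = id, start = start[keep],
                 end = start[keep] + len[keep], length = len[keep])
}

#' N50 of a set of lengths
#'
#' The largest length L such that pieces of length >= L together cover at
#' least half of the total.
#'
#' @param lengths positive integer vector (scaffold/contig lengths).
#' @return integer N50.
#' @examples
#' n50(c(10, 4, 3, 2, 1)) # 10
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) stop("n50: empty input")
  stopifnot(all(lengths > 0))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(s)
  s[which(cum >= sum(s) / 2)[1]]
}

#' Write a gap catalogue (or any interval tibble) as BED
#'
#' @param intervals tibble with `seq_id`, `start`, `end` (0-based half-open)
#'   and optionally a `name`-like fourth column.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(chrom = intervals$seq_id,
                   start = intervals$start,
                   end = intervals$end)
  if ("name" %in% names(intervals)) df$name <- intervals$name
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#' @param path BED path (first three columns used; optional fourth kept as `name`).
#' @return tibble with `seq_id`, `start`, `end`, `length` and optional `name`.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  out <- tibble::tibble(seq_id = as.character(df[[1]]),
                        start = as.integer(df[[2]]),
                        end = as.integer(df[[3]]))
  out$length <- out$end - out$start
  if (ncol(df) >= 4) out$name <- as.character(df[[4]])
  out
}

#' Write gene/TE models as GFF3
#'
#' Minimal single-interval feature writer: internal 0-based half-open
#' coordinates become 1-based inclusive on disk.
#'
#' @param features tibble with `seq_id`, `source`, `type`, `start`, `end`,
#'   `strand`, `id` and optionally `parent`.
#' @param path output path.
#' @export
write_gff3 <- function(features, path) {
  attrs <- paste0("ID=", features$id)
  if ("parent" %in% names(features)) {
    has_par <- !is.na(features$parent)
    attrs[has_par] <- paste0(attrs[has_par], ";Parent=", features$parent[has_par])
  }
  lines <- paste(features$seq_id,
                 features$source,
                 features$type,
                 features$start + 1L,
                 features$end,
                 ".",
                 features$strand,
                 ".",
                 attrs,
                 sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a GFF3 file written by [write_gff3()] (or any simple single-line
#' features); coordinates returned 0-based half-open.
#' @param path GFF3 path.
#' @return tibble `seq_id`, `source`, `type`, `start`, `end`, `strand`, `id`,
#'   `parent`.
#' @export
read_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (length(ln) == 0) {
    return(tibble::tibble(seq_id = character(), source = character(),
                          type = character(), start = integer(), end = integer(),
                          strand = character(), id = character(), parent = character()))
  }
  parts <- strsplit(ln, "\t", fixed = TRUE)
  get <- function(i) vapply(parts, `[[`, character(1), i)
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    out <- rep(NA_character_, length(attrs))
    hit <- vapply(attrs, function(a) grepl(paste0("(^|;)", key, "="), a), logical(1))
    out[hit] <- sub(paste0("^(.*;)?", key, "="), "", m)
    out
  }
  attrs <- get(9)
  tibble::tibble(seq_id = get(1), source = get(2), type = get(3),
                 start = as.integer(get(4)) - 1L, end = as.integer(get(5)),
                 strand = get(7),
                 id = attr_field(attrs, "ID"),
                 parent = attr_field(attrs, "Parent"))
}

#' Reverse complement of a nucleotide string (A/C/G/T/N)
#' @param seq nucleotide string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}
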