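# Seed-and-extend local aligner, the workhorse behind gap closure, orthology
# and flank placement. The compiled core lives in src/aligner.cpp.

#' Build a k-mer index over target sequences
#'
#' Indexes every k-mer (no N) of the target set. Seeds occurring more than
#' `max_occ` times are dropped (a deterministic stand-in for repeat
#' soft-masking).
#'
#' @param targets tibble with `id`, `seq` columns (e.g. [read_fasta()] output).
#' @param k seed length, 8..31 (default 15).
#' @param max_occ repeat-seed occurrence cap (default 100).
#' @return an object of class `kmer_index`.
#' @export
build_index <- function(targets, k = 15, max_occ = 100) {
  stopifnot(all(c("id", "seq") %in% names(targets)))
  if (k < 8 || k > 31) stop("k must be in [8, 31]")
  ptr <- cpp_build_index(targets$id, targets$seq, as.integer(k), as.integer(max_occ))
  structure(list(ptr = ptr, k = k, max_occ = max_occ,
                 target_ids = targets$id),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat("<kmer_index> k =", info$k, "| targets:", info$n_targets,
      "| distinct seeds:", format(info$n_kmers, big.mark = ","), "\n")
  invisible(x)
}

#' Local alignment of queries against an indexed target set
#'
#' Both strands are searched (the query is reverse-complemented for the minus
#' strand; reported coordinates always refer to the forward strands of query
#' and target). Seeds are clustered by diagonal and extended by affine-gap
#' local dynamic programming (match +1, mismatch -1, gap open -2, gap
#' extend -1). Overlapping hits on the same (target, strand) within
#' `merge_dist` bp are merged keeping the higher score.
#'
#' @param queries tibble with `id`, `seq` (one or many queries).
#' @param index a [build_index()] object.
#' @param min_identity minimum identity (matches / alignment columns), default 0.90.
#' @param min_len minimum alignment length in columns, default 50.
#' @param merge_dist merge distance for overlapping hits (default 10).
#' @return tibble of hits sorted per query by score descending (ties by
#'   target id then `t_start`): `query_id`, `target_id`, `q_start`, `q_end`,
#'   `t_start`, `t_end`, `strand`, `matches`, `mismatches`, `gap_opens`,
#'   `length`, `identity`, `score`.
#' @export
local_align <- function(queries, index, min_identity = 0.90, min_len = 50,
                        merge_dist = 10) {
  stopifnot(inherits(index, "kmer_index"))
  if (any(nchar(queries$seq) < index$k)) {
    stop("query shorter than seed length k = ", index$k)
  }
  df <- cpp_local_align(index$ptr, queries$id, queries$seq,
                        min_identity, as.integer(min_len), as.integer(merge_dist))
  tibble::as_tibble(df)
}

#' Occurrence count of one literal k-mer in an index
#' @param index a [build_index()] object.
#' @param kmer a string of length `k` over A/C/G/T.
#' @return integer count (0 if absent, N-containing, or capped away).
#' @export
kmer_count <- function(index, kmer) {
  cpp_kmer_count(index$ptr, kmer)
}

#' Write hits in a 12-column pairwise-hit table
#'
#' Tab-separated dump: query, target, identity%, length, mismatches, gap
#' opens, q_start, q_end, t_start, t_end, score, strand.
#'
#' @param hits a [local_align()] tibble.
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  out <- data.frame(query = hits$query_id, target = hits$target_id,
                    identity = round(100 * hits$identity, 2),
                    length = hits$length, mismatches = hits$mismatches,
                    gaps = hits$gap_opens,
                    q_start = hits$q_start, q_end = hits$q_end,
                    t_start = hits$t_start, t_end = hits$t_end,
                    score = hits$score, strand = hits$strand)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
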