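# Reciprocal-best-hit ortholog pairing between a donor gene set and the
# polyploid focal arm, the lost-gene classification cascade (ortholog on the
# focal arm -> homoeologue -> paralog elsewhere -> lost), and loss-density
# profiles along the arm.

#' Orthology thresholds
#' @param min_identity minimum hit identity before best-hit selection (0.70).
#' @param min_coverage minimum query coverage, aligned query span / query
#'   length (0.50).
#' @param k,max_occ aligner index parameters.
#' @return an `ortho_thresholds` list.
#' @export
ortho_thresholds <- function(min_identity = 0.70, min_coverage = 0.50,
                             k = 15, max_occ = 100) {
  structure(as.list(environment()), class = "ortho_thresholds")
}

# best hit per query after identity/coverage filtering; ties flagged
best_hits <- function(queries, targets, th) {
  idx <- build_index(targets, k = th$k, max_occ = th$max_occ)
  hits <- local_align(queries, idx, min_identity = th$min_identity,
                      min_len = th$k)
  qlen <- setNames(nchar(queries$seq), queries$id)
  hits <- dplyr::filter(hits,
                        (.data$q_end - .data$q_start) / qlen[.data$query_id] >=
                          th$min_coverage)
  if (nrow(hits) == 0) {
    return(tibble::tibble(query_id = character(), target_id = character(),
                          score = integer(), identity = numeric(),
                          ambiguous = logical()))
  }
  hits %>%
    dplyr::group_by(.data$query_id) %>%
    dplyr::summarise(
      target_id = .data$target_id[which.max(.data$score)],
      identity = .data$identity[which.max(.data$score)],
      # a tie between *different* targets makes the best hit ambiguous
      ambiguous = dplyr::n_distinct(
        .data$target_id[.data$score == max(.data$score)]) > 1,
      score = max(.data$score),
      .groups = "drop")
}

#' Reciprocal best hits between two gene sets
#'
#' Nucleotide CDS-vs-CDS search through the internal aligner in both
#' directions; a pair is emitted iff each gene is the other's best hit.
#' Ties for best hit flag the pair `ambiguous` (excluded from downstream
#' dN/dS selection scans).
#'
#' @param set_a,set_b gene tibbles with `gene_id` and `cds` columns.
#' @param thresholds an [ortho_thresholds()].
#' @return tibble: `gene_a`, `gene_b`, `score_ab`, `score_ba`, `identity`,
#'   `ambiguous`.
#' @export
reciprocal_best_hits <- function(set_a, set_b,
                                 thresholds = ortho_thresholds()) {
  if (nrow(set_a) == 0 || nrow(set_b) == 0) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          score_ab = integer(), score_ba = integer(),
                          identity = numeric(), ambiguous = logical()))
  }
  qa <- tibble::tibble(id = set_a$gene_id, seq = set_a$cds)
  qb <- tibble::tibble(id = set_b$gene_id, seq = set_b$cds)
  ab <- best_hits(qa, qb, thresholds)
  ba <- best_hits(qb, qa, thresholds)
  m <- dplyr::inner_join(ab, ba,
                         by = c("query_id" = "target_id",
                                "target_id" = "query_id"),
                         suffix = c("_ab", "_ba"))
  tibble::tibble(gene_a = m$query_id, gene_b = m$target_id,
                 score_ab = m$score_ab, score_ba = m$score_ba,
                 identity = m$identity_ab,
                 ambiguous = m$ambiguous_ab | m$ambiguous_ba)
}

#' Classify donor genes absent from the focal arm
#'
#' Cascade per donor gene: (1) an RBH partner on the focal arm gives
#' `ortholog_on_focal_arm`; otherwise (2) any hit passing the thresholds in a
#' homoeologue set gives `homoeologue`; otherwise (3) any such hit in the
#' remaining genome sets gives `paralog_elsewhere`; otherwise `lost`.
#'
#' @param donor_genes donor gene tibble (`gene_id`, `cds`).
#' @param focal_arm_genes focal-arm gene tibble.
#' @param homoeologue_sets list of gene tibbles (may be empty).
#' @param rest_of_genome_sets list of gene tibbles (may be empty).
#' @param thresholds an [ortho_thresholds()].
#' @return tibble: `gene_id`, `classification`, `evidence_id` (partner or hit
#'   target), plus the RBH pair table as attribute `rbh`.
#' @export
classify_absent_genes <- function(donor_genes, focal_arm_genes,
                                  homoeologue_sets = list(),
                                  rest_of_genome_sets = list(),
                                  thresholds = ortho_thresholds()) {
  rbh <- reciprocal_best_hits(donor_genes, focal_arm_genes, thresholds)
  paired <- rbh$gene_a
  cls <- setNames(rep("lost", nrow(donor_genes)), donor_genes$gene_id)
  evid <- setNames(rep(NA_character_, nrow(donor_genes)), donor_genes$gene_id)
  cls[paired] <- "ortholog_on_focal_arm"
  evid[paired] <- rbh$gene_b[match(paired, rbh$gene_a)]

  presence_scan <- function(ids, sets) {
    found <- setNames(rep(NA_character_, length(ids)), ids)
    if (length(ids) == 0) return(found)
    q <- donor_genes[match(ids, donor_genes$gene_id), ]
    qt <- tibble::tibble(id = q$gene_id, seq = q$cds)
    for (s in sets) {
      if (nrow(s) == 0) next
      remaining <- names(found)[is.na(found)]
      if (length(remaining) == 0) break
      bh <- best_hits(qt[qt$id %in% remaining, , drop = FALSE],
                      tibble::tibble(id = s$gene_id, seq = s$cds),
                      thresholds)
      if (nrow(bh) > 0) found[bh$query_id] <- bh$target_id
    }
    found
  }

  unpaired <- names(cls)[cls == "lost"]
  hom <- presence_scan(unpaired, homoeologue_sets)
  hit <- names(hom)[!is.na(hom)]
  cls[hit] <- "homoeologue"; evid[hit] <- hom[hit]

  still <- names(cls)[cls == "lost"]
  par <- presence_scan(still, rest_of_genome_sets)
  hit <- names(par)[!is.na(par)]
  cls[hit] <- "paralog_elsewhere"; evid[hit] <- par[hit]

  out <- tibble::tibble(gene_id = donor_genes$gene_id,
                        classification = unname(cls[donor_genes$gene_id]),
                        evidence_id = unname(evid[donor_genes$gene_id]))
  attr(out, "rbh") <- rbh
  out
}

#' Lost-gene density along the arm
#'
#' Counts `classification == "lost"` per coordinate bin of the donor gene
#' positions.
#'
#' @param loss_records a [classify_absent_genes()] tibble.
#' @param gene_coords tibble with `gene_id`, `start`, `end` (donor arm).
#' @param bin_size bin width in bases.
#' @param arm_length total arm length (defaults to max gene end).
#' @param telomere_right if TRUE bins are ordered centromere -> telomere with
#'   the telomere at the high-coordinate end (default); FALSE flips them.
#' @return tibble: `bin`, `bin_start`, `bin_end`, `n_lost`.
#' @export
loss_density_profile <- function(loss_records, gene_coords, bin_size,
                                 arm_length = NULL, telomere_right = TRUE) {
  stopifnot(bin_size > 0)
  if (is.null(arm_length)) arm_length <- max(gene_coords$end)
  lost <- loss_records$gene_id[loss_records$classification == "lost"]
  mid <- (gene_coords$start + gene_coords$end) / 2
  names(mid) <- gene_coords$gene_id
  n_bins <- ceiling(arm_length / bin_size)
  edges <- (0:n_bins) * bin_size
  counts <- rep(0L, n_bins)
  if (length(lost) > 0) {
    b <- pmin(n_bins, floor(mid[lost] / bin_size) + 1)
    tb <- table(b)
    counts[as.integer(names(tb))] <- as.integer(tb)
  }
  out <- tibble::tibble(bin = seq_len(n_bins),
                        bin_start = edges[-length(edges)],
                        bin_end = pmin(edges[-1], arm_length),
                        n_lost = counts)
  if (!telomere_right) {
    out$n_lost <- rev(out$n_lost)
  }
  out
}
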