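# e-PCR style placement of primer-pair markers, QTL interval anchoring from
# placed flanking markers, and gene/QTL overlap linking.

#' Place a primer pair in a genome (electronic PCR)
#'
#' The forward primer is matched on either strand with at most `max_mismatch`
#' mismatches and zero mismatches in its 3'-terminal `three_prime_exact`
#' bases; the reverse primer's reverse complement must match downstream on the
#' same molecule under the same rule. All valid placements are returned.
#'
#' @param primer_fwd,primer_rev primer sequences, length >= 15.
#' @param genome tibble (id, seq).
#' @param max_mismatch maximum mismatches per primer (default 1).
#' @param three_prime_exact 3'-terminal bases that must match exactly (3).
#' @param size_window optional c(min, max) accepted product length.
#' @return tibble sorted by position: `seq_id`, `product_start`,
#'   `product_end` (0-based half-open, both primers included), `strand` (of
#'   the forward primer), `mismatches_fwd`, `mismatches_rev`, `product_len`.
#' @export
epcr_place <- function(primer_fwd, primer_rev, genome, max_mismatch = 1,
                       three_prime_exact = 3, size_window = NULL) {
  if (nchar(primer_fwd) < 15 || nchar(primer_rev) < 15) {
    stop("epcr_place: primers must be >= 15 bases")
  }
  lf <- nchar(primer_fwd); lr <- nchar(primer_rev)
  out <- list()
  for (row in seq_len(nrow(genome))) {
    txt <- genome$seq[[row]]
    sid <- genome$id[[row]]
    # forward orientation: fwd on +, revcomp(rev) downstream (rev binds -)
    f <- cpp_scan_primer(txt, primer_fwd, max_mismatch, three_prime_exact, TRUE)
    r <- cpp_scan_primer(txt, revcomp(primer_rev), max_mismatch,
                         three_prime_exact, FALSE)
    if (nrow(f) > 0 && nrow(r) > 0) {
      for (i in seq_len(nrow(f))) {
        ok <- r$pos >= f$pos[i]
        for (j in which(ok)) {
          out[[length(out) + 1]] <- tibble::tibble(
            seq_id = sid, product_start = f$pos[i],
            product_end = r$pos[j] + lr, strand = "+",
            mismatches_fwd = f$mismatches[i], mismatches_rev = r$mismatches[j])
        }
      }
    }
    # reverse orientation: rev primer on +, revcomp(fwd) downstream
    f2 <- cpp_scan_primer(txt, primer_rev, max_mismatch, three_prime_exact, TRUE)
    r2 <- cpp_scan_primer(txt, revcomp(primer_fwd), max_mismatch,
                          three_prime_exact, FALSE)
    if (nrow(f2) > 0 && nrow(r2) > 0) {
      for (i in seq_len(nrow(f2))) {
        ok <- r2$pos >= f2$pos[i]
        for (j in which(ok)) {
          out[[length(out) + 1]] <- tibble::tibble(
            seq_id = sid, product_start = f2$pos[i],
            product_end = r2$pos[j] + lf, strand = "-",
            mismatches_fwd = r2$mismatches[j], mismatches_rev = f2$mismatches[i])
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(seq_id = character(), product_start = integer(),
                          product_end = integer(), strand = character(),
                          mismatches_fwd = integer(), mismatches_rev = integer(),
                          product_len = integer()))
  }
  res <- dplyr::bind_rows(out)
  res$product_len <- res$product_end - res$product_start
  if (!is.null(size_window)) {
    res <- dplyr::filter(res, .data$product_len >= size_window[1],
                         .data$product_len <= size_window[2])
  }
  dplyr::arrange(res, .data$seq_id, .data$product_start)
}

#' Place a table of markers
#'
#' @param markers tibble: `marker_id`, `fwd_primer`, `rev_primer`, optional
#'   `expected_size` (used as a +/- `size_tol` window when present).
#' @param genome tibble (id, seq).
#' @param max_mismatch,three_prime_exact see [epcr_place()].
#' @param size_tol relative half-width of the size window around
#'   `expected_size` (default 0.2; ignored when no expected size).
#' @return tibble of hits with `marker_id` prepended.
#' @export
place_markers <- function(markers, genome, max_mismatch = 1,
                          three_prime_exact = 3, size_tol = 0.2) {
  purrr::pmap_dfr(markers, function(marker_id, fwd_primer, rev_primer,
                                    expected_size = NA, ...) {
    win <- if (!is.na(expected_size)) {
      c(floor(expected_size * (1 - size_tol)),
        ceiling(expected_size * (1 + size_tol)))
    } else NULL
    h <- epcr_place(fwd_primer, rev_primer, genome, max_mismatch,
                    three_prime_exact, win)
    if (nrow(h) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(marker_id = marker_id), h)
  })
}

#' Anchor QTLs from their placed flanking markers
#'
#' A QTL interval spans the min..max of its markers' product midpoints; a
#' single-marker QTL becomes a point interval expanded by `point_radius`.
#' QTLs with no placed marker are reported unanchored.
#'
#' @param marker_hits a [place_markers()] tibble.
#' @param qtl_table tibble: `qtl_id`, `trait`, `marker_id` (one row per
#'   QTL-marker link).
#' @param point_radius expansion radius for single-marker QTLs (default 1e6).
#' @return tibble: `qtl_id`, `trait`, `seq_id`, `start`, `end`, `n_markers`,
#'   `anchored`.
#' @export
anchor_qtls <- function(marker_hits, qtl_table, point_radius = 1e6) {
  mids <- marker_hits %>%
    dplyr::group_by(.data$marker_id, .data$seq_id) %>%
    dplyr::summarise(mid = (min(.data$product_start) + max(.data$product_end)) / 2,
                     .groups = "drop")
  purrr::map_dfr(split(qtl_table, qtl_table$qtl_id), function(q) {
    hit <- dplyr::filter(mids, .data$marker_id %in% q$marker_id)
    if (nrow(hit) == 0) {
      return(tibble::tibble(qtl_id = q$qtl_id[1], trait = q$trait[1],
                            seq_id = NA_character_, start = NA_real_,
                            end = NA_real_, n_markers = 0L, anchored = FALSE))
    }
    sid <- hit$seq_id[1]
    hit <- dplyr::filter(hit, .data$seq_id == sid)
    lo <- min(hit$mid); hi <- max(hit$mid)
    if (nrow(hit) == 1) { lo <- lo - point_radius; hi <- hi + point_radius }
    tibble::tibble(qtl_id = q$qtl_id[1], trait = q$trait[1], seq_id = sid,
                   start = max(0, lo), end = hi, n_markers = nrow(hit),
                   anchored = TRUE)
  })
}

#' Link genes to anchored QTL intervals
#'
#' A gene links to a QTL iff its midpoint lies within the anchored interval
#' expanded by `window`; the distance is 0 inside the raw interval, else the
#' distance to the nearest edge.
#'
#' @param genes tibble: `gene_id`, `seq_id`, `start`, `end`.
#' @param anchors an [anchor_qtls()] tibble (unanchored rows are skipped).
#' @param window linkage window in bases (default 3e6, a typical
#'   marker-flanked region size).
#' @return tibble: `gene_id`, `qtl_id`, `trait`, `distance`.
#' @export
link_genes_to_qtls <- function(genes, anchors, window = 3e6) {
  stopifnot(window >= 0)
  anch <- dplyr::filter(anchors, .data$anchored)
  if (nrow(anch) == 0 || nrow(genes) == 0) {
    return(tibble::tibble(gene_id = character(), qtl_id = character(),
                          trait = character(), distance = numeric()))
  }
  mid <- (genes$start + genes$end) / 2
  out <- list()
  for (i in seq_len(nrow(anch))) {
    sel <- genes$seq_id == anch$seq_id[i] &
      mid >= anch$start[i] - window & mid <= anch$end[i] + window
    if (!any(sel)) next
    d <- pmax(0, pmax(anch$start[i] - mid[sel], mid[sel] - anch$end[i]))
    out[[length(out) + 1]] <- tibble::tibble(
      gene_id = genes$gene_id[sel], qtl_id = anch$qtl_id[i],
      trait = anch$trait[i], distance = d)
  }
  if (length(out) == 0) {
    return(tibble::tibble(gene_id = character(), qtl_id = character(),
                          trait = character(), distance = numeric()))
  }
  dplyr::bind_rows(out)
}
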