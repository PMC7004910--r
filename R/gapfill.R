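# N-gap closure: cut flanks next to each gap, align them to filler pools with
# the internal aligner, apply consistency rules (same filler, same strand,
# correct order, anchored at the gap edge, plausible patch length), patch the
# sequence and report per-source closure counts.

#' Closure rule set
#'
#' @param flank_len flank length cut next to each gap (default 1500 bp).
#' @param anchor_tol maximum distance (bp) between a flank's gap-adjacent end
#'   and the end of its alignment (default 10).
#' @param max_flank_overlap most negative implied patch length accepted, as a
#'   positive number (default 200); more negative is rejected.
#' @param max_patch largest accepted patch (default 20000 bp).
#' @param min_hit_identity,min_hit_len aligner acceptance thresholds for
#'   flank hits (defaults 0.95 and 200 bp).
#' @param k,max_occ seed length and repeat cap for the pool indexes.
#' @return a `closure_rules` list.
#' @export
closure_rules <- function(flank_len = 1500, anchor_tol = 10,
                          max_flank_overlap = 200, max_patch = 20000,
                          min_hit_identity = 0.95, min_hit_len = 200,
                          k = 15, max_occ = 100) {
  structure(as.list(environment()), class = "closure_rules")
}

#' Extract the two flanks of a gap
#'
#' Flanks are truncated at the sequence ends and at adjacent gaps so they
#' never contain N.
#'
#' @param assembly tibble (id, seq) holding the gapped sequence.
#' @param gap one row of a gap catalogue (`start`, `end`).
#' @param flank_len requested flank length (default 1500).
#' @return list: `gap`, `left_seq`, `right_seq` (empty string when absent),
#'   `left_truncated`, `right_truncated`, `terminal`.
#' @export
extract_flanks <- function(assembly, gap, flank_len = 1500) {
  seq <- assembly$seq[[1]]
  len <- nchar(seq)
  gs <- gap$start[[1]]; ge <- gap$end[[1]]
  stopifnot(gs >= 0, ge <= len, gs < ge)

  left_from <- max(0, gs - flank_len)
  left <- substr(seq, left_from + 1, gs)
  # truncate at the nearest N (adjacent gap) inside the window
  m <- gregexpr("N+", left)[[1]]
  if (m[1] != -1) {
    lastN <- max(as.integer(m) + attr(m, "match.length") - 1)
    left <- substr(left, lastN + 1, nchar(left))
  }
  right_to <- min(len, ge + flank_len)
  right <- substr(seq, ge + 1, right_to)
  m <- gregexpr("N+", right)[[1]]
  if (m[1] != -1) {
    right <- substr(right, 1, min(as.integer(m)) - 1)
  }
  list(gap = list(start = gs, end = ge, length = ge - gs),
       left_seq = left, right_seq = right,
       flank_len_requested = flank_len,
       left_truncated = nchar(left) < flank_len,
       right_truncated = nchar(right) < flank_len,
       terminal = nchar(left) == 0 || nchar(right) == 0)
}

unclosed_event <- function(flanks, reason, source_label = NA_character_) {
  tibble::tibble(start = flanks$gap$start, end = flanks$gap$end,
                 gap_len = flanks$gap$length, status = "unclosed",
                 source_label = source_label, filler_id = NA_character_,
                 strand = NA_character_, patch_seq = "", patch_len = NA_integer_,
                 overlap_trim = NA_integer_, reject_reason = reason)
}

#' Decide the closure of one gap against one filler pool
#'
#' Accepts iff some filler carries a left-flank hit and a right-flank hit on
#' the same strand, each anchored within `anchor_tol` of its flank's
#' gap-adjacent end, in the correct mutual order, with an implied patch length
#' in `[-max_flank_overlap, max_patch]` and an N-free patch. A negative
#' implied length gives status `merged_overlap` (flanks overlap; trim amount
#' recorded). Among competing fillers the highest summed hit score wins, ties
#' broken by filler id.
#'
#' @param flanks an [extract_flanks()] result.
#' @param left_hits,right_hits [local_align()] hits of the two flanks against
#'   ONE pool.
#' @param pool the pool tibble (id, seq) the hits refer to.
#' @param rules a [closure_rules()].
#' @param source_label pool name recorded in the event.
#' @return one-row closure-event tibble: `start`, `end`, `gap_len`, `status`
#'   (closed / merged_overlap / unclosed), `source_label`, `filler_id`,
#'   `strand`, `patch_seq`, `patch_len`, `overlap_trim`, `reject_reason`.
#' @export
propose_closure <- function(flanks, left_hits, right_hits, pool, rules,
                            source_label = NA_character_) {
  if (flanks$terminal) return(unclosed_event(flanks, "terminal", source_label))
  llen <- nchar(flanks$left_seq); rlen <- nchar(flanks$right_seq)
  lh <- dplyr::filter(left_hits, llen - .data$q_end <= rules$anchor_tol)
  rh <- dplyr::filter(right_hits, .data$q_start <= rules$anchor_tol)
  if (nrow(lh) == 0 || nrow(rh) == 0) {
    return(unclosed_event(flanks, "no anchored hit", source_label))
  }
  cand <- dplyr::inner_join(lh, rh, by = c("target_id", "strand"),
                            suffix = c("_l", "_r"),
                            relationship = "many-to-many")
  if (nrow(cand) == 0) {
    return(unclosed_event(flanks, "no common filler", source_label))
  }
  # inner boundaries projected onto the forward filler strand; on strand -
  # the left flank sits to the RIGHT of the right flank on the forward filler
  plus <- cand$strand == "+"
  inner_lo <- ifelse(plus, cand$t_end_l + (llen - cand$q_end_l),
                     cand$t_end_r + cand$q_start_r)
  inner_hi <- ifelse(plus, cand$t_start_r - cand$q_start_r,
                     cand$t_start_l - (llen - cand$q_end_l))
  implied <- inner_hi - inner_lo
  ok_order <- ifelse(plus, cand$t_start_l <= cand$t_start_r,
                     cand$t_start_r <= cand$t_start_l)
  ok_len <- implied >= -rules$max_flank_overlap & implied <= rules$max_patch
  keep <- ok_order & ok_len
  if (!any(keep)) {
    reason <- if (!any(ok_order)) "order/strand" else "patch length"
    return(unclosed_event(flanks, reason, source_label))
  }
  cand <- cand[keep, ]
  inner_lo <- inner_lo[keep]; inner_hi <- inner_hi[keep]; implied <- implied[keep]
  score <- cand$score_l + cand$score_r
  ord <- order(-score, cand$target_id)
  best <- ord[1]
  fid <- cand$target_id[best]
  fseq <- pool$seq[pool$id == fid][[1]]
  if (implied[best] < 0) {
    return(tibble::tibble(start = flanks$gap$start, end = flanks$gap$end,
                          gap_len = flanks$gap$length, status = "merged_overlap",
                          source_label = source_label, filler_id = fid,
                          strand = cand$strand[best], patch_seq = "",
                          patch_len = 0L,
                          overlap_trim = -implied[best],
                          reject_reason = NA_character_))
  }
  patch <- substr(fseq, inner_lo[best] + 1, inner_hi[best])
  if (cand$strand[best] == "-") patch <- revcomp(patch)
  if (grepl("N", patch)) {
    return(unclosed_event(flanks, "patch contains N", source_label))
  }
  tibble::tibble(start = flanks$gap$start, end = flanks$gap$end,
                 gap_len = flanks$gap$length, status = "closed",
                 source_label = source_label, filler_id = fid,
                 strand = cand$strand[best], patch_seq = patch,
                 patch_len = nchar(patch), overlap_trim = 0L,
                 reject_reason = NA_character_)
}

#' Close the gaps of an assembly from ordered filler pools
#'
#' Pools are tried in the order given (source priority); a gap closed or
#' merged by an earlier pool is not re-attempted, so the per-source accounting
#' is disjoint. Accepted patches are applied right-to-left so stored
#' coordinates remain valid; a liftover table maps original coordinates to the
#' patched sequence.
#'
#' @param assembly tibble (id, seq) with N-gaps.
#' @param pools named list of filler tibbles (id, seq) in priority order.
#' @param rules a [closure_rules()].
#' @param gaps optional precomputed gap catalogue; scanned if NULL.
#' @return list: `assembly` (patched tibble), `events` (closure-event tibble,
#'   one row per gap), `liftover` (tibble orig_start, orig_end, offset for
#'   every inter-gap segment).
#' @export
close_gaps <- function(assembly, pools, rules = closure_rules(), gaps = NULL) {
  if (is.null(gaps)) gaps <- scan_gaps(assembly)
  if (is.null(names(pools)) || any(!nzchar(names(pools)))) {
    stop("close_gaps: pools must be a named list (priority order)")
  }
  indexes <- lapply(pools, function(p) build_index(p, k = rules$k,
                                                   max_occ = rules$max_occ))
  events <- vector("list", nrow(gaps))
  for (gi in seq_len(nrow(gaps))) {
    flanks <- extract_flanks(assembly, gaps[gi, ], rules$flank_len)
    if (flanks$terminal) {
      events[[gi]] <- unclosed_event(flanks, "terminal")
      next
    }
    if (nchar(flanks$left_seq) < rules$min_hit_len ||
        nchar(flanks$right_seq) < rules$min_hit_len) {
      events[[gi]] <- unclosed_event(flanks, "single-flank")
      next
    }
    ev <- NULL
    for (lab in names(pools)) {
      q <- tibble::tibble(id = c("left", "right"),
                          seq = c(flanks$left_seq, flanks$right_seq))
      hits <- local_align(q, indexes[[lab]],
                         min_identity = rules$min_hit_identity,
                         min_len = rules$min_hit_len)
      cand <- propose_closure(flanks,
                              dplyr::filter(hits, .data$query_id == "left"),
                              dplyr::filter(hits, .data$query_id == "right"),
                              pools[[lab]], rules, source_label = lab)
      if (cand$status != "unclosed") { ev <- cand; break }
      if (is.null(ev)) ev <- cand  # keep the first rejection reason
    }
    events[[gi]] <- ev
  }
  events <- dplyr::bind_rows(events)
  patched <- apply_patches(assembly, events)
  list(assembly = patched$assembly, events = events,
       liftover = patched$liftover)
}

# apply closure events right-to-left; build the liftover table
apply_patches <- function(assembly, events) {
  seq <- assembly$seq[[1]]
  ev <- events[events$status != "unclosed", , drop = FALSE]
  ev <- ev[order(-ev$start), , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    s <- ev$start[i]; e <- ev$end[i]
    if (ev$status[i] == "merged_overlap") {
      # delete the N run and trim the overlap from the right flank
      e2 <- e + ev$overlap_trim[i]
      seq <- paste0(substr(seq, 1, s), substr(seq, e2 + 1, nchar(seq)))
    } else {
      seq <- paste0(substr(seq, 1, s), ev$patch_seq[i],
                    substr(seq, e + 1, nchar(seq)))
    }
  }
  # liftover: offsets accumulate left-to-right over modified intervals
  ev <- ev[order(ev$start), , drop = FALSE]
  brk_start <- c(0, ifelse(ev$status == "merged_overlap",
                           ev$end + ev$overlap_trim, ev$end))
  brk_end <- c(ev$start, nchar(assembly$seq[[1]]))
  delta <- ifelse(ev$status == "merged_overlap",
                  -(ev$gap_len + ev$overlap_trim),
                  ev$patch_len - ev$gap_len)
  offset <- cumsum(c(0, delta))
  lift <- tibble::tibble(orig_start = brk_start, orig_end = brk_end,
                         offset = offset)
  lift <- lift[lift$orig_end > lift$orig_start, , drop = FALSE]
  list(assembly = tibble::tibble(id = assembly$id[[1]], seq = seq),
       liftover = lift)
}

#' Map original coordinates through a liftover table
#'
#' @param liftover the `liftover` tibble of [close_gaps()].
#' @param pos 0-based original positions (must lie outside replaced gaps).
#' @return 0-based positions on the patched sequence (NA for positions inside
#'   a replaced interval).
#' @export
liftover_pos <- function(liftover, pos) {
  vapply(pos, function(p) {
    i <- which(liftover$orig_start <= p & p < liftover$orig_end)
    if (length(i) == 0) NA_real_ else p + liftover$offset[i[1]]
  }, numeric(1))
}

#' Per-source closure summary (gap-census shape)
#'
#' Counts per source label over non-unclosed events, total ORIGINAL gap
#' length replaced, its integer mean (halves away from zero), and total patch
#' length as an extra column; plus an overall row labelled "Total".
#'
#' @param events closure-event tibble from [close_gaps()].
#' @return tibble: `source`, `n_closed`, `gap_length_total`,
#'   `gap_length_mean`, `patch_length_total`.
#' @export
summarize_closures <- function(events) {
  ev <- dplyr::filter(events, .data$status != "unclosed")
  if (nrow(ev) == 0) {
    return(tibble::tibble(source = "Total", n_closed = 0L,
                          gap_length_total = 0, gap_length_mean = 0,
                          patch_length_total = 0))
  }
  per <- ev %>%
    dplyr::group_by(source = .data$source_label) %>%
    dplyr::summarise(n_closed = dplyr::n(),
                     gap_length_total = sum(.data$gap_len),
                     patch_length_total = sum(.data$patch_len), .groups = "drop")
  tot <- tibble::tibble(source = "Total", n_closed = sum(per$n_closed),
                        gap_length_total = sum(per$gap_length_total),
                        patch_length_total = sum(per$patch_length_total))
  out <- dplyr::bind_rows(per, tot)
  out$gap_length_mean <- round_half_away(out$gap_length_total / out$n_closed)
  dplyr::select(out, "source", "n_closed", "gap_length_total",
                "gap_length_mean", "patch_length_total")
}

# round to nearest integer, halves away from zero (as gap-census tables print)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
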