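# Synthetic chromosome-arm simulator with full truth tables: an ancestral
# (donor-like) arm carrying ORF genes and LTR retroelements; a derived
# (polyploid-arm-like) copy with controlled per-gene omega, gene losses and
# relocations and dated LTR divergence; a gapped assembly with filler pools
# whose truth is known; and primer-pair markers with unique placements.

#' Simulation configuration
#'
#' Defaults define the package's standard synthetic study: a 5 Mb arm with 200
#' ORF genes, ~40% LTR-retroelement content, 100 planted N-gaps whose true
#' fill is carried by three tiling filler pools, and 20 unique primer-pair
#' markers.
#'
#' @param seed root random seed (all stages derive their own streams from it).
#' @param arm_length arm length in bases.
#' @param n_genes number of protein-coding genes.
#' @param gene_len_codons (min, max) gene length in codons (incl. start/stop).
#' @param te_fraction approximate fraction of the arm covered by LTR elements.
#' @param te_body_len (min, max) internal-domain length of an element, bases.
#' @param ltr_len length of each long terminal repeat, bases.
#' @param per_gene_omega optional named numeric gene -> omega; when NULL,
#'   omega is drawn per gene from `omega_levels` with `omega_probs`.
#' @param omega_levels,omega_probs omega values and sampling weights.
#' @param loss_prob,reloc_prob per-gene loss / relocation probabilities in the
#'   derived arm.
#' @param rga_fraction fraction of genes tagged as disease-resistance
#'   analogues (RGA); their loss probability is multiplied by `rga_loss_mult`,
#'   emulating preferential loss of resistance genes.
#' @param rga_loss_mult RGA loss-probability multiplier.
#' @param n_categories number of non-RGA annotation categories.
#' @param subst_rate_neutral synonymous substitution rate (subs/site) applied
#'   per gene between donor and derived copies.
#' @param ltr_k_mean mean of the exponential true inter-LTR divergence K.
#' @param n_gaps number of N-gaps planted in the assembly.
#' @param gap_len_dist (min, max) gap length in bases.
#' @param protect_genes if TRUE gaps never overlap gene CDS.
#' @param filler_tile_len,filler_overlap tile length and overlap of the pools.
#' @param filler_error per-base substitution rate applied to filler tiles.
#' @param filler_rc_prob probability a filler tile is stored
#'   reverse-complemented.
#' @param withheld_frac fraction of gaps whose true fill is withheld from all
#'   pools (tests rejection paths).
#' @param pool_labels,pool_probs filler-pool names (priority order) and the
#'   probability a gap's spanning fill is assigned to each.
#' @param n_markers number of primer-pair markers.
#' @param primer_len primer length (>= 15).
#' @param product_len_dist (min, max) marker product length, bases.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 42,
                       arm_length = 5e6,
                       n_genes = 200,
                       gene_len_codons = c(100, 400),
                       te_fraction = 0.40,
                       te_body_len = c(1500, 5000),
                       ltr_len = 300,
                       per_gene_omega = NULL,
                       omega_levels = c(0.2, 5),
                       omega_probs = c(0.88, 0.12),
                       loss_prob = 0.05,
                       reloc_prob = 0.05,
                       rga_fraction = 0.10,
                       rga_loss_mult = 3,
                       n_categories = 8,
                       subst_rate_neutral = 0.05,
                       ltr_k_mean = 0.0065,
                       n_gaps = 100,
                       gap_len_dist = c(100, 800),
                       protect_genes = TRUE,
                       filler_tile_len = 5000,
                       filler_overlap = 2000,
                       filler_error = 0,
                       filler_rc_prob = 0.5,
                       withheld_frac = 0,
                       pool_labels = c("unmapped", "singleton_bac", "longread"),
                       pool_probs = c(0.05, 0.40, 0.55),
                       n_markers = 20,
                       primer_len = 20,
                       product_len_dist = c(150, 600)) {
  cfg <- as.list(environment())
  stopifnot(cfg$te_fraction >= 0, cfg$te_fraction < 1,
            cfg$loss_prob >= 0, cfg$loss_prob <= 1,
            cfg$reloc_prob >= 0, cfg$reloc_prob <= 1,
            cfg$withheld_frac >= 0, cfg$withheld_frac <= 1,
            cfg$filler_rc_prob >= 0, cfg$filler_rc_prob <= 1,
            cfg$primer_len >= 15,
            cfg$gap_len_dist[2] < cfg$filler_tile_len,
            length(cfg$pool_labels) == length(cfg$pool_probs))
  structure(cfg, class = "sim_config")
}

# uniform integer draw over [lo, hi], safe when lo == hi
sample_range <- function(lo, hi, n = 1) {
  if (lo == hi) rep(as.integer(lo), n)
  else sample(seq.int(lo, hi), n, replace = TRUE)
}

# deterministic per-stage seed fan-out from the root seed (kept below 2^31)
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587)
}

random_dna <- function(n) {
  rawToChar(charToRaw(paste(NUCS, collapse = ""))[sample.int(4, n, replace = TRUE)])
}

# overwrite substrings [starts+1, starts+nchar] of a long string in one pass;
# in-place on a raw copy, avoiding one full-string copy per assignment
str_assign_many <- function(seq, starts, replacements) {
  r <- charToRaw(seq)
  for (i in seq_along(starts)) {
    ins <- charToRaw(replacements[[i]])
    if (length(ins) > 0) r[(starts[i] + 1):(starts[i] + length(ins))] <- ins
  }
  rawToChar(r)
}

# random ORF of n_codons total codons: ATG + (n-2) sense non-stop non-ATG-free
# internal codons + one stop codon
random_orf <- function(n_codons) {
  internal <- sense_codons()
  stops <- c("TAA", "TAG", "TGA")
  body <- sample(internal, n_codons - 2, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(stops, 1))
}

#' Simulate the ancestral (donor) chromosome arm
#'
#' Places non-overlapping ORF genes and LTR retroelements (each with two
#' initially identical LTR copies) on a random background, and assigns
#' per-gene omega and annotation categories.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (tibble id/seq), `genes` (gene_id, seq_id,
#'   start, end, strand, cds, is_rga), `tes` (te_id, start, end, ltr_len),
#'   `annotation` (gene_id, category_id), and `truth` (omega_truth).
#' @export
simulate_ancestor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "ancestor"))

  n_codons <- sample_range(config$gene_len_codons[1], config$gene_len_codons[2],
                           config$n_genes)
  cds <- vapply(n_codons, random_orf, character(1))
  gene_len <- nchar(cds)

  te_target <- config$te_fraction * config$arm_length
  te_lens <- integer(0)
  while (sum(te_lens) < te_target) {
    body <- sample_range(config$te_body_len[1], config$te_body_len[2])
    te_lens <- c(te_lens, body + 2 * config$ltr_len)
  }
  n_tes <- length(te_lens)

  ent_len <- c(gene_len, te_lens)
  ent_type <- c(rep("gene", config$n_genes), rep("te", n_tes))
  n_ent <- length(ent_len)
  margin <- 50
  need <- sum(ent_len) + (n_ent + 1) * margin
  if (need > config$arm_length) {
    stop("simulate_ancestor: infeasible packing (", need, " > arm_length ",
         config$arm_length, ")")
  }
  # random inter-entity spacing: split the free length at n_ent sorted cuts
  ord <- sample(n_ent)
  free <- config$arm_length - sum(ent_len) - (n_ent + 1) * margin
  cuts <- sort(runif(n_ent, 0, free))
  spacing <- floor(c(cuts[1], diff(cuts))) + margin
  starts <- integer(n_ent)
  pos <- 0
  for (i in seq_len(n_ent)) {
    pos <- pos + spacing[i]
    starts[ord[i]] <- pos
    pos <- pos + ent_len[ord[i]]
  }

  seq <- random_dna(config$arm_length)
  gene_strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  gi <- which(ent_type == "gene")
  gene_ins <- vapply(seq_along(gi), function(j) {
    if (gene_strand[j] == "+") cds[j] else revcomp(cds[j])
  }, character(1))
  te_ids <- sprintf("te%04d", seq_len(n_tes))
  ti <- which(ent_type == "te")
  te_ins <- vapply(seq_along(ti), function(j) {
    ltr <- random_dna(config$ltr_len)
    body <- random_dna(te_lens[j] - 2 * config$ltr_len)
    paste0(ltr, body, ltr)
  }, character(1))
  seq <- str_assign_many(seq, c(starts[gi], starts[ti]), c(gene_ins, te_ins))

  genes <- tibble::tibble(gene_id = gene_ids, seq_id = "arm",
                          start = starts[gi], end = starts[gi] + gene_len,
                          strand = gene_strand, cds = cds,
                          is_rga = runif(config$n_genes) < config$rga_fraction)
  tes <- tibble::tibble(te_id = te_ids, seq_id = "arm",
                        start = starts[ti], end = starts[ti] + te_lens,
                        ltr_len = config$ltr_len)

  if (!is.null(config$per_gene_omega)) {
    omega <- config$per_gene_omega[gene_ids]
    if (any(is.na(omega))) stop("per_gene_omega: missing genes")
  } else {
    omega <- sample(config$omega_levels, config$n_genes, replace = TRUE,
                    prob = config$omega_probs)
  }
  names(omega) <- gene_ids

  other_cats <- sprintf("cat%02d", seq_len(config$n_categories))
  annotation <- tibble::tibble(
    gene_id = gene_ids,
    category_id = ifelse(genes$is_rga, "RGA",
                         sample(other_cats, config$n_genes, replace = TRUE)))

  list(genome = tibble::tibble(id = "arm", seq = seq),
       genes = genes, tes = tes, annotation = annotation,
       truth = list(omega_truth = omega), config = config)
}

# evolve one CDS to hit Poisson-drawn synonymous/nonsynonymous change targets
# via rejection sampling over single-nucleotide codon changes; stop codons and
# the first (start) and last (stop) codons are never touched
evolve_cds <- function(cds, omega, rate) {
  codons <- split_codons(cds)
  L <- length(codons)
  ss <- syn_sites_table()
  S0 <- sum(ss[codons])
  N0 <- 3 * L - S0
  sd_target <- rpois(1, rate * S0)
  nd_target <- rpois(1, omega * rate * N0)
  code <- genetic_code()
  sd_done <- 0; nd_done <- 0
  guard <- 200 * (sd_target + nd_target + 10)
  it <- 0
  while ((sd_done < sd_target || nd_done < nd_target) && it < guard) {
    it <- it + 1
    ci <- sample(2:(L - 1), 1)
    pos <- sample(1:3, 1)
    old <- codons[ci]
    nt <- sample(setdiff(NUCS, substr(old, pos, pos)), 1)
    new <- old
    substr(new, pos, pos) <- nt
    if (code[new] == "*") next
    syn <- code[new] == code[old]
    if (syn && sd_done < sd_target) {
      codons[ci] <- new; sd_done <- sd_done + 1
    } else if (!syn && nd_done < nd_target) {
      codons[ci] <- new; nd_done <- nd_done + 1
    }
  }
  paste(codons, collapse = "")
}

# JC substitution process: n ~ Poisson(len * d) events at random sites
mutate_jc <- function(seq, d) {
  len <- nchar(seq)
  nev <- rpois(1, len * d)
  if (nev == 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(len, nev, replace = TRUE)
  for (p in pos) {
    v[p] <- sample(setdiff(NUCS, v[p]), 1)
  }
  paste(v, collapse = "")
}

#' Evolve the derived (polyploid-arm) copy from the ancestor
#'
#' Applies per-gene codon evolution at synonymous rate `subst_rate_neutral`
#' and nonsynonymous rate omega times that, removes lost genes, moves
#' relocated genes to a decoy homoeologue set, and diverges each element's
#' LTR pair to its drawn true K.
#'
#' @param ancestor output of [simulate_ancestor()].
#' @param config the same [sim_config()].
#' @return list with `genome` (derived arm sequence), `genes` (derived genes
#'   present on the arm, ids d####), `homoeologue` (decoy set of relocated
#'   genes), `tes` (with `ltr5`, `ltr3` evolved copies), and `truth`
#'   (gene_fate, gene_map, omega_truth, ltr_age_truth).
#' @export
evolve_derived <- function(ancestor, config) {
  set.seed(stage_seed(config$seed, "derived"))
  genes <- ancestor$genes
  omega <- ancestor$truth$omega_truth

  p_loss <- pmin(1, config$loss_prob * ifelse(genes$is_rga, config$rga_loss_mult, 1))
  p_rel <- pmin(1 - p_loss, config$reloc_prob)
  u <- runif(nrow(genes))
  fate <- ifelse(u < p_loss, "lost",
                 ifelse(u < p_loss + p_rel, "relocated", "retained"))
  names(fate) <- genes$gene_id

  evolved <- vapply(seq_len(nrow(genes)), function(i) {
    if (fate[i] == "lost") return(NA_character_)
    evolve_cds(genes$cds[i], omega[genes$gene_id[i]], config$subst_rate_neutral)
  }, character(1))

  keep <- fate == "retained"
  gene_ins <- vapply(seq_len(nrow(genes)), function(i) {
    if (fate[i] == "retained") {
      if (genes$strand[i] == "+") evolved[i] else revcomp(evolved[i])
    } else {
      random_dna(genes$end[i] - genes$start[i]) # deletion emulation
    }
  }, character(1))
  seq <- str_assign_many(ancestor$genome$seq, genes$start, gene_ins)

  derived_ids <- sprintf("d%04d", seq_len(sum(keep)))
  gene_map <- tibble::tibble(donor_id = genes$gene_id[keep],
                             derived_id = derived_ids)
  derived_genes <- tibble::tibble(
    gene_id = derived_ids, seq_id = "arm_derived",
    start = genes$start[keep], end = genes$end[keep],
    strand = genes$strand[keep], cds = evolved[keep],
    is_rga = genes$is_rga[keep])

  rel <- fate == "relocated"
  n_rel <- sum(rel)
  hom_ids <- if (n_rel > 0) sprintf("h%04d", seq_len(n_rel)) else character(0)
  hom_start <- if (n_rel > 0) cumsum(c(0, head(nchar(evolved[rel]), -1) + 500)) else integer(0)
  homoeologue <- tibble::tibble(
    gene_id = hom_ids, seq_id = "homoeo_arm",
    start = hom_start, end = hom_start + nchar(evolved[rel]),
    strand = "+", cds = evolved[rel],
    donor_id = genes$gene_id[rel])

  tes <- ancestor$tes
  k_true <- rexp(nrow(tes), rate = 1 / config$ltr_k_mean)
  names(k_true) <- tes$te_id
  ltr5 <- character(nrow(tes)); ltr3 <- character(nrow(tes))
  for (i in seq_len(nrow(tes))) {
    s <- tes$start[i]; ll <- tes$ltr_len[i]
    l0 <- substr(seq, s + 1, s + ll)
    ltr5[i] <- mutate_jc(l0, k_true[i] / 2)
    ltr3[i] <- mutate_jc(l0, k_true[i] / 2)
  }
  seq <- str_assign_many(seq, c(tes$start, tes$end - tes$ltr_len),
                         c(ltr5, ltr3))
  tes$ltr5 <- ltr5
  tes$ltr3 <- ltr3

  list(genome = tibble::tibble(id = "arm_derived", seq = seq),
       genes = derived_genes, homoeologue = homoeologue, tes = tes,
       truth = list(gene_fate = fate, gene_map = gene_map,
                    omega_truth = omega, ltr_age_truth = k_true),
       config = config)
}

#' Plant N-gaps and build filler pools
#'
#' Overwrites `n_gaps` non-overlapping intervals with N (recording the true
#' fill), and tiles the TRUE genome into filler pools: tiles spanning a gap's
#' fill go to that gap's assigned source pool (plus one tile centred on each
#' gap, so every non-withheld gap has a spanning filler), tiles spanning a
#' withheld gap are dropped, background tiles are distributed round-robin.
#' Tiles are optionally substituted at `filler_error` and stored
#' reverse-complemented with probability `filler_rc_prob`.
#'
#' @param genome tibble (id, seq): the true (ungapped) genome.
#' @param config a [sim_config()].
#' @param protect optional tibble of intervals (`start`, `end`) that gaps must
#'   not overlap (used with `protect_genes`).
#' @return list with `assembly` (gapped tibble id/seq), `gaps` (catalogue as
#'   [scan_gaps()]), `pools` (named list of filler tibbles, priority order),
#'   and `truth` (gap_id, start, end, length, true_fill, source, withheld).
#' @export
fragment_assembly <- function(genome, config, protect = NULL) {
  set.seed(stage_seed(config$seed, "fragment"))
  seq <- genome$seq
  len <- nchar(seq)
  tl <- config$filler_tile_len
  edge <- 2000

  lens <- sample_range(config$gap_len_dist[1], config$gap_len_dist[2],
                       config$n_gaps)
  starts <- integer(0)
  tries <- 0
  prot <- if (!is.null(protect) && config$protect_genes) protect else NULL
  while (length(starts) < config$n_gaps) {
    tries <- tries + 1
    if (tries > 200 * config$n_gaps) {
      stop("fragment_assembly: could not place non-overlapping gaps")
    }
    i <- length(starts) + 1
    cand <- sample(edge:(len - edge - lens[i]), 1)
    if (length(starts) > 0 &&
        any(abs(cand - starts) < tl + max(lens))) next
    if (!is.null(prot) &&
        any(cand < prot$end + 10 & prot$start - 10 < cand + lens[i])) next
    starts <- c(starts, cand)
  }
  ord <- order(starts)
  starts <- starts[ord]; lens <- lens[ord]
  ends <- starts + lens
  gap_ids <- sprintf("gap%03d", seq_along(starts))
  true_fill <- substring(seq, starts + 1, ends)
  withheld <- runif(config$n_gaps) < config$withheld_frac
  source <- sample(config$pool_labels, config$n_gaps, replace = TRUE,
                   prob = config$pool_probs)

  asm <- str_assign_many(seq, starts, strrep("N", lens))

  # tiles over the true genome
  step <- tl - config$filler_overlap
  tile_starts <- unique(c(seq(0, max(0, len - tl), by = step), len - tl))
  # plus one tile centred on each gap
  centred <- pmax(0, pmin(len - tl, floor((starts + ends) / 2) - floor(tl / 2)))
  tile_starts <- c(tile_starts, centred)
  tile_src <- character(length(tile_starts))
  drop <- logical(length(tile_starts))
  rr <- 0
  for (ti in seq_along(tile_starts)) {
    ts <- tile_starts[ti]; te <- ts + tl
    ov <- which(starts < te & ts < ends)
    if (length(ov) == 0) {
      rr <- rr + 1
      tile_src[ti] <- config$pool_labels[(rr %% length(config$pool_labels)) + 1]
    } else if (any(withheld[ov])) {
      drop[ti] <- TRUE
    } else {
      tile_src[ti] <- source[ov[1]]
    }
  }
  tile_starts <- tile_starts[!drop]; tile_src <- tile_src[!drop]

  tile_seq <- substring(seq, tile_starts + 1, tile_starts + tl)
  if (config$filler_error > 0) {
    tile_seq <- vapply(tile_seq, mutate_jc, character(1),
                       d = config$filler_error, USE.NAMES = FALSE)
  }
  rc <- runif(length(tile_seq)) < config$filler_rc_prob
  tile_seq[rc] <- revcomp(tile_seq[rc])

  pools <- lapply(config$pool_labels, function(lab) {
    sel <- tile_src == lab
    tibble::tibble(id = sprintf("%s_f%05d", lab, which(sel)),
                   seq = tile_seq[sel])
  })
  names(pools) <- config$pool_labels

  gaps <- tibble::tibble(seq_id = genome$id[[1]], start = starts, end = ends,
                         length = lens)
  truth <- tibble::tibble(gap_id = gap_ids, start = starts, end = ends,
                          length = lens, true_fill = true_fill,
                          source = source, withheld = withheld)
  list(assembly = tibble::tibble(id = genome$id[[1]], seq = asm),
       gaps = gaps, pools = pools, truth = truth)
}

#' Simulate primer-pair markers from unique loci
#'
#' Copies primer pairs from the genome at random loci, requiring each primer
#' (and its reverse complement) to have exactly one exact match genome-wide.
#'
#' @param genome tibble (id, seq).
#' @param config a [sim_config()].
#' @param gaps optional gap catalogue; products overlapping a gap are flagged
#'   `spans_gap` in the truth table.
#' @return list with `markers` (marker_id, fwd_primer, rev_primer,
#'   expected_size) and `truth` (adds `pos`, `product_len`, `spans_gap`).
#' @export
simulate_markers <- function(genome, config, gaps = NULL) {
  set.seed(stage_seed(config$seed, "markers"))
  seq <- genome$seq
  len <- nchar(seq)
  rcg <- revcomp(seq)
  pl <- config$primer_len

  count_occ <- function(pat) {
    cnt <- function(txt) {
      m <- gregexpr(pat, txt, fixed = TRUE)[[1]]
      if (m[1] == -1) 0L else length(m)
    }
    cnt(seq) + cnt(rcg)
  }

  out_pos <- integer(0); out_len <- integer(0)
  out_f <- character(0); out_r <- character(0)
  attempts <- 0
  while (length(out_pos) < config$n_markers) {
    attempts <- attempts + 1
    if (attempts > 100 * config$n_markers) {
      stop("simulate_markers: could not find unique loci")
    }
    prod <- sample_range(config$product_len_dist[1], config$product_len_dist[2])
    p <- sample(0:(len - prod), 1)
    fwd <- substr(seq, p + 1, p + pl)
    rev_site <- substr(seq, p + prod - pl + 1, p + prod)
    if (grepl("N", fwd) || grepl("N", rev_site)) next
    rev <- revcomp(rev_site)
    if (count_occ(fwd) != 1 || count_occ(rev_site) != 1) next
    out_pos <- c(out_pos, p); out_len <- c(out_len, prod)
    out_f <- c(out_f, fwd); out_r <- c(out_r, rev)
  }
  ids <- sprintf("mk%03d", seq_along(out_pos))
  spans <- rep(FALSE, length(out_pos))
  if (!is.null(gaps) && nrow(gaps) > 0) {
    for (i in seq_along(out_pos)) {
      spans[i] <- any(gaps$start < out_pos[i] + out_len[i] &
                        out_pos[i] < gaps$end)
    }
  }
  markers <- tibble::tibble(marker_id = ids, fwd_primer = out_f,
                            rev_primer = out_r, expected_size = out_len)
  truth <- tibble::tibble(marker_id = ids, pos = out_pos,
                          product_len = out_len, spans_gap = spans)
  list(markers = markers, truth = truth)
}

#' Run the whole simulator
#'
#' Convenience wrapper: ancestor, derived copy, gapped assembly with pools
#' (built from the derived genome), and markers, all from one config.
#'
#' @param config a [sim_config()].
#' @return list: `ancestor`, `derived`, `fragments`, `markers`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  anc <- simulate_ancestor(config)
  der <- evolve_derived(anc, config)
  frag <- fragment_assembly(der$genome, config, protect = der$genes)
  mk <- simulate_markers(der$genome, config, gaps = frag$gaps)
  list(ancestor = anc, derived = der, fragments = frag, markers = mk,
       config = config)
}
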