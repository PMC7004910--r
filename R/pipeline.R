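# Pipeline orchestration: one YAML config drives the simulate / gapfill /
# orthology / selection / enrich / date-ltr / anchor stages (or `all`), each
# writing fixed filenames under outdir/<stage>/, with a run manifest carrying
# the config snapshot, seed and output digests.

pipeline_subcommands <- c("simulate", "gapfill", "orthology", "selection",
                          "enrich", "date-ltr", "anchor", "replicate-tables",
                          "all")

allowed_config_keys <- function() {
  list(top = c("seed", "outdir", "log_level", "simulate", "gapfill",
               "orthology", "selection", "enrich", "date_ltr", "anchor",
               "replicate_tables"),
       simulate = setdiff(names(formals(sim_config)), "seed"),
       gapfill = names(formals(closure_rules)),
       orthology = names(formals(ortho_thresholds)),
       selection = "bin_size",
       enrich = character(0),
       date_ltr = "r",
       anchor = c("max_mismatch", "three_prime_exact", "size_tol",
                  "point_radius", "window", "n_qtls"),
       replicate_tables = c("closure_rows", "fisher"))
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML config and fails fast on unknown keys (top level and per
#' stage section), listing the offenders.
#'
#' @param path YAML config path, or NULL for an all-defaults config.
#' @param overrides named list of `section.key` (or top-level `key`) values
#'   that win over the file.
#' @return validated config list.
#' @export
load_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  for (nm in names(overrides)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) cfg[[parts]] <- overrides[[nm]]
    else cfg[[parts[1]]][[parts[2]]] <- overrides[[nm]]
  }
  allowed <- allowed_config_keys()
  bad <- setdiff(names(cfg), allowed$top)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  for (sec in intersect(names(cfg), setdiff(allowed$top, c("seed", "outdir", "log_level")))) {
    bad <- setdiff(names(cfg[[sec]]), allowed[[sec]])
    if (length(bad) > 0) {
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
    }
  }
  cfg$seed <- cfg$seed %||% 42
  cfg$log_level <- cfg$log_level %||% "info"
  cfg
}

plog <- function(state, level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[level] < levels[state$log_level]) return(invisible())
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
  message(line)
  if (!is.null(state$log_file)) cat(line, "\n", file = state$log_file,
                                    append = TRUE)
  invisible()
}

stage_dir <- function(state, stage) {
  d <- file.path(state$outdir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

#' Run the analysis pipeline
#'
#' Subcommands: `simulate` (synthetic study with truth tables), `gapfill`
#' (close N-gaps from the simulated pools), `orthology` (RBH + loss cascade),
#' `selection` (dN/dS, codon features, correlations), `enrich` (category
#' enrichment of lost genes), `date-ltr`, `anchor` (e-PCR markers, QTLs,
#' PSG links), `replicate-tables` (closure-summary arithmetic and exact 2x2
#' tests on counts supplied in the config), or `all` (every stage in order,
#' replicate-tables excluded unless configured).
#'
#' @param subcommand one of the above.
#' @param config path to a YAML config, or a list from
#'   [load_pipeline_config()], or NULL for defaults.
#' @param outdir output directory (default `config$outdir` or "armcompare_out").
#' @param overrides named list of `section.key` overrides.
#' @return (invisibly) the run manifest list; outputs land under
#'   `outdir/<stage>/` and a `manifest.yaml` at the top.
#' @export
run_pipeline <- function(subcommand, config = NULL, outdir = NULL,
                         overrides = list()) {
  subcommand <- match.arg(subcommand, pipeline_subcommands)
  cfg <- if (is.list(config)) config else load_pipeline_config(config, overrides)
  outdir <- outdir %||% cfg$outdir %||% "armcompare_out"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  state <- list(cfg = cfg, outdir = outdir, log_level = cfg$log_level,
                log_file = file.path(outdir, "run.log"))
  stages <- if (subcommand == "all") {
    c("simulate", "gapfill", "orthology", "selection", "enrich", "date-ltr",
      "anchor", if (!is.null(cfg$replicate_tables)) "replicate-tables")
  } else subcommand
  plog(state, "info", "run: ", paste(stages, collapse = " -> "),
       " (seed ", cfg$seed, ")")
  files <- character(0)
  for (st in stages) {
    plog(state, "info", "stage ", st, " ...")
    files <- c(files, switch(st,
      "simulate" = stage_simulate(state),
      "gapfill" = stage_gapfill(state),
      "orthology" = stage_orthology(state),
      "selection" = stage_selection(state),
      "enrich" = stage_enrich(state),
      "date-ltr" = stage_date_ltr(state),
      "anchor" = stage_anchor(state),
      "replicate-tables" = stage_replicate_tables(state)))
  }
  manifest <- list(tool = "armcompare",
                   version = as.character(utils::packageVersion("armcompare")),
                   seed = cfg$seed, subcommand = subcommand,
                   config = cfg,
                   outputs = as.list(tools::md5sum(files)))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  plog(state, "info", "done: ", length(files), " output file(s)")
  invisible(manifest)
}

sim_config_from <- function(cfg) {
  do.call(sim_config, c(list(seed = cfg$seed), cfg$simulate))
}

stage_simulate <- function(state) {
  cfg <- state$cfg
  d <- stage_dir(state, "simulate")
  sim <- simulate_study(sim_config_from(cfg))
  anc <- sim$ancestor; der <- sim$derived; frag <- sim$fragments
  f <- character(0)
  wr <- function(x, name, fun) { p <- file.path(d, name); fun(x, p); c(f, p) }
  f <- wr(anc$genome, "ancestor_genome.fa", write_fasta)
  f <- wr(der$genome, "derived_genome.fa", write_fasta)
  f <- wr(frag$assembly, "assembly.fa", write_fasta)
  f <- wr(frag$gaps, "gaps.bed", write_bed)
  f <- wr(tibble::tibble(id = anc$genes$gene_id, seq = anc$genes$cds),
          "donor_cds.fa", write_fasta)
  f <- wr(tibble::tibble(id = der$genes$gene_id, seq = der$genes$cds),
          "focal_cds.fa", write_fasta)
  f <- wr(tibble::tibble(id = der$homoeologue$gene_id,
                         seq = der$homoeologue$cds),
          "homoeo_cds.fa", write_fasta)
  gff <- function(g, src) tibble::tibble(seq_id = g$seq_id, source = src,
                                         type = "gene", start = g$start,
                                         end = g$end, strand = g$strand,
                                         id = g$gene_id)
  f <- wr(gff(anc$genes, "sim"), "donor_genes.gff3", write_gff3)
  f <- wr(gff(der$genes, "sim"), "focal_genes.gff3", write_gff3)
  f <- wr(der$tes[, c("te_id", "ltr5", "ltr3")] %>%
            dplyr::rename(element_id = "te_id"),
          "ltr_pairs.tsv", readr::write_tsv)
  f <- wr(sim$markers$markers, "markers.tsv", readr::write_tsv)
  n_qtls <- cfg$anchor$n_qtls %||% floor(nrow(sim$markers$markers) / 2)
  qtl <- marker_qtl_table(sim$markers$markers, n_qtls)
  f <- wr(qtl, "qtl.tsv", readr::write_tsv)
  f <- wr(anc$annotation, "annotation.tsv", readr::write_tsv)
  f <- wr(frag$truth, "truth_gaps.tsv", readr::write_tsv)
  fates <- tibble::tibble(gene_id = names(der$truth$gene_fate),
                          fate = unname(der$truth$gene_fate),
                          omega = unname(der$truth$omega_truth[names(der$truth$gene_fate)]))
  f <- wr(fates, "truth_fates.tsv", readr::write_tsv)
  f <- wr(sim$markers$truth, "truth_markers.tsv", readr::write_tsv)
  f <- wr(tibble::tibble(element_id = names(der$truth$ltr_age_truth),
                         K_true = unname(der$truth$ltr_age_truth)),
          "truth_ltr.tsv", readr::write_tsv)
  f <- wr(der$truth$gene_map, "truth_gene_map.tsv", readr::write_tsv)
  for (lab in names(frag$pools)) {
    p <- file.path(d, paste0("pool_", lab, ".fa"))
    write_fasta(frag$pools[[lab]], p)
    f <- c(f, p)
  }
  writeLines(names(frag$pools), file.path(d, "pool_order.txt"))
  f <- c(f, file.path(d, "pool_order.txt"))
  f
}

# group markers pairwise into synthetic QTLs (two flanking markers each)
marker_qtl_table <- function(markers, n_qtls) {
  n <- min(n_qtls, floor(nrow(markers) / 2))
  if (n == 0) return(tibble::tibble(qtl_id = character(), trait = character(),
                                    marker_id = character()))
  traits <- c("grain_length", "grain_width", "grain_diameter", "spike_length",
              "tgw")
  purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(qtl_id = sprintf("qtl%02d", i),
                   trait = traits[(i - 1) %% length(traits) + 1],
                   marker_id = markers$marker_id[c(2 * i - 1, 2 * i)])
  })
}

require_stage_file <- function(state, stage, name) {
  p <- file.path(state$outdir, stage, name)
  if (!file.exists(p)) {
    stop("missing input ", p, " - run the '", stage, "' stage first")
  }
  p
}

stage_gapfill <- function(state) {
  cfg <- state$cfg
  d <- stage_dir(state, "gapfill")
  asm <- read_fasta(require_stage_file(state, "simulate", "assembly.fa"))
  order <- readLines(require_stage_file(state, "simulate", "pool_order.txt"))
  pools <- lapply(order, function(lab) {
    read_fasta(file.path(state$outdir, "simulate", paste0("pool_", lab, ".fa")))
  })
  names(pools) <- order
  rules <- do.call(closure_rules, cfg$gapfill %||% list())
  res <- close_gaps(asm, pools, rules)
  f <- c(file.path(d, "patched.fa"), file.path(d, "closure_report.tsv"),
         file.path(d, "closure_summary.tsv"), file.path(d, "liftover.tsv"))
  write_fasta(res$assembly, f[1])
  readr::write_tsv(res$events, f[2])
  readr::write_tsv(summarize_closures(res$events), f[3])
  readr::write_tsv(res$liftover, f[4])
  f
}

stage_orthology <- function(state) {
  cfg <- state$cfg
  d <- stage_dir(state, "orthology")
  donor <- cds_tibble(require_stage_file(state, "simulate", "donor_cds.fa"))
  focal <- cds_tibble(require_stage_file(state, "simulate", "focal_cds.fa"))
  hom <- cds_tibble(require_stage_file(state, "simulate", "homoeo_cds.fa"))
  th <- do.call(ortho_thresholds, cfg$orthology %||% list())
  records <- classify_absent_genes(donor, focal, list(hom), list(), th)
  gffp <- read_gff3(require_stage_file(state, "simulate", "donor_genes.gff3"))
  coords <- tibble::tibble(gene_id = gffp$id, start = gffp$start,
                           end = gffp$end)
  bin_size <- cfg$selection$bin_size %||% 250000
  prof <- loss_density_profile(records, coords, bin_size)
  f <- c(file.path(d, "loss_records.tsv"), file.path(d, "rbh_pairs.tsv"),
         file.path(d, "loss_density.tsv"))
  readr::write_tsv(records, f[1])
  readr::write_tsv(attr(records, "rbh"), f[2])
  readr::write_tsv(prof, f[3])
  f
}

cds_tibble <- function(path) {
  x <- read_fasta(path)
  tibble::tibble(gene_id = x$id, cds = x$seq)
}

stage_selection <- function(state) {
  d <- stage_dir(state, "selection")
  donor <- cds_tibble(require_stage_file(state, "simulate", "donor_cds.fa"))
  focal <- cds_tibble(require_stage_file(state, "simulate", "focal_cds.fa"))
  rbh <- readr::read_tsv(require_stage_file(state, "orthology", "rbh_pairs.tsv"),
                         show_col_types = FALSE)
  rbh <- dplyr::filter(rbh, !.data$ambiguous)
  pairs <- tibble::tibble(
    gene_a = rbh$gene_a, gene_b = rbh$gene_b,
    cds_a = donor$cds[match(rbh$gene_a, donor$gene_id)],
    cds_b = focal$cds[match(rbh$gene_b, focal$gene_id)])
  pairs <- dplyr::filter(pairs, nchar(.data$cds_a) == nchar(.data$cds_b))
  dnds <- classify_selection(ng86_dnds_pairs(pairs))
  w <- cai_reference_weights(donor$cds)
  feats <- purrr::map_dfr(seq_len(nrow(donor)), function(i) {
    ft <- codon_metrics(donor$cds[i], reference_weights = w)
    ft$gene_id <- donor$gene_id[i]
    ft
  })
  joined <- dplyr::inner_join(feats, dnds, by = c(gene_id = "gene_a"))
  corr <- feature_correlation(
    joined[, c("gc", "gc3", "length", "enc", "cai", "dN", "dS", "omega")])
  f <- c(file.path(d, "dnds_pairs.tsv"), file.path(d, "gene_features.tsv"),
         file.path(d, "feature_correlation.tsv"))
  readr::write_tsv(dnds, f[1])
  readr::write_tsv(feats, f[2])
  readr::write_tsv(tidy(corr), f[3])
  f
}

stage_enrich <- function(state) {
  d <- stage_dir(state, "enrich")
  records <- readr::read_tsv(
    require_stage_file(state, "orthology", "loss_records.tsv"),
    show_col_types = FALSE)
  ann <- readr::read_tsv(require_stage_file(state, "simulate", "annotation.tsv"),
                         show_col_types = FALSE)
  fg <- records$gene_id[records$classification == "lost"]
  res <- category_enrichment(fg, records$gene_id, ann)
  p <- file.path(d, "enrichment.tsv")
  readr::write_tsv(res, p)
  p
}

stage_date_ltr <- function(state) {
  cfg <- state$cfg
  d <- stage_dir(state, "date-ltr")
  pairs <- readr::read_tsv(require_stage_file(state, "simulate", "ltr_pairs.tsv"),
                           show_col_types = FALSE)
  r <- cfg$date_ltr$r %||% 1.3e-8
  ages <- date_ltr_cohort(pairs, r = r)
  p <- file.path(d, "ltr_ages.tsv")
  readr::write_tsv(ages, p)
  p
}

stage_anchor <- function(state) {
  cfg <- state$cfg
  d <- stage_dir(state, "anchor")
  genome_path <- file.path(state$outdir, "gapfill", "patched.fa")
  if (!file.exists(genome_path)) {
    genome_path <- require_stage_file(state, "simulate", "derived_genome.fa")
  }
  genome <- read_fasta(genome_path)
  markers <- readr::read_tsv(require_stage_file(state, "simulate", "markers.tsv"),
                             show_col_types = FALSE)
  qtl <- readr::read_tsv(require_stage_file(state, "simulate", "qtl.tsv"),
                         show_col_types = FALSE)
  hits <- place_markers(markers, genome,
                        max_mismatch = cfg$anchor$max_mismatch %||% 1,
                        three_prime_exact = cfg$anchor$three_prime_exact %||% 3,
                        size_tol = cfg$anchor$size_tol %||% 0.2)
  anchors <- anchor_qtls(hits, qtl,
                         point_radius = cfg$anchor$point_radius %||% 1e6)
  gffp <- read_gff3(require_stage_file(state, "simulate", "focal_genes.gff3"))
  genes <- tibble::tibble(gene_id = gffp$id, seq_id = genome$id[[1]],
                          start = gffp$start, end = gffp$end)
  sel_path <- file.path(state$outdir, "selection", "dnds_pairs.tsv")
  if (file.exists(sel_path)) {
    dnds <- readr::read_tsv(sel_path, show_col_types = FALSE)
    psg <- dnds$gene_b[dnds$selection_class == "PSG"]
    genes <- dplyr::filter(genes, .data$gene_id %in% psg)
  }
  links <- link_genes_to_qtls(genes, anchors,
                              window = cfg$anchor$window %||% 3e6)
  f <- c(file.path(d, "marker_hits.tsv"), file.path(d, "qtl_anchors.tsv"),
         file.path(d, "qtl_anchors.bed"), file.path(d, "gene_qtl_links.tsv"))
  readr::write_tsv(hits, f[1])
  readr::write_tsv(anchors, f[2])
  ok <- dplyr::filter(anchors, .data$anchored)
  write_bed(tibble::tibble(seq_id = ok$seq_id, start = as.integer(ok$start),
                           end = as.integer(ok$end), name = ok$qtl_id), f[3])
  readr::write_tsv(links, f[4])
  f
}

stage_replicate_tables <- function(state) {
  cfg <- state$cfg
  d <- stage_dir(state, "replicate-tables")
  rt <- cfg$replicate_tables
  if (is.null(rt)) stop("replicate-tables: no 'replicate_tables' config section")
  lines <- character(0)
  f <- character(0)
  if (!is.null(rt$closure_rows)) {
    rows <- dplyr::bind_rows(lapply(rt$closure_rows, tibble::as_tibble))
    rows$mean_length <- round_half_away(rows$total_len / rows$count)
    p <- file.path(d, "closure_means.tsv")
    readr::write_tsv(rows, p)
    f <- c(f, p)
    lines <- c(lines, sprintf("closure %s: %d gaps, %d bp, mean %d",
                              rows$source, rows$count, rows$total_len,
                              as.integer(rows$mean_length)))
  }
  if (!is.null(rt$fisher)) {
    fr <- purrr::map_dfr(rt$fisher, function(x) {
      tb <- subset_table(x$fg_hits, x$fg_size, x$bg_hits, x$bg_size)
      ft <- fisher_exact_2x2(tb["a"], tb["b"], tb["c"], tb["d"])
      tibble::tibble(k = x$fg_hits, n = x$fg_size, K = x$bg_hits,
                     N = x$bg_size,
                     pct = round_half_away(100 * x$fg_hits / x$fg_size),
                     odds_ratio = ft$odds_ratio, p = ft$p)
    })
    p <- file.path(d, "fisher_tests.tsv")
    readr::write_tsv(fr, p)
    f <- c(f, p)
    lines <- c(lines, sprintf("fisher %d/%d vs %d/%d: P = %s",
                              fr$k, fr$n, fr$K, fr$N, format_p_1sig(fr$p)))
  }
  rp <- file.path(d, "report.txt")
  writeLines(lines, rp)
  for (l in lines) plog(state, "info", l)
  c(f, rp)
}

# format a p-value to one significant figure in plain decimal notation
format_p_1sig <- function(p) {
  vapply(p, function(x) {
    if (x >= 0.1) return(as.character(signif(x, 1)))
    digits <- -floor(log10(signif(x, 1)))
    sprintf(paste0("%.", digits, "f"), signif(x, 1))
  }, character(1))
}
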