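# Generator properties are checked on a 200-300 kb arm; the full 5 Mb study
# condition is exercised in test-acceptance.R.

small_cfg <- function(...) {
  sim_config(arm_length = 2e5, n_genes = 25, n_gaps = 8, n_markers = 5, ...)
}

test_that("the simulator is bit-for-bit reproducible from (config, seed)", {
  cfg <- small_cfg(seed = 1)
  a1 <- simulate_ancestor(cfg)
  a2 <- simulate_ancestor(cfg)
  expect_identical(a1, a2)
  d1 <- evolve_derived(a1, cfg)
  d2 <- evolve_derived(a2, cfg)
  expect_identical(d1, d2)
  m1 <- simulate_markers(d1$genome, cfg)
  m2 <- simulate_markers(d2$genome, cfg)
  expect_identical(m1, m2)
})

test_that("te_fraction = 0 yields no TE annotations", {
  anc <- simulate_ancestor(small_cfg(seed = 2, te_fraction = 0))
  expect_equal(nrow(anc$tes), 0)
})

test_that("all simulated genes are clean ORFs", {
  anc <- simulate_ancestor(sim_config(seed = 3, arm_length = 1e6,
                                      n_genes = 100, n_gaps = 5,
                                      n_markers = 5))
  expect_equal(nrow(anc$genes), 100)
  for (cds in anc$genes$cds) {
    expect_equal(nchar(cds) %% 3, 0)
    prot <- armcompare:::translate_cds(cds)
    expect_equal(substr(prot, 1, 1), "M")
    expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
  }
  # the genomic locus carries the CDS (strand-aware)
  i <- which(anc$genes$strand == "-")[1]
  locus <- substr(anc$genome$seq, anc$genes$start[i] + 1, anc$genes$end[i])
  expect_equal(revcomp(locus), anc$genes$cds[i])
})

test_that("loss/relocation probabilities of zero retain every gene", {
  cfg <- small_cfg(seed = 4, loss_prob = 0, reloc_prob = 0)
  der <- evolve_derived(simulate_ancestor(cfg), cfg)
  expect_true(all(der$truth$gene_fate == "retained"))
  expect_equal(nrow(der$homoeologue), 0)
})

test_that("omega = 0 leaves the protein unchanged", {
  cfg <- small_cfg(seed = 5, loss_prob = 0, reloc_prob = 0)
  anc <- simulate_ancestor(cfg)
  cfg$per_gene_omega <- setNames(rep(0, nrow(anc$genes)), anc$genes$gene_id)
  anc$truth$omega_truth <- cfg$per_gene_omega
  der <- evolve_derived(anc, cfg)
  for (i in seq_len(nrow(der$genes))) {
    donor_cds <- anc$genes$cds[anc$genes$gene_id ==
                                 der$truth$gene_map$donor_id[i]]
    expect_equal(armcompare:::translate_cds(der$genes$cds[i]),
                 armcompare:::translate_cds(donor_cds))
  }
})

test_that("realized dN/dS rank-orders with the assigned omega", {
  cfg <- sim_config(seed = 6, arm_length = 1.2e6, n_genes = 60,
                    gene_len_codons = c(280, 320),
                    omega_levels = c(0.2, 1, 5),
                    omega_probs = c(1 / 3, 1 / 3, 1 / 3),
                    loss_prob = 0, reloc_prob = 0,
                    n_gaps = 5, n_markers = 5)
  anc <- simulate_ancestor(cfg)
  der <- evolve_derived(anc, cfg)
  map <- der$truth$gene_map
  omega_hat <- vapply(seq_len(nrow(map)), function(i) {
    a <- anc$genes$cds[anc$genes$gene_id == map$donor_id[i]]
    b <- der$genes$cds[der$genes$gene_id == map$derived_id[i]]
    cnt <- oracle_ng86_counts(a, b)   # exhaustive pathway oracle
    (cnt["Nd"] / cnt["N"]) / max(cnt["Sd"] / cnt["S"], 1e-9)
  }, numeric(1))
  om_true <- anc$truth$omega_truth[map$donor_id]
  grp <- split(omega_hat, om_true)
  expect_lt(mean(grp[["0.2"]]), mean(grp[["1"]]))
  expect_lt(mean(grp[["1"]]), mean(grp[["5"]]))
  expect_gt(cor(om_true, omega_hat, method = "spearman"), 0.5)
})

test_that("withholding every gap's fill leaves all gaps unclosable", {
  cfg <- small_cfg(seed = 7, withheld_frac = 1)
  sim <- simulate_study(cfg)
  res <- close_gaps(sim$fragments$assembly, sim$fragments$pools)
  expect_true(all(res$events$status == "unclosed"))
})

test_that("with nothing withheld every gap has a spanning filler", {
  cfg <- small_cfg(seed = 8, withheld_frac = 0)
  sim <- simulate_study(cfg)
  tr <- sim$fragments$truth
  allfill <- unlist(lapply(sim$fragments$pools, function(p) p$seq),
                    use.names = FALSE)
  genome <- sim$derived$genome$seq
  for (i in seq_len(nrow(tr))) {
    # spanning = fill plus 300 bp of context on each side inside one tile
    span <- substr(genome, tr$start[i] - 299, tr$end[i] + 300)
    hit <- any(vapply(allfill, function(f) {
      grepl(span, f, fixed = TRUE) || grepl(rc_oracle(span), f, fixed = TRUE)
    }, logical(1)))
    expect_true(hit, info = tr$gap_id[i])
  }
})

test_that("reverse-complementing filler tiles changes neither truth nor closures", {
  cfg0 <- small_cfg(seed = 9, filler_rc_prob = 0)
  cfg1 <- small_cfg(seed = 9, filler_rc_prob = 1)
  s0 <- simulate_study(cfg0)
  s1 <- simulate_study(cfg1)
  expect_identical(s0$fragments$truth, s1$fragments$truth)
  r0 <- close_gaps(s0$fragments$assembly, s0$fragments$pools)
  r1 <- close_gaps(s1$fragments$assembly, s1$fragments$pools)
  expect_identical(r0$assembly$seq, r1$assembly$seq)
})

test_that("markers come from unique loci and repeat with the seed", {
  cfg <- small_cfg(seed = 10)
  sim <- simulate_study(cfg)
  mk <- sim$markers
  expect_equal(nrow(mk$markers), 5)
  genome <- sim$derived$genome$seq
  rcg <- rc_oracle(genome)
  for (i in seq_len(nrow(mk$markers))) {
    f <- mk$markers$fwd_primer[i]
    occ <- length(gregexpr(f, genome, fixed = TRUE)[[1]][
      gregexpr(f, genome, fixed = TRUE)[[1]] > 0]) +
      length(gregexpr(f, rcg, fixed = TRUE)[[1]][
        gregexpr(f, rcg, fixed = TRUE)[[1]] > 0])
    expect_equal(occ, 1)
  }
  mk2 <- simulate_markers(sim$derived$genome, cfg, gaps = sim$fragments$gaps)
  expect_identical(mk$markers, mk2$markers)
})

test_that("products overlapping a gap are flagged gap-spanning", {
  cfg <- small_cfg(seed = 11)
  sim <- simulate_study(cfg)
  tr <- sim$markers$truth
  fake_gaps <- tibble::tibble(seq_id = "arm_derived",
                              start = tr$pos[1] + 5,
                              end = tr$pos[1] + 10,
                              length = 5L)
  mk <- simulate_markers(sim$derived$genome, cfg, gaps = fake_gaps)
  expect_true(mk$truth$spans_gap[1])
  expect_false(any(mk$truth$spans_gap[-1]))
})

test_that("infeasible packing is rejected", {
  expect_error(simulate_ancestor(sim_config(seed = 12, arm_length = 1e4,
                                            n_genes = 50)),
               "infeasible")
})
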