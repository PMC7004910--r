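test_that("an exact primer pair amplifies at its locus, wrong orientation fails", {
  set.seed(81)
  g <- rand_seq(20000)
  pos <- 5000; prod <- 400; pl <- 20
  fwd <- substr(g, pos + 1, pos + pl)
  rev <- rc_oracle(substr(g, pos + prod - pl + 1, pos + prod))
  genome <- tibble::tibble(id = "chr", seq = g)
  h <- epcr_place(fwd, rev, genome, max_mismatch = 0)
  expect_equal(nrow(h), 1)
  expect_equal(h$product_start, pos)
  expect_equal(h$product_len, prod)
  expect_equal(h$strand, "+")

  # swapping the primers gives the same product on the minus strand
  h2 <- epcr_place(rev, fwd, genome, max_mismatch = 0)
  expect_equal(h2$product_start, pos)
  expect_equal(h2$strand, "-")

  # wrong mutual orientation: both primers facing outwards
  h3 <- epcr_place(rc_oracle(fwd), rev, genome, max_mismatch = 0)
  expect_true(!any(h3$product_start == pos & h3$product_len == prod))
  expect_error(epcr_place("ACGTACGTAC", rev, genome), ">= 15")
})

test_that("placements mirror on the reverse-complemented genome", {
  set.seed(82)
  g <- rand_seq(15000)
  pos <- 7000; prod <- 300; pl <- 20
  fwd <- substr(g, pos + 1, pos + pl)
  rev <- rc_oracle(substr(g, pos + prod - pl + 1, pos + prod))
  h <- epcr_place(fwd, rev, tibble::tibble(id = "chr", seq = g), 0)
  hrc <- epcr_place(fwd, rev, tibble::tibble(id = "chr", seq = rc_oracle(g)), 0)
  expect_equal(nrow(h), nrow(hrc))
  expect_equal(hrc$product_start, 15000 - h$product_end)
  expect_equal(hrc$product_len, h$product_len)
  expect_equal(hrc$strand, chartr("+-", "-+", h$strand))
})

test_that("mismatch tolerance respects the exact 3'-end requirement", {
  set.seed(83)
  g <- rand_seq(10000)
  pos <- 3000; prod <- 350; pl <- 22
  fwd <- substr(g, pos + 1, pos + pl)
  rev <- rc_oracle(substr(g, pos + prod - pl + 1, pos + prod))
  genome <- tibble::tibble(id = "chr", seq = g)
  mutate_at <- function(p, i) {
    v <- strsplit(p, "")[[1]]
    v[i] <- setdiff(NUC4, v[i])[1]
    paste(v, collapse = "")
  }
  # one internal mismatch tolerated at max_mismatch = 1, not at 0
  fwd_mid <- mutate_at(fwd, 5)
  expect_equal(nrow(epcr_place(fwd_mid, rev, genome, 1)), 1)
  expect_equal(nrow(epcr_place(fwd_mid, rev, genome, 0)), 0)
  # a 3'-terminal mismatch is never tolerated
  fwd_3p <- mutate_at(fwd, pl)
  expect_equal(nrow(epcr_place(fwd_3p, rev, genome, 1)), 0)
})

test_that("simulated unique markers are fully recovered with no false hits", {
  cfg <- sim_config(seed = 84, arm_length = 2.5e5, n_genes = 20, n_gaps = 5,
                    n_markers = 12)
  sim <- simulate_study(cfg)
  hits <- place_markers(sim$markers$markers, sim$derived$genome,
                        max_mismatch = 0)
  expect_equal(nrow(hits), 12)
  m <- dplyr::inner_join(hits, sim$markers$truth, by = "marker_id")
  expect_equal(m$product_start, m$pos)
  expect_equal(m$product_len.x, m$product_len.y)
})

test_that("QTL anchoring spans marker midpoints, expands single markers", {
  hits <- tibble::tibble(marker_id = c("m1", "m2", "m3"), seq_id = "chr",
                         product_start = c(10e6, 13e6, 20e6) - 200,
                         product_end = c(10e6, 13e6, 20e6) + 200,
                         strand = "+", mismatches_fwd = 0L,
                         mismatches_rev = 0L, product_len = 400L)
  qtl <- tibble::tibble(qtl_id = c("q1", "q1", "q2", "q3"),
                        trait = c("gl", "gl", "gw", "sl"),
                        marker_id = c("m1", "m2", "m3", "m9"))
  anch <- anchor_qtls(hits, qtl, point_radius = 1e6)
  q1 <- anch[anch$qtl_id == "q1", ]
  expect_equal(q1$start, 10e6)
  expect_equal(q1$end, 13e6)
  q2 <- anch[anch$qtl_id == "q2", ]
  expect_equal(q2$end - q2$start, 2e6)   # point interval +/- radius
  expect_false(anch$anchored[anch$qtl_id == "q3"])
})

test_that("gene-QTL linking is window-bounded and monotone in the window", {
  anchors <- tibble::tibble(qtl_id = "q1", trait = "gl", seq_id = "chr",
                            start = 10e6, end = 13e6, n_markers = 2L,
                            anchored = TRUE)
  genes <- tibble::tibble(gene_id = c("inside", "near", "far"),
                          seq_id = "chr",
                          start = c(11e6, 13e6 + 1e6 - 500, 13e6 + 2e6),
                          end = c(11e6, 13e6 + 1e6 - 500, 13e6 + 2e6) + 1000)
  l0 <- link_genes_to_qtls(genes, anchors, window = 0)
  expect_equal(l0$gene_id, "inside")
  expect_equal(l0$distance, 0)
  l1 <- link_genes_to_qtls(genes, anchors, window = 1e6)
  expect_setequal(l1$gene_id, c("inside", "near"))
  l2 <- link_genes_to_qtls(genes, anchors, window = 3e6)
  expect_true(all(l1$gene_id %in% l2$gene_id))
  expect_gt(l2[l2$gene_id == "near", ]$distance, 0)
})

test_that("synthetic QTL anchors contain their flanking-marker truth loci", {
  cfg <- sim_config(seed = 85, arm_length = 2e5, n_genes = 15, n_gaps = 5,
                    n_markers = 8)
  sim <- simulate_study(cfg)
  hits <- place_markers(sim$markers$markers, sim$derived$genome, 0)
  qtl <- armcompare:::marker_qtl_table(sim$markers$markers, 4)
  anch <- anchor_qtls(hits, qtl)
  expect_true(all(anch$anchored))
  tr <- sim$markers$truth
  for (i in seq_len(nrow(anch))) {
    mids <- tr$pos[tr$marker_id %in%
                     qtl$marker_id[qtl$qtl_id == anch$qtl_id[i]]] +
      tr$product_len[tr$marker_id %in%
                       qtl$marker_id[qtl$qtl_id == anch$qtl_id[i]]] / 2
    expect_true(all(mids >= anch$start[i] - 1 & mids <= anch$end[i] + 1))
  }
})
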