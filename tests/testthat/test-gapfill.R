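test_that("extract_flanks truncates at sequence ends and neighbouring gaps", {
  asm <- tibble::tibble(id = "s", seq = "ACGTNNNNACGT")
  fl <- extract_flanks(asm, tibble::tibble(start = 4L, end = 8L), flank_len = 4)
  expect_equal(fl$left_seq, "ACGT")
  expect_equal(fl$right_seq, "ACGT")
  expect_false(fl$left_truncated)
  expect_false(fl$terminal)

  set.seed(31)
  s <- rand_seq(3000)
  v <- strsplit(s, "")[[1]]
  v[101:110] <- "N"          # gap at 100..110, 100 bp from the start
  v[311:320] <- "N"          # second gap 200 bp downstream
  asm2 <- tibble::tibble(id = "s", seq = paste(v, collapse = ""))
  f1 <- extract_flanks(asm2, tibble::tibble(start = 100L, end = 110L), 1500)
  expect_equal(nchar(f1$left_seq), 100)
  expect_true(f1$left_truncated)
  # right flank stops at the next gap
  expect_equal(nchar(f1$right_seq), 200)
  expect_false(grepl("N", f1$right_seq))

  # terminal gap: no left flank
  v2 <- strsplit(rand_seq(500), "")[[1]]
  v2[1:10] <- "N"
  f2 <- extract_flanks(tibble::tibble(id = "s", seq = paste(v2, collapse = "")),
                       tibble::tibble(start = 0L, end = 10L), 100)
  expect_true(f2$terminal)
})

# build a tiny closure instance by hand: flank + gap + flank inside a filler
make_instance <- function(seed, rc = FALSE) {
  set.seed(seed)
  left <- rand_seq(400); fill <- rand_seq(120); right <- rand_seq(400)
  filler <- paste0(rand_seq(150), left, fill, right, rand_seq(150))
  if (rc) filler <- rc_oracle(filler)
  asm <- tibble::tibble(id = "s",
                        seq = paste0(left, strrep("N", 120), right))
  pool <- tibble::tibble(id = "f1", seq = filler)
  list(asm = asm, pool = pool, fill = fill,
       gap = tibble::tibble(start = 400L, end = 520L))
}

test_that("propose_closure recovers the true fill on both filler strands", {
  for (rc in c(FALSE, TRUE)) {
    inst <- make_instance(32, rc = rc)
    rules <- closure_rules(flank_len = 400, min_hit_len = 100)
    fl <- extract_flanks(inst$asm, inst$gap, rules$flank_len)
    idx <- build_index(inst$pool, k = rules$k)
    hits <- local_align(tibble::tibble(id = c("left", "right"),
                                       seq = c(fl$left_seq, fl$right_seq)),
                        idx, rules$min_hit_identity, rules$min_hit_len)
    ev <- propose_closure(fl, dplyr::filter(hits, query_id == "left"),
                          dplyr::filter(hits, query_id == "right"),
                          inst$pool, rules, "test")
    expect_equal(ev$status, "closed")
    expect_equal(ev$patch_seq, inst$fill)
    expect_equal(ev$strand, if (rc) "-" else "+")
  }
})

test_that("flanks hitting different fillers only cannot close a gap", {
  inst <- make_instance(33)
  # split the filler so left and right flanks live on different sequences
  f <- inst$pool$seq
  pool2 <- tibble::tibble(id = c("fa", "fb"),
                          seq = c(substr(f, 1, 550), substr(f, 671, 1220)))
  rules <- closure_rules(flank_len = 400, min_hit_len = 100)
  fl <- extract_flanks(inst$asm, inst$gap, rules$flank_len)
  idx <- build_index(pool2, k = rules$k)
  hits <- local_align(tibble::tibble(id = c("left", "right"),
                                     seq = c(fl$left_seq, fl$right_seq)),
                      idx, rules$min_hit_identity, rules$min_hit_len)
  ev <- propose_closure(fl, dplyr::filter(hits, query_id == "left"),
                        dplyr::filter(hits, query_id == "right"),
                        pool2, rules, "test")
  expect_equal(ev$status, "unclosed")
  expect_equal(ev$reject_reason, "no common filler")
})

test_that("inverted flank order on the filler is rejected", {
  set.seed(34)
  left <- rand_seq(400); right <- rand_seq(400)
  # filler carries right BEFORE left: wrong order on either strand
  filler <- paste0(rand_seq(100), right, rand_seq(50), left, rand_seq(100))
  asm <- tibble::tibble(id = "s", seq = paste0(left, strrep("N", 80), right))
  pool <- tibble::tibble(id = "f1", seq = filler)
  rules <- closure_rules(flank_len = 400, min_hit_len = 100)
  fl <- extract_flanks(asm, tibble::tibble(start = 400L, end = 480L),
                       rules$flank_len)
  idx <- build_index(pool, k = rules$k)
  hits <- local_align(tibble::tibble(id = c("left", "right"),
                                     seq = c(fl$left_seq, fl$right_seq)),
                      idx, rules$min_hit_identity, rules$min_hit_len)
  ev <- propose_closure(fl, dplyr::filter(hits, query_id == "left"),
                        dplyr::filter(hits, query_id == "right"),
                        pool, rules, "test")
  expect_equal(ev$status, "unclosed")
  expect_equal(ev$reject_reason, "order/strand")
})

test_that("overlapping flanks give merged_overlap with the trim recorded", {
  set.seed(35)
  core <- rand_seq(1000)
  left <- substr(core, 1, 430)        # last 30 bp shared with right
  right <- substr(core, 401, 830)
  filler <- paste0(rand_seq(100), core, rand_seq(100))
  asm <- tibble::tibble(id = "s", seq = paste0(left, strrep("N", 50), right))
  pool <- tibble::tibble(id = "f1", seq = filler)
  rules <- closure_rules(flank_len = 430, min_hit_len = 100)
  fl <- extract_flanks(asm, tibble::tibble(start = 430L, end = 480L),
                       rules$flank_len)
  idx <- build_index(pool, k = rules$k)
  hits <- local_align(tibble::tibble(id = c("left", "right"),
                                     seq = c(fl$left_seq, fl$right_seq)),
                      idx, rules$min_hit_identity, rules$min_hit_len)
  ev <- propose_closure(fl, dplyr::filter(hits, query_id == "left"),
                        dplyr::filter(hits, query_id == "right"),
                        pool, rules, "test")
  expect_equal(ev$status, "merged_overlap")
  expect_equal(ev$overlap_trim, 30)
  expect_equal(ev$patch_seq, "")
})

test_that("close_gaps leaves the sequence untouched when nothing closes", {
  cfg <- sim_config(seed = 36, arm_length = 1.5e5, n_genes = 15, n_gaps = 5,
                    n_markers = 5, withheld_frac = 1)
  sim <- simulate_study(cfg)
  res <- close_gaps(sim$fragments$assembly, sim$fragments$pools)
  expect_identical(res$assembly$seq, sim$fragments$assembly$seq)
})

test_that("closure on error-free pools is exact, with a faithful liftover", {
  cfg <- sim_config(seed = 37, arm_length = 3e5, n_genes = 30, n_gaps = 12,
                    n_markers = 5)
  sim <- simulate_study(cfg)
  res <- close_gaps(sim$fragments$assembly, sim$fragments$pools)
  tr <- sim$fragments$truth
  m <- dplyr::inner_join(res$events, tr, by = "start")
  closed <- m$status == "closed"
  expect_true(all(m$patch_seq[closed] == m$true_fill[closed])) # precision 1
  expect_gte(mean(closed), 0.95)
  # length arithmetic
  expect_equal(nchar(res$assembly$seq),
               nchar(sim$fragments$assembly$seq) -
                 sum(m$gap_len[closed]) + sum(m$patch_len[closed]))
  # liftover points at the same base character
  set.seed(1)
  orig <- sim$fragments$assembly$seq
  pos <- sample(which(strsplit(orig, "")[[1]] != "N"), 200) - 1
  new_pos <- liftover_pos(res$liftover, pos)
  expect_false(any(is.na(new_pos)))
  expect_equal(substring(res$assembly$seq, new_pos + 1, new_pos + 1),
               substring(orig, pos + 1, pos + 1))
})

test_that("adding a filler pool never decreases the number of closed gaps", {
  cfg <- sim_config(seed = 38, arm_length = 2e5, n_genes = 20, n_gaps = 8,
                    n_markers = 5)
  sim <- simulate_study(cfg)
  pools <- sim$fragments$pools
  n_closed <- function(p) {
    sum(close_gaps(sim$fragments$assembly, p)$events$status != "unclosed")
  }
  n1 <- n_closed(pools[1])
  n2 <- n_closed(pools[1:2])
  n3 <- n_closed(pools)
  expect_true(n1 <= n2 && n2 <= n3)
})

test_that("summarize_closures reproduces the census-style means", {
  ev <- tibble::tibble(
    start = seq_len(2), end = seq_len(2) + 1, gap_len = c(100L, 200L),
    status = "closed", source_label = c("a", "b"), filler_id = "f",
    strand = "+", patch_seq = "", patch_len = c(90L, 210L),
    overlap_trim = 0L, reject_reason = NA_character_)
  sm <- summarize_closures(ev)
  expect_equal(sm$gap_length_total[sm$source == "Total"], 300)

  # printed-table arithmetic: totals / counts round to the published means
  expect_equal(armcompare:::round_half_away(3491264 / 8043), 434)
  expect_equal(armcompare:::round_half_away(28986 / 33), 878)
  expect_equal(armcompare:::round_half_away(5798173 / 12825), 452)

  empty <- summarize_closures(ev[0, ])
  expect_equal(empty$n_closed, 0L)
})
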