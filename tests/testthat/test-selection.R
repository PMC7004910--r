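test_that("identical sequences give zero distances and undefined omega", {
  cds <- rand_cds(50)
  r <- ng86_dnds(cds, cds)
  expect_equal(r$Sd, 0)
  expect_equal(r$Nd, 0)
  expect_equal(r$dS, 0)
  expect_equal(r$dN, 0)
  expect_true(is.na(r$omega))
  expect_equal(r$S + r$N, 3 * r$codons)
})

test_that("a single synonymous change moves dS but not dN", {
  a <- "ATGAAACCCGGGTTTCTTATTGTTTCTTAA"   # 10 codons
  b <- a
  substr(b, 6, 6) <- "G"                  # AAA -> AAG, both Lys
  r <- ng86_dnds(a, b)
  expect_equal(r$Nd, 0)
  expect_equal(r$dN, 0)
  expect_gt(r$dS, 0)
})

test_that("NG86 counts match exhaustive pathway enumeration on random pairs", {
  set.seed(51)
  for (i in 1:150) {
    n <- sample(2:5, 1)
    a <- rand_cds(n + 2)
    # mutate b at random positions, keeping it a valid, unsaturated CDS
    repeat {
      b <- a
      v <- strsplit(b, "")[[1]]
      k <- sample(1:4, 1)
      idx <- sample(length(v), k)
      v[idx] <- sample(NUC4, k, TRUE)
      b <- paste(v, collapse = "")
      r <- tryCatch(ng86_dnds(a, b), error = function(e) NULL)
      if (!is.null(r)) break
    }
    o <- oracle_ng86_counts(a, b)
    expect_equal(r$S, unname(o["S"]), tolerance = 1e-12)
    expect_equal(r$N, unname(o["N"]), tolerance = 1e-12)
    expect_equal(r$Sd, unname(o["Sd"]), tolerance = 1e-12)
    expect_equal(r$Nd, unname(o["Nd"]), tolerance = 1e-12)
  }
})

test_that("ng86_dnds is symmetric in its arguments", {
  set.seed(52)
  for (i in 1:20) {
    a <- rand_cds(30)
    b <- armcompare:::evolve_cds(a, omega = 1, rate = 0.05)
    r1 <- ng86_dnds(a, b)
    r2 <- ng86_dnds(b, a)
    expect_equal(r1[, c("S", "N", "Sd", "Nd", "dS", "dN")],
                 r2[, c("S", "N", "Sd", "Nd", "dS", "dN")])
  }
})

test_that("ng86_dnds validates its inputs", {
  expect_error(ng86_dnds("ATGAAA", "ATGAAATTT"), "mismatch")
  expect_error(ng86_dnds("ATGTAATTT", "ATGAAATTT"), "stop")
  # saturation: maximally divergent short pair
  expect_error(ng86_dnds("ATGAAAAAAAAA", "ATGCCCCCCCCC"), "saturated")
})

test_that("selection classes split at omega = 1", {
  pairs <- tibble::tibble(omega = c(5, 0.2, NA, 1))
  cls <- classify_selection(pairs)$selection_class
  expect_equal(cls, c("PSG", "NSG", "unclassified", "unclassified"))
})

test_that("ENC hits its theoretical limits", {
  # one codon per amino acid: maximal bias, ENC = 20
  one_per_aa <- c("ATG", "TGG", "TTT", "CTT", "ATT", "GTT", "TCT", "CCT",
                  "ACT", "GCT", "TAT", "CAT", "CAA", "AAT", "AAA", "GAT",
                  "GAA", "TGT", "CGT", "GGT")
  cds1 <- paste0(paste(rep(paste(one_per_aa, collapse = ""), 30),
                       collapse = ""), "TAA")
  expect_equal(codon_metrics(cds1)$enc, 20)

  # uniform use of all 61 sense codons: no bias, ENC = 61
  sense <- armcompare:::sense_codons()
  cds2 <- paste0(paste(rep(paste(sense, collapse = ""), 20), collapse = ""),
                 "TAA")
  expect_equal(codon_metrics(cds2)$enc, 61, tolerance = 1e-9)
})

test_that("the twofold ENC component decreases as usage skews", {
  # lysine-only toy family (AAA/AAG) at increasing bias
  enc_at <- function(p) {
    n <- 200
    codons <- c(rep("AAA", round(p * n)), rep("AAG", n - round(p * n)))
    armcompare:::enc_wright(codons)
  }
  vals <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9, 0.99), enc_at, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("CAI is 1 when every codon is optimal and weights behave", {
  cds <- "ATGAAACCCGGGTTTTAA"
  w <- setNames(rep(1, 64), armcompare:::all_codons())
  expect_equal(codon_metrics(cds, reference_weights = w)$cai, 1)
  expect_error(codon_metrics(cds, cai = TRUE), "reference_weights")
  # weights built from a skewed reference rank the preferred codon at 1
  ref <- paste0("ATG", strrep("AAA", 30), strrep("AAG", 10), "TAA")
  ww <- cai_reference_weights(ref)
  expect_equal(ww[["AAA"]], 1)
  expect_equal(ww[["AAG"]], 1 / 3)
})

test_that("gc and gc3 are computed over the sense codons", {
  m <- codon_metrics("ATGGGTATTTAA")   # M G I stop; thirds G,T,T
  expect_equal(m$length, 9L)
  expect_equal(m$gc3, 1 / 3)
  expect_equal(m$gc, 3 / 9)
})

test_that("Spearman correlations match rank-then-Pearson to 1e-12", {
  set.seed(53)
  feats <- tibble::tibble(a = rnorm(50), b = rnorm(50),
                          c = sample(1:10, 50, TRUE), d = runif(50))
  feats$e <- -feats$a
  fc <- feature_correlation(feats)
  for (i in names(feats)) for (j in names(feats)) {
    expect_equal(fc$rho[i, j], oracle_spearman(feats[[i]], feats[[j]]),
                 tolerance = 1e-12)
  }
  expect_equal(fc$rho["a", "a"], 1)
  expect_equal(fc$rho["a", "e"], -1)
  expect_true(all(abs(fc$rho - t(fc$rho)) < 1e-12, na.rm = TRUE))
  # p-values agree with cor.test's t approximation
  r <- unname(suppressWarnings(
    cor.test(feats$a, feats$b, method = "spearman"))$estimate)
  expect_equal(fc$p["a", "b"], 2 * pt(-abs(r * sqrt(48 / (1 - r^2))), 48),
               tolerance = 1e-10)
})

test_that("constant features are reported as missing", {
  feats <- tibble::tibble(a = rnorm(10), b = rep(2, 10))
  fc <- feature_correlation(feats)
  expect_true(is.na(fc$rho["a", "b"]))
  expect_false(is.na(fc$rho["a", "a"]))
  expect_error(feature_correlation(tibble::tibble(a = 1:3)), ">= 5")
})

test_that("tidy() returns the long form of the correlation object", {
  set.seed(54)
  fc <- feature_correlation(tibble::tibble(a = rnorm(20), b = rnorm(20)))
  td <- tidy(fc)
  expect_equal(nrow(td), 4)
  expect_equal(td$rho[td$feature_a == "a" & td$feature_b == "b"],
               fc$rho["a", "b"])
})
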