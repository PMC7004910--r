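# Independent oracles used by the tests. These deliberately share no code
# with the package implementation: the aligner oracle is a plain quadratic
# local DP, the NG86 oracle enumerates substitution pathways recursively, the
# Fisher oracle enumerates all fixed-margin tables via binomial coefficients.

NUC4 <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(NUC4, n, replace = TRUE), collapse = "")

rc_oracle <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# random in-frame CDS of n codons (start + sense body + stop)
rand_cds <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste0("ATG",
         paste(sample(sense, n_codons - 2, replace = TRUE), collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

# ---- aligner oracle: exhaustive affine local DP, score only ----------------
# match +1 / mismatch -1 / gap open -2 / gap extend -1 (first gap base -3)
sw_oracle_score <- function(q, t) {
  qv <- strsplit(q, "")[[1]]; tv <- strsplit(t, "")[[1]]
  m <- length(qv); n <- length(tv)
  NEG <- -1e9
  Hprev <- numeric(n + 1); H <- numeric(n + 1); Fv <- rep(NEG, n + 1)
  best <- 0
  for (i in 1:m) {
    tmp <- Hprev; Hprev <- H; H <- tmp
    H[1] <- 0
    E <- NEG
    sub <- ifelse(tv == qv[i], 1, -1)
    for (j in 1:n) {
      E <- max(H[j] - 3, E - 1)
      Fv[j + 1] <- max(Hprev[j + 1] - 3, Fv[j + 1] - 1)
      H[j + 1] <- max(0, Hprev[j] + sub[j], E, Fv[j + 1])
    }
    best <- max(best, max(H))
  }
  best
}

# ---- NG86 oracle: recursive pathway enumeration ----------------------------
GC_TAB <- as.character(Biostrings::GENETIC_CODE)
names(GC_TAB) <- names(Biostrings::GENETIC_CODE)

# synonymous site count of one codon: fraction of the 9 single-base changes
# that preserve the amino acid (changes to stops count as nonsynonymous)
oracle_syn_sites <- function(codon) {
  aa <- GC_TAB[codon]
  tot <- 0
  for (pos in 1:3) for (nt in setdiff(NUC4, substr(codon, pos, pos))) {
    alt <- codon
    substr(alt, pos, pos) <- nt
    if (GC_TAB[alt] != "*" && GC_TAB[alt] == aa) tot <- tot + 1
  }
  tot / 3
}

# pathway-averaged (sd, nd) between two codons, recursing over which
# differing position to change next; pathways through stops dropped
oracle_codon_sd_nd <- function(a, b) {
  paths <- list()
  recurse <- function(cur, acc_s, acc_n, blocked) {
    dif <- which(strsplit(cur, "")[[1]] != strsplit(b, "")[[1]])
    if (length(dif) == 0) {
      paths[[length(paths) + 1]] <<- c(acc_s, acc_n, blocked)
      return()
    }
    for (p in dif) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      syn <- GC_TAB[cur] != "*" && GC_TAB[nxt] != "*" &&
        GC_TAB[cur] == GC_TAB[nxt]
      recurse(nxt, acc_s + syn, acc_n + !syn,
              blocked || GC_TAB[nxt] == "*")
    }
  }
  recurse(a, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  open <- m[m[, 3] == 0, , drop = FALSE]
  use <- if (nrow(open) > 0) open else m
  c(sd = mean(use[, 1]), nd = mean(use[, 2]))
}

oracle_ng86_counts <- function(cds_a, cds_b) {
  ca <- substring(cds_a, seq(1, nchar(cds_a), 3), seq(3, nchar(cds_a), 3))
  cb <- substring(cds_b, seq(1, nchar(cds_b), 3), seq(3, nchar(cds_b), 3))
  S <- sum((vapply(ca, oracle_syn_sites, 0) +
              vapply(cb, oracle_syn_sites, 0)) / 2)
  sdnd <- vapply(seq_along(ca),
                 function(i) oracle_codon_sd_nd(ca[i], cb[i]), numeric(2))
  c(S = S, N = 3 * length(ca) - S, Sd = sum(sdnd[1, ]), Nd = sum(sdnd[2, ]))
}

# ---- Fisher oracle: enumeration over fixed-margin tables -------------------
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- a + b + c + d
  xs <- max(0, c1 - r2):min(c1, r1)
  lp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(N, c1)
  lobs <- lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(N, c1)
  sum(exp(lp[lp <= lobs + log(1 + 1e-7)]))
}

# ---- Benjamini-Hochberg oracle ---------------------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# ---- Spearman oracle: rank then Pearson ------------------------------------
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
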