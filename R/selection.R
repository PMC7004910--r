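# Pairwise dN/dS by the Nei-Gojobori (1986) counting method with Jukes-Cantor
# correction, PSG/NSG classification, Wright's effective number of codons,
# the codon adaptation index, and Spearman feature correlations.

split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

validate_cds <- function(cds, what = "cds") {
  if (nchar(cds) %% 3 != 0) stop(what, ": length not divisible by 3")
  if (grepl("[^ACGT]", cds)) stop(what, ": contains non-ACGT characters")
  codons <- split_codons(cds)
  aa <- genetic_code()[codons]
  if (any(aa[-length(aa)] == "*")) stop(what, ": internal stop codon")
  codons
}

#' Nei-Gojobori dN/dS for one aligned coding pair
#'
#' Counting estimator: per-codon synonymous site fractions are averaged over
#' the two sequences; codons differing at more than one position have their
#' synonymous/nonsynonymous difference counts averaged uniformly over all
#' shortest substitution pathways, discarding pathways that pass through a
#' stop codon. Proportions are Jukes-Cantor corrected,
#' d = -(3/4) ln(1 - 4p/3). `omega` is `dN/dS`, `NA` when `dS = 0`.
#'
#' @param cds_a,cds_b gap-free, equal-length, in-frame coding sequences
#'   (terminal stop codons allowed and compared like any codon; internal stops
#'   rejected).
#' @return one-row tibble: `gene_a`, `gene_b` (names if given, else "a"/"b"),
#'   `codons`, `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`.
#' @examples
#' ng86_dnds("ATGAAACCC", "ATGAAGCCC")
#' @export
ng86_dnds <- function(cds_a, cds_b) {
  name_a <- names(cds_a) %||% "a"
  name_b <- names(cds_b) %||% "b"
  cds_a <- unname(cds_a); cds_b <- unname(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) stop("ng86_dnds: length mismatch")
  ca <- validate_cds(cds_a, "cds_a")
  cb <- validate_cds(cds_b, "cds_b")
  L <- length(ca)
  ss <- syn_sites_table()
  S <- sum((ss[ca] + ss[cb]) / 2)
  N <- 3 * L - S
  tab <- codon_diff_table()
  keys <- paste0(ca, cb)
  Sd <- sum(unlist(tab$sd[keys], use.names = FALSE))
  Nd <- sum(unlist(tab$nd[keys], use.names = FALSE))
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) {
    if (p >= 3 / 4) stop("ng86_dnds: saturated (p >= 3/4), distance undefined")
    -(3 / 4) * log(1 - 4 * p / 3)
  }
  dS <- jc(pS)
  dN <- jc(pN)
  omega <- if (dS == 0) NA_real_ else dN / dS
  tibble::tibble(gene_a = name_a, gene_b = name_b, codons = L,
                 S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, omega = omega)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' dN/dS over a table of coding pairs
#'
#' @param pairs tibble with columns `gene_a`, `gene_b`, `cds_a`, `cds_b`.
#' @return tibble with one [ng86_dnds()] row per pair.
#' @export
ng86_dnds_pairs <- function(pairs) {
  purrr::pmap_dfr(pairs[, c("gene_a", "gene_b", "cds_a", "cds_b")],
                  function(gene_a, gene_b, cds_a, cds_b) {
    out <- ng86_dnds(cds_a, cds_b)
    out$gene_a <- gene_a
    out$gene_b <- gene_b
    out
  })
}

#' Classify coding pairs into positively / negatively selected genes
#'
#' `omega > 1` is positively selected (PSG), `omega < 1` negatively selected
#' (NSG); pairs with undefined omega (dS = 0) or omega exactly 1 are
#' unclassified.
#'
#' @param pairs tibble with at least `omega` (e.g. from [ng86_dnds_pairs()]).
#' @return the input with a `selection_class` column in
#'   {"PSG", "NSG", "unclassified"}.
#' @export
classify_selection <- function(pairs) {
  cls <- dplyr::case_when(
    is.na(pairs$omega) ~ "unclassified",
    pairs$omega > 1 ~ "PSG",
    pairs$omega < 1 ~ "NSG",
    TRUE ~ "unclassified"
  )
  dplyr::mutate(pairs, selection_class = cls)
}

#' Codon-usage features of one coding sequence
#'
#' Computes GC content, GC at third codon positions, Wright's effective number
#' of codons (ENC) and, when reference weights are supplied, the codon
#' adaptation index (CAI, geometric mean of relative adaptiveness over
#' non-Met/Trp/stop codons).
#'
#' ENC uses the homozygosity estimator F = (n * sum p^2 - 1) / (n - 1) per
#' amino acid (n = codon count for that amino acid, used when n >= 2), class
#' means over the degeneracy classes of the standard code (2 one-codon, 9
#' twofold, 1 threefold, 5 fourfold, 3 sixfold), with a missing class mean
#' imputed from the average of the available class means (the threefold class,
#' isoleucine only, is imputed as the 2- and 4-fold average when both exist);
#' the result is capped to [20, 61].
#'
#' @param cds in-frame coding sequence.
#' @param reference_weights optional named numeric: codon -> relative
#'   adaptiveness in (0, 1]; required if `cai = TRUE`.
#' @param cai compute CAI? Default `TRUE` when weights given.
#' @param expression optional numeric covariate carried through.
#' @return one-row tibble: `gc`, `gc3`, `length`, `enc`, `cai`, `expression`.
#' @export
codon_metrics <- function(cds, reference_weights = NULL,
                          cai = !is.null(reference_weights),
                          expression = NA_real_) {
  codons <- validate_cds(cds)
  code <- genetic_code()
  # drop terminal stop from usage statistics
  if (code[codons[length(codons)]] == "*") codons <- codons[-length(codons)]
  bases <- strsplit(paste(codons, collapse = ""), "", fixed = TRUE)[[1]]
  gc <- mean(bases %in% c("G", "C"))
  third <- substr(codons, 3, 3)
  gc3 <- mean(third %in% c("G", "C"))

  enc <- enc_wright(codons)

  cai_val <- NA_real_
  if (cai) {
    if (is.null(reference_weights)) {
      stop("codon_metrics: CAI requested but no reference_weights supplied")
    }
    keep <- !(code[codons] %in% c("M", "W", "*"))
    w <- reference_weights[codons[keep]]
    if (any(is.na(w))) stop("codon_metrics: reference_weights missing codons")
    cai_val <- exp(mean(log(w)))
  }
  tibble::tibble(gc = gc, gc3 = gc3, length = 3L * length(codons),
                 enc = enc, cai = cai_val, expression = expression)
}

# Wright's ENC over a vector of (sense) codons
enc_wright <- function(codons) {
  deg <- degeneracy_classes()
  code <- genetic_code()
  aa <- code[codons]
  fhat <- numeric(0)
  fsize <- integer(0)
  for (a in names(deg$families)) {
    idx <- aa == a
    n <- sum(idx)
    if (n >= 2) {
      p <- table(factor(codons[idx], levels = deg$families[[a]])) / n
      f <- (n * sum(p^2) - 1) / (n - 1)
      fhat <- c(fhat, f)
      fsize <- c(fsize, deg$sizes[[a]])
    }
  }
  class_sizes <- c(2, 3, 4, 6)
  class_counts <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)
  means <- vapply(class_sizes, function(sz) {
    v <- fhat[fsize == sz]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  names(means) <- as.character(class_sizes)
  # impute missing classes
  if (is.na(means["3"]) && !is.na(means["2"]) && !is.na(means["4"])) {
    means["3"] <- (means["2"] + means["4"]) / 2
  }
  glob <- mean(means, na.rm = TRUE)
  means[is.na(means)] <- glob
  # guard against zero class means (extreme small samples)
  means[means <= 0] <- 1e-9
  enc <- 2 + class_counts["2"] / means["2"] + class_counts["3"] / means["3"] +
    class_counts["4"] / means["4"] + class_counts["6"] / means["6"]
  unname(min(61, max(20, enc)))
}

#' Relative-adaptiveness weights from a reference sequence set
#'
#' Standard CAI reference table: within each amino-acid family, w(codon) =
#' count(codon) / count(most used synonym). Zero counts get a small floor
#' (0.01) so the geometric mean stays defined.
#'
#' @param cds_vec character vector of in-frame coding sequences.
#' @return named numeric vector codon -> weight in (0, 1].
#' @export
cai_reference_weights <- function(cds_vec) {
  codons <- unlist(lapply(cds_vec, split_codons), use.names = FALSE)
  code <- genetic_code()
  codons <- codons[code[codons] != "*"]
  deg <- degeneracy_classes()
  w <- setNames(rep(0.01, length(sense_codons())), sense_codons())
  for (a in names(deg$families)) {
    fam <- deg$families[[a]]
    cnt <- table(factor(codons[code[codons] == a], levels = fam))
    if (sum(cnt) == 0 || max(cnt) == 0) { w[fam] <- 1; next }
    ww <- as.numeric(cnt) / max(cnt)
    ww[ww == 0] <- 0.01
    w[fam] <- ww
  }
  w
}

#' Spearman rank-correlation matrix of gene features
#'
#' Spearman rho with average ranks for ties; two-sided p-values from the
#' t approximation, t = rho * sqrt((n-2) / (1-rho^2)). Constant features give
#' `NA` rows/columns.
#'
#' @param features tibble of numeric per-gene columns (e.g. gc, gc3, length,
#'   enc, cai, dN, dS, omega); non-numeric columns are dropped.
#' @return object of class `feature_correlation`: list with `rho` and `p`
#'   matrices and `n` (genes used per pair, complete cases).
#' @export
feature_correlation <- function(features) {
  num <- features[vapply(features, is.numeric, logical(1))]
  if (nrow(num) < 5) stop("feature_correlation: need >= 5 genes")
  vars <- names(num)
  k <- length(vars)
  rho <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  pmat <- rho
  nmat <- matrix(NA_integer_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    x <- num[[i]]; y <- num[[j]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    nmat[i, j] <- n
    if (n < 5) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    r <- stats::cor(x[ok], y[ok], method = "spearman")
    rho[i, j] <- r
    if (i == j) { pmat[i, j] <- 0; next }
    if (abs(r) >= 1) { pmat[i, j] <- 0; next }
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    pmat[i, j] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  diag(rho)[!is.na(diag(rho))] <- 1
  structure(list(rho = rho, p = pmat, n = nmat), class = "feature_correlation")
}

#' @export
print.feature_correlation <- function(x, ...) {
  cat("<feature_correlation> Spearman rho over", ncol(x$rho), "features\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' Tidy a feature correlation into long form
#'
#' @param x a [feature_correlation()] object.
#' @param ... unused.
#' @return tibble: `feature_a`, `feature_b`, `rho`, `p`, `n`.
#' @importFrom generics tidy
#' @export
tidy.feature_correlation <- function(x, ...) {
  vars <- colnames(x$rho)
  grid <- expand.grid(feature_a = vars, feature_b = vars,
                      stringsAsFactors = FALSE)
  tibble::tibble(feature_a = grid$feature_a, feature_b = grid$feature_b,
                 rho = as.vector(x$rho), p = as.vector(x$p),
                 n = as.vector(x$n))
}

#' @export
generics::tidy
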