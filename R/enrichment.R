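# Exact 2x2 association tests and category enrichment with BH control.
# Point-probability two-sided rule, computed from log hypergeometric masses.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditions on the margins; the two-sided p-value is the sum of
#' hypergeometric point probabilities not exceeding that of the observed table
#' (within relative tolerance 1e-7, guarding floating-point ties). Masses are
#' evaluated in log space. The odds ratio is the sample odds ratio
#' a*d / (b*c).
#'
#' @param a,b,c,d nonnegative integer cell counts, laid out as rows
#'   (a, b) / (c, d).
#' @return named list: `p` (two-sided), `odds_ratio`.
#' @examples
#' fisher_exact_2x2(12, 41, 126, 2738)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    warning("fisher_exact_2x2: degenerate table (zero margin); p = 1")
    return(list(p = 1, odds_ratio = NA_real_))
  }
  m <- a + b        # row 1 total
  n <- c + d        # row 2 total
  k <- a + c        # column 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  x <- lo:hi
  logp <- stats::dhyper(x, m, n, k, log = TRUE)
  lobs <- stats::dhyper(a, m, n, k, log = TRUE)
  p <- sum(exp(logp[logp <= lobs + log(1 + 1e-7)]))
  p <- min(1, p)
  or <- (a * d) / (b * c)
  list(p = p, odds_ratio = or)
}

#' 2x2 table from subset counts
#'
#' Given k category hits in a foreground of size n drawn from a background of
#' size N containing K category hits overall, build the 2x2 table in which the
#' background EXCLUDES the foreground: (k, n-k, K-k, N-n-(K-k)).
#'
#' @param k foreground category hits; `n` foreground size; `K` background
#'   category hits (foreground included); `N` background size.
#' @param n,K,N see above.
#' @return named integer vector c(a, b, c, d).
#' @examples
#' subset_table(12, 53, 138, 2917) # c(12, 41, 126, 2738)
#' @export
subset_table <- function(k, n, K, N) {
  if (!(k <= n && k <= K && n <= N && K <= N)) {
    stop("subset_table: need k <= n, k <= K, n <= N, K <= N")
  }
  d <- (N - n) - (K - k)
  if (d < 0) stop("subset_table: inconsistent counts (negative cell)")
  c(a = k, b = n - k, c = K - k, d = d)
}

#' Category enrichment of a foreground gene set
#'
#' One exact test per category with at least one foreground hit, on the
#' subset-construction table of [subset_table()], with Benjamini-Hochberg
#' adjustment across the tested categories.
#'
#' @param foreground character vector of gene ids, a subset of `background`.
#' @param background character vector of gene ids.
#' @param annotation tibble with columns `gene_id`, `category_id` and
#'   optionally `category_name` (genes may carry several categories).
#' @param method multiple-testing method; only "BH" supported.
#' @return tibble sorted by `p`: `category_id`, `category_name`, `k`, `n`,
#'   `K`, `N`, `odds_ratio`, `p`, `p_adj`.
#' @export
category_enrichment <- function(foreground, background, annotation,
                                method = "BH") {
  method <- match.arg(method, "BH")
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background)) {
    stop("category_enrichment: foreground must be a subset of background")
  }
  ann <- dplyr::filter(annotation, .data$gene_id %in% background)
  ann <- dplyr::distinct(ann, .data$gene_id, .data$category_id,
                         .keep_all = TRUE)
  n <- length(foreground)
  N <- length(background)
  fg_ann <- dplyr::filter(ann, .data$gene_id %in% foreground)
  cats <- unique(fg_ann$category_id)
  if (length(cats) == 0) {
    return(tibble::tibble(category_id = character(), category_name = character(),
                          k = integer(), n = integer(), K = integer(),
                          N = integer(), odds_ratio = numeric(),
                          p = numeric(), p_adj = numeric()))
  }
  rows <- purrr::map_dfr(cats, function(cat) {
    in_cat <- unique(ann$gene_id[ann$category_id == cat])
    k <- sum(foreground %in% in_cat)
    K <- length(in_cat)
    tb <- subset_table(k, n, K, N)
    ft <- fisher_exact_2x2(tb["a"], tb["b"], tb["c"], tb["d"])
    nm <- if ("category_name" %in% names(ann)) {
      ann$category_name[ann$category_id == cat][1]
    } else NA_character_
    tibble::tibble(category_id = cat, category_name = nm,
                   k = k, n = n, K = K, N = N,
                   odds_ratio = ft$odds_ratio, p = ft$p)
  })
  rows$p_adj <- stats::p.adjust(rows$p, method = "BH")
  dplyr::arrange(rows, .data$p)
}
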