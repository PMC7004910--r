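# LTR retrotransposon insertion dating. At insertion the two long terminal
# repeats of an element are identical; their divergence K (Jukes-Cantor
# corrected) dates the insertion via T = K / (2 r), with r the substitution
# rate per site per year.

#' Divergence between the paired LTRs of one element
#'
#' Columns containing a gap character (`-`) or `N` in either copy are dropped
#' (count reported); `p` is the mismatch proportion over the remaining columns
#' and `K` its Jukes-Cantor correction -(3/4) ln(1 - 4p/3).
#'
#' @param ltr5,ltr3 equal-length aligned LTR strings (>= 50 comparable
#'   columns required).
#' @return one-row tibble: `columns` (compared), `dropped`, `mismatches`,
#'   `p`, `K`.
#' @examples
#' ltr_divergence(strrep("ACGT", 20), strrep("ACGT", 20))
#' @export
ltr_divergence <- function(ltr5, ltr3) {
  if (nchar(ltr5) != nchar(ltr3)) stop("ltr_divergence: length mismatch")
  a <- strsplit(toupper(ltr5), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(ltr3), "", fixed = TRUE)[[1]]
  bad <- a %in% c("-", "N") | b %in% c("-", "N")
  dropped <- sum(bad)
  if (dropped > 0) message(dropped, " gap/N column(s) dropped")
  a <- a[!bad]; b <- b[!bad]
  ncol_cmp <- length(a)
  if (ncol_cmp < 50) stop("ltr_divergence: fewer than 50 comparable columns")
  mm <- sum(a != b)
  p <- mm / ncol_cmp
  if (p >= 3 / 4) stop("ltr_divergence: saturated (p >= 3/4)")
  K <- -(3 / 4) * log(1 - 4 * p / 3)
  tibble::tibble(columns = ncol_cmp, dropped = dropped, mismatches = mm,
                 p = p, K = K)
}

#' Insertion time from divergence, T = K / (2 r)
#'
#' @param K corrected divergence, substitutions/site (>= 0).
#' @param r substitution rate, substitutions/site/year; default 1.3e-8 (the
#'   conventional grass rate).
#' @return insertion time in years.
#' @examples
#' insertion_time(0.0065) # 250000
#' @export
insertion_time <- function(K, r = 1.3e-8) {
  if (any(r <= 0)) stop("insertion_time: r must be > 0")
  stopifnot(all(K >= 0))
  K / (2 * r)
}

#' Date a cohort of LTR elements
#'
#' @param elements tibble with columns `element_id`, `ltr5`, `ltr3`.
#' @param r substitution rate per site per year.
#' @return tibble: `element_id`, `columns`, `p`, `K`, `T_years`.
#' @export
date_ltr_cohort <- function(elements, r = 1.3e-8) {
  out <- purrr::pmap_dfr(elements[, c("element_id", "ltr5", "ltr3")],
                         function(element_id, ltr5, ltr3) {
    d <- suppressMessages(ltr_divergence(ltr5, ltr3))
    d$element_id <- element_id
    d
  })
  out$T_years <- insertion_time(out$K, r)
  dplyr::select(out, "element_id", "columns", "p", "K", "T_years")
}
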