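# Standard genetic code tables shared by the simulator (codon evolver) and the
# selection module (NG86, ENC, CAI). All tables are built in code at first use
# and cached in .armcompare_cache.

NUCS <- c("A", "C", "G", "T")

#' All 64 codons in lexicographic order
#' @keywords internal
#' @noRd
all_codons <- function() {
  g <- expand.grid(p3 = NUCS, p2 = NUCS, p1 = NUCS, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

#' The standard genetic code as a named character vector codon -> amino acid
#' (one-letter, "*" for stop)
#' @keywords internal
#' @noRd
genetic_code <- function() {
  if (!is.null(.armcompare_cache$gc)) return(.armcompare_cache$gc)
  aa <- Biostrings::GENETIC_CODE
  code <- setNames(as.character(aa), names(aa))
  .armcompare_cache$gc <- code
  code
}

is_stop_codon <- function(codon) unname(genetic_code()[codon] == "*")

sense_codons <- function() {
  code <- genetic_code()
  names(code)[code != "*"]
}

#' Translate a CDS string to protein; "*" marks stops.
#' @keywords internal
#' @noRd
translate_cds <- function(cds) {
  stopifnot(nchar(cds) %% 3 == 0)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste0(genetic_code()[codons], collapse = "")
}

#' Per-codon synonymous site count (NG86 convention).
#'
#' For each codon position the fraction of the three possible single-nucleotide
#' changes that are synonymous; changes creating a stop codon count as
#' nonsynonymous, so the per-codon synonymous + nonsynonymous site counts sum
#' to exactly 3.
#' @keywords internal
#' @noRd
syn_sites_table <- function() {
  if (!is.null(.armcompare_cache$syn_sites)) return(.armcompare_cache$syn_sites)
  code <- genetic_code()
  codons <- all_codons()
  s <- vapply(codons, function(cd) {
    aa <- code[cd]
    tot <- 0
    for (pos in 1:3) {
      for (nt in setdiff(NUCS, substr(cd, pos, pos))) {
        alt <- cd
        substr(alt, pos, pos) <- nt
        if (code[alt] != "*" && code[alt] == aa) tot <- tot + 1 / 3
      }
    }
    tot
  }, numeric(1))
  .armcompare_cache$syn_sites <- s
  s
}

#' Pathway-averaged synonymous/nonsynonymous difference counts for a codon pair.
#'
#' Enumerates all shortest substitution pathways between two codons, drops
#' pathways passing through a stop codon, and averages per-step synonymous and
#' nonsynonymous counts uniformly over the surviving pathways. If every pathway
#' is blocked by a stop (cannot happen for sense end-points differing at < 3
#' sites in the standard code, but guarded), all pathways are used.
#' @return c(sd, nd)
#' @keywords internal
#' @noRd
codon_pair_diffs <- function(codon_a, codon_b) {
  key <- paste0(codon_a, codon_b)
  tab <- codon_diff_table()
  c(sd = tab$sd[[key]], nd = tab$nd[[key]])
}

# Build the full 64x64 lookup of pathway-averaged (Sd, Nd) as named lists.
codon_diff_table <- function() {
  if (!is.null(.armcompare_cache$diff_tab)) return(.armcompare_cache$diff_tab)
  code <- genetic_code()
  codons <- all_codons()
  sd <- new.env(parent = emptyenv())
  nd <- new.env(parent = emptyenv())

  step_counts <- function(from, to) {
    # single-nucleotide step from -> to: c(syn, nonsyn)
    if (code[from] != "*" && code[to] != "*" && code[from] == code[to]) c(1, 0) else c(0, 1)
  }

  pair_value <- function(a, b) {
    pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    d <- length(pos)
    if (d == 0) return(c(0, 0))
    perms <- if (d == 1) list(pos) else if (d == 2) {
      list(pos, rev(pos))
    } else {
      list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
           pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
    }
    acc <- list(); blocked_acc <- list()
    for (ord in perms) {
      cur <- a; tot <- c(0, 0); blocked <- FALSE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(b, p, p)
        tot <- tot + step_counts(cur, nxt)
        if (code[nxt] == "*") blocked <- TRUE
        cur <- nxt
      }
      if (blocked) blocked_acc[[length(blocked_acc) + 1]] <- tot
      else acc[[length(acc) + 1]] <- tot
    }
    use <- if (length(acc) > 0) acc else blocked_acc
    Reduce(`+`, use) / length(use)
  }

  for (a in codons) for (b in codons) {
    v <- pair_value(a, b)
    key <- paste0(a, b)
    assign(key, v[1], envir = sd)
    assign(key, v[2], envir = nd)
  }
  tab <- list(sd = as.list(sd), nd = as.list(nd))
  .armcompare_cache$diff_tab <- tab
  tab
}

#' Synonymous-codon degeneracy classes of the standard code.
#'
#' Amino acids grouped by family size counting stop-free synonym sets:
#' 2 one-codon (M, W), 9 twofold, 1 threefold (I), 5 fourfold and 3 sixfold
#' (L, S, R) families.
#' @keywords internal
#' @noRd
degeneracy_classes <- function() {
  if (!is.null(.armcompare_cache$degen)) return(.armcompare_cache$degen)
  code <- genetic_code()
  code <- code[code != "*"]
  fam <- split(names(code), code)
  sizes <- vapply(fam, length, integer(1))
  .armcompare_cache$degen <- list(families = fam, sizes = sizes)
  .armcompare_cache$degen
}
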