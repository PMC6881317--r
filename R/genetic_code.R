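# Internal codon-state tables for the 61-state Markov model (standard code).
# Built once at load time; stop codons are excluded from the state space.

.codon <- new.env(parent = emptyenv())

.build_codon_tables <- function() {
  gc_tab <- Biostrings::GENETIC_CODE
  all_codons <- names(gc_tab)
  sense <- all_codons[gc_tab != "*"]
  aa <- unname(gc_tab[sense])
  n <- length(sense)
  stopifnot(n == 61L)

  # pairwise single-nucleotide-difference metadata
  split3 <- do.call(rbind, strsplit(sense, ""))
  one_diff <- matrix(FALSE, n, n)
  is_ts <- matrix(FALSE, n, n)      # transition at the differing position
  is_syn <- matrix(FALSE, n, n)     # same encoded amino acid
  purines <- c("A", "G")
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      diff_pos <- which(split3[i, ] != split3[j, ])
      if (length(diff_pos) != 1L) next
      one_diff[i, j] <- one_diff[j, i] <- TRUE
      a <- split3[i, diff_pos]; b <- split3[j, diff_pos]
      ts <- (a %in% purines) == (b %in% purines)
      is_ts[i, j] <- is_ts[j, i] <- ts
      syn <- aa[i] == aa[j]
      is_syn[i, j] <- is_syn[j, i] <- syn
    }
  }

  .codon$codons <- sense
  .codon$aa <- aa
  .codon$stops <- all_codons[gc_tab == "*"]
  .codon$one_diff <- one_diff
  .codon$is_ts <- is_ts
  .codon$is_syn <- is_syn
  .codon$translate <- stats::setNames(c(aa, rep("*", 3L)),
                                      c(sense, all_codons[gc_tab == "*"]))
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  .build_codon_tables()
}

#' Sense codons of the standard genetic code
#'
#' The 61 codon states of the substitution model, in the fixed internal
#' order used by all rate matrices and likelihood routines.
#'
#' @return Character vector of 61 codons.
#' @export
sense_codons <- function() .codon$codons

#' Translate codons to amino acids
#'
#' @param codons character vector of codons (uppercase, no gaps).
#' @return Character vector of one-letter amino acids (`"*"` for stops).
#' @export
translate_codons <- function(codons) {
  aa <- .codon$translate[codons]
  if (anyNA(aa)) {
    bad <- unique(codons[is.na(aa)])
    stop("not a codon over {A,C,G,T}: ", paste(bad, collapse = ", "))
  }
  unname(aa)
}

# codon string -> state index 1..61 (NA for gaps/ambiguity/stops)
.codon_index <- function(codons) match(codons, .codon$codons)
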