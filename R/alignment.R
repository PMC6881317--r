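# Codon alignments: construction, FASTA input, back-translation, and the
# complete-deletion filter applied before every likelihood or diversity
# computation.

#' Construct a codon alignment
#'
#' A `CodonAlignment` stores aligned in-frame coding sequences as a matrix of
#' 3-letter codon strings (rows = taxa, columns = codon sites) over the
#' standard genetic code. It is the unit of all likelihood computation.
#'
#' @param sequences named character vector of aligned nucleotide sequences
#'   (equal lengths, multiples of 3), or a character matrix of codon strings
#'   with row names.
#' @return An object of class `CodonAlignment` with fields `taxa`, `codons`
#'   (character matrix) and `code`.
#' @export
codon_alignment <- function(sequences) {
  if (is.matrix(sequences)) {
    codons <- toupper(sequences)
    taxa <- rownames(codons)
    if (is.null(taxa)) stop("codon matrix must have row names")
  } else {
    taxa <- names(sequences)
    if (is.null(taxa)) stop("sequences must be named")
    seqs <- toupper(sequences)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("alignment error: sequences have unequal lengths")
    if (lens[1] %% 3L != 0L)
      stop("frame error: alignment length ", lens[1], " is not a multiple of 3")
    n_sites <- lens[1] %/% 3L
    codons <- matrix("", length(seqs), n_sites)
    for (i in seq_along(seqs))
      codons[i, ] <- substring(seqs[i], 3L * seq_len(n_sites) - 2L,
                               3L * seq_len(n_sites))
    rownames(codons) <- taxa
  }
  if (anyDuplicated(taxa))
    stop("label error: duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  structure(list(taxa = taxa, codons = codons, code = "standard"),
            class = "CodonAlignment")
}

#' @export
print.CodonAlignment <- function(x, ...) {
  cat("CodonAlignment:", length(x$taxa), "taxa x", ncol(x$codons),
      "codon sites\n")
  invisible(x)
}

#' Number of codon columns in an alignment
#' @param aln a `CodonAlignment`.
#' @export
site_count <- function(aln) ncol(aln$codons)

#' Read an in-frame codon alignment from FASTA
#'
#' @param path FASTA file of aligned coding sequences.
#' @param frame_check require the alignment length to be a multiple of 3
#'   (default `TRUE`).
#' @return A [codon_alignment()], record order preserved, lowercase
#'   normalized to uppercase.
#' @export
read_codon_fasta <- function(path, frame_check = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("alignment error: ragged sequence lengths in ", path)
  if (lens[1] %% 3L != 0L) {
    if (frame_check)
      stop("frame error: length ", lens[1], " not a multiple of 3 in ", path)
    seqs <- substr(seqs, 1L, (lens[1] %/% 3L) * 3L)  # drop partial codon
  }
  codon_alignment(seqs)
}

#' Write a codon alignment to FASTA
#' @param aln a `CodonAlignment`.
#' @param path output file.
#' @export
write_codon_fasta <- function(aln, path) {
  seqs <- apply(aln$codons, 1L, paste0, collapse = "")
  writeLines(paste0(">", aln$taxa, "\n", seqs), path)
  invisible(path)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Maps each amino-acid column of an aligned protein matrix onto one codon
#' column of the corresponding unaligned coding sequences; protein gaps
#' become codon gaps `"---"`. The ungapped translation of each coding
#' sequence must equal the ungapped protein row.
#'
#' @param protein_alignment named character vector of aligned amino-acid
#'   sequences (gaps as `-`), or a character matrix of residues.
#' @param cds named character vector of unaligned coding sequences (no
#'   terminal stop).
#' @return A [codon_alignment()] with gap codons where the protein has gaps.
#' @export
backtranslate <- function(protein_alignment, cds) {
  if (is.matrix(protein_alignment)) {
    prot <- apply(protein_alignment, 1L, paste0, collapse = "")
    names(prot) <- rownames(protein_alignment)
  } else prot <- protein_alignment
  prot <- toupper(prot)
  cds <- toupper(cds)
  if (!all(names(prot) %in% names(cds)))
    stop("back-translation error: coding sequence missing for ",
         paste(setdiff(names(prot), names(cds)), collapse = ", "))
  n_col <- unique(nchar(prot))
  if (length(n_col) != 1L)
    stop("alignment error: protein rows have unequal lengths")
  out <- matrix("---", length(prot), n_col, dimnames = list(names(prot), NULL))
  for (tx in names(prot)) {
    residues <- strsplit(prot[[tx]], "")[[1]]
    keep <- residues != "-"
    seq_tx <- cds[[tx]]
    n_cod <- nchar(seq_tx) %/% 3L
    if (sum(keep) != n_cod)
      stop("back-translation error: ", tx, ": ", sum(keep),
           " aligned residues but ", n_cod, " codons")
    codons <- substring(seq_tx, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
    trans <- translate_codons(codons)
    mism <- which(trans != residues[keep] & residues[keep] != "X")
    if (length(mism))
      stop("back-translation error: ", tx, " position ", mism[1],
           ": codon ", codons[mism[1]], " translates to ", trans[mism[1]],
           " not ", residues[keep][mism[1]])
    out[tx, keep] <- codons
  }
  codon_alignment(out)
}

#' Remove all columns containing gaps, ambiguity codes, or stop codons
#'
#' The complete-deletion filter: any codon column in which any taxon has a
#' gap, an ambiguity code (anything outside `{A,C,G,T}`), or a stop codon is
#' removed. The order of surviving columns is preserved. The result is the
#' gap-free alignment over which all likelihoods, Tajima's D, and Ka/Ks are
#' computed.
#'
#' @param aln a `CodonAlignment`.
#' @return A `CodonAlignment` whose every cell is one of the 61 sense codons.
#' @export
complete_deletion <- function(aln) {
  idx <- matrix(.codon_index(aln$codons), nrow = nrow(aln$codons))
  keep <- colSums(is.na(idx)) == 0L
  if (!any(keep))
    stop("empty-alignment error: no codon column survives complete deletion")
  out <- aln
  out$codons <- aln$codons[, keep, drop = FALSE]
  out
}

# integer state matrix (taxa x sites), errors if gaps remain
.state_matrix <- function(aln) {
  idx <- matrix(.codon_index(aln$codons), nrow = nrow(aln$codons),
                dimnames = list(aln$taxa, NULL))
  if (anyNA(idx))
    stop("alignment contains gaps/ambiguity/stop codons; run complete_deletion() first")
  idx
}
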