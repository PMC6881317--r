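# Neutrality and dating statistics: Tajima's D under complete deletion,
# Nei-Gojobori (1986) pathway-counting Ka/Ks with Jukes-Cantor correction,
# synonymous-clock age estimation, and the cohort enrichment test.

# a1 = sum_{i=1}^{m-1} 1/i
.tajima_a1 <- function(m) sum(1 / seq_len(m - 1L))

#' Watterson's theta per site from the proportion of segregating sites
#'
#' `theta = ps / a1` with `ps = S / n_sites` and
#' `a1 = sum_{i=1}^{m-1} 1/i`, `m` the number of sequences.
#'
#' @param ps proportion of segregating sites.
#' @param m number of sequences.
#' @export
watterson_theta <- function(ps, m) ps / .tajima_a1(m)

#' Tajima's D neutrality test
#'
#' Computes the number of segregating sites, mean pairwise nucleotide
#' diversity, Watterson's theta and Tajima's D over the nucleotide columns
#' of a codon alignment, after complete deletion of gapped columns.
#'
#' @param aln a `CodonAlignment` (complete deletion is applied internally),
#'   or a character matrix of single nucleotides (rows = sequences).
#' @return A `TajimaResult`: `m`, `n_sites`, `S`, `ps`, `a1`, `theta`,
#'   `pi` (per site), `D` (`NA` with a `note` when `S = 0`).
#' @export
tajima_d <- function(aln) {
  if (inherits(aln, "CodonAlignment")) {
    aln <- complete_deletion(aln)
    nuc <- matrix("", nrow(aln$codons), 3L * ncol(aln$codons))
    for (j in seq_len(ncol(aln$codons))) {
      sp <- strsplit(aln$codons[, j], "")
      nuc[, (3L * j - 2L):(3L * j)] <- do.call(rbind, sp)
    }
  } else nuc <- aln
  m <- nrow(nuc)
  if (m < 4L) stop("Tajima's D needs at least 4 sequences")
  n_sites <- ncol(nuc)
  S <- sum(vapply(seq_len(n_sites),
                  function(j) length(unique(nuc[, j])) > 1L, TRUE))
  ps <- S / n_sites
  a1 <- .tajima_a1(m)
  # mean pairwise difference count
  kbar <- 0
  n_pairs <- m * (m - 1L) / 2
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
    kbar <- kbar + sum(nuc[i, ] != nuc[j, ])
  kbar <- kbar / n_pairs
  res <- list(m = m, n_sites = n_sites, S = S, ps = ps, a1 = a1,
              theta = ps / a1, pi = kbar / n_sites, D = NA_real_,
              note = NULL)
  if (S == 0L) {
    res$note <- "no segregating sites: D undefined"
    return(structure(res, class = "TajimaResult"))
  }
  a2 <- sum(1 / seq_len(m - 1L)^2)
  b1 <- (m + 1) / (3 * (m - 1))
  b2 <- 2 * (m^2 + m + 3) / (9 * m * (m - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (m + 2) / (a1 * m) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  res$D <- (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  structure(res, class = "TajimaResult")
}

#' @export
print.TajimaResult <- function(x, ...) {
  cat(sprintf("Tajima: m=%d sites=%d S=%d ps=%.3f theta=%.3f pi=%.3f D=%s\n",
              x$m, x$n_sites, x$S, x$ps, x$theta, x$pi,
              ifelse(is.na(x$D), "NA", sprintf("%.3f", x$D))))
  invisible(x)
}

# --- NG86 ------------------------------------------------------------------

# memo tables for NG86 (filled lazily; codon-pair keys)
.ng86_cache <- new.env(parent = emptyenv())

# synonymous/nonsynonymous site counts of one codon (changes to stop codons
# contribute to neither count)
.ng86_sites_raw <- function(codon) {
  nuc <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1]]
  aa <- .codon$translate[[codon]]
  s <- 0; n <- 0
  for (pos in 1:3) for (alt in setdiff(nuc, chars[pos])) {
    mut <- chars; mut[pos] <- alt
    aa2 <- .codon$translate[[paste0(mut, collapse = "")]]
    if (aa2 == "*") next
    if (aa2 == aa) s <- s + 1 / 3 else n <- n + 1 / 3
  }
  c(S = s, N = n)
}

.ng86_sites <- function(codon) {
  key <- paste0("s.", codon)
  v <- .ng86_cache[[key]]
  if (is.null(v)) {
    v <- .ng86_sites_raw(codon)
    .ng86_cache[[key]] <- v
  }
  v
}

# synonymous/nonsynonymous differences between two codons, averaged with
# equal weight over all minimal substitution pathways; pathways through a
# stop codon are excluded (unless every pathway is blocked)
.ng86_diffs_raw <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  if (!length(pos)) return(c(Sd = 0, Nd = 0))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  paths <- perms(pos)
  tally <- list()
  for (ord in paths) {
    cur <- a; s <- 0; n <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      c1 <- paste0(cur, collapse = ""); c2 <- paste0(nxt, collapse = "")
      if (.codon$translate[[c2]] == "*") { blocked <- TRUE; break }
      if (.codon$translate[[c1]] == .codon$translate[[c2]]) s <- s + 1
      else n <- n + 1
      cur <- nxt
    }
    tally[[length(tally) + 1L]] <- list(s = s, n = n, blocked = blocked)
  }
  ok <- !vapply(tally, `[[`, TRUE, "blocked")
  use <- if (any(ok)) tally[ok] else tally
  c(Sd = mean(vapply(use, `[[`, 0, "s")),
    Nd = mean(vapply(use, `[[`, 0, "n")))
}

.ng86_diffs <- function(ca, cb) {
  key <- paste0(ca, cb)
  v <- .ng86_cache[[key]]
  if (is.null(v)) {
    v <- .ng86_diffs_raw(ca, cb)
    .ng86_cache[[key]] <- v
  }
  v
}

#' Nei-Gojobori (1986) Ka and Ks between two coding sequences
#'
#' Counts synonymous and nonsynonymous sites by the 1/3-per-position
#' convention averaged over the two sequences (changes to stop codons are
#' disregarded), counts differences by equal-weight averaging over all
#' minimal substitution pathways per codon, and applies the Jukes-Cantor
#' correction `d = -(3/4) log(1 - 4 p / 3)` to both proportions.
#'
#' @param seqA,seqB equal-length in-frame gap-free nucleotide strings or
#'   codon vectors.
#' @return list `Ka`, `Ks`, `Ka_Ks`, plus the raw counts `S_sites`,
#'   `N_sites`, `Sd`, `Nd`, `pS`, `pN`.
#' @export
ng86 <- function(seqA, seqB) {
  to_codons <- function(s) {
    if (length(s) > 1L) return(toupper(s))
    s <- toupper(s)
    if (nchar(s) %% 3L != 0L) stop("frame error: length not a multiple of 3")
    substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  }
  ca <- to_codons(seqA); cb <- to_codons(seqB)
  if (length(ca) != length(cb)) stop("sequences differ in length")
  if (anyNA(.codon_index(ca)) || anyNA(.codon_index(cb)))
    stop("sequences must be gap-free sense codons")
  sa <- vapply(ca, .ng86_sites, numeric(2))
  sb <- vapply(cb, .ng86_sites, numeric(2))
  S_sites <- (sum(sa["S", ]) + sum(sb["S", ])) / 2
  N_sites <- (sum(sa["N", ]) + sum(sb["N", ])) / 2
  d <- vapply(seq_along(ca), function(i) .ng86_diffs(ca[i], cb[i]),
              numeric(2))
  Sd <- sum(d["Sd", ]); Nd <- sum(d["Nd", ])
  jc <- function(p) {
    if (p == 0) return(0)
    arg <- 1 - 4 * p / 3
    if (arg <= 0) stop("saturation error: p = ", signif(p, 4),
                       " >= 3/4, Jukes-Cantor correction undefined")
    -0.75 * log(arg)
  }
  pS <- Sd / S_sites; pN <- Nd / N_sites
  Ks <- jc(pS); Ka <- jc(pN)
  list(Ka = Ka, Ks = Ks,
       Ka_Ks = if (Ks > 0) Ka / Ks else if (Ka > 0) Inf else NA_real_,
       S_sites = S_sites, N_sites = N_sites, Sd = Sd, Nd = Nd,
       pS = pS, pN = pN)
}

#' Age of a duplication from its synonymous divergence
#'
#' `T = Ks / (2 r)` under a synonymous molecular clock, reported in million
#' years. The default rate is the rice synonymous substitution rate
#' 6.5e-9 substitutions per site per year.
#'
#' @param ks synonymous substitutions per synonymous site (vectorized).
#' @param rate substitutions/site/year.
#' @return Age(s) in million years.
#' @export
age_from_ks <- function(ks, rate = 6.5e-9) {
  stopifnot(all(ks >= 0), rate > 0)
  ks / (2 * rate) / 1e6
}

#' Codon-bootstrap confidence interval for NG86 Ks
#'
#' Resamples codon columns with replacement, recomputes Ks, and reports the
#' point estimate with a 95% half-width `1.96 * SE(bootstrap)`.
#'
#' @param seqA,seqB as in [ng86()] (>= 30 codons).
#' @param n_boot bootstrap replicates.
#' @param seed integer; the replicate set is deterministic given the seed.
#' @return list `ks`, `ci_half_width`, `n_boot`, `n_failed` (saturated
#'   replicates, dropped); a warning is attached when more than 5% fail.
#' @export
ks_confidence <- function(seqA, seqB, n_boot = 1000L, seed = 1L) {
  to_codons <- function(s) {
    if (length(s) > 1L) return(toupper(s))
    s <- toupper(s)
    substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  }
  ca <- to_codons(seqA); cb <- to_codons(seqB)
  if (length(ca) < 30L) stop("need at least 30 codons for the bootstrap")
  point <- ng86(ca, cb)$Ks
  set.seed(seed)
  boots <- numeric(n_boot); failed <- 0L
  for (r in seq_len(n_boot)) {
    idx <- sample.int(length(ca), replace = TRUE)
    boots[r] <- tryCatch(ng86(ca[idx], cb[idx])$Ks,
                         error = function(e) NA_real_)
    if (is.na(boots[r])) failed <- failed + 1L
  }
  ok <- !is.na(boots)
  out <- list(ks = point,
              ci_half_width = 1.96 * stats::sd(boots[ok]),
              n_boot = n_boot, n_failed = failed)
  if (failed > 0.05 * n_boot)
    warning("saturation in ", failed, " of ", n_boot,
            " bootstrap replicates")
  out
}

#' Fisher exact enrichment of positive selection in a cohort
#'
#' Two-sided Fisher exact test of `hits / total` against an expected
#' baseline proportion, with the baseline represented as
#' `round(baseline_rate * baseline_n)` hits out of `baseline_n`.
#'
#' @param hits positives in the cohort.
#' @param total cohort size.
#' @param baseline_rate expected genome-wide proportion.
#' @param baseline_n size of the comparison set the proportion refers to.
#' @return list `odds_ratio` (conditional MLE), `p`, `table`.
#' @export
enrichment_test <- function(hits, total, baseline_rate, baseline_n) {
  stopifnot(hits <= total)
  base_hits <- round(baseline_rate * baseline_n)
  tab <- matrix(c(hits, total - hits, base_hits, baseline_n - base_hits),
                2L, 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    return(list(odds_ratio = NA_real_, p = 1, table = tab))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}
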