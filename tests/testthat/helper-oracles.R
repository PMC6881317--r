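# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately written as plain loops from first principles,
# separate from the package's vectorized/c cached implementations.

# Tajima's D from the original formula set, straight off a nucleotide
# matrix (rows = sequences)
oracle_tajima <- function(nuc) {
  m <- nrow(nuc); n <- ncol(nuc)
  S <- 0L
  for (j in seq_len(n)) if (length(unique(nuc[, j])) > 1L) S <- S + 1L
  diffs <- c()
  for (i in seq_len(m - 1L)) for (k in (i + 1L):m)
    diffs <- c(diffs, sum(nuc[i, ] != nuc[k, ]))
  khat <- mean(diffs)
  a1 <- sum(1 / (1:(m - 1)))
  a2 <- sum(1 / (1:(m - 1))^2)
  b1 <- (m + 1) / (3 * (m - 1))
  b2 <- 2 * (m^2 + m + 3) / (9 * m * (m - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (m + 2) / (a1 * m) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(S = S, pi = khat / n,
       D = if (S == 0) NA_real_ else
         (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1)))
}

# NG86 site and difference counts by exhaustive per-codon enumeration,
# using the genetic code table directly
oracle_ng86_counts <- function(codA, codB) {
  GC <- Biostrings::GENETIC_CODE
  nuc <- c("A", "C", "G", "T")
  count_sites <- function(codon) {
    ch <- strsplit(codon, "")[[1]]
    s <- 0
    n <- 0
    for (pos in 1:3) {
      for (alt in nuc[nuc != ch[pos]]) {
        mut <- ch
        mut[pos] <- alt
        aa <- GC[[paste(mut, collapse = "")]]
        if (aa == "*") next
        if (aa == GC[[codon]]) s <- s + 1 / 3 else n <- n + 1 / 3
      }
    }
    c(s, n)
  }
  all_orders <- function(v) {
    if (length(v) == 1) return(list(v))
    res <- list()
    for (i in seq_along(v)) {
      for (tail in all_orders(v[-i])) res[[length(res) + 1]] <- c(v[i], tail)
    }
    res
  }
  count_diffs <- function(c1, c2) {
    x <- strsplit(c1, "")[[1]]; y <- strsplit(c2, "")[[1]]
    dp <- which(x != y)
    if (!length(dp)) return(c(0, 0))
    res <- list()
    for (ord in all_orders(dp)) {
      cur <- x; sd <- 0; nd <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur; nxt[p] <- y[p]
        a1 <- GC[[paste(cur, collapse = "")]]
        a2 <- GC[[paste(nxt, collapse = "")]]
        if (a2 == "*") { ok <- FALSE; break }
        if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      res[[length(res) + 1]] <- list(sd = sd, nd = nd, ok = ok)
    }
    good <- Filter(function(r) r$ok, res)
    if (!length(good)) good <- res
    c(mean(sapply(good, `[[`, "sd")), mean(sapply(good, `[[`, "nd")))
  }
  S_sites <- 0; N_sites <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(codA)) {
    sa <- count_sites(codA[i]); sb <- count_sites(codB[i])
    S_sites <- S_sites + (sa[1] + sb[1]) / 2
    N_sites <- N_sites + (sa[2] + sb[2]) / 2
    d <- count_diffs(codA[i], codB[i])
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  list(S_sites = S_sites, N_sites = N_sites, Sd = Sd, Nd = Nd)
}

# matrix exponential by scaled Taylor series (small matrices only)
oracle_expm <- function(Q, t, terms = 40L) {
  n <- nrow(Q)
  A <- Q * t
  k <- max(0L, ceiling(log2(max(1e-12, max(abs(A))) / 0.25)))
  A <- A / 2^k
  P <- diag(n)
  term <- diag(n)
  for (i in seq_len(terms)) {
    term <- term %*% A / i
    P <- P + term
  }
  for (i in seq_len(k)) P <- P %*% P
  P
}

# random gap-free codon alignment (uniform codons)
rand_codon_aln <- function(ntaxa, nsites, seed) {
  set.seed(seed)
  m <- matrix(sample(sense_codons(), ntaxa * nsites, replace = TRUE),
              ntaxa, nsites,
              dimnames = list(paste0("t", seq_len(ntaxa)), NULL))
  codon_alignment(m)
}

# the standard 6-taxon test tree (substitutions per codon)
tree6 <- function() read_newick(
  text = "((A:0.05,B:0.07):0.03,(C:0.04,D:0.06):0.02,(E:0.08,F:0.2):0.04);")

nuc_matrix <- function(aln) {
  nuc <- matrix("", nrow(aln$codons), 3L * ncol(aln$codons))
  for (j in seq_len(ncol(aln$codons)))
    nuc[, (3 * j - 2):(3 * j)] <- do.call(rbind, strsplit(aln$codons[, j], ""))
  nuc
}
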