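# The 61-state codon substitution model: Goldman-Yang style rates with a
# transition/transversion ratio kappa and a nonsynonymous/synonymous ratio
# omega, equilibrium frequencies over sense codons, matrix exponentials via
# the reversible (pi^1/2) symmetrization, and Felsenstein pruning.

.OMEGA_MIN <- 1e-6
.OMEGA_CAP <- 999      # reporting convention for effectively infinite omega
.KAPPA_MIN <- 1e-3
.KAPPA_MAX <- 100

#' Codon model specification
#'
#' Bundles the parameters of the codon substitution model: kappa
#' (transition/transversion rate ratio), one omega (dN/dS) per branch via
#' `omega_of_branch` or a single shared value, and equilibrium codon
#' frequencies.
#'
#' @param kappa transition/transversion rate ratio, in `[1e-3, 100]`.
#' @param omega shared dN/dS ratio, in `[1e-6, 999]`; ignored when
#'   `omega_of_branch` is given.
#' @param freqs numeric vector of 61 equilibrium sense-codon frequencies
#'   (summing to 1); default uniform.
#' @param freq_mode one of `"uniform"`, `"F1x4"`, `"F3x4"`,
#'   `"observed-codon"`; recorded for provenance when `freqs` came from
#'   [codon_frequencies()].
#' @param omega_of_branch optional numeric vector of per-branch omegas,
#'   indexed by branch id.
#' @return An object of class `CodonModelSpec`.
#' @export
codon_model_spec <- function(kappa = 2, omega = 0.3, freqs = NULL,
                             freq_mode = "uniform", omega_of_branch = NULL) {
  if (is.null(freqs)) freqs <- rep(1 / 61, 61L)
  stopifnot(length(freqs) == 61L, all(freqs >= 0))
  if (abs(sum(freqs) - 1) > 1e-12) stop("frequencies must sum to 1")
  check_omega <- function(w) {
    if (any(w < .OMEGA_MIN - 1e-15 | w > .OMEGA_CAP + 1e-12))
      stop("omega out of [", .OMEGA_MIN, ", ", .OMEGA_CAP, "]")
  }
  check_omega(omega)
  if (!is.null(omega_of_branch)) check_omega(omega_of_branch)
  if (kappa < .KAPPA_MIN || kappa > .KAPPA_MAX)
    stop("kappa out of [", .KAPPA_MIN, ", ", .KAPPA_MAX, "]")
  structure(list(kappa = kappa, omega = omega, freqs = freqs,
                 freq_mode = freq_mode, omega_of_branch = omega_of_branch),
            class = "CodonModelSpec")
}

#' @export
print.CodonModelSpec <- function(x, ...) {
  cat("CodonModelSpec\n")
  cat("  kappa:", x$kappa, "\n")
  cat("  omega:", if (is.null(x$omega_of_branch)) x$omega
      else paste(signif(x$omega_of_branch, 4), collapse = ","), "\n")
  cat("  freq_mode:", x$freq_mode, "\n")
  invisible(x)
}

#' Equilibrium codon frequencies from an alignment
#'
#' @param aln gap-free `CodonAlignment`.
#' @param mode `"uniform"` (1/61 each), `"F1x4"` (overall nucleotide
#'   frequencies), `"F3x4"` (per-codon-position nucleotide frequencies), or
#'   `"observed-codon"` (empirical sense-codon proportions, the analogue of
#'   estimating frequencies from the data). Stop-codon mass is renormalized
#'   away for the nucleotide-product modes; zero observed frequencies are
#'   floored at 1e-10 so likelihoods stay finite.
#' @return Numeric vector of 61 frequencies summing to 1, named by codon.
#' @export
codon_frequencies <- function(aln, mode = c("observed-codon", "uniform",
                                            "F1x4", "F3x4")) {
  mode <- match.arg(mode)
  codons <- .codon$codons
  if (mode == "uniform")
    return(stats::setNames(rep(1 / 61, 61L), codons))
  states <- .state_matrix(aln)
  if (mode == "observed-codon") {
    cnt <- tabulate(states, nbins = 61L)
    f <- cnt / sum(cnt)
    f <- pmax(f, 1e-10)
    return(stats::setNames(f / sum(f), codons))
  }
  nuc <- c("A", "C", "G", "T")
  split3 <- do.call(rbind, strsplit(codons, ""))
  chars <- matrix(unlist(strsplit(aln$codons, "")), nrow = 3L)
  if (mode == "F1x4") {
    p <- prop.table(table(factor(chars, levels = nuc)))
    f <- p[split3[, 1]] * p[split3[, 2]] * p[split3[, 3]]
  } else { # F3x4
    p_pos <- lapply(1:3, function(k)
      prop.table(table(factor(chars[k, ], levels = nuc))))
    f <- p_pos[[1]][split3[, 1]] * p_pos[[2]][split3[, 2]] *
      p_pos[[3]][split3[, 3]]
  }
  f <- pmax(as.numeric(f), 1e-10)
  stats::setNames(f / sum(f), codons)
}

# unscaled rate matrix: r[i,j] = pi_j * kappa^[ts] * omega^[nonsyn] on
# single-difference pairs, zero elsewhere, zero diagonal
.unscaled_rates <- function(freqs, kappa, omega) {
  r <- matrix(0, 61L, 61L)
  od <- .codon$one_diff
  r[od] <- rep(freqs, each = 61L)[od]     # pi_j: column j recycled by row
  r[od & .codon$is_ts] <- r[od & .codon$is_ts] * kappa
  ns <- od & !.codon$is_syn
  r[ns] <- r[ns] * omega
  r
}

# total, synonymous and nonsynonymous flux of an unscaled rate matrix
.flux <- function(r, freqs) {
  per_row <- freqs * r
  syn <- .codon$one_diff & .codon$is_syn
  c(S = sum(per_row[syn]), N = sum(per_row[.codon$one_diff & !.codon$is_syn]))
}

#' Codon rate matrix (generator)
#'
#' Builds the 61x61 generator with entries
#' `q(i,j) = pi_j * kappa^[transition] * omega^[nonsynonymous]` on
#' single-nucleotide-difference codon pairs, diagonal set so rows sum to
#' zero, and (by default) scaled so the expected number of substitutions per
#' unit time is 1 at this omega, so branch lengths read as substitutions per
#' codon.
#'
#' @param spec a [codon_model_spec()].
#' @param omega dN/dS used for this matrix (defaults to `spec$omega`).
#' @param scale normalize total flux to 1 (default `TRUE`).
#' @return 61x61 generator matrix, rownames/colnames = codons.
#' @export
rate_matrix <- function(spec, omega = spec$omega, scale = TRUE) {
  r <- .unscaled_rates(spec$freqs, spec$kappa, omega)
  if (scale) {
    fl <- sum(.flux(r, spec$freqs))
    if (fl > 0) r <- r / fl
  }
  diag(r) <- -rowSums(r)
  dimnames(r) <- list(.codon$codons, .codon$codons)
  r
}

# eigen machinery for P(t) = exp(Qt), exploiting reversibility:
# A = D^{1/2} Q D^{-1/2} is symmetric (D = diag(pi))
.eigen_Q <- function(Q, freqs) {
  sq <- sqrt(freqs)
  A <- Q * (sq %o% (1 / sq))
  A <- (A + t(A)) / 2              # symmetrize against rounding
  e <- eigen(A, symmetric = TRUE)
  list(values = e$values,
       U1 = e$vectors / sq,              # D^{-1/2} U   (rows scaled)
       U2 = t(e$vectors * sq))           # U' D^{1/2}
}

.pmat_from_eigen <- function(eig, t) {
  P <- eig$U1 %*% (exp(eig$values * t) * eig$U2)
  P[P < 0] <- 0
  P
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q t)` computed by symmetric eigendecomposition; rows sum to 1
#' and `P(0)` is the identity.
#'
#' @param Q generator from [rate_matrix()].
#' @param t branch length (>= 0), expected substitutions per codon when `Q`
#'   is flux-scaled.
#' @param freqs the equilibrium frequencies `Q` was built with; needed for
#'   the stable reversible eigendecomposition.
#' @return 61x61 stochastic matrix.
#' @export
transition_matrix <- function(Q, t, freqs) {
  if (t < 0) stop("branch length must be >= 0")
  P <- .pmat_from_eigen(.eigen_Q(Q, freqs), t)
  if (any(!is.finite(P)))
    stop("computation error: matrix exponential did not converge")
  P
}

# --- pruning ---------------------------------------------------------------

# site-pattern compression: states (ntaxa x nsites) -> list(patterns, weights)
.compress_patterns <- function(states) {
  key <- apply(states, 2L, paste, collapse = ".")
  f <- factor(key, levels = unique(key))
  list(patterns = states[, !duplicated(key), drop = FALSE],
       weights = as.numeric(table(f)[levels(f)]),
       index = as.integer(f))
}

# Felsenstein pruning over compressed patterns.
# patterns: ntip x npat integer states (rows ordered as phy$tip.label);
# P_list: per-branch transition matrices (branch id = postorder edge row).
# Returns vector of per-pattern log-likelihoods. The fast path carries raw
# conditional likelihoods (safe for the tree depths this package targets);
# if the root value underflows it reruns with per-node rescaling.
.prune_site_loglik <- function(patterns, phy, P_list, root_freqs,
                               rescale = FALSE) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  L <- vector("list", nnode)
  logsc <- if (rescale) vector("list", nnode) else NULL
  edge <- phy$edge
  nst <- nrow(P_list[[1L]])
  for (b in seq_len(nrow(edge))) {
    p <- edge[b, 1L]; ch <- edge[b, 2L]
    if (ch <= ntip) {
      contrib <- P_list[[b]][, patterns[ch, ], drop = FALSE]
      sc <- 0
    } else {
      contrib <- P_list[[b]] %*% L[[ch]]
      sc <- if (rescale) logsc[[ch]] else 0
    }
    if (is.null(L[[p]])) {
      L[[p]] <- contrib
      if (rescale) logsc[[p]] <- sc
    } else {
      L[[p]] <- L[[p]] * contrib
      if (rescale) logsc[[p]] <- logsc[[p]] + sc
    }
    if (rescale) {
      cs <- .colSums(L[[p]], nst, ncol(L[[p]]))
      cs[cs <= 0] <- 1
      L[[p]] <- L[[p]] * rep(1 / cs, each = nst)
      logsc[[p]] <- logsc[[p]] + log(cs)
    }
  }
  root <- ntip + 1L
  v <- drop(root_freqs %*% L[[root]])
  if (!rescale) {
    if (any(v <= 0) || any(!is.finite(v)))
      return(.prune_site_loglik(patterns, phy, P_list, root_freqs,
                                rescale = TRUE))
    return(log(v))
  }
  log(v) + logsc[[root]]
}

#' Log likelihood of a codon alignment on a tree
#'
#' Felsenstein pruning over codon sites, sites independent, with each
#' branch's rate matrix using that branch's omega (from
#' `spec$omega_of_branch`, or the shared `spec$omega`) and scaled so its
#' length is in expected substitutions per codon. The model is reversible,
#' so the value is invariant to re-rooting.
#'
#' @param aln gap-free `CodonAlignment`.
#' @param tree a `PhyloTree` with branch lengths (ignored for single-taxon
#'   alignments, where the likelihood is the product of equilibrium
#'   frequencies).
#' @param spec a [codon_model_spec()].
#' @return Log likelihood in nats.
#' @export
log_likelihood <- function(aln, tree, spec) {
  states <- .state_matrix(aln)
  if (length(aln$taxa) == 1L)
    return(sum(log(spec$freqs[states[1L, ]])))
  phy <- tree$phylo
  if (!setequal(phy$tip.label, aln$taxa))
    stop("pairing error: tree tips and alignment taxa differ")
  states <- states[phy$tip.label, , drop = FALSE]
  cp <- .compress_patterns(states)
  B <- nrow(phy$edge)
  omega_b <- spec$omega_of_branch
  if (is.null(omega_b)) omega_b <- rep(spec$omega, B)
  tlen <- phy$edge.length
  if (is.null(tlen)) stop("tree has no branch lengths")
  eigs <- list()
  P_list <- vector("list", B)
  for (b in seq_len(B)) {
    key <- format(omega_b[b], digits = 15)
    if (is.null(eigs[[key]])) {
      Q <- rate_matrix(spec, omega = omega_b[b])
      eigs[[key]] <- .eigen_Q(Q, spec$freqs)
    }
    P_list[[b]] <- .pmat_from_eigen(eigs[[key]], tlen[b])
  }
  sum(cp$weights *
        .prune_site_loglik(cp$patterns, phy, P_list, spec$freqs))
}

#' Expected synonymous and nonsynonymous substitution counts on a branch
#'
#' Decomposes the substitution flux along a branch into its equilibrium
#' nonsynonymous and synonymous fractions under that branch's rate matrix:
#' `nN = n_codons * t * rhoN`, `nS = n_codons * t * rhoS`, with
#' `nN + nS = n_codons * t` (t in substitutions per codon).
#'
#' @param spec a [codon_model_spec()].
#' @param t branch length, substitutions per codon.
#' @param n_codons number of codon sites.
#' @param omega dN/dS on the branch (defaults to `spec$omega`); pass the
#'   branch's class omega for a fitted branch model.
#' @return Named vector `c(nN=, nS=)`.
#' @export
expected_substitutions <- function(spec, t, n_codons, omega = spec$omega) {
  r <- .unscaled_rates(spec$freqs, spec$kappa, omega)
  fl <- .flux(r, spec$freqs)
  tot <- sum(fl)
  if (tot == 0) return(c(nN = 0, nS = 0))
  c(nN = n_codons * t * fl[["N"]] / tot,
    nS = n_codons * t * fl[["S"]] / tot)
}
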