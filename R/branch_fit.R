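# Branch partitions and maximum-likelihood fitting of branch-specific
# omega-class models (one-ratio, free-ratio, and arbitrary partitions).

#' Branch partition into omega classes
#'
#' Assigns every branch of a tree to one of `R` omega classes. Class labels
#' are contiguous integers `1..R`.
#'
#' @param classes integer vector, one class label per branch id.
#' @return Object of class `BranchPartition` with fields `classes`, `R`.
#' @export
branch_partition <- function(classes) {
  classes <- as.integer(classes)
  R <- max(classes)
  if (!setequal(unique(classes), seq_len(R)))
    stop("classes must be contiguous integers 1..R covering every branch")
  structure(list(classes = classes, R = R), class = "BranchPartition")
}

#' @rdname branch_partition
#' @param tree a `PhyloTree`.
#' @export
one_ratio_partition <- function(tree)
  branch_partition(rep(1L, n_branches(tree)))

#' @rdname branch_partition
#' @export
free_ratio_partition <- function(tree)
  branch_partition(seq_len(n_branches(tree)))

# renumber class labels to contiguous 1..R preserving first-appearance order
.relabel_partition <- function(classes)
  branch_partition(match(classes, unique(classes)))

# is partition a (coarser) nested within b (finer)? i.e. b refines a
.partition_refines <- function(fine, coarse) {
  tab <- table(fine$classes, coarse$classes)
  all(rowSums(tab > 0) == 1L)
}

#' Free-parameter count of a branch-specific model
#'
#' `np = B + 1 + R`: one length per branch, kappa, and one omega per free
#' class. Codon frequencies are empirical and not counted.
#'
#' @param B branch count.
#' @param R number of free omega classes.
#' @export
np_branch_model <- function(B, R) B + 1L + R

#' Free-ratio np implied by a one-ratio np
#'
#' Under the accounting `np = B + 1 + R`, a one-ratio model has
#' `np = B + 2`, so the free-ratio model on the same tree has
#' `np = 2 * np_one_ratio - 3`.
#'
#' @param np_one_ratio reported one-ratio parameter count.
#' @export
free_ratio_np <- function(np_one_ratio) 2L * as.integer(np_one_ratio) - 3L

# decode an optimizer parameter vector
.decode_par <- function(par, B, free_idx, R, fixed_omega) {
  tlen <- exp(par[seq_len(B)])
  kappa <- exp(par[B + 1L])
  omega <- numeric(R)
  if (length(fixed_omega))
    omega[as.integer(names(fixed_omega))] <- fixed_omega
  omega[free_idx] <- exp(par[B + 1L + seq_along(free_idx)])
  list(tlen = tlen, kappa = kappa, omega = omega)
}

# shared likelihood data for repeated fits on one alignment/tree
.lik_data <- function(aln, tree, freqs) {
  states <- .state_matrix(aln)
  phy <- tree$phylo
  if (!setequal(phy$tip.label, aln$taxa))
    stop("pairing error: tree tips and alignment taxa differ")
  states <- states[phy$tip.label, , drop = FALSE]
  cp <- .compress_patterns(states)
  list(phy = phy, patterns = cp$patterns, weights = cp$weights,
       B = nrow(phy$edge), n_codons = ncol(states), freqs = freqs)
}

# lnL of a branch model at explicit parameter values
.branch_lnL <- function(ld, tlen, kappa, omega_class, classes) {
  eigs <- vector("list", length(omega_class))
  P_list <- vector("list", ld$B)
  for (b in seq_len(ld$B)) {
    cl <- classes[b]
    if (is.null(eigs[[cl]])) {
      r <- .unscaled_rates(ld$freqs, kappa, omega_class[cl])
      fl <- sum(.flux(r, ld$freqs))
      Q <- r / fl
      diag(Q) <- -rowSums(Q)
      eigs[[cl]] <- .eigen_Q(Q, ld$freqs)
    }
    P_list[[b]] <- .pmat_from_eigen(eigs[[cl]], tlen[b])
  }
  sum(ld$weights * .prune_site_loglik(ld$patterns, ld$phy, P_list, ld$freqs))
}

.T_LO <- log(1e-7); .T_HI <- log(20)

#' Fit a branch-specific omega-class model
#'
#' Maximizes the codon-model likelihood over all branch lengths, kappa, and
#' one omega per free class of `partition`. Classes listed in `fixed_omega`
#' are pinned (e.g. to 1 for the fixed-omega test) and do not count towards
#' `np`. Optimization is bounded quasi-Newton (L-BFGS-B) on log-transformed
#' parameters; fresh fits use three deterministic omega multi-starts
#' (0.1, 1, 3), warm-started fits a single start.
#'
#' @param aln gap-free `CodonAlignment`.
#' @param tree `PhyloTree` with branch lengths used as starting values.
#' @param partition a [branch_partition()]; default one-ratio.
#' @param fixed_omega named numeric vector, names = class labels to pin.
#' @param freq_mode passed to [codon_frequencies()]; the default
#'   observed-codon mode estimates frequencies empirically.
#' @param kappa_init starting kappa.
#' @param init optional warm start: a previous `BranchFit` or a list with
#'   `tlen`, `kappa`, `omega` (length R of the new partition).
#' @param control passed to [stats::optim()] (after defaults).
#' @return A `BranchFit`: `lnL`, `np`, `kappa_hat`, `omega_hat` (per class),
#'   `branch_lengths_hat`, `counts` (per-branch expected nN, nS),
#'   `converged`, plus the partition and frequencies used.
#' @export
fit_partition <- function(aln, tree, partition = one_ratio_partition(tree),
                          fixed_omega = NULL,
                          freq_mode = "observed-codon",
                          kappa_init = 2, init = NULL, control = list()) {
  freqs <- codon_frequencies(aln, freq_mode)
  ld <- .lik_data(aln, tree, freqs)
  B <- ld$B
  stopifnot(length(partition$classes) == B)
  R <- partition$R
  fixed_idx <- if (length(fixed_omega)) as.integer(names(fixed_omega)) else integer(0)
  free_idx <- setdiff(seq_len(R), fixed_idx)
  np <- B + 1L + length(free_idx)

  negll <- function(par) {
    d <- .decode_par(par, B, free_idx, R, fixed_omega)
    v <- -.branch_lnL(ld, d$tlen, d$kappa, d$omega, partition$classes)
    if (!is.finite(v)) 1e10 else v
  }

  t0 <- branch_lengths(tree)
  t0 <- if (all(is.na(t0))) rep(0.05, B) else pmax(t0, 5e-3)
  lower <- c(rep(.T_LO, B), log(.KAPPA_MIN), rep(log(.OMEGA_MIN), length(free_idx)))
  upper <- c(rep(.T_HI, B), log(.KAPPA_MAX), rep(log(.OMEGA_CAP), length(free_idx)))
  ctrl <- utils::modifyList(list(maxit = 400L, factr = 1e7), control)

  # multi-start over omega; after the first full optimization, later starts
  # reuse the incumbent branch lengths and kappa (the nuisance optimum) and
  # restart only the omegas, where the surface can be multimodal
  omega_starts <- if (!is.null(init)) NULL else c(0.1, 1, 3)
  if (!is.null(init)) {
    if (inherits(init, "BranchFit"))
      init <- list(tlen = init$branch_lengths_hat, kappa = init$kappa_hat,
                   omega = init$omega_hat)
  }

  run_one <- function(s) {
    s <- pmin(pmax(s, lower), upper)
    tryCatch(
      stats::optim(s, negll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = ctrl),
      error = function(e) NULL)
  }

  best <- NULL
  if (!is.null(init)) {
    w0 <- pmin(pmax(init$omega[free_idx], .OMEGA_MIN), .OMEGA_CAP)
    best <- run_one(c(log(pmax(init$tlen, 1e-6)), log(init$kappa), log(w0)))
  } else {
    for (w_start in omega_starts) {
      s <- if (is.null(best))
        c(log(t0), log(kappa_init), rep(log(w_start), length(free_idx)))
      else
        c(best$par[seq_len(B + 1L)], rep(log(w_start), length(free_idx)))
      opt <- run_one(s)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value))
        best <- opt
    }
  }
  if (is.null(best))
    stop("optimizer failure: no start converged for the branch model")

  d <- .decode_par(best$par, B, free_idx, R, fixed_omega)
  spec <- codon_model_spec(kappa = d$kappa, omega = 1, freqs = freqs,
                           freq_mode = freq_mode)
  counts <- t(vapply(seq_len(B), function(b)
    expected_substitutions(spec, d$tlen[b], ld$n_codons,
                           omega = d$omega[partition$classes[b]]),
    numeric(2)))
  structure(list(lnL = -best$value, np = np, kappa_hat = d$kappa,
                 omega_hat = d$omega, branch_lengths_hat = d$tlen,
                 counts = data.frame(branch = seq_len(B),
                                     class = partition$classes,
                                     nN = counts[, "nN"], nS = counts[, "nS"]),
                 converged = best$convergence == 0L,
                 partition = partition, fixed_omega = fixed_omega,
                 freq_mode = freq_mode, freqs = freqs,
                 n_codons = ld$n_codons),
            class = "BranchFit")
}

#' @export
print.BranchFit <- function(x, ...) {
  cat("BranchFit: lnL =", format(x$lnL, digits = 10), " np =", x$np,
      " R =", x$partition$R, "\n")
  cat("  kappa =", signif(x$kappa_hat, 4), " omega:",
      paste(signif(x$omega_hat, 4), collapse = ", "), "\n")
  invisible(x)
}
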