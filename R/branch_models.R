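# Likelihood-ratio machinery, AIC, the substitution-count heuristic, the
# fixed-omega test, and the stepwise search for the optimal branch-specific
# model (three strategies, with an audit trail).

#' Upper tail of the chi-square distribution
#'
#' Reference distribution for all nested LRTs; for `df = 2` this equals
#' `exp(-x/2)` exactly.
#'
#' @param x test statistic (>= 0).
#' @param df degrees of freedom (positive integer).
#' @export
chi_square_sf <- function(x, df) {
  stopifnot(x >= 0, df >= 1)
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' Likelihood-ratio test between nested models
#'
#' @param lnL_null log likelihood of the null (smaller) model.
#' @param lnL_alt log likelihood of the alternative; must be >= the null up
#'   to numerical tolerance.
#' @param df difference in free parameters.
#' @return list with `stat` (2 * delta lnL, clamped at 0), `p`, `df`.
#' @export
lrt <- function(lnL_null, lnL_alt, df) {
  if (lnL_alt < lnL_null - 1e-6)
    stop("nesting error: alternative lnL ", lnL_alt,
         " below null lnL ", lnL_null)
  stat <- max(0, 2 * (lnL_alt - lnL_null))
  list(stat = stat, p = chi_square_sf(stat, df), df = as.integer(df))
}

#' Akaike information criterion of a fit
#'
#' `AIC = 2 np - 2 lnL`; lower is preferred between non-nested candidates.
#'
#' @param fit any object with `lnL` and `np` fields (`BranchFit`,
#'   `SiteClassFit`).
#' @export
aic <- function(fit) 2 * fit$np - 2 * fit$lnL

#' Substitution-count heuristic for positive selection
#'
#' Flags a branch as a positive-selection candidate when more than 9
#' nonsynonymous substitutions co-occur with (effectively) zero synonymous
#' substitutions (Nozawa et al. 2009). Counts are model expectations, so
#' "zero" is tested with tolerance 0.5.
#'
#' @param nN expected nonsynonymous substitutions on the branch.
#' @param nS expected synonymous substitutions on the branch.
#' @return logical.
#' @export
nozawa_flag <- function(nN, nS) {
  stopifnot(all(nN >= 0), all(nS >= 0))
  nN > 9 & nS <= 0.5
}

#' Fixed-omega test of positive selection on chosen classes
#'
#' Refits the branch model with the omega of each target class pinned to 1
#' and compares against the unconstrained fit by LRT with df = number of
#' fixed classes.
#'
#' @param aln gap-free `CodonAlignment`.
#' @param tree `PhyloTree`.
#' @param partition the final model's [branch_partition()].
#' @param target_classes integer class labels whose omega is fixed to 1.
#' @param fit optional unconstrained `BranchFit` for this partition
#'   (refit when missing).
#' @param ... passed to [fit_partition()].
#' @return list `stat`, `p`, `df`, `fit_alt`, `fit_null`.
#' @export
fix_model_test <- function(aln, tree, partition, target_classes, fit = NULL,
                           ...) {
  if (!all(target_classes %in% seq_len(partition$R)))
    stop("target class not present in partition")
  if (is.null(fit))
    fit <- fit_partition(aln, tree, partition, ...)
  fixed <- stats::setNames(rep(1, length(target_classes)),
                           as.character(target_classes))
  init <- list(tlen = fit$branch_lengths_hat, kappa = fit$kappa_hat,
               omega = replace(fit$omega_hat, target_classes, 1))
  fit0 <- fit_partition(aln, tree, partition, fixed_omega = fixed,
                        init = init, ...)
  res <- lrt(fit0$lnL, fit$lnL, df = length(target_classes))
  c(res, list(fit_alt = fit, fit_null = fit0))
}

# ---- optimal branch-specific model search --------------------------------

.trail_entry <- function(step, method, action, partition, lnL, np, decision) {
  data.frame(step = step, method = method, action = action,
             R = partition$R, lnL = lnL, np = np, aic = 2 * np - 2 * lnL,
             decision = decision, stringsAsFactors = FALSE)
}

# screened lnL of a candidate partition: branch lengths and kappa held at
# the incumbent's MLEs, only the omegas of `changed` classes re-optimized
# one dimension at a time. A cheap lower bound used to rank candidates; the
# chosen candidate is always refit fully before any accept decision.
.screen_partition <- function(ld, incumbent, partition, omega_start, changed) {
  tlen <- incumbent$branch_lengths_hat
  kappa <- incumbent$kappa_hat
  omega <- omega_start
  best <- -Inf
  for (cl in changed) {
    f <- function(lw) {
      omega[cl] <- exp(lw)
      .branch_lnL(ld, tlen, kappa, omega, partition$classes)
    }
    op <- stats::optimize(f, interval = c(log(.OMEGA_MIN), log(.OMEGA_CAP)),
                          maximum = TRUE, tol = 0.01)
    omega[cl] <- exp(op$maximum)
    best <- op$objective
  }
  list(lnL = best, omega = omega)
}

# candidate generators -----------------------------------------------------

# all single-branch splits: move branch b out of a class with >1 member
# into a brand-new class
.split_candidates <- function(partition) {
  out <- list()
  sizes <- table(partition$classes)
  for (b in seq_along(partition$classes)) {
    cl <- partition$classes[b]
    if (sizes[as.character(cl)] <= 1L) next
    cls <- partition$classes
    cls[b] <- partition$R + 1L
    out[[length(out) + 1L]] <- list(partition = .relabel_partition(cls),
                                    moved = b, from = cl,
                                    kind = "split")
  }
  out
}

# all single-branch moves into a different existing class
.move_candidates <- function(partition) {
  out <- list()
  if (partition$R < 2L) return(out)
  for (b in seq_along(partition$classes)) {
    for (cl in seq_len(partition$R)) {
      if (cl == partition$classes[b]) next
      cls <- partition$classes
      cls[b] <- cl
      if (length(unique(cls)) < partition$R &&
          sum(partition$classes == partition$classes[b]) == 1L) {
        # moving the last member of a class empties it: that is a merge
        out[[length(out) + 1L]] <- list(partition = .relabel_partition(cls),
                                        moved = b, to = cl, kind = "merge")
      } else {
        out[[length(out) + 1L]] <- list(partition = .relabel_partition(cls),
                                        moved = b, to = cl, kind = "move")
      }
    }
  }
  out
}

# all pairwise class merges
.merge_candidates <- function(partition) {
  out <- list()
  if (partition$R < 2L) return(out)
  for (r in seq_len(partition$R - 1L)) for (s in (r + 1L):partition$R) {
    cls <- partition$classes
    cls[cls == s] <- r
    out[[length(out) + 1L]] <- list(partition = .relabel_partition(cls),
                                    merged = c(r, s), kind = "merge")
  }
  out
}

# map incumbent class omegas onto a candidate partition (majority rule per
# candidate class), returning start omegas and which classes changed
.transfer_omegas <- function(incumbent_part, incumbent_omega, candidate) {
  R_new <- candidate$R
  omega <- numeric(R_new)
  changed <- integer(0)
  for (cl in seq_len(R_new)) {
    members <- which(candidate$classes == cl)
    src <- incumbent_part$classes[members]
    if (length(unique(src)) == 1L) {
      omega[cl] <- incumbent_omega[src[1L]]
      if (sum(incumbent_part$classes == src[1L]) != length(members))
        changed <- c(changed, cl)
    } else {
      omega[cl] <- exp(mean(log(pmax(incumbent_omega[unique(src)],
                                     .OMEGA_MIN))))
      changed <- c(changed, cl)
    }
  }
  list(omega = omega, changed = changed)
}

#' Stepwise search for the optimal branch-specific model
#'
#' Three search strategies over branch partitions, all recording an audit
#' trail:
#' * **Method I** (fast greedy split): from the one-ratio model, repeatedly
#'   try moving each branch into a new omega class; the best candidate
#'   (ranked by a screened likelihood) is refit fully and accepted if its
#'   LRT against the incumbent is significant at the per-step
#'   Bonferroni-corrected level `alpha / n_candidates`; stop when no move is
#'   accepted.
#' * **Method II** (deeper search): at each step all single-branch moves
#'   (to new or existing classes) and all class merges are screened, the
#'   best candidate by AIC is refit fully, and accepted if it lowers AIC -
#'   with the same corrected LRT guard whenever the move adds a class; stops
#'   at an AIC local minimum.
#' * **Method III** (estimate-guided clustering): fits the free-ratio
#'   model, sorts the branch omegas and cuts the sorted sequence wherever
#'   consecutive estimates differ by a factor exceeding `(1 + k) / k`
#'   (3x at the default `k = 0.5`), refits the induced partition, refines it
#'   by Method-II-style steps, and finally keeps the result only if it beats
#'   the one-ratio model by LRT at `alpha`.
#'
#' @param aln gap-free `CodonAlignment`.
#' @param tree `PhyloTree`.
#' @param method `"I"`, `"II"` or `"III"`.
#' @param k clustering granularity of Method III: consecutive sorted omegas
#'   differing by more than `(1 + k) / k`-fold start a new class.
#' @param alpha significance level for the LRT guards.
#' @param freq_mode codon frequency mode (see [codon_frequencies()]).
#' @param base optional one-ratio `BranchFit` to reuse across methods.
#' @param max_steps safety cap on accepted steps.
#' @return A `ModelSearchResult`: `partition`, `fit`, `method`, `trail`.
#' @export
obsm_search <- function(aln, tree, method = c("I", "II", "III"), k = 0.5,
                        alpha = 0.05, freq_mode = "observed-codon",
                        base = NULL, max_steps = 10L) {
  method <- match.arg(method)
  if (length(tree_taxa(tree)) < 4L)
    stop("optimal-model search needs at least 4 taxa")
  freqs <- codon_frequencies(aln, freq_mode)
  ld <- .lik_data(aln, tree, freqs)
  if (is.null(base))
    base <- fit_partition(aln, tree, one_ratio_partition(tree),
                          freq_mode = freq_mode)
  trail <- .trail_entry(0L, method, "one-ratio", base$partition, base$lnL,
                        base$np, "start")
  incumbent <- base

  refit <- function(candidate, omega_start) {
    fit_partition(aln, tree, candidate$partition, freq_mode = freq_mode,
                  init = list(tlen = incumbent$branch_lengths_hat,
                              kappa = incumbent$kappa_hat,
                              omega = omega_start))
  }

  step_greedy <- function(use_aic) {
    # returns TRUE if a candidate was accepted
    cands <- .split_candidates(incumbent$partition)
    if (use_aic)
      cands <- c(cands, .move_candidates(incumbent$partition),
                 .merge_candidates(incumbent$partition))
    if (!length(cands)) return(FALSE)
    n_split <- sum(vapply(cands, function(cc) cc$kind == "split", TRUE))
    screened <- vector("list", length(cands))
    score <- numeric(length(cands))
    for (i in seq_along(cands)) {
      tr <- .transfer_omegas(incumbent$partition, incumbent$omega_hat,
                             cands[[i]]$partition)
      sc <- .screen_partition(ld, incumbent, cands[[i]]$partition,
                              tr$omega, tr$changed)
      screened[[i]] <- sc
      np_i <- ld$B + 1L + cands[[i]]$partition$R
      score[i] <- if (use_aic) -(2 * np_i - 2 * sc$lnL) else sc$lnL
    }
    best_i <- which.max(score)
    cand <- cands[[best_i]]
    fit_c <- refit(cand, screened[[best_i]]$omega)
    np_diff <- fit_c$np - incumbent$np
    accept <- FALSE
    reason <- ""
    if (np_diff > 0L) {
      alpha_step <- alpha / max(1L, n_split)
      tst <- lrt(incumbent$lnL, max(fit_c$lnL, incumbent$lnL), np_diff)
      ok_aic <- !use_aic || aic(fit_c) < aic(incumbent)
      accept <- tst$p < alpha_step && ok_aic
      reason <- sprintf("%s LRT p=%.3g at alpha'=%.3g", cand$kind, tst$p,
                        alpha_step)
    } else if (np_diff == 0L) {
      accept <- use_aic && fit_c$lnL > incumbent$lnL + 1e-6
      reason <- sprintf("move dlnL=%.3g", fit_c$lnL - incumbent$lnL)
    } else {
      # coarsening: accept if AIC improves (i.e. the dropped classes were
      # not supported)
      accept <- use_aic && aic(fit_c) < aic(incumbent)
      reason <- sprintf("merge dAIC=%.3g", aic(fit_c) - aic(incumbent))
    }
    trail <<- rbind(trail, .trail_entry(max(trail$step) + 1L, method,
                                        cand$kind, fit_c$partition,
                                        fit_c$lnL, fit_c$np,
                                        paste(if (accept) "accept" else
                                              "reject", reason)))
    if (accept) incumbent <<- fit_c
    accept
  }

  if (method == "I") {
    for (i in seq_len(max_steps)) if (!step_greedy(use_aic = FALSE)) break
  } else if (method == "II") {
    for (i in seq_len(max_steps)) if (!step_greedy(use_aic = TRUE)) break
  } else {
    free <- fit_partition(aln, tree, free_ratio_partition(tree),
                          freq_mode = freq_mode,
                          init = list(tlen = base$branch_lengths_hat,
                                      kappa = base$kappa_hat,
                                      omega = rep(base$omega_hat,
                                                  n_branches(tree))))
    trail <- rbind(trail, .trail_entry(1L, method, "free-ratio",
                                       free$partition, free$lnL, free$np,
                                       "estimate guide"))
    w <- pmax(free$omega_hat, 1e-4)
    o <- order(w)
    cut_after <- which(w[o][-1L] / w[o][-length(w)] > (1 + k) / k)
    grp <- cumsum(c(1L, seq_along(w[o])[-1L] %in% (cut_after + 1L)))
    classes <- integer(length(w))
    classes[o] <- grp
    part3 <- .relabel_partition(classes)
    cls_omega <- vapply(seq_len(part3$R), function(cl)
      exp(mean(log(w[part3$classes == cl]))), 0)
    incumbent <- fit_partition(aln, tree, part3, freq_mode = freq_mode,
                               init = list(tlen = free$branch_lengths_hat,
                                           kappa = free$kappa_hat,
                                           omega = cls_omega))
    trail <- rbind(trail, .trail_entry(2L, method, "cluster-cut",
                                       part3, incumbent$lnL, incumbent$np,
                                       sprintf("cut ratio > %.3g",
                                               (1 + k) / k)))
    for (i in seq_len(max_steps)) if (!step_greedy(use_aic = TRUE)) break
    if (incumbent$partition$R > 1L) {
      guard <- lrt(base$lnL, max(incumbent$lnL, base$lnL),
                   incumbent$partition$R - 1L)
      if (guard$p >= alpha) {
        trail <- rbind(trail, .trail_entry(max(trail$step) + 1L, method,
                                           "guard", base$partition,
                                           base$lnL, base$np,
                                           sprintf("vs one-ratio p=%.3g: revert",
                                                   guard$p)))
        incumbent <- base
      }
    }
  }

  structure(list(partition = incumbent$partition, fit = incumbent,
                 method = method, trail = trail),
            class = "ModelSearchResult")
}

#' @export
print.ModelSearchResult <- function(x, ...) {
  cat("ModelSearchResult (method ", x$method, "): R = ", x$partition$R,
      ", lnL = ", format(x$fit$lnL, digits = 10), ", np = ", x$fit$np,
      "\n", sep = "")
  invisible(x)
}

#' Choose the final model among search results
#'
#' Pairwise comparison rule: equal class counts - higher log likelihood;
#' unequal and nested - LRT at `alpha` (the richer model must earn its
#' extra classes); unequal and non-nested - lower AIC. Deterministic
#' tie-break: fewer classes, then method order III > II > I.
#'
#' @param results list of `ModelSearchResult`.
#' @param alpha significance level for nested comparisons.
#' @return The winning `ModelSearchResult`.
#' @export
select_final <- function(results, alpha = 0.05) {
  if (!length(results)) stop("argument error: no search results")
  method_rank <- function(m) match(m, c("III", "II", "I"))
  beats <- function(challenger, champ) {
    Ra <- champ$partition$R; Rb <- challenger$partition$R
    la <- champ$fit$lnL; lb <- challenger$fit$lnL
    if (Ra == Rb) {
      if (abs(lb - la) > 1e-9) return(lb > la)
    } else {
      fine <- if (Ra > Rb) champ else challenger
      coarse <- if (Ra > Rb) challenger else champ
      if (.partition_refines(fine$partition, coarse$partition) &&
          fine$fit$lnL >= coarse$fit$lnL - 1e-6) {
        tst <- lrt(coarse$fit$lnL, max(fine$fit$lnL, coarse$fit$lnL),
                   fine$partition$R - coarse$partition$R)
        winner_is_fine <- tst$p < alpha
        return(identical(challenger, fine) == winner_is_fine)
      }
      if (abs(aic(challenger$fit) - aic(champ$fit)) > 1e-9)
        return(aic(challenger$fit) < aic(champ$fit))
    }
    # ties
    if (Rb != Ra) return(Rb < Ra)
    method_rank(challenger$method) < method_rank(champ$method)
  }
  champ <- results[[1L]]
  for (r in results[-1L]) if (beats(r, champ)) champ <- r
  champ
}
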