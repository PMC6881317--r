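# Branch-site analysis on a designated foreground branch set: the M1a
# site-class model, Model A and its fixed-omega2 null, the two standard
# LRTs, and Bayes empirical Bayes identification of positively selected
# sites.
#
# Site classes of Model A: class 0 has omega0 (purifying) on every branch,
# class 1 is neutral (omega = 1) everywhere, classes 2a/2b switch to omega2
# on the foreground branches from backgrounds omega0 and 1 respectively,
# with proportions (p0, p1, p2a, p2b) built as
# p2a = (1 - p0 - p1) p0 / (p0 + p1), p2b = (1 - p0 - p1) p1 / (p0 + p1).
# Each branch's rate matrices share that branch's mixture-average flux
# scale, so a site in the selected class genuinely evolves faster on the
# foreground branch, and branch lengths stay in expected substitutions per
# codon averaged over classes.

.modelA_props <- function(p0, p1) {
  p2 <- 1 - p0 - p1
  s <- p0 + p1
  c(p0 = p0, p1 = p1, p2a = p2 * p0 / s, p2b = p2 * p1 / s)
}

# class omegas per branch: matrix classes x branches
.site_class_omegas <- function(model, omega0, omega2, fg_mask) {
  if (model == "M1a")
    return(rbind(rep(omega0, length(fg_mask)), rep(1, length(fg_mask))))
  rbind(rep(omega0, length(fg_mask)),
        rep(1, length(fg_mask)),
        ifelse(fg_mask, omega2, omega0),
        ifelse(fg_mask, omega2, 1))
}

# per-class per-pattern log-likelihood vectors for a site-class model.
# `cache` (an environment) persists across optimizer evaluations: eigens
# are rebuilt only when kappa or an omega value changes, and per-branch P
# matrices only when their effective time (t / mixture scale) changes.
.site_class_logliks <- function(ld, tlen, kappa, model, omega0, omega2,
                                fg_mask, props,
                                cache = new.env(parent = emptyenv())) {
  B <- ld$B
  if (model == "M1a") {
    womega <- c(omega0, 1)
    cls_idx <- rbind(rep(1L, B), rep(2L, B))
  } else {
    womega <- c(omega0, 1, omega2)
    cls_idx <- rbind(rep(1L, B), rep(2L, B),
                     ifelse(fg_mask, 3L, 1L), ifelse(fg_mask, 3L, 2L))
  }
  K <- length(womega)
  if (is.null(cache$kappa) || cache$kappa != kappa ||
      length(cache$womega) != K) {
    cache$kappa <- kappa
    cache$womega <- rep(NA_real_, K)
    cache$eigs <- vector("list", K)
    cache$flux <- rep(NA_real_, K)
    cache$teff <- matrix(NA_real_, K, B)
    cache$P <- vector("list", K * B)
  }
  for (k in seq_len(K)) {
    if (is.na(cache$womega[k]) || cache$womega[k] != womega[k]) {
      r <- .unscaled_rates(ld$freqs, kappa, womega[k])
      Q <- r; diag(Q) <- -rowSums(Q)
      cache$eigs[[k]] <- .eigen_Q(Q, ld$freqs)
      cache$flux[k] <- sum(.flux(r, ld$freqs))
      cache$womega[k] <- womega[k]
      cache$teff[k, ] <- NA_real_
    }
  }
  scale_b <- drop(crossprod(props, matrix(cache$flux[cls_idx], nrow(cls_idx))))
  pmat_for <- function(k, b) {
    te <- tlen[b] / scale_b[b]
    i <- (k - 1L) * B + b
    if (is.na(cache$teff[k, b]) || cache$teff[k, b] != te) {
      cache$P[[i]] <- .pmat_from_eigen(cache$eigs[[k]], te)
      cache$teff[k, b] <- te
    }
    cache$P[[i]]
  }
  F <- matrix(0, nrow(cls_idx), ncol(ld$patterns))
  for (cl in seq_len(nrow(cls_idx))) {
    P_list <- lapply(seq_len(B), function(b) pmat_for(cls_idx[cl, b], b))
    F[cl, ] <- .prune_site_loglik(ld$patterns, ld$phy, P_list, ld$freqs)
  }
  F
}

# total lnL of a site-class mixture from the class log-lik matrix
.mixture_lnL <- function(F, props, weights) {
  m <- apply(F, 2L, max)
  site <- log(colSums(props * exp(sweep(F, 2L, m)))) + m
  sum(weights * site)
}

#' Fit a site-class model (M1a, Model A, or the fixed-omega2 null)
#'
#' @param aln gap-free `CodonAlignment`.
#' @param tree `PhyloTree` with branch lengths as starting values.
#' @param foreground integer branch ids of the foreground set (may be empty
#'   for M1a; taken from `tree$foreground` when `NULL`).
#' @param model `"M1a"`, `"ModelA"`, or `"ModelA_fixed"` (Model A with
#'   omega2 pinned to 1, the null of test 2).
#' @param freq_mode codon frequency mode.
#' @param init optional warm start (a `SiteClassFit`).
#' @param control passed to [stats::optim()].
#' @return A `SiteClassFit`: `lnL`, `np`, proportions `p0, p1, p2a, p2b`,
#'   `omega0`, `omega2`, `kappa_hat`, `branch_lengths_hat`, `converged`.
#' @export
fit_site_model <- function(aln, tree, foreground = NULL,
                           model = c("ModelA", "M1a", "ModelA_fixed"),
                           freq_mode = "observed-codon", init = NULL,
                           control = list()) {
  model <- match.arg(model)
  if (is.null(foreground)) foreground <- tree$foreground
  if (model != "M1a" && !length(foreground))
    stop("Model A needs a non-empty foreground branch set")
  freqs <- codon_frequencies(aln, freq_mode)
  ld <- .lik_data(aln, tree, freqs)
  fg_mask <- seq_len(ld$B) %in% foreground
  B <- ld$B
  is_a <- model != "M1a"
  fix_w2 <- model == "ModelA_fixed"
  # par: log t (B), log kappa, a, [b], logit omega0, [log(omega2 - 1)]
  np <- B + 1L + if (model == "M1a") 2L else if (fix_w2) 3L else 4L

  decode <- function(par) {
    tlen <- exp(par[seq_len(B)])
    kappa <- exp(par[B + 1L])
    i <- B + 2L
    if (model == "M1a") {
      p0 <- stats::plogis(par[i]); i <- i + 1L
      props <- c(p0, 1 - p0)
    } else {
      ea <- exp(par[i]); eb <- exp(par[i + 1L]); i <- i + 2L
      den <- 1 + ea + eb
      props <- .modelA_props(ea / den, eb / den)
    }
    omega0 <- stats::plogis(par[i]) * (1 - 1e-8); i <- i + 1L
    omega2 <- if (model == "M1a") NA_real_
              else if (fix_w2) 1
              else 1 + exp(par[i])
    list(tlen = tlen, kappa = kappa, props = props,
         omega0 = max(omega0, .OMEGA_MIN), omega2 = min(omega2, .OMEGA_CAP))
  }

  lik_cache <- new.env(parent = emptyenv())
  negll <- function(par) {
    d <- decode(par)
    F <- .site_class_logliks(ld, d$tlen, d$kappa, model, d$omega0,
                             d$omega2, fg_mask, d$props, lik_cache)
    v <- -.mixture_lnL(F, d$props, ld$weights)
    if (!is.finite(v)) 1e10 else v
  }

  t0 <- branch_lengths(tree)
  t0 <- if (all(is.na(t0))) rep(0.05, B) else pmax(t0, 5e-3)
  n_extra <- np - B - 1L
  lower <- c(rep(.T_LO, B), log(.KAPPA_MIN), rep(-20, n_extra))
  upper <- c(rep(.T_HI, B), log(.KAPPA_MAX),
             if (model == "M1a") c(20, 20)
             else c(20, 20, 20, if (!fix_w2) log(.OMEGA_CAP - 1)))
  ctrl <- utils::modifyList(list(maxit = 150L, factr = 1e8), control)

  starts <- list()
  if (!is.null(init)) {
    p0i <- max(init$p0, 1e-4); p1i <- max(init$p1, 1e-4)
    prest <- max(1 - p0i - p1i, 1e-4)
    base <- c(log(pmax(init$branch_lengths_hat, 1e-6)), log(init$kappa_hat))
    w0i <- min(max(init$omega0, 1e-4), 1 - 1e-4)
    if (model == "M1a") {
      starts[[1]] <- c(base, stats::qlogis(min(max(p0i, 1e-4), 1 - 1e-4)),
                       stats::qlogis(w0i))
    } else {
      ab <- log(c(p0i, p1i) / prest)
      w2i <- if (fix_w2) NULL else log(max(init$omega2, 1.001) - 1)
      starts[[1]] <- c(base, ab, stats::qlogis(w0i), w2i)
    }
  } else {
    base <- c(log(t0), log(2))
    if (model == "M1a") {
      starts[[1]] <- c(base, stats::qlogis(0.7), stats::qlogis(0.15))
    } else {
      ab <- log(c(0.65, 0.25) / 0.10)
      starts[[1]] <- c(base, ab, stats::qlogis(0.15),
                       if (!fix_w2) log(3 - 1))
      if (!fix_w2)
        starts[[2]] <- c(base, ab, stats::qlogis(0.15), log(8 - 1))
    }
  }

  best <- NULL
  for (s in starts) {
    # later starts reuse the incumbent branch lengths and kappa; only the
    # site-class parameters (the potentially multimodal part) restart
    if (!is.null(best))
      s[seq_len(B + 1L)] <- best$par[seq_len(B + 1L)]
    s <- pmin(pmax(s, lower), upper)
    opt <- tryCatch(
      stats::optim(s, negll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimizer failure: site model did not converge")
  d <- decode(best$par)
  props4 <- unname(if (model == "M1a") c(d$props, 0, 0) else d$props)
  structure(list(model = model, lnL = -best$value, np = np,
                 p0 = props4[1], p1 = props4[2],
                 p2a = props4[3], p2b = props4[4],
                 omega0 = d$omega0, omega2 = d$omega2,
                 kappa_hat = d$kappa, branch_lengths_hat = d$tlen,
                 foreground = foreground,
                 converged = best$convergence == 0L,
                 freq_mode = freq_mode, freqs = freqs),
            class = "SiteClassFit")
}

#' @export
print.SiteClassFit <- function(x, ...) {
  cat("SiteClassFit [", x$model, "]: lnL = ", format(x$lnL, digits = 9),
      ", np = ", x$np, "\n", sep = "")
  cat(sprintf("  p0=%.3f p1=%.3f p2a=%.3f p2b=%.3f  w0=%.3f w2=%s\n",
              x$p0, x$p1, x$p2a, x$p2b, x$omega0,
              ifelse(is.na(x$omega2), "-", format(x$omega2, digits = 4))))
  invisible(x)
}

#' Branch-site LRTs (tests 1 and 2) on a foreground branch set
#'
#' Test 1 compares M1a against Model A (df 2); test 2 compares Model A
#' against its omega2 = 1 null (df 1). Evidence of positive selection on
#' the foreground requires Model A to beat both nulls.
#'
#' @param aln gap-free `CodonAlignment`.
#' @param tree `PhyloTree`.
#' @param foreground integer branch ids.
#' @param alpha significance level for the joint verdict.
#' @param freq_mode codon frequency mode.
#' @param which `"all"` fits the three models; `"test1"` skips the
#'   fixed-omega2 null (test 2 is then `NULL`).
#' @return list `test1`, `test2` (each `stat`, `p`, `df`), `fits` (named
#'   list of the three `SiteClassFit`s), `positive` (both tests < alpha).
#' @export
branch_site_tests <- function(aln, tree, foreground, alpha = 0.05,
                              freq_mode = "observed-codon",
                              which = c("all", "test1")) {
  which <- match.arg(which)
  m1a <- fit_site_model(aln, tree, foreground, "M1a", freq_mode)
  # Model A warm-started from the M1a solution (branch lengths and kappa
  # are already near their optima there) at two omega2 starts
  mk_init <- function(w2, p2tot = 0.1) {
    list(branch_lengths_hat = m1a$branch_lengths_hat,
         kappa_hat = m1a$kappa_hat,
         p0 = m1a$p0 * (1 - p2tot), p1 = (1 - m1a$p0) * (1 - p2tot),
         omega0 = m1a$omega0, omega2 = w2)
  }
  fits_a <- lapply(c(2, 8), function(w2)
    fit_site_model(aln, tree, foreground, "ModelA", freq_mode,
                   init = mk_init(w2)))
  ma <- fits_a[[which.max(vapply(fits_a, `[[`, 0, "lnL"))]]
  ma0 <- if (which == "all")
    fit_site_model(aln, tree, foreground, "ModelA_fixed", freq_mode,
                   init = ma)
  # Model A nests both nulls; if a null beat it the optimizer stalled, so
  # restart Model A from that null's solution
  null_best <- max(m1a$lnL, if (is.null(ma0)) -Inf else ma0$lnL)
  if (ma$lnL < null_best) {
    seed_fit <- if (is.null(ma0) || m1a$lnL > ma0$lnL) {
      tmp <- m1a; tmp$p1 <- 1 - m1a$p0 - 2e-3; tmp$p0 <- m1a$p0 - 1e-3
      tmp$omega2 <- 1.001; tmp
    } else {
      tmp <- ma0; tmp$omega2 <- 1.001; tmp
    }
    ma2 <- fit_site_model(aln, tree, foreground, "ModelA", freq_mode,
                          init = seed_fit)
    if (ma2$lnL > ma$lnL) ma <- ma2
  }
  t1 <- lrt(m1a$lnL, max(ma$lnL, m1a$lnL), 2L)
  t2 <- if (!is.null(ma0)) lrt(ma0$lnL, max(ma$lnL, ma0$lnL), 1L)
  list(test1 = t1, test2 = t2,
       fits = list(M1a = m1a, ModelA = ma, ModelA_fixed = ma0),
       positive = t1$p < alpha && (is.null(t2) || t2$p < alpha))
}

#' Bayes empirical Bayes identification of positively selected sites
#'
#' Computes, for every codon site, the posterior probability of membership
#' in the positively selected classes (2a or 2b) of Model A, integrating
#' over a uniform prior grid on the class proportions (a 10-point triangle
#' on `(p0, p1)`) and 10-point grids on `omega0` in (0,1) and `omega2` in
#' (1, 999] (log-spaced), with branch lengths, kappa and the per-branch
#' flux scales held at their MLEs. Sites exceeding the threshold are
#' flagged and labeled with their 1-based position in the gap-stripped
#' alignment and the reference (first) sequence's residue, e.g. `"43D"`.
#'
#' @param aln gap-free `CodonAlignment`.
#' @param tree `PhyloTree`.
#' @param foreground integer branch ids (defaults to `fit$foreground`).
#' @param fit a converged Model A `SiteClassFit`.
#' @param threshold posterior cutoff (default 0.95).
#' @return A `BEBReport`: `posterior` (per site), `flagged_sites`
#'   (data.frame `site`, `residue`, `label`, `posterior`), `threshold`.
#' @export
beb_sites <- function(aln, tree, foreground = NULL, fit,
                      threshold = 0.95) {
  stopifnot(inherits(fit, "SiteClassFit"), fit$model == "ModelA")
  if (is.null(foreground)) foreground <- fit$foreground
  ld <- .lik_data(aln, tree, fit$freqs)
  cp_index <- .compress_patterns(
    .state_matrix(aln)[ld$phy$tip.label, , drop = FALSE])$index
  fg_mask <- seq_len(ld$B) %in% foreground
  B <- ld$B
  tlen <- fit$branch_lengths_hat
  kappa <- fit$kappa_hat

  # fixed per-branch time scale from the MLE mixture
  props_mle <- c(fit$p0, fit$p1, fit$p2a, fit$p2b)
  cw_mle <- .site_class_omegas("ModelA", fit$omega0, fit$omega2, fg_mask)
  flux_at <- function(w) {
    r <- .unscaled_rates(ld$freqs, kappa, w)
    sum(.flux(r, ld$freqs))
  }
  scale_b <- vapply(seq_len(B), function(b)
    sum(props_mle * vapply(cw_mle[, b], flux_at, 0)), 0)
  t_eff <- tlen / scale_b

  eig_for <- local({
    cache <- list()
    function(w) {
      key <- format(w, digits = 15)
      if (is.null(cache[[key]])) {
        r <- .unscaled_rates(ld$freqs, kappa, w)
        Q <- r; diag(Q) <- -rowSums(Q)
        cache[[key]] <<- .eigen_Q(Q, ld$freqs)
      }
      cache[[key]]
    }
  })
  pass <- function(omega_b) {   # one pruning pass, per-branch omegas
    P_list <- vector("list", B)
    for (b in seq_len(B))
      P_list[[b]] <- .pmat_from_eigen(eig_for(omega_b[b]), t_eff[b])
    .prune_site_loglik(ld$patterns, ld$phy, P_list, ld$freqs)
  }

  # 10-point grids; the proportion grid covers the (p0, p1) triangle by
  # stick-breaking - p0 on a 10-point grid, the remainder split between p1
  # and p2a+p2b on a second 10-point grid - so that the small selected-class
  # proportions typical of real data fall inside the grid's resolution
  g <- 10L
  mid <- (2 * seq_len(g) - 1) / (2 * g)
  w0_grid <- mid
  w2_grid <- exp(seq(log(1.05), log(.OMEGA_CAP), length.out = g))
  p_pts <- expand.grid(i = seq_len(g), j = seq_len(g))
  p0_grid <- mid[p_pts$i]
  p1_grid <- (1 - p0_grid) * mid[p_pts$j]

  f1 <- pass(rep(1, B))
  f0 <- lapply(w0_grid, function(w0) pass(rep(w0, B)))
  f2b <- lapply(w2_grid, function(w2) pass(ifelse(fg_mask, w2, 1)))
  f2a <- lapply(seq_len(g), function(i0)
    lapply(seq_len(g), function(i2)
      pass(ifelse(fg_mask, w2_grid[i2], w0_grid[i0]))))

  npat <- ncol(ld$patterns)
  n_pp <- nrow(p_pts)
  n_grid <- n_pp * g * g
  logM <- numeric(n_grid)
  ratio <- matrix(0, n_grid, npat)
  idx <- 0L
  for (i0 in seq_len(g)) for (i2 in seq_len(g)) {
    F <- rbind(f0[[i0]], f1, f2a[[i0]][[i2]], f2b[[i2]])
    m <- apply(F, 2L, max)
    E <- exp(sweep(F, 2L, m))
    for (pp in seq_len(n_pp)) {
      pr <- .modelA_props(p0_grid[pp], p1_grid[pp])
      site_lik <- colSums(pr * E)
      idx <- idx + 1L
      logM[idx] <- sum(ld$weights * (log(site_lik) + m))
      ratio[idx, ] <- (pr[3] * E[3, ] + pr[4] * E[4, ]) / site_lik
    }
  }
  post_grid <- exp(logM - max(logM))
  post_grid <- post_grid / sum(post_grid)
  post_pat <- colSums(post_grid * ratio)
  posterior <- post_pat[cp_index]

  ref_res <- translate_codons(aln$codons[1L, ])
  flagged <- which(posterior > threshold)
  structure(list(posterior = posterior,
                 flagged_sites = data.frame(
                   site = flagged,
                   residue = ref_res[flagged],
                   label = paste0(flagged, ref_res[flagged]),
                   posterior = posterior[flagged],
                   stringsAsFactors = FALSE),
                 threshold = threshold,
                 reference = aln$taxa[1L]),
            class = "BEBReport")
}

#' @export
print.BEBReport <- function(x, ...) {
  cat("BEBReport:", length(x$posterior), "sites,",
      nrow(x$flagged_sites), "flagged at >", x$threshold, "\n")
  if (nrow(x$flagged_sites))
    cat(" ", paste(x$flagged_sites$label, collapse = ", "), "\n")
  invisible(x)
}
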