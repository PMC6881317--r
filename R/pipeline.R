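# Per-pair orchestration: complete deletion, optimal branch-model search,
# fixed-omega and count-heuristic positive-selection calls, branch-site
# tests with BEB sites on each selected branch, Tajima's D, NG86 dating,
# and classification into the three post-duplication evolutionary patterns.

#' Default analysis configuration
#'
#' @param alpha significance level for all LRTs.
#' @param freq_mode codon frequency mode (observed-codon by default, i.e.
#'   empirical sense-codon proportions).
#' @param methods which optimal-model search strategies to run.
#' @param k Method III clustering granularity.
#' @param beb_threshold BEB posterior cutoff for flagging sites.
#' @param clock_rate synonymous substitutions/site/year for dating.
#' @param n_boot bootstrap replicates for the Ks confidence interval.
#' @param seed base seed for the bootstrap.
#' @param site_tests run branch-site tests and BEB on selected branches.
#' @param verdict_rule `"both"` requires branch-site tests 1 and 2 to both
#'   reject for the site-level call (the conservative reading); `"test1"`
#'   accepts test 1 alone.
#' @export
default_config <- function(alpha = 0.05, freq_mode = "observed-codon",
                           methods = c("I", "II", "III"), k = 0.5,
                           beb_threshold = 0.95, clock_rate = 6.5e-9,
                           n_boot = 1000L, seed = 1L, site_tests = TRUE,
                           verdict_rule = c("both", "test1")) {
  list(alpha = alpha, freq_mode = freq_mode, methods = methods, k = k,
       beb_threshold = beb_threshold, clock_rate = clock_rate,
       n_boot = n_boot, seed = seed, site_tests = site_tests,
       verdict_rule = match.arg(verdict_rule))
}

#' Classify a pair's evolutionary pattern from the final branch model
#'
#' Pattern 1: an omega > 1 class includes the retrocopy stem (the
#' retrocopy-side branch incident to the duplication node), with or without
#' parental-side elevation - adaptive evolution of the young retrogene.
#' Pattern 2: omega > 1 only on the parental stem - the parental gene
#' evolved rapidly right after the duplication. Pattern 3: omega > 1 only
#' on parental-side branches deeper in the parental clade - the parental
#' gene evolved only after some time had passed. Anything else: none.
#'
#' @param final_model a `ModelSearchResult` (or `BranchFit`) whose omega > 1
#'   classes define the selected branches.
#' @param tree the `PhyloTree` the model was fit on.
#' @param parental_taxa,retro_taxa tip labels of the parental and retrocopy
#'   copies; each must form one side of a branch, and the two stems must
#'   meet at the duplication node.
#' @return `"1"`, `"2"`, `"3"`, or `"none"`.
#' @export
classify_pattern <- function(final_model, tree, parental_taxa, retro_taxa) {
  fit <- if (inherits(final_model, "ModelSearchResult")) final_model$fit
         else final_model
  part <- fit$partition
  pos_classes <- which(fit$omega_hat > 1)
  pos <- which(part$classes %in% pos_classes)
  retro_stem <- stem_branch(tree, retro_taxa)
  par_stem <- stem_branch(tree, parental_taxa)
  if (is.na(retro_stem) || is.na(par_stem))
    stop("classification error: parental or retrocopy copies are not ",
         "monophyletic on this tree")
  if (retro_stem == par_stem)
    stop("classification error: the retrocopy and parental stems are the ",
         "same unrooted branch; an outgroup is needed to orient the ",
         "duplication node")
  ends <- function(b) tree$phylo$edge[b, ]
  if (!length(intersect(ends(retro_stem), ends(par_stem))))
    stop("classification error: the two stems do not meet at a single ",
         "duplication node")
  if (!length(pos)) return("none")
  ls <- .branch_leafsets(tree)
  parental_side <- which(vapply(ls, function(s)
    all(s %in% parental_taxa), TRUE))
  parental_side <- union(parental_side, par_stem)
  if (retro_stem %in% pos) return("1")
  if (all(pos %in% parental_side)) {
    if (length(pos) == 1L && pos == par_stem) return("2")
    if (!(par_stem %in% pos)) return("3")
  }
  "none"
}

#' Analyze one retrogene / parental gene pair
#'
#' Runs the full per-pair pipeline: complete deletion, one-ratio fit, the
#' requested optimal-model searches, final-model selection, the fixed-omega
#' LRT on omega > 1 classes, the substitution-count heuristic, branch-site
#' tests and BEB site identification on each selected branch, Tajima's D,
#' NG86 Ks dating of the parental-vs-retro split, and pattern
#' classification.
#'
#' @param aln `CodonAlignment` (gaps allowed; complete deletion is applied).
#' @param tree `PhyloTree` over the alignment's taxa.
#' @param parental_taxa,retro_taxa tip labels of the two copies.
#' @param config a [default_config()].
#' @param pair_id label used in reports.
#' @return A `PairVerdict` list; on a stage failure, a partial verdict with
#'   the failing stage named in `$failed_stage`.
#' @export
analyze_pair <- function(aln, tree, parental_taxa, retro_taxa,
                         config = default_config(), pair_id = "pair") {
  v <- list(pair_id = pair_id, positive = FALSE, tier = "none",
            pattern = "none", foreground_branches = integer(0),
            failed_stage = NULL)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (is.null(v$failed_stage))
        v$failed_stage <<- paste0(name, ": ", conditionMessage(e))
      NULL
    })
  }

  aln <- stage("complete_deletion", complete_deletion(aln))
  if (is.null(aln)) return(structure(v, class = "PairVerdict"))

  base <- stage("one_ratio_fit",
                fit_partition(aln, tree, one_ratio_partition(tree),
                              freq_mode = config$freq_mode))
  results <- list()
  if (!is.null(base)) {
    for (m in config$methods) {
      r <- stage(paste0("obsm_", m),
                 obsm_search(aln, tree, m, k = config$k,
                             alpha = config$alpha,
                             freq_mode = config$freq_mode, base = base))
      if (!is.null(r)) results[[m]] <- r
    }
  }
  if (length(results)) {
    v$final_model <- stage("select_final",
                           select_final(unname(results), config$alpha))
    v$search_results <- results
  }

  if (!is.null(v$final_model)) {
    fit <- v$final_model$fit
    pos_classes <- which(fit$omega_hat > 1)
    v$foreground_branches <-
      which(fit$partition$classes %in% pos_classes)
    if (length(pos_classes)) {
      v$fix_model <- stage("fix_model_test",
                           fix_model_test(aln, tree, fit$partition,
                                          pos_classes, fit = fit,
                                          freq_mode = config$freq_mode))
    }
    v$counts <- fit$counts
    v$count_flags <- which(nozawa_flag(fit$counts$nN, fit$counts$nS))
    if (!is.null(v$fix_model) && v$fix_model$p < config$alpha) {
      v$positive <- TRUE; v$tier <- "LRT-significant"
    } else if (length(v$count_flags)) {
      v$positive <- TRUE; v$tier <- "count-heuristic"
    }
  }

  if (config$site_tests && length(v$foreground_branches)) {
    v$site_reports <- list()
    for (b in v$foreground_branches) {
      bs <- stage(paste0("branch_site_", b),
                  branch_site_tests(aln, tree, b, alpha = config$alpha,
                                    freq_mode = config$freq_mode))
      if (is.null(bs)) next
      ok <- if (config$verdict_rule == "both") bs$positive
            else bs$test1$p < config$alpha
      beb <- NULL
      if (ok)
        beb <- stage(paste0("beb_", b),
                     beb_sites(aln, tree, b, bs$fits$ModelA,
                               threshold = config$beb_threshold))
      v$site_reports[[as.character(b)]] <-
        list(branch = b, tests = bs[c("test1", "test2", "positive")],
             fits = bs$fits, beb = beb)
    }
  }

  if (length(aln$taxa) >= 4L) v$tajima <- stage("tajima_d", tajima_d(aln))

  pa <- intersect(aln$taxa, parental_taxa)
  ra <- intersect(aln$taxa, retro_taxa)
  if (length(pa) && length(ra)) {
    v$age <- stage("dating", {
      sA <- aln$codons[pa[1L], ]
      sB <- aln$codons[ra[1L], ]
      kc <- ks_confidence(sA, sB, n_boot = config$n_boot,
                          seed = config$seed)
      list(ks = kc$ks, ks_ci = kc$ci_half_width,
           rate = config$clock_rate,
           age_my = age_from_ks(kc$ks, config$clock_rate),
           age_ci_my = age_from_ks(kc$ci_half_width, config$clock_rate),
           taxa = c(pa[1L], ra[1L]))
    })
  }

  if (v$positive && !is.null(v$final_model)) {
    pat <- stage("classify_pattern",
                 classify_pattern(v$final_model, tree, parental_taxa,
                                  retro_taxa))
    if (!is.null(pat)) v$pattern <- pat
  }
  structure(v, class = "PairVerdict")
}

#' @export
print.PairVerdict <- function(x, ...) {
  cat("PairVerdict [", x$pair_id, "]: ",
      if (x$positive) "POSITIVE" else "not positive",
      " (", x$tier, "), pattern ", x$pattern, "\n", sep = "")
  if (length(x$foreground_branches))
    cat("  selected branches:", paste(x$foreground_branches, collapse = ","),
        "\n")
  if (!is.null(x$failed_stage)) cat("  failed stage:", x$failed_stage, "\n")
  invisible(x)
}

#' Cohort summary across pair verdicts
#'
#' @param verdicts list of `PairVerdict`.
#' @param baseline_rate,baseline_n optional genome-wide baseline for the
#'   Fisher enrichment test (e.g. 0.10 of `baseline_n` coding genes).
#' @return list with `n`, `positives`, `percent` (2 decimals), `patterns`
#'   (table), `ages` (data.frame), and `enrichment` when a baseline is
#'   given.
#' @export
summarize_cohort <- function(verdicts, baseline_rate = NULL,
                             baseline_n = NULL) {
  stopifnot(length(verdicts) >= 1L)
  n <- length(verdicts)
  pos <- sum(vapply(verdicts, function(v) isTRUE(v$positive), TRUE))
  out <- list(n = n, positives = pos, percent = round(100 * pos / n, 2),
              patterns = table(vapply(verdicts, function(v)
                v$pattern %||% "none", "")),
              ages = do.call(rbind, lapply(verdicts, function(v) {
                if (is.null(v$age)) return(NULL)
                data.frame(pair = v$pair_id, ks = v$age$ks,
                           ks_ci = v$age$ks_ci, age_my = v$age$age_my,
                           age_ci_my = v$age$age_ci_my,
                           stringsAsFactors = FALSE)
              })))
  if (!is.null(baseline_rate) && !is.null(baseline_n))
    out$enrichment <- enrichment_test(pos, n, baseline_rate, baseline_n)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a pair verdict to JSON
#'
#' Writes the report-level content of a verdict (calls, tiers, sites,
#' neutrality and age statistics) so that a read/write cycle is lossless.
#'
#' @param v a `PairVerdict`.
#' @param path output file; `NULL` returns the JSON string.
#' @export
write_verdict <- function(v, path = NULL) {
  flat <- list(
    pair_id = v$pair_id, positive = v$positive, tier = v$tier,
    pattern = v$pattern, foreground_branches = v$foreground_branches,
    final_lnL = if (!is.null(v$final_model)) v$final_model$fit$lnL,
    final_np = if (!is.null(v$final_model)) v$final_model$fit$np,
    final_R = if (!is.null(v$final_model)) v$final_model$partition$R,
    omega_hat = if (!is.null(v$final_model)) v$final_model$fit$omega_hat,
    fix_model = if (!is.null(v$fix_model))
      v$fix_model[c("stat", "p", "df")],
    flagged_sites = {
      labs <- unlist(lapply(v$site_reports, function(sr)
        if (!is.null(sr$beb)) sr$beb$flagged_sites$label))
      if (is.null(labs)) character(0) else labs
    },
    tajima = if (!is.null(v$tajima))
      v$tajima[c("m", "n_sites", "S", "ps", "theta", "pi", "D")],
    age = if (!is.null(v$age))
      v$age[c("ks", "ks_ci", "age_my", "age_ci_my")],
    failed_stage = v$failed_stage)
  js <- jsonlite::toJSON(flat, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a serialized verdict
#' @param path JSON file written by [write_verdict()].
#' @export
read_verdict <- function(path) jsonlite::fromJSON(path, simplifyVector = TRUE)

#' Candidate-model report table
#'
#' One row per search trail entry across methods, mirroring the layout of a
#' per-gene model-selection table (method, class count, lnL, np, AIC,
#' decision).
#'
#' @param results list of `ModelSearchResult` (e.g. `v$search_results`).
#' @param path optional TSV output file.
#' @export
report_model_table <- function(results, path = NULL) {
  tab <- do.call(rbind, lapply(results, function(r) r$trail))
  rownames(tab) <- NULL
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tab
}
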