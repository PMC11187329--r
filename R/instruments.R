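#' Select cis SNPs for a drug target
#'
#' Keeps SNPs on the target's chromosome with position inside the gene body
#' extended by `window_bp` on each side (boundaries inclusive) and exposure
#' p-value strictly below `p_threshold`. An empty result is valid: some
#' targets have no genome-wide-significant cis SNP.
#'
#' @param table exposure `summary_table`.
#' @param target one-row `target_spec`.
#' @param window_bp cis-window flank in bp (default 100 kb).
#' @param p_threshold genome-wide significance threshold (default 5e-8),
#'   applied strictly (`pval < p_threshold`).
#' @return `summary_table` of the selected SNPs (possibly zero rows).
#' @export
select_cis_snps <- function(table, target, window_bp = 100000L,
                            p_threshold = 5e-8) {
  stopifnot(inherits(table, "summary_table"), nrow(target) == 1L,
            window_bp >= 0)
  w <- cis_window(target, window_bp)
  keep <- table$chrom == target$chrom &
    table$pos >= w[1] & table$pos <= w[2] &
    table$pval < p_threshold
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping of candidate instruments
#'
#' Candidates are ranked by ascending p-value (ties broken by ascending
#' position, then lexicographic SNP id). The best remaining SNP is retained
#' and every remaining SNP with r-squared at or above `r2_threshold` against
#' it is discarded; this repeats until no candidate remains. Retained SNPs
#' are therefore pairwise below the threshold and each discarded SNP has a
#' retained, better-ranked partner at or above it.
#'
#' @param candidates `summary_table` of candidate SNPs.
#' @param ld square numeric matrix of r-squared values with SNP ids as
#'   row/column names, covering all candidates; symmetric, unit diagonal.
#' @param r2_threshold independence threshold (default 0.001): SNP pairs
#'   with `r2 >= r2_threshold` are considered linked.
#' @return `summary_table` of retained SNPs in retention order.
#' @export
ld_clump <- function(candidates, ld, r2_threshold = 0.001) {
  stopifnot(inherits(candidates, "summary_table"))
  if (nrow(candidates) == 0L) return(candidates)
  absent <- setdiff(candidates$snp_id, rownames(ld))
  if (length(absent) > 0L) {
    stop("SNP(s) absent from LD matrix: ", paste(absent, collapse = ", "))
  }
  ord <- order(candidates$pval, candidates$pos, candidates$snp_id)
  queue <- candidates$snp_id[ord]
  retained <- character(0)
  while (length(queue) > 0L) {
    best <- queue[1L]
    retained <- c(retained, best)
    r2 <- ld[best, queue]
    queue <- queue[r2 < r2_threshold & queue != best]
  }
  out <- candidates[match(retained, candidates$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instrument-strength F statistics
#'
#' The default per-SNP F is the squared Wald z, `(beta/se)^2`. The
#' alternative `method = "r2"` uses the variance explained by the SNP under
#' a standardized trait, `r2 = 2*eaf*(1-eaf)*beta^2`, giving
#' `F = r2*(n-2)/(1-r2)` (requires `eaf` and `n`). Mean F at or below 10
#' flags the set as weak.
#'
#' @param snps `summary_table` of instruments, or a data.frame of harmonized
#'   pairs (columns `beta_exposure`/`se_exposure` used in that case).
#' @param method `"wald"` (default) or `"r2"`.
#' @return list with `f_per_snp`, `mean_f`, `weak_instruments`.
#' @export
f_statistics <- function(snps, method = c("wald", "r2")) {
  method <- match.arg(method)
  if (all(c("beta_exposure", "se_exposure") %in% names(snps))) {
    beta <- snps$beta_exposure; se <- snps$se_exposure
    eaf <- snps$eaf_exposure; n <- rep(NA_real_, nrow(snps))
  } else {
    beta <- snps$beta; se <- snps$se; eaf <- snps$eaf; n <- snps$n
  }
  if (length(beta) == 0L) stop("no instruments: cannot compute F statistics")
  stopifnot(all(se > 0))
  if (method == "wald") {
    f <- (beta / se)^2
  } else {
    if (anyNA(eaf) || anyNA(n)) stop("method 'r2' requires eaf and n")
    r2 <- 2 * eaf * (1 - eaf) * beta^2
    if (any(r2 >= 1)) stop("r2 >= 1: betas are not on a standardized scale")
    f <- r2 * (n - 2) / (1 - r2)
  }
  mean_f <- mean(f)
  list(f_per_snp = f, mean_f = mean_f, weak_instruments = mean_f <= 10)
}

#' Build the genetic instrument set for a drug target
#'
#' Composes the selection pipeline: cis-window + significance filter on the
#' exposure, greedy LD clumping, harmonization against the outcome (dropping
#' palindromic/mismatched SNPs and SNPs absent from the outcome), and
#' F-statistic screening. Selection happens on the exposure table before
#' harmonization, so SNPs lost at harmonization reduce the final count. A
#' per-stage SNP count log is kept for provenance.
#'
#' @param exposure,outcome `summary_table` objects.
#' @param target one-row `target_spec`.
#' @param ld r-squared matrix covering the cis candidates.
#' @param window_bp,p_threshold,r2_threshold,palindrome_eaf_window selection
#'   parameters; see [select_cis_snps()], [ld_clump()], [harmonize()].
#' @param f_method passed to [f_statistics()].
#' @return an `instrument_set`: list with `target`, `pairs` (kept/flipped
#'   harmonized pairs), `f_per_snp`, `mean_f`, `weak_instruments`, `n_snps`,
#'   and `log` (named per-stage counts). With zero instruments the F fields
#'   are `NA` and `n_snps` is 0.
#' @export
build_instrument_set <- function(exposure, outcome, target, ld,
                                 window_bp = 100000L, p_threshold = 5e-8,
                                 r2_threshold = 0.001,
                                 palindrome_eaf_window = 0.08,
                                 f_method = "wald") {
  cis <- select_cis_snps(exposure, target, window_bp, p_threshold)
  clumped <- if (nrow(cis) > 0L) ld_clump(cis, ld, r2_threshold) else cis
  if (nrow(clumped) > 0L) {
    pairs <- harmonize(clumped, outcome, palindrome_eaf_window)
    kept <- kept_pairs(pairs)
  } else {
    pairs <- kept <- data.frame()
  }
  log <- c(n_cis = nrow(cis), n_clumped = nrow(clumped),
           n_shared = nrow(pairs), n_kept = nrow(kept))
  if (nrow(kept) > 0L) {
    fs <- f_statistics(kept, method = f_method)
  } else {
    fs <- list(f_per_snp = numeric(0), mean_f = NA_real_,
               weak_instruments = NA)
  }
  structure(list(target = target, pairs = kept,
                 f_per_snp = fs$f_per_snp, mean_f = fs$mean_f,
                 weak_instruments = fs$weak_instruments,
                 n_snps = nrow(kept), log = log),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %s (%s, %s)\n", x$target$gene_symbol,
              x$target$lipid_trait, x$target$drug_label))
  cat(sprintf("  stages: cis %d -> clumped %d -> shared %d -> kept %d\n",
              x$log["n_cis"], x$log["n_clumped"], x$log["n_shared"],
              x$log["n_kept"]))
  if (x$n_snps > 0L) {
    cat(sprintf("  mean F = %.2f%s\n", x$mean_f,
                if (isTRUE(x$weak_instruments)) " (weak: mean F <= 10)" else ""))
  }
  invisible(x)
}
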