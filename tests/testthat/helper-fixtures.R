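# quick builders for tiny fixtures, all generated in code

make_st <- function(snp_id, pos, beta, se, pval,
                    chrom = "1", effect_allele = "A", other_allele = "G",
                    eaf = 0.3, n = 1e5, trait = "LDL") {
  k <- length(snp_id)
  summary_table(data.frame(
    snp_id = snp_id, chrom = rep_len(chrom, k), pos = pos,
    effect_allele = rep_len(effect_allele, k),
    other_allele = rep_len(other_allele, k),
    eaf = rep_len(eaf, k), beta = beta, se = se, pval = pval,
    n = rep_len(n, k), stringsAsFactors = FALSE), trait_label = trait)
}

make_pairs <- function(bx, by, sy, sx = rep(0.01, length(bx)),
                       eaf = rep(0.3, length(bx))) {
  data.frame(snp_id = sprintf("snp_%03d", seq_along(bx)),
             beta_exposure = bx, se_exposure = sx, eaf_exposure = eaf,
             beta_outcome = by, se_outcome = sy, action = "kept",
             stringsAsFactors = FALSE)
}

# the 3-SNP worked example: ratios (0.5, 0.4, 0.6), all ratio weights 100
example_pairs_3snp <- function() {
  make_pairs(bx = c(0.1, 0.2, 0.5), by = c(0.05, 0.08, 0.30),
             sy = c(0.01, 0.02, 0.05))
}

make_target <- function(gene = "GENE1", chrom = "1",
                        start = 1000000L, end = 1050000L,
                        trait = "LDL", drug = "drug") {
  target_spec(gene, chrom, start, end, trait, drug)
}

# independent greedy-clumping oracle: walk candidates in (pval, pos, snp_id)
# rank order, keep a SNP iff its r2 with every already-kept SNP is below the
# threshold
clump_oracle <- function(candidates, ld, r2_threshold) {
  ord <- order(candidates$pval, candidates$pos, candidates$snp_id)
  kept <- character(0)
  for (id in candidates$snp_id[ord]) {
    if (length(kept) == 0L || all(ld[id, kept] < r2_threshold)) {
      kept <- c(kept, id)
    }
  }
  kept
}

# three-target study: GENE1 causal on both outcomes, GENE2 null on the
# control outcome (fails the gate), GENE3 control-only
sim_small_study <- function(seed = 17) {
  targets <- rbind(
    target_spec("GENE1", "1", 1000000L, 1050000L, "LDL", "drugA"),
    target_spec("GENE2", "2", 2000000L, 2040000L, "LDL", "drugB"),
    target_spec("GENE3", "3", 3000000L, 3030000L, "TG", "drugC"))
  class(targets) <- c("target_spec", "data.frame")
  simulate_study(targets, cfg = sim_config(j_snps = 8L, n_decoys = 4L),
                 j_snps = list(GENE1.LDL = 8L, GENE2.LDL = 8L, GENE3.TG = 8L),
                 theta_control = list(GENE1.LDL = 0.4, GENE2.LDL = 0,
                                      GENE3.TG = 0.4),
                 theta_disease = list(GENE1.LDL = 0.5, GENE2.LDL = 0,
                                      GENE3.TG = 0),
                 seed = seed)
}

random_clump_instance <- function(j, r2_threshold = 0.05) {
  ids <- sprintf("rs%02d", seq_len(j))
  pv <- signif(stats::runif(j, 1e-12, 1e-8), 3)
  if (j > 2 && stats::runif(1) < 0.3) pv[2] <- pv[1]  # occasional ties
  st <- make_st(ids, pos = sample.int(1e6, j), beta = 0.1, se = 0.01,
                pval = pv)
  ld <- diag(1, j)
  dimnames(ld) <- list(ids, ids)
  for (a in seq_len(j - 1)) {
    for (b in (a + 1):j) {
      r2 <- if (stats::runif(1) < 0.3) stats::runif(1) else 0
      ld[a, b] <- ld[b, a] <- r2
    }
  }
  list(st = st, ld = ld, thr = r2_threshold)
}
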