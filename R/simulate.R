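#' Simulation configuration for synthetic GWAS summary statistics
#'
#' Defaults emulate the scale of the real data sources: a quantitative-lipid
#' exposure GWAS of 188,577 participants, a positive-control outcome GWAS of
#' 184,305 (60,801 cases + 123,504 controls) and a disease outcome GWAS of
#' 212,231 (1,092 cases + 211,139 controls). Per-SNP standard errors follow
#' `se = 1/sqrt(2*eaf*(1-eaf)*n)`, the standard approximation for a
#' variance-standardized trait. True exposure effects are drawn with random
#' sign and magnitude uniform on `beta_range`, chosen so that planted
#' instruments are comfortably genome-wide significant at these sample
#' sizes.
#'
#' @param j_snps number of significant cis instruments planted per target.
#' @param window_bp cis-window flank the generator places SNPs within.
#' @param beta_range magnitude range of true per-allele exposure effects
#'   (SD units).
#' @param eaf_range effect-allele frequency range.
#' @param n_exposure,n_control,n_disease GWAS sample sizes.
#' @param theta_control,theta_disease true causal effects of the exposure on
#'   the two outcomes (log-odds per SD).
#' @param pleiotropy `"none"`, `"balanced"` (offsets `N(0, sigma_alpha)`) or
#'   `"directional"` (offsets `N(mu_alpha, sigma_alpha)`); offsets are
#'   defined on the exposure-increasing allele orientation and apply to both
#'   outcomes independently.
#' @param mu_alpha,sigma_alpha pleiotropy offset distribution parameters.
#' @param n_outliers number of planted pleiotropic outliers.
#' @param outlier_offset outlier offset in multiples of the SNP's outcome
#'   standard error, applied on the exposure-increasing orientation.
#' @param n_ld_pairs number of planted-instrument pairs put in LD with each
#'   other (pair k is planted SNPs 2k-1 and 2k).
#' @param ld_pair_r2 within-pair r-squared for planted LD pairs.
#' @param palindromic_fraction fraction of SNPs given A/T or C/G alleles;
#'   their frequencies are kept away from 0.5 so strand can be resolved.
#' @param palindrome_eaf_window ambiguity window the generator steers
#'   palindromic frequencies clear of (matching the harmonizer default).
#' @param n_decoys non-instrument SNPs added per target: half significant
#'   but outside the cis window, half inside the window with a null
#'   exposure effect.
#' @param flip_fraction fraction of outcome rows stored on the opposite
#'   allele orientation (alleles swapped, beta negated, eaf complemented),
#'   to exercise harmonization.
#' @param strand_fraction fraction of outcome rows stored on the opposite
#'   strand (alleles complemented).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(j_snps = 12L, window_bp = 100000L,
                       beta_range = c(0.06, 0.14),
                       eaf_range = c(0.05, 0.95),
                       n_exposure = 188577, n_control = 184305,
                       n_disease = 212231,
                       theta_control = 0.4, theta_disease = 0.5,
                       pleiotropy = c("none", "balanced", "directional"),
                       mu_alpha = 0, sigma_alpha = 0,
                       n_outliers = 0L, outlier_offset = 0,
                       n_ld_pairs = 0L, ld_pair_r2 = 1.0,
                       palindromic_fraction = 0.1,
                       palindrome_eaf_window = 0.08,
                       n_decoys = 10L, flip_fraction = 0.5,
                       strand_fraction = 0.3) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(j_snps >= 0, window_bp >= 0, length(beta_range) == 2L,
            beta_range[1] > 0, beta_range[1] <= beta_range[2],
            eaf_range[1] > 0, eaf_range[2] < 1,
            n_exposure >= 2, n_control >= 2, n_disease >= 2,
            sigma_alpha >= 0, n_outliers >= 0, outlier_offset >= 0,
            n_ld_pairs >= 0, ld_pair_r2 >= 0, ld_pair_r2 <= 1,
            palindromic_fraction >= 0, palindromic_fraction <= 1,
            2L * n_ld_pairs <= j_snps)
  structure(as.list(environment()), class = "sim_config")
}

# se of a per-allele GWAS effect for a standardized trait
gwas_se <- function(eaf, n) 1 / sqrt(2 * eaf * (1 - eaf) * n)

draw_pleiotropy <- function(j, regime, mu, sigma) {
  switch(regime,
         none = rep(0, j),
         balanced = stats::rnorm(j, 0, sigma),
         directional = stats::rnorm(j, mu, sigma))
}

#' Simulate a harmonized instrument set with known ground truth
#'
#' The low-level statistical generator behind all calibration and recovery
#' checks: draws `j` independent instruments with true exposure effects,
#' simulates estimated exposure and outcome effects with the GWAS-scale
#' standard errors implied by the sample sizes, and returns them as already
#' harmonized pairs. Pleiotropy offsets and planted outliers enter the true
#' outcome effect on the exposure-increasing allele orientation; exposure
#' and outcome draws are independent, matching the two-sample design.
#'
#' @param j number of instruments.
#' @param theta true causal effect.
#' @param n_exposure,n_outcome sample sizes.
#' @param beta_range,eaf_range,pleiotropy,mu_alpha,sigma_alpha,n_outliers,outlier_offset
#'   see [sim_config()].
#' @param seed optional seed.
#' @return data.frame of harmonized pairs with attribute `truth`: list with
#'   `theta`, `beta_x_true`, `alpha`, `outlier_ids`.
#' @export
simulate_instruments <- function(j, theta = 0,
                                 n_exposure = 188577, n_outcome = 184305,
                                 beta_range = c(0.06, 0.14),
                                 eaf_range = c(0.05, 0.95),
                                 pleiotropy = c("none", "balanced",
                                                "directional"),
                                 mu_alpha = 0, sigma_alpha = 0,
                                 n_outliers = 0L, outlier_offset = 0,
                                 seed = NULL) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(j >= 1, n_outliers <= j)
  if (!is.null(seed)) set.seed(seed)
  eaf <- stats::runif(j, eaf_range[1], eaf_range[2])
  sgn <- sample(c(-1, 1), j, replace = TRUE)
  bx_true <- sgn * stats::runif(j, beta_range[1], beta_range[2])
  se_x <- gwas_se(eaf, n_exposure)
  se_y <- gwas_se(eaf, n_outcome)
  alpha <- draw_pleiotropy(j, pleiotropy, mu_alpha, sigma_alpha)
  offset <- rep(0, j)
  outlier_ids <- character(0)
  if (n_outliers > 0L) {
    idx <- sample.int(j, n_outliers)
    offset[idx] <- outlier_offset * se_y[idx]
    outlier_ids <- sprintf("snp_%03d", idx)
  }
  by_true <- theta * bx_true + sgn * (alpha + offset)
  bx_hat <- stats::rnorm(j, bx_true, se_x)
  by_hat <- stats::rnorm(j, by_true, se_y)
  pairs <- data.frame(snp_id = sprintf("snp_%03d", seq_len(j)),
                      beta_exposure = bx_hat, se_exposure = se_x,
                      eaf_exposure = eaf,
                      beta_outcome = by_hat, se_outcome = se_y,
                      action = "kept", stringsAsFactors = FALSE)
  attr(pairs, "truth") <- list(theta = theta, beta_x_true = bx_true,
                               alpha = alpha, outlier_ids = outlier_ids)
  pairs
}

# allele assignment: palindromic SNPs get A/T or C/G; others a non-ambiguous
# pair. Palindromic eaf is pushed outside the ambiguity window so that
# frequency-based strand alignment works.
assign_alleles <- function(n, palindromic, eaf, w) {
  non_pal <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                  c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pal <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  ea <- oa <- character(n)
  for (i in seq_len(n)) {
    al <- if (palindromic[i]) pal[[sample.int(4, 1)]] else
      non_pal[[sample.int(8, 1)]]
    ea[i] <- al[1]; oa[i] <- al[2]
  }
  margin <- w + 0.03
  amb <- palindromic & abs(eaf - 0.5) <= margin
  eaf[amb] <- ifelse(stats::runif(sum(amb)) < 0.5,
                     0.5 - margin - stats::runif(sum(amb)) * 0.05,
                     0.5 + margin + stats::runif(sum(amb)) * 0.05)
  list(effect_allele = ea, other_allele = oa, eaf = eaf)
}

make_table <- function(ids, chrom, pos, al, beta, se, n, trait) {
  # floored so that extreme z-scores do not underflow to an invalid p = 0
  pval <- pmax(2 * stats::pnorm(-abs(beta) / se), .Machine$double.xmin)
  summary_table(data.frame(
    snp_id = ids, chrom = chrom, pos = pos,
    effect_allele = al$effect_allele, other_allele = al$other_allele,
    eaf = al$eaf, beta = beta, se = se,
    pval = pval, n = n,
    stringsAsFactors = FALSE), trait_label = trait)
}

# store a fraction of outcome rows on the opposite allele orientation and/or
# strand; downstream harmonization must undo this exactly
scramble_orientation <- function(tab, flip_fraction, strand_fraction) {
  n <- nrow(tab)
  flip <- stats::runif(n) < flip_fraction
  ea <- tab$effect_allele; oa <- tab$other_allele
  tab$effect_allele[flip] <- oa[flip]
  tab$other_allele[flip] <- ea[flip]
  tab$beta[flip] <- -tab$beta[flip]
  tab$eaf[flip] <- 1 - tab$eaf[flip]
  strand <- stats::runif(n) < strand_fraction
  tab$effect_allele[strand] <- complement_allele(tab$effect_allele[strand])
  tab$other_allele[strand] <- complement_allele(tab$other_allele[strand])
  tab
}

#' Simulate exposure/outcome summary statistics for one drug target
#'
#' Plants `j_snps` genome-wide-significant instruments inside the target's
#' cis window, adds decoys (significant SNPs outside the window and null
#' SNPs inside it), builds a block LD matrix (identity except planted LD
#' pairs), and produces three summary tables: the lipid exposure, the
#' positive-control outcome with true effect `theta_control`, and the
#' disease outcome with true effect `theta_disease`. Outcome tables are
#' stored with randomly scrambled allele orientation and strand so that the
#' harmonization step is exercised end to end.
#'
#' @param target one-row `target_spec`.
#' @param cfg a [sim_config()].
#' @param seed optional seed.
#' @param id_prefix prefix for SNP identifiers (unique ids across targets).
#' @return list with `exposure`, `control`, `disease` (summary tables),
#'   `ld` (r-squared matrix over all simulated SNPs), and `truth` (list:
#'   `theta_control`, `theta_disease`, `planted_ids`, `ld_pair_ids`,
#'   `outlier_ids`, `beta_x_true`).
#' @export
simulate_target <- function(target, cfg = sim_config(), seed = NULL,
                            id_prefix = NULL) {
  stopifnot(inherits(cfg, "sim_config"), nrow(target) == 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(id_prefix)) {
    id_prefix <- paste0(target$gene_symbol, "_", target$lipid_trait)
  }
  j <- cfg$j_snps
  n_out_decoy <- ceiling(cfg$n_decoys / 2)
  n_null_decoy <- cfg$n_decoys - n_out_decoy
  n_all <- j + cfg$n_decoys

  win <- cis_window(target, cfg$window_bp)
  pos_in <- sample((win[1] + 1L):(win[2] - 1L), j + n_null_decoy)
  pos_out <- win[2] + sample(10000L:1000000L, n_out_decoy)
  ids <- sprintf("%s_snp%03d", id_prefix, seq_len(n_all))
  planted_ids <- ids[seq_len(j)]
  pos <- c(pos_in[seq_len(j)],
           pos_out,
           pos_in[j + seq_len(n_null_decoy)])

  eaf <- stats::runif(n_all, cfg$eaf_range[1], cfg$eaf_range[2])
  palindromic <- stats::runif(n_all) < cfg$palindromic_fraction
  al <- assign_alleles(n_all, palindromic, eaf, cfg$palindrome_eaf_window)
  eaf <- al$eaf

  sgn <- sample(c(-1, 1), n_all, replace = TRUE)
  mag <- stats::runif(n_all, cfg$beta_range[1], cfg$beta_range[2])
  bx_true <- sgn * mag
  bx_true[j + n_out_decoy + seq_len(n_null_decoy)] <- 0  # null in-window decoys

  se_x <- gwas_se(eaf, cfg$n_exposure)
  bx_hat <- stats::rnorm(n_all, bx_true, se_x)
  exposure <- make_table(ids, target$chrom, pos, al, bx_hat, se_x,
                         cfg$n_exposure, target$lipid_trait)

  outcome_table <- function(theta, n_outcome, trait) {
    se_y <- gwas_se(eaf, n_outcome)
    alpha <- draw_pleiotropy(n_all, cfg$pleiotropy, cfg$mu_alpha,
                             cfg$sigma_alpha)
    offset <- rep(0, n_all)
    out_ids <- character(0)
    if (cfg$n_outliers > 0L && j > 0L) {
      idx <- sample.int(j, min(cfg$n_outliers, j))
      offset[idx] <- cfg$outlier_offset * se_y[idx]
      out_ids <- ids[idx]
    }
    by_true <- theta * bx_true + sgn * (alpha + offset)
    by_hat <- stats::rnorm(n_all, by_true, se_y)
    tab <- make_table(ids, target$chrom, pos, al, by_hat, se_y, n_outcome,
                      trait)
    tab <- scramble_orientation(tab, cfg$flip_fraction, cfg$strand_fraction)
    list(table = tab, outlier_ids = out_ids)
  }
  ctrl <- outcome_table(cfg$theta_control, cfg$n_control, "control")
  dis <- outcome_table(cfg$theta_disease, cfg$n_disease, "disease")

  ld <- diag(1, n_all)
  dimnames(ld) <- list(ids, ids)
  ld_pair_ids <- list()
  if (cfg$n_ld_pairs > 0L) {
    for (k in seq_len(cfg$n_ld_pairs)) {
      a <- 2L * k - 1L; b <- 2L * k
      ld[a, b] <- ld[b, a] <- cfg$ld_pair_r2
      ld_pair_ids[[k]] <- ids[c(a, b)]
    }
  }

  list(exposure = exposure, control = ctrl$table, disease = dis$table,
       ld = ld,
       truth = list(theta_control = cfg$theta_control,
                    theta_disease = cfg$theta_disease,
                    planted_ids = planted_ids,
                    ld_pair_ids = ld_pair_ids,
                    outlier_ids = ctrl$outlier_ids,
                    disease_outlier_ids = dis$outlier_ids,
                    beta_x_true = bx_true[seq_len(j)]))
}

# study-level defaults: instrument counts per target follow the per-target
# SNP counts the selection stage is expected to yield, true control-stage
# effects are nonzero for the targets with an established positive-control
# effect, and true disease-stage effects are planted at the PCSK9-, LDLR-
# and LPL-like targets only.
default_study_truth <- function() {
  list(
    j_snps = c(HMGCR.LDL = 7L, PCSK9.LDL = 12L, NPC1L1.LDL = 3L,
               APOB.LDL = 20L, ANGPTL3.LDL = 3L, PPARA.LDL = 0L,
               LDLR.LDL = 14L, LPL.LDL = 0L,
               ANGPTL3.TG = 4L, PPARA.TG = 0L, APOC3.TG = 10L,
               LDLR.TG = 0L, LPL.TG = 24L),
    theta_control = c(HMGCR.LDL = 0.368, PCSK9.LDL = 0.421,
                      NPC1L1.LDL = 0.504, APOB.LDL = 0.217,
                      ANGPTL3.LDL = 0, PPARA.LDL = 0, LDLR.LDL = 0.599,
                      LPL.LDL = 0,
                      ANGPTL3.TG = 0, PPARA.TG = 0, APOC3.TG = 0.217,
                      LDLR.TG = 0, LPL.TG = 0.428),
    theta_disease = c(HMGCR.LDL = 0, PCSK9.LDL = 0.578, NPC1L1.LDL = 0,
                      APOB.LDL = 0, ANGPTL3.LDL = 0, PPARA.LDL = 0,
                      LDLR.LDL = 0.458, LPL.LDL = 0,
                      ANGPTL3.TG = 0, PPARA.TG = 0, APOC3.TG = 0,
                      LDLR.TG = 0, LPL.TG = 0.475))
}

#' Simulate a full multi-target study with known ground truth
#'
#' Assembles a [study_config()] covering every requested target: per-trait
#' exposure tables, shared control and disease outcome tables, and per-trait
#' LD matrices, all generated by [simulate_target()]. Defaults plant the
#' finding pattern of the motivating study: positive-control effects at the
#' gate-passing targets, disease effects only at the PCSK9-, LDLR- and
#' LPL-like targets, and zero planted instruments where the selection stage
#' is expected to come up empty.
#'
#' @param targets `target_spec` data.frame (default [lipid_targets()]).
#' @param cfg base [sim_config()] applied to every target.
#' @param j_snps,theta_control,theta_disease optional named vectors (names
#'   `GENE.TRAIT`) overriding the per-target defaults.
#' @param seed seed for the whole study (per-target seeds derived from it).
#' @return list with `config` (a `study_config`) and `truth` (per-target
#'   ground-truth list, names `GENE.TRAIT`).
#' @export
simulate_study <- function(targets = lipid_targets(), cfg = sim_config(),
                           j_snps = NULL, theta_control = NULL,
                           theta_disease = NULL, seed = 1L) {
  defaults <- default_study_truth()
  j_snps <- utils::modifyList(as.list(defaults$j_snps),
                              as.list(j_snps %||% integer(0)))
  theta_control <- utils::modifyList(as.list(defaults$theta_control),
                                     as.list(theta_control %||% numeric(0)))
  theta_disease <- utils::modifyList(as.list(defaults$theta_disease),
                                     as.list(theta_disease %||% numeric(0)))

  per_target <- list()
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, , drop = FALSE]
    key <- paste0(tg$gene_symbol, ".", tg$lipid_trait)
    tcfg <- cfg
    tcfg$j_snps <- as.integer(j_snps[[key]] %||% cfg$j_snps)
    tcfg$theta_control <- theta_control[[key]] %||% cfg$theta_control
    tcfg$theta_disease <- theta_disease[[key]] %||% cfg$theta_disease
    if (tcfg$j_snps == 0L && tcfg$n_decoys == 0L) next
    per_target[[key]] <- simulate_target(tg, tcfg,
                                         seed = seed + 7919L * i,
                                         id_prefix = key)
  }

  empty_table <- function(trait) {
    summary_table(data.frame(snp_id = character(0), chrom = character(0),
                             pos = integer(0), effect_allele = character(0),
                             other_allele = character(0), eaf = numeric(0),
                             beta = numeric(0), se = numeric(0),
                             pval = numeric(0), n = numeric(0)),
                  trait_label = trait)
  }
  bind_tables <- function(keys, what, trait) {
    if (length(keys) == 0L) return(empty_table(trait))
    parts <- lapply(per_target[keys], function(x) as.data.frame(x[[what]]))
    summary_table(do.call(rbind, parts), trait_label = trait)
  }
  bind_ld <- function(keys) {
    mats <- lapply(per_target[keys], `[[`, "ld")
    n <- sum(vapply(mats, nrow, integer(1)))
    big <- diag(0, n)
    ids <- unlist(lapply(mats, rownames), use.names = FALSE)
    dimnames(big) <- list(ids, ids)
    at <- 0L
    for (m in mats) {
      idx <- at + seq_len(nrow(m))
      big[idx, idx] <- m
      at <- at + nrow(m)
    }
    big
  }

  keys <- names(per_target)
  trait_of <- sub("^.*\\.", "", keys)
  exposures <- list()
  ld <- list()
  for (tr in unique(trait_of)) {
    k <- keys[trait_of == tr]
    exposures[[tr]] <- bind_tables(k, "exposure", tr)
    ld[[tr]] <- bind_ld(k)
  }
  control <- bind_tables(keys, "control", "control")
  disease <- bind_tables(keys, "disease", "disease")

  config <- study_config(exposures = exposures, control_outcome = control,
                         disease_outcome = disease, targets = targets,
                         ld = ld, seed = seed)
  list(config = config, truth = lapply(per_target, `[[`, "truth"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
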