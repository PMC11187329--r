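#' Assemble a study configuration
#'
#' Bundles the inputs of the two-stage gated workflow: one exposure summary
#' table per lipid trait, a positive-control outcome table, the disease
#' outcome table, the target list, LD matrices, and the selection/analysis
#' thresholds.
#'
#' @param exposures named list of `summary_table`s keyed by lipid trait
#'   (`"LDL"`, `"TG"`); every target's trait must have an entry.
#' @param control_outcome,disease_outcome `summary_table`s.
#' @param targets `target_spec` data.frame.
#' @param ld a single r-squared matrix, or a named list of matrices keyed by
#'   lipid trait.
#' @param p_threshold,window_bp,r2_threshold,palindrome_eaf_window instrument
#'   selection parameters.
#' @param f_threshold weak-instrument threshold on the mean F (flagging
#'   only; weak sets are not excluded).
#' @param gate_alpha significance level of the positive-control gate.
#' @param seed seed used for stochastic diagnostics (MR-PRESSO).
#' @param presso_n_sim MR-PRESSO simulation count.
#' @return list of class `study_config`.
#' @export
study_config <- function(exposures, control_outcome, disease_outcome,
                         targets, ld, p_threshold = 5e-8,
                         window_bp = 100000L, r2_threshold = 0.001,
                         palindrome_eaf_window = 0.08, f_threshold = 10,
                         gate_alpha = 0.05, seed = 1L,
                         presso_n_sim = 1000L) {
  missing_traits <- setdiff(unique(targets$lipid_trait), names(exposures))
  if (length(missing_traits) > 0L) {
    stop("no exposure table for lipid trait(s): ",
         paste(missing_traits, collapse = ", "))
  }
  structure(list(exposures = exposures, control_outcome = control_outcome,
                 disease_outcome = disease_outcome, targets = targets,
                 ld = ld, p_threshold = p_threshold, window_bp = window_bp,
                 r2_threshold = r2_threshold,
                 palindrome_eaf_window = palindrome_eaf_window,
                 f_threshold = f_threshold, gate_alpha = gate_alpha,
                 seed = as.integer(seed),
                 presso_n_sim = as.integer(presso_n_sim)),
            class = "study_config")
}

ld_for_trait <- function(cfg, trait) {
  if (is.list(cfg$ld)) cfg$ld[[trait]] else cfg$ld
}

#' Run the gated two-stage analysis for one drug target
#'
#' Stage 1 builds the cis instrument set from the target's lipid exposure
#' and estimates its IVW effect on the positive-control outcome, with the
#' sensitivity battery. The target passes the gate when it has at least one
#' instrument and the control IVW p-value is below `gate_alpha`. Stage 2,
#' run only for gate-passing targets, rebuilds and re-harmonizes the
#' instruments against the disease outcome (so instrument counts may differ
#' between stages) and repeats estimation and sensitivity analysis.
#'
#' @param cfg a [study_config()].
#' @param target one-row `target_spec`.
#' @return list of class `target_report` with `target`, `control_set`,
#'   `control_mr`, `control_sensitivity`, `gate_passed`, and (when the gate
#'   passes) `disease_set`, `disease_mr`, `disease_sensitivity`.
#' @export
run_target <- function(cfg, target) {
  stopifnot(inherits(cfg, "study_config"), nrow(target) == 1L)
  exposure <- cfg$exposures[[target$lipid_trait]]
  if (is.null(exposure)) {
    stop("no exposure table for trait ", target$lipid_trait)
  }
  ld <- ld_for_trait(cfg, target$lipid_trait)
  build <- function(outcome) {
    build_instrument_set(exposure, outcome, target, ld,
                         window_bp = cfg$window_bp,
                         p_threshold = cfg$p_threshold,
                         r2_threshold = cfg$r2_threshold,
                         palindrome_eaf_window = cfg$palindrome_eaf_window)
  }
  control_set <- build(cfg$control_outcome)
  report <- list(target = target, control_set = control_set,
                 control_mr = NULL, control_sensitivity = NULL,
                 gate_passed = FALSE, disease_set = NULL,
                 disease_mr = NULL, disease_sensitivity = NULL)
  class(report) <- "target_report"
  if (control_set$n_snps == 0L) {
    return(report)
  }
  report$control_mr <- suppressWarnings(ivw(control_set$pairs))
  report$control_sensitivity <- sensitivity_report(
    control_set$pairs, n_sim = cfg$presso_n_sim, seed = cfg$seed)
  report$gate_passed <- report$control_mr$pval < cfg$gate_alpha
  if (!report$gate_passed) {
    return(report)
  }
  disease_set <- build(cfg$disease_outcome)
  report$disease_set <- disease_set
  if (disease_set$n_snps > 0L) {
    report$disease_mr <- suppressWarnings(ivw(disease_set$pairs))
    report$disease_sensitivity <- sensitivity_report(
      disease_set$pairs, n_sim = cfg$presso_n_sim, seed = cfg$seed)
  }
  report
}

#' Run the gated study over all targets
#'
#' Applies [run_target()] to every target in configuration order. A failure
#' in one target is caught, recorded on its report (`failed = TRUE` with the
#' message), and does not abort the remaining targets.
#'
#' @param cfg a [study_config()].
#' @return list of class `study_report`: one `target_report` per target,
#'   named `GENE.TRAIT`, in config order.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  reports <- list()
  for (i in seq_len(nrow(cfg$targets))) {
    target <- cfg$targets[i, , drop = FALSE]
    key <- paste0(target$gene_symbol, ".", target$lipid_trait)
    reports[[key]] <- tryCatch(run_target(cfg, target), error = function(e) {
      structure(list(target = target, failed = TRUE,
                     message = conditionMessage(e), gate_passed = FALSE),
                class = "target_report")
    })
  }
  class(reports) <- c("study_report", "list")
  reports
}

#' Format a p-value the way the result tables print it
#'
#' Three decimals, switching to scientific notation with two decimals and an
#' upper-case exponent marker (e.g. `1.18E-07`) below 0.001.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
format_pval <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, toupper(sprintf("%.2e", p)), sprintf("%.3f", p)))
}

fmt3 <- function(x) ifelse(is.na(x), "", sprintf("%.3f", x))

#' One rendered table row for an MR result
#'
#' @param target_label target name.
#' @param f_stat mean F of the instrument set (`NA` to leave blank).
#' @param result one-row `mr_result`, or `NULL` for a blank row.
#' @return one-row data.frame with the columns `Targets`, `F`, `SNP_n`,
#'   `Beta_95CI`, `Se`, `OR_95CI`, `p` (beta/OR to 3 decimals; p via
#'   [format_pval()]).
#' @export
render_row <- function(target_label, f_stat = NA_real_, result = NULL) {
  if (is.null(result)) {
    return(data.frame(Targets = target_label, F = "", SNP_n = "0",
                      Beta_95CI = "", Se = "", OR_95CI = "", p = "",
                      stringsAsFactors = FALSE))
  }
  data.frame(
    Targets = target_label,
    F = ifelse(is.na(f_stat), "", format(f_stat)),
    SNP_n = as.character(result$n_snps),
    Beta_95CI = sprintf("%s (%s, %s)", fmt3(result$beta),
                        fmt3(result$ci_low), fmt3(result$ci_high)),
    Se = fmt3(result$se),
    OR_95CI = sprintf("%s (%s, %s)", fmt3(result$or_value),
                      fmt3(result$or_ci_low), fmt3(result$or_ci_high)),
    p = format_pval(result$pval),
    stringsAsFactors = FALSE)
}

#' Render study reports as per-stage, per-trait result tables
#'
#' Writes one tab-separated table per lipid trait and stage (control and,
#' for gate-passing targets, disease), with the schema
#' `Targets F SNP_n Beta_95CI Se OR_95CI p`. Targets with zero instruments
#' appear as blank rows with `SNP_n = 0`.
#'
#' @param reports a `study_report`.
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @return named list of data.frames (also written as
#'   `<stage>_<trait>.tsv` when `out_dir` is given), invisibly when writing.
#' @export
render_tables <- function(reports, out_dir = NULL) {
  traits <- unique(vapply(reports, function(r) r$target$lipid_trait,
                          character(1)))
  out <- list()
  for (tr in traits) {
    sel <- Filter(function(r) r$target$lipid_trait == tr, reports)
    ctrl <- do.call(rbind, lapply(sel, function(r) {
      render_row(r$target$gene_symbol,
                 f_stat = if (is.null(r$control_set)) NA_real_ else
                   r$control_set$mean_f,
                 result = r$control_mr)
    }))
    dis_sel <- Filter(function(r) isTRUE(r$gate_passed), sel)
    dis <- if (length(dis_sel) > 0L) {
      do.call(rbind, lapply(dis_sel, function(r) {
        render_row(r$target$gene_symbol,
                   f_stat = NA_real_, result = r$disease_mr)
      }))
    } else {
      render_row("placeholder")[0, , drop = FALSE]
    }
    rownames(ctrl) <- rownames(dis) <- NULL
    out[[paste0("control_", tr)]] <- ctrl
    out[[paste0("disease_", tr)]] <- dis
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      utils::write.table(out[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(invisible(out))
  }
  out
}

#' Gate decisions of a study report
#'
#' @param reports a `study_report`.
#' @return data.frame with `target`, `lipid_trait`, `n_snps`, `control_p`,
#'   `gate_passed`.
#' @export
gate_summary <- function(reports) {
  do.call(rbind, lapply(unname(reports), function(r) {
    data.frame(target = r$target$gene_symbol,
               lipid_trait = r$target$lipid_trait,
               n_snps = if (is.null(r$control_set)) 0L else
                 r$control_set$n_snps,
               control_p = if (is.null(r$control_mr)) NA_real_ else
                 r$control_mr$pval,
               gate_passed = isTRUE(r$gate_passed),
               stringsAsFactors = FALSE)
  }))
}
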