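#' Construct a drug-target specification
#'
#' A target is the gene encoding a lipid-lowering drug's protein target,
#' with its genomic region (1-based inclusive), the lipid trait whose
#' GWAS provides the exposure (LDL cholesterol or triglycerides), and the
#' drug class it proxies.
#'
#' @param gene_symbol gene symbol, e.g. `"PCSK9"`.
#' @param chrom chromosome label (no "chr" prefix required).
#' @param gene_start,gene_end gene body, 1-based inclusive, start <= end.
#' @param lipid_trait `"LDL"` or `"TG"`.
#' @param drug_label drug-class annotation, e.g. `"statins"`.
#' @return one-row data.frame of class `target_spec`.
#' @export
target_spec <- function(gene_symbol, chrom, gene_start, gene_end,
                        lipid_trait = c("LDL", "TG"), drug_label = NA_character_) {
  lipid_trait <- match.arg(lipid_trait)
  gene_start <- as.integer(gene_start)
  gene_end <- as.integer(gene_end)
  if (is.na(gene_start) || is.na(gene_end) || gene_start > gene_end) {
    stop("gene_start must be <= gene_end")
  }
  structure(
    data.frame(gene_symbol = as.character(gene_symbol),
               chrom = as.character(chrom),
               gene_start = gene_start, gene_end = gene_end,
               lipid_trait = lipid_trait,
               drug_label = as.character(drug_label),
               stringsAsFactors = FALSE),
    class = c("target_spec", "data.frame"))
}

#' Lipid-lowering drug targets shipped with the package
#'
#' The nine genes encoding targets of LDL-lowering drugs (statins ->
#' HMGCR, alirocumab -> PCSK9, ezetimibe -> NPC1L1, mipomersen -> APOB,
#' evinacumab -> ANGPTL3, fenofibrate -> PPARA, plus LDLR and LPL) and of
#' triglyceride-lowering drugs (evinacumab, fenofibrate, volanesorsen ->
#' APOC3, LDLR, LPL), one row per gene x lipid trait, with GRCh37 gene-body
#' coordinates.
#'
#' @param lipid_trait optional filter, `"LDL"` or `"TG"`.
#' @return data.frame with one `target_spec` row per target.
#' @export
lipid_targets <- function(lipid_trait = NULL) {
  path <- system.file("extdata", "lipid_targets.tsv", package = "lipidmr",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  if (!is.null(lipid_trait)) {
    df <- df[df$lipid_trait == lipid_trait, , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("target_spec", "data.frame")
  df
}

#' Published per-target MR results used as reference inputs
#'
#' The per-target IVW summaries (mean F, SNP count, beta with 95% CI,
#' standard error, odds ratio with 95% CI, p-value) reported for the
#' positive-control (coronary heart disease) and disease (acne vulgaris)
#' stages, by lipid trait. The `p` column is kept as printed (including
#' `"<0.001"` and scientific notation); `p_num` carries a numeric reading
#' with `"<0.001"` read as its upper bound 0.001.
#'
#' @param stage optional filter, `"control"` or `"disease"`.
#' @return data.frame of reported rows.
#' @export
reported_mr_results <- function(stage = NULL) {
  path <- system.file("extdata", "reported_mr_results.tsv",
                      package = "lipidmr", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$p_num <- vapply(df$p, function(p) {
    if (is.na(p)) return(NA_real_)
    if (grepl("^<", p)) return(as.numeric(sub("^<", "", p)))
    as.numeric(p)
  }, numeric(1), USE.NAMES = FALSE)
  if (!is.null(stage)) {
    df <- df[df$stage == stage, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Cis window of a target
#'
#' @param target one-row `target_spec`.
#' @param window_bp flank added to each side of the gene body.
#' @return integer vector `c(start, end)`, 1-based inclusive, floored at 1.
#' @export
cis_window <- function(target, window_bp = 100000L) {
  stopifnot(nrow(target) == 1L, window_bp >= 0)
  c(max(1L, target$gene_start - as.integer(window_bp)),
    target$gene_end + as.integer(window_bp))
}

#' Export cis windows of a target set as BED
#'
#' BED uses 0-based half-open coordinates; the 1-based inclusive windows
#' are converted accordingly.
#'
#' @param targets `target_spec` data.frame (any number of rows).
#' @param path output file path.
#' @param window_bp flank size in bp.
#' @return `path`, invisibly.
#' @export
write_cis_bed <- function(targets, path, window_bp = 100000L) {
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    w <- cis_window(targets[i, , drop = FALSE], window_bp)
    data.frame(chrom = targets$chrom[i], start = w[1] - 1L, end = w[2],
               name = paste0(targets$gene_symbol[i], "_",
                             targets$lipid_trait[i]))
  })
  bed <- do.call(rbind, rows)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
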