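#' @keywords internal
"_PACKAGE"

# Canonical column order for a summary-statistics table.
SUMMARY_COLUMNS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                     "eaf", "beta", "se", "pval", "n")

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a validated GWAS summary-statistics table
#'
#' A summary table holds one row per SNP with the per-allele association
#' summary for a single trait: identifier, genomic location (1-based),
#' effect/other allele, effect-allele frequency, beta (log-odds for binary
#' traits, SD units for quantitative lipids), standard error, p-value and
#' sample size. Rows violating the invariants (non-positive `se`, `pval`
#' outside (0, 1], identical or non-ACGT alleles, `eaf` outside [0, 1],
#' `pos < 1`, duplicated `snp_id`) are dropped with a warning that reports
#' per-reason counts; row order is otherwise preserved.
#'
#' @param df data.frame containing at least the canonical columns
#'   `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`,
#'   `se`, `pval`; `eaf` and `n` are optional and filled with `NA`.
#' @param trait_label optional label naming the trait (e.g. `"LDL"`).
#' @return A `summary_table`: a data.frame in canonical column order with
#'   attribute `trait_label`.
#' @export
summary_table <- function(df, trait_label = NULL) {
  required <- setdiff(SUMMARY_COLUMNS, c("eaf", "n"))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  if (!"n" %in% names(df)) df$n <- NA_real_
  df <- df[, SUMMARY_COLUMNS, drop = FALSE]

  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- as.numeric(df[[col]])
  }

  reasons <- character(0)
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    if (any(cond)) reasons <<- c(reasons, sprintf("%d row(s) %s", sum(cond), why))
    cond
  }
  drop <- bad(!(df$effect_allele %in% VALID_ALLELES) |
              !(df$other_allele %in% VALID_ALLELES), "with non-SNV alleles")
  drop <- drop | bad(df$effect_allele == df$other_allele, "with identical alleles")
  drop <- drop | bad(!is.finite(df$se) | df$se <= 0, "with se <= 0")
  drop <- drop | bad(!is.finite(df$beta), "with non-numeric beta")
  drop <- drop | bad(!is.finite(df$pval) | df$pval <= 0 | df$pval > 1,
                     "with pval outside (0, 1]")
  drop <- drop | bad(!is.finite(df$pos) | df$pos < 1L, "with pos < 1")
  eaf_bad <- !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)
  if (any(eaf_bad)) reasons <- c(reasons, sprintf("%d row(s) with eaf outside [0, 1]", sum(eaf_bad)))
  drop <- drop | eaf_bad
  n_bad <- !is.na(df$n) & df$n <= 0
  if (any(n_bad)) reasons <- c(reasons, sprintf("%d row(s) with n <= 0", sum(n_bad)))
  drop <- drop | n_bad
  dup <- duplicated(df$snp_id) & !drop
  if (any(dup)) reasons <- c(reasons, sprintf("%d row(s) with duplicated snp_id", sum(dup)))
  drop <- drop | dup

  if (any(drop)) {
    warning("dropped ", sum(drop), " invalid row(s): ",
            paste(reasons, collapse = "; "), call. = FALSE)
    df <- df[!drop, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, trait_label = trait_label,
            class = c("summary_table", "data.frame"))
}

#' Read a GWAS summary-statistics table from tab-separated text
#'
#' Reads a tab-delimited file with a header line and validates it with
#' [summary_table()]. Non-canonical column names can be mapped with
#' `column_map`, allowing GWAS-catalog-style exports to be read directly.
#'
#' @param path path to a tab-separated file with header.
#' @param column_map optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(snp_id = "rsid", pval = "p")`.
#' @param trait_label optional trait label stored on the result.
#' @return A `summary_table`.
#' @export
read_summary_tsv <- function(path, column_map = NULL, trait_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(df))
    if (length(missing_src) > 0L) {
      stop("column_map refers to absent column(s): ",
           paste(missing_src, collapse = ", "))
    }
    for (canon in names(column_map)) {
      names(df)[names(df) == column_map[[canon]]] <- canon
    }
  }
  summary_table(df, trait_label = trait_label)
}

#' Write a summary table as tab-separated text
#'
#' Numeric columns are written with 17 significant digits so that a
#' write/read round trip reproduces the values exactly.
#'
#' @param table a `summary_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(table, path) {
  stopifnot(inherits(table, "summary_table"))
  out <- as.data.frame(table)
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         sprintf("%.17g", out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read or write a square LD (r-squared) matrix as tab-separated text
#'
#' The format is a square numeric matrix with SNP identifiers as both row
#' and column labels. On read, symmetry and a unit diagonal are checked.
#'
#' @param path file path.
#' @return `read_ld_tsv`: a named numeric matrix.
#' @export
read_ld_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("LD matrix must be square with matching row/column labels")
  }
  if (max(abs(m - t(m))) > 1e-8 || max(abs(diag(m) - 1)) > 1e-8) {
    stop("LD matrix must be symmetric with unit diagonal")
  }
  m
}

#' @param ld square r-squared matrix with SNP-id dimnames.
#' @rdname read_ld_tsv
#' @export
write_ld_tsv <- function(ld, path) {
  out <- data.frame(snp_id = rownames(ld), ld, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

complement_allele <- function(a) {
  c(A = "T", T = "A", C = "G", G = "C")[a]
}

#' Harmonize exposure and outcome summary statistics to one effect allele
#'
#' Joins the two tables on `snp_id` and aligns each shared SNP so that the
#' outcome beta refers to the exposure's effect allele:
#' \itemize{
#'   \item same orientation (directly or after strand complement): kept;
#'   \item swapped alleles: outcome beta negated and eaf complemented
#'     (`flipped`);
#'   \item strand-ambiguous palindromic SNPs (A/T, C/G) with exposure eaf in
#'     `[0.5 - w, 0.5 + w]` (or missing eaf): `dropped_palindromic`;
#'     palindromic SNPs outside the window are aligned by comparing which
#'     side of 0.5 the two eafs fall on;
#'   \item allele sets irreconcilable even after strand complement:
#'     `dropped_mismatch`.
#' }
#' SNPs absent from either table are omitted; no LD-proxy lookup is done.
#'
#' @param exposure,outcome `summary_table` objects.
#' @param palindrome_eaf_window half-width `w` of the ambiguous-frequency
#'   window around 0.5 within which palindromic SNPs are dropped.
#' @return data.frame of harmonized pairs with columns `snp_id`,
#'   `beta_exposure`, `se_exposure`, `eaf_exposure`, `beta_outcome`,
#'   `se_outcome`, `action`; `action` is one of `kept`, `flipped`,
#'   `dropped_palindromic`, `dropped_mismatch`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  stopifnot(inherits(exposure, "summary_table"),
            inherits(outcome, "summary_table"))
  w <- palindrome_eaf_window
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  ex <- exposure[match(shared, exposure$snp_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp_id), , drop = FALSE]

  n <- length(shared)
  action <- character(n)
  beta_out <- ou$beta

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  for (i in seq_len(n)) {
    e1 <- ex$effect_allele[i]; e2 <- ex$other_allele[i]
    o1 <- ou$effect_allele[i]; o2 <- ou$other_allele[i]
    if (pal[i]) {
      # allele labels cannot resolve strand for palindromes; use frequency
      if (!(o1 %in% c(e1, e2)) || !(o2 %in% c(e1, e2))) {
        action[i] <- "dropped_mismatch"
        next
      }
      ef <- ex$eaf[i]; of <- ou$eaf[i]
      if (is.na(ef) || abs(ef - 0.5) <= w) {
        action[i] <- "dropped_palindromic"
      } else if (is.na(of)) {
        action[i] <- "dropped_palindromic"
      } else if ((ef > 0.5) == (of > 0.5)) {
        action[i] <- "kept"
      } else {
        action[i] <- "flipped"
        beta_out[i] <- -beta_out[i]
      }
      next
    }
    if (o1 == e1 && o2 == e2) {
      action[i] <- "kept"
    } else if (o1 == e2 && o2 == e1) {
      action[i] <- "flipped"
      beta_out[i] <- -beta_out[i]
    } else {
      c1 <- complement_allele(o1); c2 <- complement_allele(o2)
      if (c1 == e1 && c2 == e2) {
        action[i] <- "kept"
      } else if (c1 == e2 && c2 == e1) {
        action[i] <- "flipped"
        beta_out[i] <- -beta_out[i]
      } else {
        action[i] <- "dropped_mismatch"
      }
    }
  }

  data.frame(snp_id = shared,
             beta_exposure = ex$beta,
             se_exposure = ex$se,
             eaf_exposure = ex$eaf,
             beta_outcome = beta_out,
             se_outcome = ou$se,
             action = action,
             stringsAsFactors = FALSE)
}

#' Restrict harmonized pairs to those usable as instruments
#'
#' @param pairs output of [harmonize()].
#' @return the `kept`/`flipped` rows.
#' @export
kept_pairs <- function(pairs) {
  pairs[pairs$action %in% c("kept", "flipped"), , drop = FALSE]
}
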