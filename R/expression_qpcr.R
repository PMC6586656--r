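#' Differential-expression filter configuration
#'
#' The default thresholds are the study-standard candidate criteria:
#' absolute log2 fold change strictly greater than 1 (that is, a fold change
#' above 2), adjusted p-value strictly below 0.001, and mean abundance
#' strictly above 200 transcripts per million (TPM).
#'
#' @param lfc_min Minimum absolute log2 fold change (exclusive).
#' @param padj_max Maximum adjusted p-value (exclusive).
#' @param tpm_min Minimum mean TPM across conditions (exclusive).
#' @return A `filter_config` list.
#' @export
filter_config <- function(lfc_min = 1, padj_max = 0.001, tpm_min = 200) {
  stopifnot(lfc_min > 0, padj_max > 0, tpm_min > 0)
  structure(list(lfc_min = lfc_min, padj_max = padj_max,
                 tpm_min = tpm_min),
            class = "filter_config")
}

#' Read a differential-expression results table
#'
#' Expects a TSV with header columns `transcript_id`, optionally
#' `annotation`, one or more `tpm_<condition>` columns, `log2fc`,
#' `pvalue`, `padj`.
#'
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_de_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Flag differential-expression candidates
#'
#' Applies the candidate filter row-wise: `de_significant` when
#' `|log2fc| > lfc_min` and `padj < padj_max` (strict inequalities; a
#' missing `padj` is never significant and is warned about);
#' `abundant` when the mean of the per-condition TPM columns exceeds
#' `tpm_min`; `candidate` when both hold. Malformed rows are flagged
#' `FALSE` and reported in the `row_errors` attribute; the remaining rows
#' proceed.
#'
#' @param records Data frame with `log2fc`, `padj` and one or more TPM
#'   columns.
#' @param cfg A [filter_config()].
#' @param tpm_cols Names of the per-condition TPM columns; by default all
#'   columns starting with `tpm_`.
#' @return `records` with logical columns `de_significant`, `abundant`,
#'   `candidate` appended; attribute `row_errors` (data frame of row and
#'   message, possibly empty).
#' @export
filter_de <- function(records, cfg = filter_config(), tpm_cols = NULL) {
  stopifnot(is.data.frame(records), is(cfg, "filter_config"))
  if (is.null(tpm_cols)) tpm_cols <- grep("^tpm_", names(records), value = TRUE)
  if (!length(tpm_cols)) stop("no TPM columns found", call. = FALSE)
  needed <- c("log2fc", "padj", tpm_cols)
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(records)
  errors <- data.frame(row = integer(), message = character(),
                       stringsAsFactors = FALSE)
  lfc <- suppressWarnings(as.numeric(records$log2fc))
  padj <- suppressWarnings(as.numeric(records$padj))
  tpm <- as.matrix(records[, tpm_cols, drop = FALSE])
  suppressWarnings(storage.mode(tpm) <- "numeric")
  bad <- is.na(lfc) | apply(tpm, 1L, function(x) any(is.na(x) | x < 0))
  if (any(bad)) {
    errors <- data.frame(row = which(bad),
                         message = "non-numeric or negative field",
                         stringsAsFactors = FALSE)
  }
  mean_tpm <- rowMeans(tpm)
  de_sig <- !is.na(lfc) & !is.na(padj) &
    abs(lfc) > cfg$lfc_min & padj < cfg$padj_max
  abundant <- !is.na(mean_tpm) & mean_tpm > cfg$tpm_min
  de_sig[bad] <- FALSE
  abundant[bad] <- FALSE
  n_missing_padj <- sum(is.na(padj) & !bad)
  if (n_missing_padj > 0L) {
    warning(n_missing_padj,
            " row(s) with missing padj treated as not significant",
            call. = FALSE)
  }
  records$de_significant <- de_sig
  records$abundant <- abundant
  records$candidate <- de_sig & abundant
  attr(records, "row_errors") <- errors
  records
}

#' Read a qPCR Cq table
#'
#' Expects a CSV with columns `sample_id`, `group` (`control` or
#' `heat_shock`), `gene`, `cq`, `minus_rt_cq`; undetected reactions are
#' empty fields or `NA`.
#'
#' @param path Path to the CSV file.
#' @return A data frame.
#' @export
read_cq_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Quality-control qPCR samples on the reference gene
#'
#' A sample is discarded when its reference-gene quantification cycle is
#' above the cutoff or undetected (below detection), when the
#' reference-gene minus-RT control is below the cutoff (genomic DNA
#' contamination), or when it lacks a reference-gene measurement
#' altogether.
#'
#' @param measurements Data frame with `sample_id`, `group`, `gene`, `cq`,
#'   `minus_rt_cq`.
#' @param cq_cutoff Detection/contamination cutoff (default 30 cycles).
#' @param ref_gene Name of the reference gene (default `"gapdh"`).
#' @return List with `kept` (measurements of surviving samples) and
#'   `discarded` (data frame `sample_id`, `reason`).
#' @export
qc_cq <- function(measurements, cq_cutoff = 30, ref_gene = "gapdh") {
  stopifnot(is.data.frame(measurements))
  samples <- unique(measurements$sample_id)
  reasons <- character(0)
  bad_samples <- character(0)
  for (s in samples) {
    rows <- measurements[measurements$sample_id == s &
                           measurements$gene == ref_gene, , drop = FALSE]
    if (nrow(rows) == 0L) {
      bad_samples <- c(bad_samples, s)
      reasons <- c(reasons, "missing_reference")
    } else if (is.na(rows$cq[1L]) || rows$cq[1L] > cq_cutoff) {
      bad_samples <- c(bad_samples, s)
      reasons <- c(reasons, "below_detection")
    } else if (!is.na(rows$minus_rt_cq[1L]) &&
               rows$minus_rt_cq[1L] < cq_cutoff) {
      bad_samples <- c(bad_samples, s)
      reasons <- c(reasons, "contaminated")
    }
  }
  list(kept = measurements[!measurements$sample_id %in% bad_samples, ,
                           drop = FALSE],
       discarded = data.frame(sample_id = bad_samples, reason = reasons,
                              stringsAsFactors = FALSE))
}

#' Per-sample delta-Cq values
#'
#' Delta-Cq is the target gene's quantification cycle minus the reference
#' gene's, per sample (lower delta-Cq means higher relative expression).
#' Samples whose target reaction is undetected are flagged `censored`:
#' they are excluded from testing but counted in the detection report.
#'
#' @inheritParams qc_cq
#' @return Data frame `sample_id`, `group`, `gene`, `delta_cq`,
#'   `censored`, one row per sample and target gene.
#' @export
delta_cq <- function(measurements, ref_gene = "gapdh") {
  stopifnot(is.data.frame(measurements))
  refs <- measurements[measurements$gene == ref_gene, , drop = FALSE]
  targets <- measurements[measurements$gene != ref_gene, , drop = FALSE]
  ref_cq <- setNames(refs$cq, refs$sample_id)
  missing_ref <- setdiff(unique(targets$sample_id), refs$sample_id)
  if (length(missing_ref)) {
    stop("no reference-gene measurement for sample(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  data.frame(sample_id = targets$sample_id, group = targets$group,
             gene = targets$gene,
             delta_cq = targets$cq - ref_cq[targets$sample_id],
             censored = is.na(targets$cq),
             row.names = NULL, stringsAsFactors = FALSE)
}

rank_sum_u <- function(a, b) {
  r <- rank(c(a, b))  # midranks for ties
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Exact Wilcoxon-Mann-Whitney test
#'
#' The U statistic is computed for the first group with midranks for
#' ties. For combined sample sizes up to `exact_max_n`, the two-sided
#' p-value is exact: all `choose(n+m, n)` group labelings are enumerated
#' and the p-value is the probability of a U at least as far from its
#' null mean `nm/2` as observed (deviation-based two-sided rule, not
#' doubling of one tail). For larger samples a normal approximation with
#' tie correction and continuity correction is used. The method actually
#' applied is reported.
#'
#' @param group_a,group_b Numeric vectors, each non-empty.
#' @param exact_max_n Largest combined size for exact enumeration
#'   (default 12).
#' @return An `mw_test` list: `U`, `p_value`, `method` (`"exact"` or
#'   `"normal_approx"`), `n_a`, `n_b`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
mann_whitney <- function(group_a, group_b, exact_max_n = 12L) {
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n <- length(group_a); m <- length(group_b)
  u_obs <- rank_sum_u(group_a, group_b)
  dev_obs <- abs(u_obs - n * m / 2)
  if (n + m <= exact_max_n) {
    pooled <- c(group_a, group_b)
    r <- rank(pooled)
    labelings <- combn(n + m, n)
    u_all <- colSums(matrix(r[labelings], nrow = n)) - n * (n + 1) / 2
    p <- mean(abs(u_all - n * m / 2) >= dev_obs - 1e-9)
    method <- "exact"
  } else {
    N <- n + m
    ties <- table(c(group_a, group_b))
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      # continuity-corrected z for the deviation-based two-sided rule
      z <- max(0, dev_obs - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal_approx"
  }
  structure(list(U = u_obs, p_value = p, method = method, n_a = n, n_b = m),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Wilcoxon-Mann-Whitney (%s): U = %g, n = %d/%d, p = %.4g\n",
              x$method, x$U, x$n_a, x$n_b, x$p_value))
  invisible(x)
}

#' Holm step-down adjustment
#'
#' Thin, validating wrapper around [stats::p.adjust()] with
#' `method = "holm"`: the i-th smallest p-value is multiplied by
#' `m - i + 1`, monotonicity is enforced, results are capped at 1 and
#' returned in input order.
#'
#' @param ps Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @examples
#' holm_adjust(c(0.01, 0.04))  # 0.02 0.04
#' @export
holm_adjust <- function(ps) {
  if (any(is.na(ps)) || any(ps < 0 | ps > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(ps, method = "holm")
}

#' Full qPCR delta-Cq analysis
#'
#' Pipeline: reference-gene quality control ([qc_cq()]), per-sample
#' delta-Cq ([delta_cq()]), a control vs heat-shock Wilcoxon-Mann-Whitney
#' test per target gene (censored samples excluded from testing, counted
#' in the report), and Holm correction across the target genes (the
#' multiple-testing family is the set of primer pairs / target genes
#' tested per run).
#'
#' @inheritParams qc_cq
#' @return A `delta_cq_result`: `samples` (per-sample delta-Cq data
#'   frame), `tests` (per-gene data frame with group sizes, censored
#'   counts, `U`, `p_value`, `p_holm`, `method`), `discarded` (QC
#'   failures).
#' @export
qpcr_analysis <- function(measurements, cq_cutoff = 30, ref_gene = "gapdh") {
  qc <- qc_cq(measurements, cq_cutoff = cq_cutoff, ref_gene = ref_gene)
  dcq <- delta_cq(qc$kept, ref_gene = ref_gene)
  genes <- unique(dcq$gene)
  tests <- lapply(genes, function(g) {
    rows <- dcq[dcq$gene == g & !dcq$censored, , drop = FALSE]
    a <- rows$delta_cq[rows$group == "control"]
    b <- rows$delta_cq[rows$group == "heat_shock"]
    n_cens <- sum(dcq$gene == g & dcq$censored)
    if (!length(a) || !length(b)) {
      return(data.frame(gene = g, n_control = length(a),
                        n_heat_shock = length(b), n_censored = n_cens,
                        U = NA_real_, p_value = NA_real_,
                        method = NA_character_, stringsAsFactors = FALSE))
    }
    mw <- mann_whitney(a, b)
    data.frame(gene = g, n_control = length(a), n_heat_shock = length(b),
               n_censored = n_cens, U = mw$U, p_value = mw$p_value,
               method = mw$method, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests)
  tests$p_holm <- NA_real_
  tested <- !is.na(tests$p_value)
  if (any(tested)) tests$p_holm[tested] <- holm_adjust(tests$p_value[tested])
  structure(list(samples = dcq, tests = tests, discarded = qc$discarded),
            class = "delta_cq_result")
}

#' @export
print.delta_cq_result <- function(x, ...) {
  cat("<delta_cq_result>\n")
  if (nrow(x$discarded)) {
    cat("  discarded samples:",
        paste0(x$discarded$sample_id, " (", x$discarded$reason, ")",
               collapse = ", "), "\n")
  }
  print(x$tests, row.names = FALSE)
  invisible(x)
}
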