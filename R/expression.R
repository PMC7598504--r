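#' Log2 fold change between two FPKM values
#'
#' Fold-change direction is low-Mg over high-Mg — `log2(fpkm_low_mg /
#' fpkm_high_mg)` — so a gene induced at 0.8 mM Mg2+ gets a positive value.
#' Both inputs must be positive unless a pseudocount is supplied, in which
#' case it is added to both before taking the ratio.
#'
#' @param fpkm_high_mg Expression (FPKM) in the 10 mM Mg2+ condition.
#' @param fpkm_low_mg Expression (FPKM) in the 0.8 mM Mg2+ condition.
#' @param pseudocount Optional nonnegative constant added to both values;
#'   default none (zero FPKM is then an error).
#' @return The log2 fold change (vectorized).
#' @examples
#' log2_fold_change(5296, 454)  # -3.54
#' log2_fold_change(377, 674)   #  0.84
#' @export
log2_fold_change <- function(fpkm_high_mg, fpkm_low_mg, pseudocount = NULL) {
  if (any(fpkm_high_mg < 0) || any(fpkm_low_mg < 0)) {
    stop_tq("topoquant_invalid_parameter", "FPKM values must be nonnegative")
  }
  if (is.null(pseudocount)) {
    if (any(fpkm_high_mg == 0) || any(fpkm_low_mg == 0)) {
      stop_tq("topoquant_undefined_fold_change_error",
              "zero FPKM: fold change undefined without a pseudocount")
    }
    pc <- 0
  } else {
    if (!is_num1(pseudocount) || pseudocount < 0) {
      stop_tq("topoquant_invalid_parameter", "pseudocount must be >= 0")
    }
    pc <- pseudocount
  }
  log2((fpkm_low_mg + pc) / (fpkm_high_mg + pc))
}

#' Read a per-gene expression table
#'
#' Expects a TSV with columns `pathway`, `gene`, `fpkm_10mM`, `fpkm_0.8mM`,
#' `q`, and optionally `printed_log2fc` (the fold-change column as printed in
#' the source table, for cross-checks). q-value cells of the form `"<x"` are
#' parsed as an upper bound `x` with `q_is_upper_bound` set; threshold
#' comparisons then use the bound. Fold changes are recomputed from the FPKM
#' columns at full precision.
#'
#' The table distributed with the package
#' (`system.file("extdata", "table1_expression.tsv", package = "topoquant")`)
#' transcribes a published RNA-seq comparison of *S.* Typhimurium grown in
#' 10 mM versus 0.8 mM Mg2+: 32 genes in 6 pathway groups covering putrescine
#' biosynthesis, import, export, degradation, arginine biosynthesis, and the
#' DNA topoisomerases.
#'
#' @param path Path to the TSV.
#' @return A data.frame: `gene`, `pathway`, `fpkm_high_mg`, `fpkm_low_mg`,
#'   `log2_fc` (recomputed), `printed_log2fc` (if present), `q_value`,
#'   `q_is_upper_bound`. Zero rows (with a warning) for an empty file.
#' @export
read_expression_table <- function(path) {
  empty <- data.frame(gene = character(), pathway = character(),
                      fpkm_high_mg = numeric(), fpkm_low_mg = numeric(),
                      log2_fc = numeric(), q_value = numeric(),
                      q_is_upper_bound = logical())
  if (!file.exists(path)) stop_tq("topoquant_parse_error", sprintf("no such file: %s", path))
  if (file.size(path) == 0L) {
    warn_tq("topoquant_empty_input_warning", "expression table is empty")
    return(empty)
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(d) == 0L) {
    warn_tq("topoquant_empty_input_warning", "expression table has no rows")
    return(empty)
  }
  need <- c("pathway", "gene", "fpkm_10mM", "fpkm_0.8mM", "q")
  if (!all(need %in% names(d))) {
    stop_tq("topoquant_parse_error",
            sprintf("expression table must have columns: %s", paste(need, collapse = ", ")))
  }
  parse_num <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad)) {
      stop_tq("topoquant_parse_error",
              sprintf("malformed numeric in column '%s', row %d ('%s')",
                      col, bad[1], x[bad[1]]))
    }
    v
  }
  hi <- parse_num(d$fpkm_10mM, "fpkm_10mM")
  lo <- parse_num(d$`fpkm_0.8mM`, "fpkm_0.8mM")
  qraw <- trimws(d$q)
  is_ub <- startsWith(qraw, "<")
  qval <- parse_num(sub("^<", "", qraw), "q")
  if (any(qval < 0 | qval > 1)) {
    stop_tq("topoquant_parse_error", "q values must lie in [0, 1]")
  }
  dup <- duplicated(paste(d$pathway, d$gene, sep = "\r"))
  if (any(dup)) {
    stop_tq("topoquant_duplicate_record_error",
            sprintf("duplicate gene '%s' within pathway '%s'",
                    d$gene[dup][1], d$pathway[dup][1]))
  }
  out <- data.frame(gene = d$gene, pathway = d$pathway,
                    fpkm_high_mg = hi, fpkm_low_mg = lo,
                    log2_fc = log2_fold_change(hi, lo),
                    q_value = qval, q_is_upper_bound = is_ub,
                    stringsAsFactors = FALSE)
  if ("printed_log2fc" %in% names(d)) {
    out$printed_log2fc <- parse_num(d$printed_log2fc, "printed_log2fc")
  }
  out
}

#' Flag differentially expressed genes
#'
#' A gene is differential iff its q-value (or its upper bound, for `"<x"`
#' entries) is strictly below the threshold. q-values come from the upstream
#' differential-expression engine and are never recomputed here.
#'
#' @param records Data.frame from [read_expression_table()].
#' @param q_threshold FDR threshold (default 0.05).
#' @return `records` with a logical `differential` column.
#' @export
flag_differential <- function(records, q_threshold = 0.05) {
  if (!is_num1(q_threshold) || q_threshold <= 0 || q_threshold > 1) {
    stop_tq("topoquant_invalid_parameter", "q_threshold must be in (0, 1]")
  }
  records$differential <- records$q_value < q_threshold
  records
}

#' Summarize expression direction per pathway
#'
#' Counts, for each pathway group, the genes, the differential genes, and the
#' split by fold-change direction: up in low Mg2+ (`log2_fc > 0`) versus up
#' in high Mg2+ (`log2_fc < 0`).
#'
#' @param records Flagged records from [flag_differential()].
#' @return A data.frame `pathway`, `n_genes`, `n_differential`,
#'   `n_up_low_mg`, `n_up_high_mg`; zero rows for empty input.
#' @export
summarize_pathways <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(pathway = character(), n_genes = integer(),
                      n_differential = integer(), n_up_low_mg = integer(),
                      n_up_high_mg = integer()))
  }
  if (is.null(records$differential)) {
    stop_tq("topoquant_invalid_parameter", "records must be flagged first (flag_differential)")
  }
  parts <- split(records, factor(records$pathway, levels = unique(records$pathway)))
  do.call(rbind, lapply(parts, function(p) {
    data.frame(pathway = p$pathway[1], n_genes = nrow(p),
               n_differential = sum(p$differential),
               n_up_low_mg = sum(p$log2_fc > 0),
               n_up_high_mg = sum(p$log2_fc < 0),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
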