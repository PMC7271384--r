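#' MA-plot preparation of an FPKM table
#'
#' Adds the pseudocount to the treated sample, discards low-abundance
#' genes, and computes the MA coordinates: `M = log2(treat' / ctrl)`
#' (log2 fold change) and `A` (mean abundance). By default the
#' low-abundance discard (`< discard_min`) is applied to both samples
#' (raw control, pseudocounted treated), which also guarantees the log
#' ratio is defined; `discard_scope = "treated"` restricts it to the
#' treated sample.
#'
#' @param records Data.frame with columns `fpkm_ctrl` and `fpkm_treat`
#'   (non-negative) and optionally `id` and `p_value`.
#' @param pseudocount Value added to the treated FPKM before anything
#'   else (default 0.001).
#' @param discard_min Records with FPKM below this (see `discard_scope`)
#'   are discarded (default 0.01).
#' @param discard_scope `"both"` (default) or `"treated"`.
#' @param a_mode `"arithmetic"` (default): `A = (ctrl + treat') / 2`;
#'   `"geometric"`: `A = sqrt(ctrl * treat')`.
#' @return The input data.frame with added columns `M`, `A` and
#'   `discarded`; `M` and `A` are `NA` for discarded records.
#' @examples
#' ma_transform(data.frame(fpkm_ctrl = 1, fpkm_treat = 3.999))  # M = 2
#' @export
ma_transform <- function(records,
                         pseudocount = 0.001,
                         discard_min = 0.01,
                         discard_scope = c("both", "treated"),
                         a_mode = c("arithmetic", "geometric")) {
  discard_scope <- match.arg(discard_scope)
  a_mode <- match.arg(a_mode)
  stopifnot(is.data.frame(records),
            all(c("fpkm_ctrl", "fpkm_treat") %in% names(records)))
  if (any(records$fpkm_ctrl < 0) || any(records$fpkm_treat < 0)) {
    stop("FPKM values must be non-negative")
  }
  treat_adj <- records$fpkm_treat + pseudocount
  discarded <- if (discard_scope == "both") {
    records$fpkm_ctrl < discard_min | treat_adj < discard_min
  } else {
    treat_adj < discard_min
  }
  M <- ifelse(discarded, NA_real_, log2(treat_adj / records$fpkm_ctrl))
  A <- if (a_mode == "arithmetic") {
    ifelse(discarded, NA_real_, (records$fpkm_ctrl + treat_adj) / 2)
  } else {
    ifelse(discarded, NA_real_, sqrt(records$fpkm_ctrl * treat_adj))
  }
  records$M <- M
  records$A <- A
  records$discarded <- discarded
  records
}

#' Select differentially expressed genes by fold change and significance
#'
#' Flags as DEG hits the non-discarded records whose log2 fold change
#' strictly exceeds `log2(min_fold)` ("more than a `min_fold`-fold
#' increase") and whose p-value is strictly below `alpha`. Boundary
#' records (exactly `min_fold`-fold, or `p == alpha`) are not hits.
#'
#' @param records Data.frame after [ma_transform()] (columns `M`,
#'   `discarded`) with a `p_value` column for non-discarded records.
#' @param min_fold Minimum fold increase, strict (default 2).
#' @param alpha Significance level, strict (default 0.05).
#' @return The data.frame with an added logical `deg_hit` column; the
#'   hit count is `sum(x$deg_hit)`.
#' @examples
#' tab <- ma_transform(generate_expression_table(100, 10, 4, seed = 1))
#' sum(select_degs(tab)$deg_hit)   # 10
#' @export
select_degs <- function(records, min_fold = 2, alpha = 0.05) {
  stopifnot(is.data.frame(records),
            all(c("M", "discarded") %in% names(records)))
  if (min_fold <= 0) stop("min_fold must be > 0")
  candidates <- !records$discarded
  if (!"p_value" %in% names(records)) {
    if (any(candidates)) stop("records lack a p_value column")
    records$p_value <- numeric(0)
  }
  missing_p <- candidates & is.na(records$p_value)
  if (any(missing_p)) {
    ids <- if ("id" %in% names(records)) records$id[missing_p] else
      which(missing_p)
    stop("missing p-values for candidate records: ",
         paste(utils::head(ids, 10), collapse = ", "))
  }
  records$deg_hit <- candidates &
    records$M > log2(min_fold) &
    records$p_value < alpha
  records$deg_hit[is.na(records$deg_hit)] <- FALSE
  records
}

#' Call antibody-array hits from duplicate spot densities
#'
#' Averages the two duplicate spots of each condition, computes the
#' treated/control fold change, and flags analytes whose fold change
#' strictly exceeds `min_fold`. Analytes with zero control mean have an
#' undefined fold (`NA`), are never hits, and are flagged in
#' `fold_undefined` for reporting.
#'
#' @param spot_records Data.frame with columns `ctrl_1`, `ctrl_2`,
#'   `treat_1`, `treat_2` (non-negative densities) and optionally `id`.
#' @param min_fold Minimum fold increase, strict (default 1.2).
#' @return The data.frame with added columns `mean_ctrl`, `mean_treat`,
#'   `fold`, `hit`, `fold_undefined`; the hit count is `sum(x$hit)`.
#' @examples
#' cytokine_hits(data.frame(ctrl_1 = 10, ctrl_2 = 12,
#'                          treat_1 = 14, treat_2 = 16))$fold  # 1.364
#' @export
cytokine_hits <- function(spot_records, min_fold = 1.2) {
  stopifnot(is.data.frame(spot_records),
            all(c("ctrl_1", "ctrl_2", "treat_1", "treat_2") %in%
                  names(spot_records)))
  dens <- spot_records[c("ctrl_1", "ctrl_2", "treat_1", "treat_2")]
  if (any(as.matrix(dens) < 0)) stop("spot densities must be non-negative")
  mean_ctrl <- (spot_records$ctrl_1 + spot_records$ctrl_2) / 2
  mean_treat <- (spot_records$treat_1 + spot_records$treat_2) / 2
  fold <- ifelse(mean_ctrl > 0, mean_treat / mean_ctrl, NA_real_)
  spot_records$mean_ctrl <- mean_ctrl
  spot_records$mean_treat <- mean_treat
  spot_records$fold <- fold
  spot_records$hit <- !is.na(fold) & fold > min_fold
  spot_records$fold_undefined <- mean_ctrl == 0 & mean_treat > 0
  spot_records
}
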