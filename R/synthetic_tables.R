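#' Generate a toy gene-expression table with known up-regulated rows
#'
#' Builds an FPKM-like table of `n_genes` rows in which `n_up` randomly
#' chosen genes are increased exactly `up_fold`-fold in the treated
#' sample, with a fixed low p-value, and the remaining genes are
#' unchanged with null p-values. Intended as ground-truth input for
#' [ma_transform()] and [select_degs()].
#'
#' @param n_genes Number of rows.
#' @param n_up Number of truly up-regulated rows (`n_up <= n_genes`).
#' @param up_fold Fold increase of true hits (`> 1`).
#' @param baseline_range Length-2 numeric, uniform range of control FPKM.
#' @param p_hit P-value assigned to true hits.
#' @param p_null_uniform If `TRUE`, null p-values are Uniform(0, 1); if
#'   `FALSE` they are Uniform(0.5, 1), guaranteeing no null passes an
#'   `alpha < 0.5` significance cut.
#' @param seed Integer seed.
#' @return A data.frame with columns `id`, `fpkm_ctrl`, `fpkm_treat`,
#'   `p_value` and the ground-truth flag `is_up`.
#' @examples
#' tab <- generate_expression_table(100, 10, up_fold = 4, seed = 1)
#' sum(tab$is_up)
#' @export
generate_expression_table <- function(n_genes,
                                      n_up,
                                      up_fold,
                                      baseline_range = c(1, 100),
                                      p_hit = 0.001,
                                      p_null_uniform = TRUE,
                                      seed = 1L) {
  if (n_up > n_genes) stop("n_up must not exceed n_genes")
  if (n_up > 0 && up_fold <= 1) stop("up_fold must be > 1")
  stopifnot(n_genes >= 0, n_up >= 0, length(baseline_range) == 2L,
            baseline_range[1] > 0, baseline_range[2] >= baseline_range[1],
            p_hit > 0, p_hit < 1)
  set.seed(seed)
  fpkm_ctrl <- stats::runif(n_genes, baseline_range[1], baseline_range[2])
  is_up <- rep(FALSE, n_genes)
  if (n_up > 0) is_up[sample.int(n_genes, n_up)] <- TRUE
  fpkm_treat <- fpkm_ctrl
  fpkm_treat[is_up] <- fpkm_ctrl[is_up] * up_fold
  p_value <- if (p_null_uniform) {
    stats::runif(n_genes)
  } else {
    stats::runif(n_genes, 0.5, 1)
  }
  p_value[is_up] <- p_hit
  data.frame(
    id = sprintf("gene_%05d", seq_len(n_genes)),
    fpkm_ctrl = fpkm_ctrl,
    fpkm_treat = fpkm_treat,
    p_value = p_value,
    is_up = is_up,
    stringsAsFactors = FALSE
  )
}

#' Generate a toy duplicate-spot antibody-array table with known hits
#'
#' Emulates a cytokine antibody array in which every analyte is spotted
#' in duplicate under a control and a treated condition. True hits have
#' treated spot densities centered at `hit_fold` times the control mean;
#' duplicate spots scatter around their condition mean with coefficient
#' of variation `duplicate_cv`. Negative densities are resampled, never
#' emitted.
#'
#' @param n_analytes Number of analytes (rows).
#' @param n_hits Number of true hits (`n_hits <= n_analytes`).
#' @param hit_fold Fold increase of true hits (`> 1`, or exactly 1 for a
#'   null table).
#' @param duplicate_cv Coefficient of variation of duplicate spots
#'   around the condition mean (`>= 0`; `0` gives exact duplicates).
#' @param baseline_range Length-2 numeric, uniform range of control mean
#'   densities.
#' @param seed Integer seed.
#' @return A data.frame with columns `id`, `ctrl_1`, `ctrl_2`,
#'   `treat_1`, `treat_2` and the ground-truth flag `is_hit`.
#' @examples
#' spots <- generate_spot_table(40, 5, hit_fold = 1.5,
#'                              duplicate_cv = 0, seed = 1)
#' sum(spots$is_hit)
#' @export
generate_spot_table <- function(n_analytes,
                                n_hits,
                                hit_fold,
                                duplicate_cv = 0.05,
                                baseline_range = c(50, 200),
                                seed = 1L) {
  if (n_hits > n_analytes) stop("n_hits must not exceed n_analytes")
  if (n_hits > 0 && hit_fold < 1) stop("hit_fold must be >= 1")
  stopifnot(n_analytes >= 0, n_hits >= 0, duplicate_cv >= 0,
            length(baseline_range) == 2L, baseline_range[1] > 0)
  set.seed(seed)
  mean_ctrl <- stats::runif(n_analytes, baseline_range[1], baseline_range[2])
  is_hit <- rep(FALSE, n_analytes)
  if (n_hits > 0) is_hit[sample.int(n_analytes, n_hits)] <- TRUE
  mean_treat <- mean_ctrl
  mean_treat[is_hit] <- mean_ctrl[is_hit] * hit_fold

  spot <- function(m) {
    if (duplicate_cv == 0) return(m)
    vapply(m, function(mu) {
      for (attempt in 1:1000) {
        v <- mu * (1 + stats::rnorm(1, sd = duplicate_cv))
        if (v >= 0) return(v)
      }
      stop("could not sample a non-negative spot density (duplicate_cv too large?)")
    }, numeric(1))
  }

  data.frame(
    id = sprintf("analyte_%03d", seq_len(n_analytes)),
    ctrl_1 = spot(mean_ctrl),
    ctrl_2 = spot(mean_ctrl),
    treat_1 = spot(mean_treat),
    treat_2 = spot(mean_treat),
    is_hit = is_hit,
    stringsAsFactors = FALSE
  )
}
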