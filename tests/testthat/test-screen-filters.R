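test_that("MA transform applies pseudocount, discard and exact arithmetic", {
  tab <- ma_transform(data.frame(fpkm_ctrl = c(1, 0.005, 2),
                                 fpkm_treat = c(3.999, 100, 1.999)))
  expect_equal(tab$M, c(2, NA, 0))              # exact after pseudocount
  expect_equal(tab$A, c(2.5, NA, 2))
  expect_equal(tab$discarded, c(FALSE, TRUE, FALSE))
  expect_error(ma_transform(data.frame(fpkm_ctrl = -1, fpkm_treat = 1)),
               "non-negative")
  # treated-only discard scope keeps the low-control record
  t2 <- ma_transform(data.frame(fpkm_ctrl = 0.005, fpkm_treat = 100),
                     discard_scope = "treated")
  expect_false(t2$discarded)
  g <- ma_transform(data.frame(fpkm_ctrl = 4, fpkm_treat = 0.999),
                    a_mode = "geometric")
  expect_equal(g$A, 2)                          # sqrt(4 * 1)
})

test_that("DEG selection is strict on both the fold and the p boundary", {
  recs <- data.frame(id = letters[1:4],
                     M = c(1.5, 1.0, 2.0, 3.0),
                     p_value = c(0.01, 0.01, 0.05, 0.2),
                     discarded = FALSE)
  out <- select_degs(recs)
  expect_equal(out$deg_hit, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(sum(out$deg_hit), 1L)
  empty <- select_degs(data.frame(M = numeric(0), p_value = numeric(0),
                                  discarded = logical(0)))
  expect_equal(sum(empty$deg_hit), 0L)
  bad <- data.frame(id = c("x", "y"), M = c(2, 2),
                    p_value = c(NA, 0.01), discarded = FALSE)
  expect_error(select_degs(bad), "x")
})

test_that("DEG selection recovers generator ground truth exactly", {
  tab <- generate_expression_table(100, 10, up_fold = 4, p_hit = 0.001,
                                   p_null_uniform = FALSE, seed = 6)
  out <- select_degs(ma_transform(tab))
  expect_equal(out$deg_hit, tab$is_up)
  null_tab <- generate_expression_table(100, 0, up_fold = 2, seed = 6)
  expect_equal(sum(select_degs(ma_transform(null_tab))$deg_hit), 0L)
})

test_that("cytokine hit calling is exact and strict at the boundary", {
  tab <- data.frame(ctrl_1 = c(10, 10, 10, 0),
                    ctrl_2 = c(12, 10, 10, 0),
                    treat_1 = c(14, 12, 10, 5),
                    treat_2 = c(16, 12, 10, 5))
  out <- cytokine_hits(tab)
  expect_equal(out$fold, c(15 / 11, 1.2, 1, NA))
  expect_equal(out$hit, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$fold_undefined, c(FALSE, FALSE, FALSE, TRUE))
  spots <- generate_spot_table(50, 7, hit_fold = 1.5, duplicate_cv = 0,
                               seed = 4)
  expect_equal(cytokine_hits(spots)$hit, spots$is_hit)
  flat <- generate_spot_table(50, 7, hit_fold = 1.0, duplicate_cv = 0,
                              seed = 4)
  expect_equal(sum(cytokine_hits(flat)$hit), 0L)
})

test_that("filter counts equal brute-force enumeration on random tables", {
  set.seed(21)
  n <- 1000
  tab <- data.frame(
    id = sprintf("g%04d", 1:n),
    fpkm_ctrl = round(stats::rlnorm(n, 0, 2), 3),
    fpkm_treat = round(stats::rlnorm(n, 0.5, 2), 3),
    p_value = stats::runif(n)
  )
  out <- select_degs(ma_transform(tab))
  brute <- 0L
  for (i in 1:n) {
    treat <- tab$fpkm_treat[i] + 0.001
    if (tab$fpkm_ctrl[i] >= 0.01 && treat >= 0.01 &&
        log2(treat / tab$fpkm_ctrl[i]) > 1 && tab$p_value[i] < 0.05) {
      brute <- brute + 1L
    }
  }
  expect_equal(sum(out$deg_hit), brute)

  spots <- data.frame(ctrl_1 = stats::runif(n, 0, 100),
                      ctrl_2 = stats::runif(n, 0, 100),
                      treat_1 = stats::runif(n, 0, 130),
                      treat_2 = stats::runif(n, 0, 130))
  hits <- cytokine_hits(spots)
  brute_hits <- 0L
  for (i in 1:n) {
    mc <- (spots$ctrl_1[i] + spots$ctrl_2[i]) / 2
    mt <- (spots$treat_1[i] + spots$treat_2[i]) / 2
    if (mc > 0 && mt / mc > 1.2) brute_hits <- brute_hits + 1L
  }
  expect_equal(sum(hits$hit), brute_hits)
})

test_that("record order never changes per-record outcomes", {
  tab <- generate_expression_table(200, 20, up_fold = 3, seed = 13)
  out <- select_degs(ma_transform(tab))
  perm <- sample(nrow(tab))
  out_perm <- select_degs(ma_transform(tab[perm, ]))
  expect_equal(out_perm$deg_hit, out$deg_hit[perm])
  expect_equal(out_perm$M, out$M[perm])
})

test_that("the hit set shrinks as thresholds tighten", {
  tab <- ma_transform(generate_expression_table(300, 40, up_fold = 3,
                                                seed = 17))
  hits <- function(mf, a) which(select_degs(tab, min_fold = mf,
                                            alpha = a)$deg_hit)
  h_base <- hits(2, 0.05)
  expect_true(all(hits(3, 0.05) %in% h_base))
  expect_true(all(hits(2, 0.01) %in% h_base))
  expect_true(all(hits(4, 0.005) %in% hits(3, 0.01)))
})
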