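# Statistical machinery: paired t, Pearson r, Shapiro-Wilk, population
# summaries, per-second Bonferroni tests, summary tables.

test_that("paired t matches hand arithmetic and guards degeneracy", {
  ht <- paired_t(c(0, 0, 0, 0), c(1, 1, 1, -1))
  # differences -1,-1,-1,1: mean -0.5, sd 1, t = -1, df 3
  expect_equal(ht$t, -1)
  expect_equal(ht$df, 3)
  expect_equal(ht$mean_diff, -0.5)
  expect_error(paired_t(1:3, 1:3), "identical")
  expect_error(paired_t(1:3, 1:4), "equal length")
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("paired t is calibrated under the null", {
  set.seed(99)
  reps <- 4000
  rej <- mean(replicate(reps, paired_t(rnorm(14), rnorm(14))$p < 0.05))
  expect_gt(rej, 0.04)
  expect_lt(rej, 0.06)
})

test_that("pearson r handles exact linear relations and affine invariance", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  y <- c(2, 1, 5, 4, 8)
  expect_equal(pearson_r(3 * x - 2, y)$r, pearson_r(x, y)$r)
  expect_equal(pearson_r(x, 0.5 * y + 7)$r, pearson_r(x, y)$r)
  expect_error(pearson_r(x, rep(1, 5)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("Shapiro-Wilk check is calibrated and powered", {
  p_norm <- sapply(1:100, function(s) {
    set.seed(s)
    normality_check(rnorm(14))$p
  })
  expect_gte(mean(p_norm > 0.05), 0.9)
  p_lnorm <- sapply(1:100, function(s) {
    set.seed(s)
    normality_check(exp(rnorm(14)))$p
  })
  expect_gte(mean(p_lnorm < 0.05), 0.5)
  expect_error(normality_check(rep(1, 10)), "constant")
  expect_error(normality_check(1:2), "3 <= n")
})

test_that("summary statistics use the population divisor", {
  st <- summary_stats(c(2, 4, 6))
  expect_equal(st$mean, 4)
  expect_equal(st$sd_pop, sqrt(mean((c(2, 4, 6) - 4)^2)))
  one <- summary_stats(5)
  expect_equal(one$mean, 5)
  expect_equal(one$sd_pop, 0)
  expect_error(summary_stats(numeric(0)), "empty")
})

test_that("per-second Bonferroni flags only the separated seconds", {
  mk_series <- function(effect_at) {
    purrr::map(1:14, function(s) {
      set.seed(100 + s)
      purrr::map(c("Attention", "Inattention"), function(cnd) {
        shift <- ifelse(1:5 %in% effect_at & cnd == "Attention", -0.8, 0)
        tibble::tibble(subject = s, time = 1:5, condition = cnd,
                       tbr = 2.5 + shift + rnorm(5, sd = 0.1))
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  }
  res <- bonferroni_per_second(mk_series(2:4))
  expect_equal(res$time[res$significant], c(2, 3, 4))
  expect_equal(res$p_corrected, pmin(1, res$p_raw * 5))
  # identical series: no flags
  ser <- mk_series(integer(0))
  ser$tbr <- rep(seq(2, 3, length.out = 5), 28) + rep(rnorm(14), each = 10)
  expect_error(bonferroni_per_second(ser), "identical")   # zero differences
  # single second: corrected p equals raw p
  one <- mk_series(integer(0)) |> dplyr::filter(.data$time == 3)
  res1 <- bonferroni_per_second(one)
  expect_equal(res1$p_corrected, res1$p_raw)
  bad <- mk_series(1)
  bad <- bad[!(bad$subject == 3 & bad$condition == "Attention"), ]
  expect_error(bonferroni_per_second(bad), "misaligned")
})

test_that("summary table reproduces per-subject layout with recomputable rows", {
  idx <- reference_indices(c("erd", "ami"))
  tab <- build_summary_table(idx, c("erd", "ami"))
  expect_equal(nrow(tab), 14 + 4)
  mrow <- tab[tab$subject == "Mean", ]
  srow <- tab[tab$subject == "SDT", ]
  vals <- tab$erd_Attention[1:14]
  expect_equal(mrow$erd_Attention, mean(vals))
  expect_equal(srow$erd_Attention, sqrt(mean((vals - mean(vals))^2)))
  rrow <- tab[tab$subject == "r", ]
  expect_equal(rrow$erd_Attention,
               pearson_r(vals, tab$ami_Attention[1:14])$r)
  expect_true(is.na(rrow$ami_Attention))
  # glance exposes the summary rows
  g <- glance(tab)
  expect_equal(g$mean_erd_Attention, mean(vals))
  expect_s3_class(tidy(tab), "tbl_df")
  # single subject: mean = row, SDT = 0, r absent
  one <- idx[idx$subject == "S1", ]
  t1 <- build_summary_table(one, c("erd", "ami"))
  expect_equal(t1$erd_Attention[t1$subject == "Mean"],
               one$erd[one$condition == "Attention"])
  expect_equal(t1$erd_Attention[t1$subject == "SDT"], 0)
  expect_true(is.na(t1$erd_Attention[t1$subject == "r"]))
  expect_error(build_summary_table(idx[-1, ], c("erd", "ami")), "incomplete")
})
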