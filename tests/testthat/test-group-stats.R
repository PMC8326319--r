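fake_effects <- function(df) {
  # minimal som_effects-shaped table from participant/group/condition/value
  out <- tibble::tibble(
    participant = df$participant, group = df$group,
    condition = df$condition, session = NA_integer_,
    session_id = paste(df$participant, df$condition, sep = "_"),
    som_StoO_raw = df$value, som_StoO_vw = df$value,
    som_OtoS_raw = df$value, som_OtoS_vw = df$value,
    context_S_raw = 0.1, context_S_vw = 0.1,
    context_O_raw = 0.1, context_O_vw = 0.1,
    n_engage = 50L, converged = TRUE
  )
  structure(out, class = c("som_effects", class(out)))
}

test_that("baseline t equals the closed form mean / (sd / sqrt(n))", {
  vals <- c(0.4, -0.1, 0.9, 0.3, 0.2, 0.6, -0.2, 0.5)
  eff <- fake_effects(tibble::tibble(
    participant = sprintf("P%02d", 1:8), group = "dmPFC",
    condition = "no-cTBS", value = vals))
  res <- baseline_som_tests(eff)
  t_expected <- mean(vals) / (sd(vals) / sqrt(length(vals)))
  expect_equal(res$statistic[res$test == "SOM_int(S->O)"], t_expected,
               tolerance = 1e-10)
  expect_equal(res$df[1], 7)
  expect_equal(res$n[1], 8L)
})

test_that("all-zero effects give t = 0 and p = 1", {
  eff <- fake_effects(tibble::tibble(
    participant = sprintf("P%02d", 1:6), group = "vertex",
    condition = "no-cTBS", value = 0))
  res <- baseline_som_tests(eff)
  row <- res[res$test == "SOM_int(O->S)", ]
  expect_equal(row$statistic, 0)
  expect_equal(row$p.value, 1)
  small <- fake_effects(tibble::tibble(
    participant = "P1", group = "g", condition = "no-cTBS", value = 0.1))
  expect_error(baseline_som_tests(small),
               class = "somtrack_insufficient_data")
})

make_2x2 <- function(values) {
  # values: named list dmPFC_cTBS, dmPFC_no, vertex_cTBS, vertex_no (each n)
  n <- length(values$dmPFC_cTBS)
  ids_d <- sprintf("D%02d", 1:n)
  ids_v <- sprintf("V%02d", 1:n)
  tibble::tibble(
    participant = c(ids_d, ids_d, ids_v, ids_v),
    group = rep(c("dmPFC", "vertex"), each = 2 * n),
    condition = rep(c("cTBS", "no-cTBS", "cTBS", "no-cTBS"), each = n),
    value = c(values$dmPFC_cTBS, values$dmPFC_no,
              values$vertex_cTBS, values$vertex_no)
  )
}

test_that("interaction F equals t-squared on condition differences", {
  vals <- withr::with_seed(13, list(
    dmPFC_cTBS = rnorm(6, 0.5), dmPFC_no = rnorm(6, 0.1),
    vertex_cTBS = rnorm(6), vertex_no = rnorm(6)))
  df <- make_2x2(vals)
  res <- ctbs_interaction_test(fake_effects(df))
  f <- res$statistic[res$test == "group x stimulation interaction"]
  wide <- tidyr::pivot_wider(df, id_cols = c("participant", "group"),
                             names_from = "condition", values_from = "value")
  d <- wide$cTBS - wide$`no-cTBS`
  tt <- t.test(d[wide$group == "dmPFC"], d[wide$group == "vertex"],
               var.equal = TRUE)
  expect_equal(f, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(res$df1[1], 1)
  expect_equal(res$df2[1], 10)
})

test_that("interaction F matches a from-scratch sums-of-squares oracle", {
  vals <- withr::with_seed(17, list(
    dmPFC_cTBS = rnorm(6, 0.4), dmPFC_no = rnorm(6),
    vertex_cTBS = rnorm(6, -0.1), vertex_no = rnorm(6)))
  df <- make_2x2(vals)
  res <- ctbs_interaction_test(fake_effects(df))
  f <- res$statistic[res$test == "group x stimulation interaction"]
  f_oracle <- oracle_mixed_interaction_F(df$participant, df$group,
                                         df$condition, df$value)
  expect_equal(f, f_oracle, tolerance = 1e-8)
})

test_that("identical values in all four cells give F = 0", {
  df <- make_2x2(list(dmPFC_cTBS = rep(0.3, 5), dmPFC_no = rep(0.3, 5),
                      vertex_cTBS = rep(0.3, 5), vertex_no = rep(0.3, 5)))
  res <- ctbs_interaction_test(fake_effects(df))
  expect_equal(res$statistic[res$test == "group x stimulation interaction"], 0)
})

test_that("the paired dmPFC t is reported alongside the interaction", {
  vals <- withr::with_seed(19, list(
    dmPFC_cTBS = rnorm(8, 0.6, 0.2), dmPFC_no = rnorm(8, 0.1, 0.2),
    vertex_cTBS = rnorm(8, 0.1, 0.2), vertex_no = rnorm(8, 0.1, 0.2)))
  df <- make_2x2(vals)
  res <- ctbs_interaction_test(fake_effects(df))
  paired <- res[res$test == "paired t (cTBS - no-cTBS)" &
                  res$group == "dmPFC", ]
  wide <- tidyr::pivot_wider(df[df$group == "dmPFC", ],
                             id_cols = "participant",
                             names_from = "condition", values_from = "value")
  tt <- t.test(wide$cTBS, wide$`no-cTBS`, paired = TRUE)
  expect_equal(paired$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_gt(paired$estimate, 0)
})

test_that("participants with a missing session are dropped complete-case", {
  vals <- withr::with_seed(23, list(
    dmPFC_cTBS = rnorm(5), dmPFC_no = rnorm(5),
    vertex_cTBS = rnorm(5), vertex_no = rnorm(5)))
  df <- make_2x2(vals)
  df <- df[!(df$participant == "D01" & df$condition == "cTBS"), ]
  expect_message(res <- ctbs_interaction_test(fake_effects(df)),
                 "dropped")
  expect_equal(res$n[res$test == "group x stimulation interaction"], 9L)
})

test_that("interaction p-values are uniform under the null", {
  pvals <- withr::with_seed(29, vapply(1:300, function(i) {
    vals <- list(dmPFC_cTBS = rnorm(8), dmPFC_no = rnorm(8),
                 vertex_cTBS = rnorm(8), vertex_no = rnorm(8))
    res <- ctbs_interaction_test(fake_effects(make_2x2(vals)))
    res$p.value[res$test == "group x stimulation interaction"]
  }, numeric(1)))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})
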