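test_that("pooled t matches hand computation and stats::t.test", {
  st <- study_from_groups(matrix(c(3, 4, 5), 1), matrix(c(1, 2, 3), 1))
  res <- de_test(st)
  expect_equal(res$logfc, 2)
  expect_equal(res$t_stat, 2.449, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$pvalue, 0.0705, tolerance = 5e-4)

  # independent oracle across random genes, pooled and Welch
  set.seed(21)
  case <- matrix(rnorm(30, 5, 1.2), nrow = 5)
  ctrl <- matrix(rnorm(40, 4.5, 0.8), nrow = 5)
  st2 <- study_from_groups(case, ctrl)
  for (method in c("pooled_t", "welch_t")) {
    mine <- de_test(st2, method = method)
    for (i in 1:5) {
      ref <- t.test(case[i, ], ctrl[i, ], var.equal = method == "pooled_t")
      expect_equal(mine$pvalue[i], ref$p.value, tolerance = 1e-10)
      expect_equal(mine$t_stat[i], unname(ref$statistic), tolerance = 1e-10)
    }
  }
})

test_that("DE test symmetry, degeneracy and invariance properties hold", {
  set.seed(31)
  case <- matrix(rnorm(40, 6, 1), nrow = 4)
  ctrl <- matrix(rnorm(32, 5.5, 1), nrow = 4)
  st <- study_from_groups(case, ctrl)
  sw <- study_from_groups(ctrl, case)
  a <- de_test(st)
  b <- de_test(sw)
  expect_equal(a$logfc, -b$logfc)           # label swap negates logFC
  expect_equal(a$pvalue, b$pvalue)          # ... but not significance

  # location invariance: adding a constant changes nothing
  shifted <- study_from_groups(case + 3.7, ctrl + 3.7)
  expect_equal(de_test(shifted)$pvalue, a$pvalue, tolerance = 1e-9)
  expect_equal(de_test(shifted)$logfc, a$logfc, tolerance = 1e-9)

  # identical groups: logFC 0, p 1
  ident <- study_from_groups(matrix(rep(1:3, 2), 2), matrix(rep(1:3, 2), 2))
  expect_equal(de_test(ident)$logfc, c(0, 0))
  expect_equal(de_test(ident)$pvalue, c(1, 1))

  # a group with < 2 usable samples yields a flagged NA result
  case_na <- case
  case_na[1, 2:ncol(case_na)] <- NA
  stna <- study_from_groups(case_na, ctrl)
  resna <- de_test(stna)
  expect_true(resna$flagged[1])
  expect_true(is.na(resna$pvalue[1]))

  # sign(logfc) agrees with sign(t) whenever both are nonzero
  nz <- !is.na(a$t_stat) & a$t_stat != 0
  expect_equal(sign(a$logfc[nz]), sign(a$t_stat[nz]))
})

test_that("DE p-values are uniform under the global null", {
  set.seed(41)
  case <- matrix(rnorm(2000 * 8), nrow = 2000)
  ctrl <- matrix(rnorm(2000 * 10), nrow = 2000)
  p <- de_test(study_from_groups(case, ctrl))$pvalue
  expect_gt(ks.test(p, punif)$p.value, 0.01)
})

test_that("moderated t agrees with the unmoderated test at large n", {
  skip_if_not_installed("limma")
  set.seed(51)
  case <- matrix(rnorm(20 * 50, 5), nrow = 20)
  ctrl <- matrix(rnorm(20 * 50, 5), nrow = 20)
  st <- study_from_groups(case, ctrl)
  mod <- de_test(st, method = "moderated_t")
  raw <- de_test(st, method = "pooled_t")
  expect_equal(mod$logfc, raw$logfc, tolerance = 1e-9)
  expect_gt(cor(mod$t_stat, raw$t_stat), 0.99)
})

test_that("shared-significance classification applies strict per-disease minima", {
  tbl <- tibble::tibble(
    gene = rep(c("g1", "g2", "g3"), each = 4),
    study_id = rep(c("A1", "A2", "B1", "B2"), 3),
    disease = rep(c("d1", "d1", "d2", "d2"), 3),
    pvalue = c(1e-5, 0.5, 1e-4, 0.9,    # shared
               1e-5, 0.5, 0.9, 0.8,     # one disease only
               1, 1, 1, 1)              # nothing
  )
  cl <- classify_shared(tbl, n_genes = 3)
  expect_equal(cl$any_significant, c(TRUE, TRUE, FALSE))
  expect_equal(cl$shared_significant, c(TRUE, FALSE, FALSE))
  expect_equal(attr(cl, "threshold"), 0.05 / 3)

  # NA p-values are ignored in minima; absence from one disease blocks sharing
  tbl2 <- tbl[tbl$gene == "g1", ]
  tbl2$pvalue[tbl2$disease == "d2"] <- NA
  cl2 <- classify_shared(dplyr::bind_rows(tbl2, tbl[tbl$gene == "g3", ]),
                         n_genes = 2)
  expect_false(cl2$shared_significant[cl2$gene == "g1"])

  # threshold is strict: p exactly at alpha/G does not count
  tbl3 <- tbl
  tbl3$pvalue <- 0.05 / 3
  expect_equal(sum(classify_shared(tbl3, n_genes = 3)$any_significant), 0)
})

test_that("run_de recovers planted effects and stays quiet under the null", {
  design <- list(
    list(study_id = "A1", disease = "d1", n_case = 15, n_control = 15,
         sigma = 0.5),
    list(study_id = "A2", disease = "d1", n_case = 15, n_control = 15,
         sigma = 0.5),
    list(study_id = "B1", disease = "d2", n_case = 15, n_control = 15,
         sigma = 0.5),
    list(study_id = "B2", disease = "d2", n_case = 15, n_control = 15,
         sigma = 0.5)
  )
  planted <- sprintf("G%03d", 1:5)
  cfg <- sim_config(seed = 61, n_genes = 50, causal_genes = planted,
                    expression_design = design,
                    planted_logfc = setNames(rep(1, 5), planted))
  studies <- make_expression(cfg)
  res <- run_de(studies)
  expect_setequal(res$shared$gene[res$shared$shared_significant], planted)

  # per gene x disease the smallest-p study is reported
  expect_equal(nrow(res$best), 2 * dplyr::n_distinct(res$de$gene))
  g1 <- res$de[res$de$gene == "G001" & res$de$disease == "d1", ]
  expect_equal(res$best$pvalue[res$best$gene == "G001" &
                                 res$best$disease == "d1"],
               min(g1$pvalue))

  # no planted effects: no shared calls at G = 24
  cfg0 <- sim_config(seed = 62, n_genes = 24, causal_genes = character(0),
                     expression_design = design,
                     planted_logfc = setNames(numeric(0), character(0)))
  res0 <- run_de(make_expression(cfg0))
  expect_equal(sum(res0$shared$shared_significant), 0)

  # single study per disease, one gene: two DE results
  small <- run_de(make_expression(cfg)[c(1, 3)], genes = "G001")
  expect_equal(nrow(small$de), 2)
})
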