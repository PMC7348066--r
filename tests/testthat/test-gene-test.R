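test_that("chi-square conversion matches independent quantile oracles", {
  expect_equal(chisq_from_p(1), 0)
  # z = 1 two-tail identity: p = 0.3173 corresponds to chi-square 1
  expect_equal(chisq_from_p(2 * pnorm(-1)), 1, tolerance = 1e-10)
  expect_equal(chisq_from_p(0.3173), 1, tolerance = 1e-3)
  # independent numeric root-find on the chi-square survival function
  oracle <- uniroot(function(q) pchisq(q, 1, lower.tail = FALSE) - 0.05,
                    c(0, 100), tol = 1e-12)$root
  expect_equal(chisq_from_p(0.05), oracle, tolerance = 1e-9)
  expect_error(chisq_from_p(0), "\\(0, 1\\]")
  expect_error(chisq_from_p(1.2), "\\(0, 1\\]")

  expect_equal(gene_statistic(c(1, 1, 1)), 0)
  expect_equal(gene_statistic(0.05), chisq_from_p(0.05))
  expect_equal(gene_statistic(c(0.05, 0.05)), 2 * chisq_from_p(0.05),
               tolerance = 1e-12)
})

test_that("LD matrix is signed, PSD-repaired, and handles degeneracies", {
  x <- rep(c(0, 1, 2), 20)
  pan <- panel_from_dosages(a = x, b = x, c = 2 - x)
  r <- ld_matrix(pan, c("a", "b", "c"))
  expect_equal(r["a", "b"], 1, tolerance = 1e-8)
  expect_equal(r["a", "c"], -1, tolerance = 1e-8)  # signed r, not r^2
  expect_true(min(eigen(r, symmetric = TRUE)$values) >= 0)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))

  # two independent SNPs, 10,000 individuals: sampling bound on |r|
  pan2 <- random_panel(10000, c(0.3, 0.4), seed = 5)
  r2 <- ld_matrix(pan2, c("snp1", "snp2"))
  expect_lt(abs(r2[1, 2]), 0.05)

  expect_equal(ld_matrix(pan2, "snp1"), matrix(1, 1, 1,
               dimnames = list("snp1", "snp1")))

  # monomorphic members are dropped; all-monomorphic is untestable
  pan3 <- panel_from_dosages(a = x, b = rep(1, 60))
  expect_warning(r3 <- ld_matrix(pan3, c("a", "b")), "monomorphic")
  expect_equal(colnames(r3), "a")
  pan4 <- panel_from_dosages(b = rep(1, 60))
  expect_warning(expect_null(ld_matrix(pan4, "b")), "untestable")

  # missing dosages are mean-imputed before correlation
  xm <- x
  xm[1:5] <- NA
  pan5 <- panel_from_dosages(a = x, b = xm)
  expect_false(anyNA(ld_matrix(pan5, c("a", "b"))))
})

test_that("SNP-gene assignment follows the window + LD-link rule", {
  set.seed(42)
  inside <- rbinom(400, 2, 0.3)
  linked <- ifelse(runif(400) < 0.95, inside, rbinom(400, 2, 0.3))  # r2 ~ 0.9
  free <- rbinom(400, 2, 0.3)
  mat <- cbind(s_in = inside, s_link = linked, s_free = free,
               s_other = rbinom(400, 2, 0.4))
  map <- tibble::tibble(rsid = colnames(mat),
                        chrom = c("1", "1", "1", "2"),
                        pos = c(150L, 5150L, 9000L, 150L))
  pan <- ref_panel(mat, map)
  snps <- tibble::tibble(rsid = c(colnames(mat), "s_absent"),
                         pvalue = c(0.01, 0.02, 0.03, 0.04, 0.5))
  genes <- tibble::tibble(gene = "G", chrom = "1", start = 150L, end = 400L)

  expect_message(asg <- assign_snps_to_genes(snps, genes, pan),
                 "absent from the reference panel")
  # boundary SNP included by rule (a); distant high-r2 SNP recruited by (b);
  # low-r2 and other-chromosome SNPs excluded
  expect_setequal(asg$rsid, c("s_in", "s_link"))
  expect_equal(asg$inside, c(TRUE, FALSE))

  # below the r2 threshold nothing is recruited
  asg2 <- assign_snps_to_genes(snps[1:4, ], genes, pan, r2_link = 0.999)
  expect_equal(asg2$rsid, "s_in")

  # zero-member genes are legal and simply absent
  far <- tibble::tibble(gene = "H", chrom = "7", start = 1L, end = 10L)
  expect_equal(nrow(assign_snps_to_genes(snps[1:4, ], far, pan)), 0)
})

test_that("simulated null matches closed-form distributions", {
  n1 <- simulate_null(diag(1), 1e4, seed = 3)
  expect_gt(ks.test(n1, pchisq, df = 1)$p.value, 0.01)

  n5 <- simulate_null(diag(5), 1e4, seed = 4)
  expect_gt(ks.test(n5, pchisq, df = 5)$p.value, 0.01)

  # perfect LD collapses to a single degree of freedom scaled by n
  ones <- pleioscan:::repair_correlation(matrix(1, 3, 3))
  n3 <- simulate_null(ones, 1e4, seed = 5)
  expect_gt(ks.test(n3 / 3, pchisq, df = 1)$p.value, 0.01)

  expect_identical(simulate_null(diag(2), 1000, seed = 9),
                   simulate_null(diag(2), 1000, seed = 9))
})

test_that("empirical p follows (r+1)/(m+1) with ties not surpassing", {
  expect_equal(empirical_p(5, rep(1, 999)), 0.001)
  expect_equal(empirical_p(0, rep(1, 999)), 1)
  nulls <- c(rep(10, 49), rep(0.1, 950))
  expect_equal(empirical_p(5, nulls), 0.05)
  # ties count as not surpassing
  expect_equal(empirical_p(1, c(1, 1, 2)), (1 + 1) / (3 + 1))
  # decreasing in the observed statistic for a fixed null sample
  nulls <- simulate_null(diag(3), 1000, seed = 1)
  ps <- vapply(c(0, 2, 5, 10, 20), empirical_p, numeric(1), nulls = nulls)
  expect_true(all(diff(ps) <= 0))
})

test_that("test_gene handles degenerate and closed-form cases", {
  pan <- random_panel(300, c(0.3, 0.35, 0.4), seed = 7)
  members <- tibble::tibble(gene = "G", rsid = paste0("snp", 1:3),
                            pos = c(100L, 200L, 300L), pvalue = rep(1, 3))
  res <- test_gene(members, pan, stages = 1e3, seed = 2)
  expect_equal(res$statistic, 0)
  expect_equal(res$empirical_p, 1)
  expect_equal(res$n_snps, 3L)

  # top SNP is the minimum p, ties broken by position
  members$pvalue <- c(0.5, 0.01, 0.01)
  res2 <- test_gene(members, pan, stages = 1e3, seed = 2)
  expect_equal(res2$top_snp, "snp2")
  expect_equal(res2$top_snp_p, 0.01)

  # perfect-LD limit: identical dosages, equal member p -> gene p ~ p0
  x <- rbinom(500, 2, 0.3)
  panp <- panel_from_dosages(a = x, b = x, c = x)
  mp <- tibble::tibble(gene = "G", rsid = c("a", "b", "c"),
                       pos = c(100L, 200L, 300L), pvalue = rep(0.2, 3))
  resp <- test_gene(mp, panp, stages = 1e5, seed = 3)
  expect_equal(resp$empirical_p, 0.2, tolerance = 3 * sqrt(0.2 * 0.8 / 1e5) / 0.2)

  # empirical p never leaves [1/(m+1), 1]
  expect_gte(resp$empirical_p, 1 / (1e5 + 1))
  expect_lte(resp$empirical_p, 1)
})

test_that("adaptive schedule escalates only while exceedances are scarce", {
  pan <- random_panel(300, 0.3, seed = 8)
  mem <- tibble::tibble(gene = "G", rsid = "snp1", pos = 100L, pvalue = 0.5)
  res <- test_gene(mem, pan, stages = c(1e3, 1e4), seed = 1)
  expect_equal(res$n_sims, 1000L)  # plenty of exceedances at stage one
  mem$pvalue <- 1e-6
  res2 <- test_gene(mem, pan, stages = c(1e3, 1e4), seed = 1)
  expect_equal(res2$n_sims, 10000L)  # escalates to the cap
  res3 <- test_gene(mem, pan, stages = c(1e3, 1e4), max_sims = 1e3, seed = 1)
  expect_equal(res3$n_sims, 1000L)  # cap respected
})

test_that("gene scan is deterministic and order-stable", {
  cfg <- sim_config(seed = 31, n_genes = 12, n_individuals = 250,
                    causal_genes = "G002")
  inp <- sim_pipeline_inputs(cfg)
  scan1 <- run_gene_test(inp$gwas_a, inp$genes, inp$panel, seed = 5,
                         max_sims = 1e4)
  # shuffled SNP input order: bitwise-identical per-gene results
  shuffled <- inp$gwas_a[sample.int(nrow(inp$gwas_a)), ]
  scan2 <- run_gene_test(shuffled, inp$genes, inp$panel, seed = 5,
                         max_sims = 1e4)
  expect_identical(tibble::as_tibble(scan1), tibble::as_tibble(scan2))

  # planted gene ranks first
  expect_equal(scan1$gene[which.min(scan1$empirical_p)], "G002")

  # empty intersection with the panel -> empty scan with a warning
  stray <- tibble::tibble(rsid = c("rsX", "rsY"), pvalue = c(0.1, 0.2))
  suppressMessages(expect_warning(
    empty <- run_gene_test(stray, inp$genes, inp$panel, seed = 5),
    "no SNP"))
  expect_equal(nrow(empty), 0)
})
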