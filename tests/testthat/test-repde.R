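test_that("the fitted object carries selections, DE sets and the combined rule", {
  sim <- simulate_expression(sim_config(seed = 1))
  fit <- repde(sim$x)
  expect_s3_class(fit, "repde")
  expect_named(fit$fits, c("pd", "pfc"))
  for (rule in names(fit$fits)) {
    expect_s3_class(fit$fits[[rule]]$selection, "pair_selection")
    expect_s3_class(fit$fits[[rule]]$de, "de_gene_set")
  }
  comb <- de_genes(fit)  # defaults to the combined set
  expect_true(all(de_genes(fit, "pd")$gene_id %in%
                    union(comb$gene_id, fit$combined$dropped_conflicts)))
  expect_output(print(fit), "combined PD\\+PFC")
  expect_output(print(summary(fit)), "pair comparisons")
})

test_that("identical replicates yield empty DE lists under both rules", {
  vals <- matrix(rep(c(100, 20, 7, 350), 4), ncol = 4,
                 dimnames = list(paste0("g", 1:4), c("R1", "R2", "S1", "S2")))
  x <- expr_matrix(vals, c(R1 = "R", R2 = "R", S1 = "S", S2 = "S"))
  w <- capture_warnings(fit <- repde(x, score = c("pd", "pfc"), init_step = 2))
  expect_match(w, "no independent duo", all = TRUE)
  expect_equal(nrow(de_genes(fit, "pd")), 0L)
  expect_equal(nrow(de_genes(fit, "pfc")), 0L)
  expect_equal(nrow(de_genes(fit, "combined")), 0L)
})

test_that("refitting the same simulated data reproduces the result exactly", {
  sim <- simulate_expression(sim_config(n_genes = 500, n_high = 50, n_low = 50,
                                        seed = 33))
  f1 <- repde(sim$x, score = "pd", init_step = 100)
  f2 <- repde(sim$x, score = "pd", init_step = 100)
  expect_identical(de_genes(f1, "pd"), de_genes(f2, "pd"))
  expect_identical(f1$fits$pd$selection$selected, f2$fits$pd$selection$selected)
})

test_that("every DE gene direction traces back to the selected pairs' rankings", {
  sim <- simulate_expression(sim_config(n_genes = 600, n_high = 60, n_low = 60,
                                        seed = 12))
  fit <- repde(sim$x, score = "pd", init_step = 100)
  de <- de_genes(fit, "pd")
  ranked <- fit$fits$pd$selection$ranked[fit$fits$pd$selection$selected$pair_id]
  for (i in seq_len(nrow(de))) {
    g <- de$gene_id[i]
    in_lists <- vapply(ranked, function(r) g %in% r$gene_id, logical(1L))
    expect_gte(sum(in_lists), 2L)  # present in both lists of at least one duo
  }
})

test_that("the command-line interface runs the pipeline and writes its artifacts", {
  cli <- system.file("cli", "repde.R", package = "repde")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  dir <- withr::local_tempdir()
  st <- system2(rscript, c(cli, "simulate", "--out-dir", shQuote(dir),
                           "--n-genes", "300", "--n-high", "30", "--n-low", "30",
                           "--seed", "3"), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "matrix.tsv")))
  expect_true(file.exists(file.path(dir, "annotation.tsv")))
  outdir <- file.path(dir, "out")
  log <- system2(rscript, c(cli, "run", "--matrix", shQuote(file.path(dir, "matrix.tsv")),
                            "--annotation", shQuote(file.path(dir, "annotation.tsv")),
                            "--out-dir", shQuote(outdir), "--score", "pd",
                            "--init-step", "50", "--top-n", "100"),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(outdir, "de_pd.tsv")))
  expect_true(file.exists(file.path(outdir, "pairs_pd.tsv")))
  expect_true(file.exists(file.path(outdir, "manifest.json")))
  manifest <- jsonlite::fromJSON(file.path(outdir, "manifest.json"))
  de <- utils::read.delim(file.path(outdir, "de_pd.tsv"))
  expect_equal(manifest$counts$pd, nrow(de))
  expect_gt(nrow(de), 0L)
  # truth recovered on this small instance: planted directions all correct
  truth <- utils::read.delim(file.path(dir, "truth.tsv"))
  tmap <- setNames(truth$truth, truth$gene_id)
  hit <- de$gene_id[tmap[de$gene_id] != "null"]
  expect_true(all(de$direction[match(hit, de$gene_id)] == tmap[hit]))
})
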