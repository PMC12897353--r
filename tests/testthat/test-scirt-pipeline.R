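test_that("build_schedule reproduces the worked examples", {
  s <- build_schedule(430, 5)
  expect_equal(s$mean_number, 6)
  expect_equal(s$times, c(2, 4, 8, 16, 32, 64))
  expect_equal(s$eec, 77)
  expect_equal(s$p_schedule[1:5], 1 / c(2, 4, 8, 16, 32))
  expect_equal(s$p_schedule[6], 5 / 430)  # flat top layer

  expect_equal(build_schedule(29, 7)$mean_number, 2)
  s84 <- build_schedule(8, 4)
  expect_equal(s84$mean_number, 1)
  expect_equal(s84$times, 2)
  expect_error(build_schedule(5, 5), "exceed")
  expect_error(build_schedule(7, 4), "no layering")
})

test_that("layer count follows floor(log2(y/nc)) over a small exhaustive range", {
  for (nc in 2:6) {
    for (y in seq(2 * nc, 200, by = 7)) {
      expect_equal(build_schedule(y, nc)$mean_number, floor(log2(y / nc)),
                   info = sprintf("y=%d nc=%d", y, nc))
    }
  }
})

test_that("the p schedule decreases strictly down to the flat top layer", {
  for (y in c(64, 150, 430)) {
    for (nc in c(2, 5)) {
      p <- build_schedule(y, nc)$p_schedule
      expect_true(all(diff(p) < 0))
    }
  }
})

test_that("RE = 0 makes the pipeline pure NMF denoising of the input", {
  m <- random_expr(12, 8, seed = 2)
  res <- run_scirt(m, nc = 3, re = 0, seed = 5)
  expect_equal(dim(res$high_dim), dim(m))
  expect_true(all(res$per_layer_rms >= 0))
  # imputation identity => first layer residual equals raw-vs-NMF residual
  set.seed(5)
  fit1 <- nmf_factorize(m, k = 3)
  expect_equal(res$per_layer_rms[1],
               sqrt(mean((unclass(m) - reconstruct(fit1))^2)),
               tolerance = 1e-10)
})

test_that("pipeline output shapes, non-negativity and residual contract hold", {
  sim <- simulate_counts(n_cells = 36, n_genes = 50, n_clusters = 3, seed = 3)
  res <- run_scirt(sim$matrix, nc = 3, seed = 9)
  expect_equal(dim(res$high_dim), dim(sim$matrix))
  expect_equal(ncol(res$low_dim), 3)
  expect_equal(nrow(res$low_dim), 36)
  expect_true(all(unclass(res$high_dim) >= 0))
  expect_true(all(res$low_dim >= 0))
  expect_length(res$per_layer_rms, res$schedule$mean_number)
  expect_true(all(is.finite(res$per_layer_rms)))
  expect_equal(rownames(res$low_dim), cell_ids(sim$matrix))
})

test_that("the whole pipeline is deterministic under a master seed", {
  sim <- simulate_counts(n_cells = 24, n_genes = 30, n_clusters = 2, seed = 4)
  a <- run_scirt(sim$matrix, nc = 2, seed = 123)
  b <- run_scirt(sim$matrix, nc = 2, seed = 123)
  expect_identical(unclass(a$high_dim), unclass(b$high_dim))
  expect_identical(a$low_dim, b$low_dim)
  expect_identical(a$per_layer_rms, b$per_layer_rms)
  c2 <- run_scirt(sim$matrix, nc = 2, seed = 124)
  expect_false(identical(a$low_dim, c2$low_dim))
})

test_that("cluster separation sharpens across layers on two-group data", {
  sep_ratio <- function(x, lab) {
    d <- as.matrix(dist(unclass(x)))
    within <- mean(d[lab == 1, lab == 1][upper.tri(d[lab == 1, lab == 1])]) +
      mean(d[lab == 2, lab == 2][upper.tri(d[lab == 2, lab == 2])])
    between <- mean(d[lab == 1, lab == 2])
    between / (within / 2)
  }
  improves <- sapply(1:10, function(s) {
    sim <- simulate_counts(n_cells = 32, n_genes = 60, n_clusters = 2,
                           effect_size = 8, seed = s)
    lab <- as.integer(factor(sim$labels))
    res <- run_scirt(sim$matrix, nc = 2, seed = s, keep_layers = TRUE)
    ratios <- c(sep_ratio(sim$matrix, lab),
                sapply(res$layer_matrices, sep_ratio, lab = lab))
    tail(ratios, 1) >= head(ratios, 1)
  })
  expect_gte(sum(improves), 8)
})

test_that("tidy and glance summarise the layer schedule and result", {
  sim <- simulate_counts(n_cells = 20, n_genes = 24, n_clusters = 2, seed = 6)
  res <- run_scirt(sim$matrix, nc = 2, seed = 2)
  td <- tidy(res)
  expect_named(td, c("layer", "times", "p", "rms_residual"))
  expect_equal(nrow(td), res$schedule$mean_number)
  gl <- glance(res)
  expect_equal(gl$n_cells, 20)
  expect_equal(gl$k, 2)
})

test_that("cli_impute writes matrices, layer log and manifest; bad input fails", {
  skip_if_not_installed("optparse")
  dir <- withr::local_tempdir()
  sim <- simulate_counts(n_cells = 20, n_genes = 25, n_clusters = 2, seed = 8)
  input <- file.path(dir, "counts.csv")
  write_matrix(sim$matrix, input)  # genes_by_cells on disk
  prefix <- file.path(dir, "run1")

  status <- cli_impute(c("--input", input, "--clusters", "2",
                         "--seed", "7", "--out-prefix", prefix))
  expect_equal(status, 0L)
  expect_true(all(file.exists(paste0(prefix, c(".highdim", ".lowdim",
                                               ".layers.log", ".manifest.json")))))
  manifest <- jsonlite::read_json(paste0(prefix, ".manifest.json"))
  expect_equal(manifest$seed, 7)
  expect_equal(manifest$n_cells, 20)

  # identical reruns reproduce byte-identical outputs
  prefix2 <- file.path(dir, "run2")
  cli_impute(c("--input", input, "--clusters", "2",
               "--seed", "7", "--out-prefix", prefix2))
  expect_identical(readLines(paste0(prefix, ".highdim")),
                   readLines(paste0(prefix2, ".highdim")))
  expect_identical(readLines(paste0(prefix, ".lowdim")),
                   readLines(paste0(prefix2, ".lowdim")))

  expect_equal(suppressMessages(
    cli_impute(c("--input", file.path(dir, "missing.csv"),
                 "--clusters", "2", "--out-prefix", prefix))
  ), 1L)
  expect_equal(suppressMessages(cli_impute(character())), 1L)
})

test_that("cli_simulate and cli_evaluate round-trip through files", {
  skip_if_not_installed("optparse")
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "sim")
  status <- cli_simulate(c("--cells", "24", "--genes", "30", "--clusters", "2",
                           "--dropout", "0.2", "--seed", "3",
                           "--out-prefix", prefix))
  expect_equal(status, 0L)
  m <- read_matrix(paste0(prefix, ".counts.csv"))
  expect_equal(dim(m), c(24L, 30L))
  labs <- read_labels(paste0(prefix, ".labels.txt"))
  expect_length(labs, 24)

  out <- file.path(dir, "metrics.tsv")
  status <- cli_evaluate(c("--matrix", paste0(prefix, ".counts.csv"),
                           "--labels", paste0(prefix, ".labels.txt"),
                           "--truth", paste0(prefix, ".labels.txt"),
                           "--metrics", "ari,nmi,sc,dbi", "--out", out))
  expect_equal(status, 0L)
  tab <- read.delim(out)
  expect_equal(tab$value[tab$metric == "ari"], 1)
  expect_equal(tab$value[tab$metric == "nmi"], 1)
})
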