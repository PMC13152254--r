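test_that("normalize_rna implements log1p(count / total * scale)", {
  m <- omics_matrix(matrix(c(1, 1, 2), 1, 3), modality = "rna")
  out <- normalize_rna(m)
  expect_equal(as.numeric(out$values),
               log1p(c(2500, 2500, 5000)), tolerance = 1e-12)
  expect_equal(as.numeric(out$values), c(7.8245, 7.8245, 8.5173),
               tolerance = 1e-4)
  ## zero-count cell stays an all-zero row, with a warning
  m2 <- omics_matrix(matrix(c(0, 0, 0, 1, 2, 3), 2, 3, byrow = TRUE),
                     modality = "rna")
  expect_warning(out2 <- normalize_rna(m2), "zero total")
  expect_equal(as.numeric(out2$values[1, ]), c(0, 0, 0))
  ## negative input rejected
  bad <- omics_matrix(matrix(1, 2, 2), modality = "rna", normalized = TRUE)
  bad$values[1, 1] <- -1
  expect_error(normalize_rna(bad), class = "hamgcn_invalid_input")
})

test_that("scale_features standardizes columns and zeroes constants", {
  m <- omics_matrix(cbind(c(1, 2, 3), c(5, 5, 5)), modality = "rna",
                    normalized = TRUE)
  out <- scale_features(m)
  expect_equal(out$values[, 1], (c(1, 2, 3) - 2) / sd(c(1, 2, 3)),
               ignore_attr = TRUE)
  expect_equal(as.numeric(out$values[, 2]), c(0, 0, 0))
  set.seed(5)
  r <- omics_matrix(matrix(rnorm(200, 3, 2), 20, 10), modality = "rna",
                    normalized = TRUE)
  sr <- scale_features(r)$values
  expect_true(all(abs(colMeans(sr)) < 1e-8))
  expect_equal(unname(apply(sr, 2, sd)), rep(1, 10), tolerance = 1e-8)
})

test_that("select_hvg ranks by standardized variance, deterministically", {
  set.seed(11)
  v <- matrix(5 + abs(rnorm(600, 0, 0.05)), 30, 20)   # variance ~ 0
  v[, 7] <- pmax(rnorm(30, 5, sqrt(10)), 0)  # dominant variance, same mean
  m <- omics_matrix(v, modality = "rna")
  sel <- select_hvg(m, 1)
  expect_equal(sel$selected_ids, m$feature_ids[7])
  expect_error(select_hvg(m, 21), "exceeds")
  ## permutation invariance of the ranking
  perm <- sample(20)
  mp <- omics_matrix(v[, perm], feature_ids = m$feature_ids[perm],
                     modality = "rna")
  s1 <- select_hvg(m, 5)$selected_ids
  s2 <- select_hvg(mp, 5)$selected_ids
  expect_setequal(s1, s2)
  ## bit-identical across repeated calls
  expect_identical(select_hvg(m, 5), select_hvg(m, 5))
})

test_that("qc_filter_atac keeps boundary cells and drops failures", {
  qc <- tibble::tibble(
    nucleosome_signal = c(2.5, 1.0, 2.0, 1.5),
    tss_enrichment = c(3.0, 1.5, 2.0, 4.0))
  expect_equal(qc_filter_atac(qc), c(FALSE, FALSE, TRUE, TRUE))
  qc$nucleosome_signal[4] <- NA
  expect_warning(keep <- qc_filter_atac(qc), "missing")
  expect_false(keep[4])
})

test_that("tfidf_transform matches a scalar double-loop oracle", {
  ## hand example: N = 2 cells, df = 1 peak -> IDF = log(3)
  m <- omics_matrix(matrix(c(2, 0, 1, 1), 2, 2, byrow = TRUE),
                    modality = "atac")
  out <- tfidf_transform(m)
  expect_equal(out$values[1, 1], log1p(1 * log(1 + 2 / 2)))
  expect_equal(out$values[1, 2], 0)     # zero count -> exactly 0
  expect_equal(out$values[2, 1], log1p(0.5 * log(1 + 2 / 2)))
  expect_equal(out$values[2, 2], log1p(0.5 * log(1 + 2 / 1)))
  ## random matrices against an independent scalar-loop implementation
  set.seed(42)
  for (rep in 1:3) {
    v <- matrix(rpois(600, 0.8), 20, 30)
    v[1, ] <- pmax(v[1, ], 1)           # avoid zero-total warning
    om <- omics_matrix(v, modality = "atac")
    got <- tfidf_transform(om)$values
    n <- nrow(v)
    want <- v * 0
    for (i in seq_len(n)) {
      for (j in seq_len(ncol(v))) {
        tf <- v[i, j] / sum(v[i, ])
        df <- sum(v[, j] > 0)
        idf <- if (df > 0) log(1 + n / df) else 0
        want[i, j] <- log(1 + tf * idf)
      }
    }
    expect_equal(got, want, tolerance = 1e-10, ignore_attr = TRUE)
  }
  ## determinism
  om <- omics_matrix(matrix(rpois(60, 2) + 1, 6, 10), modality = "atac")
  expect_identical(tfidf_transform(om), tfidf_transform(om))
})

test_that("lsi_reduce captures rank and improves monotonically", {
  set.seed(3)
  u <- matrix(rnorm(40), 20, 2)
  v <- matrix(rnorm(16), 8, 2)
  x <- u %*% t(v)                        # rank 2
  s1 <- lsi_reduce(x, 2)
  rec <- s1 %*% t(attr(s1, "v"))
  expect_equal(rec, x, tolerance = 1e-8, ignore_attr = TRUE)
  ## reconstruction error non-increasing in component count
  xn <- x + matrix(rnorm(160, 0, 0.5), 20, 8)
  errs <- vapply(1:5, function(k) {
    s <- lsi_reduce(xn, k)
    sum((s %*% t(attr(s, "v")) - xn)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
  expect_error(lsi_reduce(xn, 9), "exceeds")
  expect_identical(lsi_reduce(xn, 3), lsi_reduce(xn, 3))
})

test_that("wilcoxon_de matches wilcox.test and only sees training cells", {
  set.seed(21)
  n <- 40
  v <- matrix(rnorm(n * 6), n, 6)
  grp <- rep(c("a", "b"), each = n / 2)
  v[grp == "b", 1] <- v[grp == "b", 1] + 10   # disjoint ranges
  v[, 2] <- 1                                  # constant everywhere
  m <- omics_matrix(v, modality = "rna", normalized = TRUE)
  res <- wilcoxon_de(m, grp, rep(TRUE, n))
  expect_true(m$feature_ids[1] %in% res$selected_ids)
  expect_false(m$feature_ids[2] %in% res$selected_ids)
  ## p-values agree with the base-R oracle (normal approx, tie-corrected)
  for (j in c(1, 3, 4)) {
    ref <- stats::wilcox.test(v[grp == "a", j], v[grp == "b", j],
                              exact = FALSE, correct = TRUE)$p.value
    expect_equal(res$stats$p_value[j], ref, tolerance = 1e-10)
  }
  ## leakage guard: corrupting non-training cells changes nothing
  train <- seq_len(n) <= 30
  r1 <- wilcoxon_de(m, grp, train)
  v2 <- v
  v2[!train, ] <- matrix(rnorm(10 * 6, 50, 100), 10, 6)
  m2 <- omics_matrix(v2, modality = "rna", normalized = TRUE)
  r2 <- wilcoxon_de(m2, grp, train)
  expect_identical(r1$selected_ids, r2$selected_ids)
  ## single-group input errors
  expect_error(wilcoxon_de(m, rep("a", n), rep(TRUE, n)), "two groups")
})

test_that("wilcoxon_de controls false positives under label permutation", {
  set.seed(77)
  n <- 60; f <- 200
  v <- matrix(rnorm(n * f), n, f)
  m <- omics_matrix(v, modality = "rna", normalized = TRUE)
  grp <- rep(c("a", "b"), each = n / 2)
  hits <- vapply(1:50, function(i) {
    gp <- sample(grp)
    length(wilcoxon_de(m, gp, rep(TRUE, n), alpha = 0.05)$selected_ids)
  }, numeric(1))
  ## BH at alpha on null data: expected selections well below alpha * F
  expect_lt(mean(hits), 0.05 * f)
})

test_that("normalize + scale commute with cell-order permutation", {
  set.seed(9)
  v <- matrix(rpois(300, 4) + 1, 15, 20)
  m <- omics_matrix(v, modality = "rna")
  out <- scale_features(normalize_rna(m))$values
  perm <- sample(15)
  mp <- omics_matrix(v[perm, ], cell_ids = m$cell_ids[perm],
                     modality = "rna")
  outp <- scale_features(normalize_rna(mp))$values
  expect_equal(outp, out[perm, ], tolerance = 1e-12)
})

test_that("feature selections round-trip through the id-list format", {
  dir <- withr::local_tempdir()
  sel <- feature_selection(c("g3", "g1", "g7"), method = "wilcoxon_de",
                           derived_from = paste0("c", 1:5))
  p <- file.path(dir, "sel.txt")
  write_feature_selection(sel, p)
  back <- read_feature_selection(p)
  expect_identical(back$selected_ids, sel$selected_ids)
  expect_identical(back$method, "wilcoxon_de")
  side <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
  expect_equal(side$n_train, 5)
})

test_that("omics matrices round-trip through MTX and TSV", {
  dir <- withr::local_tempdir()
  m <- small_multiome()$rna
  m <- subset_omics(m, cells = 1:15, features = 1:10)
  write_omics(m, file.path(dir, "mtx"), format = "mtx")
  back <- read_omics(file.path(dir, "mtx"), modality = "rna")
  expect_equal(back$values, m$values, ignore_attr = TRUE)
  expect_equal(back$cell_ids, m$cell_ids)
  tsv <- file.path(dir, "m.tsv")
  write_omics(m, tsv, format = "tsv")
  back2 <- read_omics(tsv, modality = "rna")
  expect_equal(back2$values, m$values, ignore_attr = TRUE)
})
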