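test_that("1 Mb binning assigns sites by start and conserves counts", {
  sizes <- c(chr1 = 3.5e6, chr2 = 1e6)
  sites <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                      start = c(1500000, 1999000, 200, 5),
                      end = c(1502000, 2001000, 2200, 2005))
  b <- bin_1mb(sites, sizes, "chr1")
  expect_length(b, 4)             # ceiling(3.5e6 / 1e6)
  expect_equal(unname(b), c(1, 2, 0, 0))  # boundary-straddler binned by start
  expect_equal(sum(b), 3)         # trans site ignored
  expect_equal(sum(bin_1mb(sites[0, ], sizes, "chr1")), 0)
  bad <- data.frame(chrom = "chr1", start = 4e6, end = 4e6 + 2000)
  expect_error(bin_1mb(bad, sizes, "chr1"), "beyond")
})

test_that("correlation clustering handles self, anti and degenerate profiles", {
  x <- c(1, 3, 2, 5, 4, 8)
  res <- correlation_cluster(list(a = x, b = x, c = -x))
  expect_equal(res$correlation["a", "b"], 1)
  expect_equal(res$correlation["a", "c"], -1)
  # degenerate profile is NA and excluded from the dendrogram
  res2 <- correlation_cluster(list(a = x, b = x + 1, z = rep(2, 6)))
  expect_true(all(is.na(res2$correlation["z", ])))
  expect_false("z" %in% res2$order)
  expect_true(all(c("a", "b") %in% res2$order))
})

test_that("replicate correlation reproduces cor() on 1 Mb site profiles", {
  sizes <- c(chrX = 4e6)
  mk_calls <- function(sig_starts) {
    starts <- seq(0, 4e6 - 2000, by = 2000)
    df <- data.frame(chrom = "chrX", start = starts, end = starts + 2000,
                     window_id = paste0("chrX:", starts),
                     significant = starts %in% sig_starts)
    structure(df, window_size = 2000L,
              viewpoint = structure(list(name = "v", chrom = "chrX",
                                         position = 0L, fragment_index = 1L),
                                    class = "viewpoint"),
              class = c("interaction_calls", "data.frame"))
  }
  a <- mk_calls(c(0, 2000, 1e6, 3e6))        # bins 1,1,1,0,1 -> (2,1,0,1)
  b <- mk_calls(c(0, 1e6, 1.2e6, 2e6))       # bins (1,2,1,0)
  r <- replicate_correlation(a, b, sizes)
  expect_equal(r$pearson, stats::cor(c(2, 1, 0, 1), c(1, 2, 1, 0)))
  expect_identical(r$passes_corr_gate, r$pearson > 0.4)
  # a constant profile has no defined correlation and fails the gate
  const <- mk_calls(numeric(0))
  expect_true(is.na(replicate_correlation(a, const, sizes)$pearson))
  expect_false(replicate_correlation(a, const, sizes)$passes_corr_gate)
})

test_that("replicates pair together in the dendrogram of planted profiles", {
  # condition-specific enhancers in distinct 1 Mb bins give each muscle its
  # own binned profile; replicates of a condition should cluster together
  paired <- vapply(1:8, function(s) {
    cfg <- tiny_sim(
      seed = s, n_reads = 1e5,
      chrom_sizes = c(chr1 = 5e6, chr2 = 2e5),
      viewpoint = list(chrom = "chr1", position = 2.5e6),
      planted = list(
        planted_enhancer("chr1", 5e5, effect = c(quadriceps = 8, soleus = 1)),
        planted_enhancer("chr1", 1.4e6, effect = c(quadriceps = 8, soleus = 1)),
        planted_enhancer("chr1", 3.6e6, effect = c(quadriceps = 1, soleus = 8)),
        planted_enhancer("chr1", 4.5e6, effect = c(quadriceps = 1, soleus = 8))))
    gen <- make_genome(cfg)
    truth <- sim_truth(cfg, gen$fmap)
    vp <- truth$viewpoint
    prof <- list()
    for (cond in cfg$conditions) for (r in 1:2) {
      sm <- simulate_sample(cfg, gen$fmap, truth, cond, r)
      calls <- call_interactions(window_rpm(filter_invalid(sm, vp), gen$fmap),
                                 vp, fmap = gen$fmap)
      prof[[paste0(cond, r)]] <-
        bin_1mb(calls[calls$significant, ], cfg$chrom_sizes, vp$chrom)
    }
    hc <- correlation_cluster(prof)$hclust
    m <- stats::cutree(hc, k = 2)
    m[["quadriceps1"]] == m[["quadriceps2"]] &&
      m[["soleus1"]] == m[["soleus2"]] &&
      m[["quadriceps1"]] != m[["soleus1"]]
  }, logical(1))
  expect_gte(mean(paired), 0.75)
})

test_that("PCA is centred, sign-fixed and separates planted conditions", {
  x <- matrix(rnorm(40), nrow = 10,
              dimnames = list(NULL, paste0("s", 1:4)))
  p <- pca_profiles(x)
  expect_equal(sum(p$explained), 1)
  # duplicated samples coincide in PC space
  y <- cbind(x, s5 = x[, 1])
  p2 <- pca_profiles(y)
  expect_equal(p2$coordinates["s1", ], p2$coordinates["s5", ],
               tolerance = 1e-8)
  expect_error(pca_profiles(matrix(1, 3, 3)), "constant")
  # largest-magnitude loading of each component is positive
  for (j in seq_len(ncol(p$loadings))) {
    expect_gte(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
})

test_that("overlap summaries implement inclusion-exclusion exactly", {
  o <- overlap_sets(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_equal(o$shared, 2)
  expect_equal(o$union, 4)
  expect_equal(o$shared_fraction, 0.5)
  expect_equal(sum(o$partition), o$union)
  same <- overlap_sets(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(same$shared_fraction, 1)
  three <- overlap_sets(list(A = letters[1:4], B = letters[3:6],
                             C = letters[4:8]))
  expect_equal(three$shared, 1)           # "d"
  expect_equal(sum(three$partition), three$union)
  expect_error(overlap_sets(list(A = "a", B = "b", C = "c", D = "d")),
               "2 or 3")
})

test_that("differential analysis has exact null and closed-form spike behaviour", {
  # identical conditions: zero SDIS, log2FC identically zero
  m <- matrix(rpois(80, 20), nrow = 20)
  counts <- cbind(m[, 1:2], m[, 1:2])
  colnames(counts) <- c("a1", "a2", "b1", "b2")
  rownames(counts) <- paste0("w", 1:20)
  d0 <- differential(counts, c("A", "A", "B", "B"))
  expect_equal(sum(d0$sdis), 0)
  expect_equal(max(abs(d0$log2fc)), 0)
  expect_true(all(d0$pvalue == 1))

  # (0,0) vs (100,100) on a flat background is a certain SDIS; verify the
  # Wald machinery against hand-computed values of the specified test
  flat <- matrix(10, nrow = 50, ncol = 4,
                 dimnames = list(paste0("w", 1:50),
                                 c("a1", "a2", "b1", "b2")))
  flat[1, ] <- c(0, 0, 100, 100)
  d <- differential(flat, c("A", "A", "B", "B"))
  expect_true(d$sdis[1])
  expect_false(any(d$sdis[-1]))
  # hand computation: size factors 1 (flat rows dominate the median),
  # lfc = log2(101 / 1), dispersion at the floor, Wald z as specified
  expect_equal(d$log2fc[1], log2(101), tolerance = 1e-6)
  v_b <- (100 + 0.01 * 100^2) / 2
  se <- sqrt(v_b / 101^2) / log(2)
  expect_equal(d$se[1], se, tolerance = 1e-6)
  expect_equal(d$pvalue[1], 2 * pnorm(-abs(log2(101) / se)),
               tolerance = 1e-6)

  expect_error(differential(flat, c("A", "B", "B", "B")), "2 replicates")
  expect_error(differential(flat, c("A", "A", "A", "A")), "two conditions")
})

test_that("label swap negates log2FC and preserves p-values", {
  set.seed(77)
  counts <- matrix(rnbinom(200, mu = 30, size = 5), nrow = 50,
                   dimnames = list(paste0("w", 1:50),
                                   c("a1", "a2", "b1", "b2")))
  fwd <- differential(counts, c("A", "A", "B", "B"))
  rev <- differential(counts[, c(3, 4, 1, 2)], c("B", "B", "A", "A"))
  expect_equal(rev$log2fc, -fwd$log2fc, tolerance = 1e-12)
  expect_equal(rev$pvalue, fwd$pvalue, tolerance = 1e-12)
  expect_equal(rev$padj, fwd$padj, tolerance = 1e-12)
})

test_that("differential log2FC tracks an independent DESeq2 analysis", {
  set.seed(42)
  n <- 200
  mu_a <- rgamma(n, 2, scale = 20)
  fc <- rep(1, n); fc[1:20] <- 8
  counts <- cbind(
    a1 = rnbinom(n, mu = mu_a, size = 20),
    a2 = rnbinom(n, mu = mu_a, size = 20),
    b1 = rnbinom(n, mu = mu_a * fc, size = 20),
    b2 = rnbinom(n, mu = mu_a * fc, size = 20))
  rownames(counts) <- paste0("w", 1:n)
  ours <- differential(counts, c("A", "A", "B", "B"))

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      counts, S4Vectors::DataFrame(condition = factor(c("A", "A", "B", "B"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds, contrast = c("condition", "B", "A"))
  })
  keep <- !is.na(res$log2FoldChange)
  expect_gt(cor(ours$log2fc[keep], res$log2FoldChange[keep]), 0.9)
  # the planted eight-fold windows are recovered by both routes
  expect_true(all(ours$sdis[1:20]))
  expect_true(all(res$padj[1:20] < 0.05, na.rm = TRUE))
})

test_that("mean absolute log2FC summarises selections correctly", {
  d <- structure(data.frame(window_id = c("a", "b", "c"),
                            log2fc = c(1, -3, 0),
                            sdis = c(TRUE, TRUE, FALSE)),
                 class = c("differential_result", "data.frame"))
  expect_equal(mean_abs_lfc(d), 4 / 3)
  expect_equal(mean_abs_lfc(d, sdis_only = TRUE), 2)
  d$sdis <- FALSE
  expect_error(mean_abs_lfc(d, sdis_only = TRUE), "empty selection")

  # selection effect: SDIS average dominates the overall average
  set.seed(5)
  counts <- matrix(rnbinom(400, mu = 25, size = 10), nrow = 100,
                   dimnames = list(paste0("w", 1:100),
                                   c("a1", "a2", "b1", "b2")))
  counts[1:10, 3:4] <- counts[1:10, 3:4] * 10
  dd <- differential(counts, c("A", "A", "B", "B"))
  if (any(dd$sdis)) {
    expect_gte(mean_abs_lfc(dd, sdis_only = TRUE), mean_abs_lfc(dd))
  }
})
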