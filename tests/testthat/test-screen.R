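bed <- function(chrom, start, end, name = NULL) {
  df <- data.frame(chrom = chrom, start = start, end = end)
  if (!is.null(name)) df$name <- name
  df
}

flat_signal <- function(chrom, len, value = 1, bin = 100) {
  starts <- seq(0, len - bin, by = bin)
  data.frame(chrom = chrom, start = starts, end = starts + bin,
             value = value)
}

test_that("the screen applies its five rules in order", {
  sites <- bed("chr1", c(0, 2000, 4000, 6000, 8000) * 1L,
               c(2000, 4000, 6000, 8000, 10000))
  sites$window_id <- paste0("chr1:", sites$start)
  k27 <- bed("chr1", c(100, 4100, 6100), c(900, 4900, 6900))
  atac <- bed("chr1", c(2100, 4100, 6100), c(2900, 4900, 6900))
  prom <- bed("chr1", 6500, 7500)
  sig <- flat_signal("chr1", 10000)

  out <- screen_enhancers(sites, k27, atac, prom, sig,
                          viewpoint_chrom = "chr1")
  # window 0 has H3K27ac only, window 2000 ATAC only -> both excluded;
  # window 6000 has both marks but a promoter -> excluded; 4000 survives
  expect_equal(out$region_start, 4000)
  expect_equal(out$region_end, 6000)
  # uniform signal: leftmost 1000 bp window by tie-break
  expect_equal(out$start, 4000)
  expect_equal(out$end, 5000)
  expect_false(out$zero_summit)

  # trans sites are dropped first; empty interactions are not an error
  trans <- bed("chr9", 0, 2000); trans$window_id <- "chr9:0"
  expect_equal(nrow(screen_enhancers(trans, k27, atac, prom, sig,
                                     viewpoint_chrom = "chr1")), 0)
  expect_equal(nrow(screen_enhancers(sites[0, ], k27, atac, prom, sig,
                                     viewpoint_chrom = "chr1")), 0)
  expect_error(screen_enhancers(sites, NULL, atac, prom, sig,
                                viewpoint_chrom = "chr1"), "missing")
})

test_that("adjacent surviving windows merge into one candidate region", {
  sites <- bed("chr1", c(4000, 6000), c(6000, 8000))
  k27 <- bed("chr1", 4500, 7500)
  atac <- bed("chr1", 4500, 7500)
  prom <- bed("chr1", 0, 100)
  sig <- flat_signal("chr1", 10000, value = 0)
  sig$value[sig$start >= 5500 & sig$start < 6500] <- 5
  out <- screen_enhancers(sites, k27, atac, prom, sig,
                          viewpoint_chrom = "chr1")
  expect_equal(nrow(out), 1)
  expect_equal(out$region_start, 4000)
  expect_equal(out$region_end, 8000)
  # the 1000 bp max-signal window sits on the signal plateau
  expect_equal(out$start, 5500)
  expect_equal(out$end, 6500)
  expect_lte(out$end - out$start, 1000)
})

test_that("screen is monotone in its peak inputs", {
  set.seed(404)
  sites <- bed("chr1", seq(0, 18000, by = 2000), seq(2000, 20000, by = 2000))
  sig <- flat_signal("chr1", 20000)
  k27 <- bed("chr1", c(300, 8300), c(1700, 9700))
  atac <- bed("chr1", c(300, 8300, 12300), c(1700, 9700, 13700))
  prom <- bed("chr1", 19000, 19500)
  base <- screen_enhancers(sites, k27, atac, prom, sig,
                           viewpoint_chrom = "chr1")
  # adding an H3K27ac peak can only add candidates
  more <- rbind(k27, bed("chr1", 12300, 13700))
  grown <- screen_enhancers(sites, more, atac, prom, sig,
                            viewpoint_chrom = "chr1")
  expect_true(all(base$region_start %in% grown$region_start))
  expect_gte(nrow(grown), nrow(base))
  # adding promoters can only remove candidates
  prom2 <- rbind(prom, bed("chr1", 8500, 8600))
  shrunk <- screen_enhancers(sites, more, atac, prom2, sig,
                             viewpoint_chrom = "chr1")
  expect_true(all(shrunk$region_start %in% grown$region_start))
  expect_lte(nrow(shrunk), nrow(grown))
})

test_that("max-signal window matches exhaustive scan on random fixtures", {
  set.seed(99)
  for (i in 1:60) {
    len <- sample(1500:4000, 1)
    n_runs <- sample(3:10, 1)
    starts <- sort(sample(0:(len - 60), n_runs))
    runs <- data.frame(chrom = "c", start = starts,
                       end = pmin(starts + sample(30:500, n_runs,
                                                  replace = TRUE), len),
                       value = sample(0:9, n_runs, replace = TRUE))
    runs <- runs[runs$end > runs$start, ]
    runs <- runs[!duplicated(runs$start), ]
    # de-overlap by clipping each run at the next start
    if (nrow(runs) > 1) {
      runs$end <- pmin(runs$end, c(runs$start[-1], len))
      runs <- runs[runs$end > runs$start, ]
    }
    cap <- sample(c(200, 500, 1000), 1)
    got <- max_signal_window(runs, "c", 0, len, width_cap = cap)
    want <- brute_max_signal_window(runs, "c", 0, len, cap)
    expect_equal(got$start, want$start)
    expect_equal(got$signal, want$signal)
  }
})

test_that("max-signal window edge cases follow the stated conventions", {
  sig <- flat_signal("c", 3000)
  # uniform signal over 3 kb: leftmost kb window
  w <- max_signal_window(sig, "c", 0, 3000)
  expect_equal(c(w$start, w$end), c(0, 1000))
  # region shorter than the cap: the whole region
  w2 <- max_signal_window(sig, "c", 100, 700)
  expect_equal(c(w2$start, w2$end), c(100, 700))
  # zero signal: leftmost window, flagged
  z <- max_signal_window(flat_signal("c", 3000, value = 0), "c", 0, 3000)
  expect_true(z$zero_summit)
  expect_equal(z$start, 0)
})

test_that("conservation annotation uses half-open one-bp overlap", {
  cand <- structure(bed("chr1", c(100, 2100, 4100), c(900, 2900, 4900)),
                    class = c("candidate_enhancers", "data.frame"))
  cons <- bed("chr1", c(850, 2900), c(950, 3000))  # second abuts candidate 2
  ann <- annotate_conservation(cand, cons)
  expect_equal(ann$conserved, c(TRUE, FALSE, FALSE))
  expect_equal(attr(ann, "conserved_fraction"), 1 / 3)
  none <- annotate_conservation(cand, cons[0, ])
  expect_equal(attr(none, "conserved_fraction"), 0)
})

test_that("printed genomic spans parse to the right widths", {
  r <- region_width("chr11:67,104,519–67,142,456")
  expect_equal(r$width_bp, 37937)
  expect_equal(r$width_kb, 38)
  expect_equal(region_width("chr1:0-1,000")$width_bp, 1000)
  expect_equal(region_width("chr1:0-1,000")$width_kb, 1)
  expect_error(region_width("chr1:5-5"), "exceed")
  expect_error(region_width("nonsense"), "cannot parse")
})

test_that("screened candidates recover planted enhancers and no decoys", {
  hits <- vapply(1:5, function(s) {
    cfg <- tiny_sim(seed = s)
    gen <- make_genome(cfg)
    truth <- sim_truth(cfg, gen$fmap)
    trk <- simulate_tracks(cfg, truth)
    vp <- truth$viewpoint
    calls <- lapply(1:2, function(r) {
      sm <- simulate_sample(cfg, gen$fmap, truth, "soleus", r)
      call_interactions(window_rpm(filter_invalid(sm, vp), gen$fmap), vp,
                        fmap = gen$fmap)
    })
    hf <- high_fidelity(calls[[1]], calls[[2]])
    out <- screen_enhancers(hf, trk$h3k27ac, trk$atac, trk$promoters,
                            trk$atac_signal, viewpoint_chrom = vp$chrom)
    nrow(out) == nrow(truth$planted) &&
      all(abs((out$start + out$end) / 2 - sort(truth$planted$summit)) <= 500)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
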