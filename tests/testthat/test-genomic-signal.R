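test_that("CPM normalization scales to one million and is stable", {
  tr <- coverage_track(list(chr1 = rep(1, 1e4), chr2 = rep(3, 1e4)))
  cpm <- cpm_normalize(tr)
  expect_equal(txkinetics:::track_total(cpm), 1e6)
  expect_equal(cpm$values$chr1[1], 1e6 / 4e4)
  # idempotent up to scaling: a second pass changes nothing
  expect_equal(cpm_normalize(cpm)$values, cpm$values)

  one <- coverage_track(list(chr1 = c(0, 200, 0)))
  expect_equal(cpm_normalize(one)$values$chr1, c(0, 1e6, 0))
  expect_error(cpm_normalize(coverage_track(list(chr1 = c(0, 0)))),
               "no signal")
  expect_error(coverage_track(list(chr1 = c(-1, 2))), "non-negative")
})

test_that("gene regions follow the fixed TSS/TES offsets", {
  g <- gene_annotation(data.frame(gene = "g1", contig = "chr1", strand = "+",
                                  tss = 10000, tes = 12000))
  rs <- define_regions(g)
  got <- rs[match(c("UAS", "promoter", "transcript", "terminator"),
                  rs$region), c("start", "end")]
  expect_equal(unname(as.matrix(got)),
               rbind(c(9500, 9849), c(9850, 10025),
                     c(10026, 11924), c(11925, 12150)))
  expect_equal(got$end - got$start + 1, c(350, 176, 1899, 226))
})

test_that("minus-strand regions are exact mirror images", {
  L <- 30000
  gp <- gene_annotation(data.frame(gene = "g", contig = "c", strand = "+",
                                   tss = 10000, tes = 12000))
  gm <- gene_annotation(data.frame(gene = "g", contig = "c", strand = "-",
                                   tss = L + 1 - 10000, tes = L + 1 - 12000))
  rp <- define_regions(gp)
  rm_ <- define_regions(gm)
  for (reg in c("UAS", "promoter", "transcript", "terminator")) {
    p <- rp[rp$region == reg, ]
    m <- rm_[rm_$region == reg, ]
    expect_equal(m$start, L + 1 - p$end)
    expect_equal(m$end, L + 1 - p$start)
  }
})

test_that("too-short transcripts are excluded with a reason", {
  g <- gene_annotation(data.frame(gene = c("ok", "tiny"), contig = "c",
                                  strand = "+", tss = c(1000, 5000),
                                  tes = c(3000, 5050)))
  rs <- define_regions(g)
  expect_equal(unique(rs$gene), "ok")
  exc <- attr(rs, "excluded")
  expect_equal(exc$gene, "tiny")
  expect_match(exc$reason, "shorter")
})

test_that("region signal computes per-bp means and unit-sum fractions", {
  g <- gene_annotation(data.frame(gene = "g1", contig = "chr1", strand = "+",
                                  tss = 2000, tes = 4000))
  rs <- define_regions(g)
  uni <- coverage_track(list(chr1 = rep(2.5, 6000)), units = "CPMn")
  m <- region_signal(uni, rs)
  expect_equal(m$value, rep(2.5, 4))
  f <- region_signal(uni, rs, mode = "fraction-of-total")
  expect_equal(f$value, rep(0.25, 4))

  v <- numeric(6000)
  v[1850:2025] <- 1  # promoter only
  prom <- coverage_track(list(chr1 = v), units = "CPMn")
  fp <- region_signal(prom, rs, mode = "fraction-of-total")
  expect_equal(fp$value[fp$region == "promoter"], 1)
  expect_equal(sum(fp$value), 1)

  out <- gene_annotation(data.frame(gene = "far", contig = "chr1",
                                    strand = "+", tss = 5900, tes = 8000))
  expect_error(region_signal(uni, define_regions(out)), "far")
})

test_that("metagene reproduces segment-constant coverage exactly", {
  g <- gene_annotation(data.frame(gene = c("a", "b"), contig = "c",
                                  strand = c("+", "-"),
                                  tss = c(3000, 12000), tes = c(5000, 10500)))
  tr <- coverage_track(list(c = rep(4.2, 15000)), units = "CPMn")
  prof <- metagene(tr, g)
  expect_equal(nrow(prof), 300)
  expect_equal(prof$mean, rep(4.2, 300))
})

test_that("metagene length-normalizes: scaled genes give identical bins", {
  # same triangular relative profile painted over genes of different lengths
  L <- 30000
  v <- numeric(L)
  paint <- function(v, tss, tes) {
    n <- tes - tss + 1
    v[tss:tes] <- 1 - abs(2 * (seq_len(n) - 1) / (n - 1) - 1)
    v
  }
  v <- paint(v, 5000, 6999)   # 2000 bp
  v <- paint(v, 15000, 18999) # 4000 bp
  tr <- coverage_track(list(c = v), units = "CPMn")
  g <- gene_annotation(data.frame(gene = c("short", "long"), contig = "c",
                                  strand = "+", tss = c(5000, 15000),
                                  tes = c(6999, 18999)))
  both <- metagene(tr, g)
  single <- metagene(tr, g[1, ])
  tx <- both$segment == "transcript"
  expect_equal(both$mean[tx], single$mean[tx], tolerance = 1e-3)
  # single gene profile equals its own binned profile by construction
  expect_equal(attr(single, "n_genes"), 1)
})

test_that("metasite aligns, orients and excludes clipped sites", {
  v <- numeric(5000)
  v[1000] <- 12  # delta at a plus-strand site
  v[3000 - 40] <- 6  # offset -40 from a minus site lands at +40 after flip
  tr <- coverage_track(list(c = v), units = "CPMn")
  sites <- data.frame(contig = "c", pos = c(1000, 3000, 10), # third clipped
                      strand = c("+", "-", "+"))
  prof <- metasite(tr, sites, smooth = FALSE)
  expect_equal(attr(prof, "n_sites"), 2)
  expect_equal(prof$mean[prof$offset == 0], 6)   # 12 averaged over 2 sites
  expect_equal(prof$mean[prof$offset == 40], 3)  # mirrored minus-strand peak
  expect_equal(sum(prof$mean != 0), 2)

  flat <- metasite(coverage_track(list(c = rep(1.5, 5000)), units = "CPMn"),
                   sites)
  expect_true(all(abs(flat$mean - 1.5) < 1e-12))
  expect_error(metasite(tr, sites[0, ]), "no sites")
})

test_that("sliding-window smoothing uses truncated centered windows", {
  s <- smooth_signal(rep(7, 100))
  expect_true(all(s$value == 7))
  s2 <- smooth_signal(c(rep(0, 5), rep(10, 5)), window = 10, step = 5)
  expect_equal(s2$value[1], 5)    # first full window
  expect_equal(s2$value[2], 10)   # truncated tail window
  s3 <- smooth_signal(1:10, window = 4, step = 10)
  expect_equal(nrow(s3), 1)
  s4 <- smooth_signal(1:3, window = 10, step = 5)
  expect_equal(nrow(s4), 1)       # single truncated window
  expect_equal(s4$value, 2)
})

test_that("background subtraction is element-wise and sign-preserving", {
  a <- coverage_track(list(c = c(1, 2, 3)), units = "CPMn")
  b <- coverage_track(list(c = c(1, 5, 1)), units = "CPMn")
  d <- subtract_background(a, b)
  expect_equal(d$values$c, c(0, -3, 2))  # depletion retained, not clipped
  cnt <- coverage_track(list(c = c(1, 2, 3)), units = "counts")
  expect_error(subtract_background(a, cnt), "unit mismatch")
  short <- coverage_track(list(c = c(1, 2)), units = "CPMn")
  expect_error(subtract_background(a, short), "shapes differ")
})

test_that("expression filter applies the 50-count threshold inclusively", {
  g <- gene_annotation(data.frame(gene = c("a", "b", "c", "d"), contig = "x",
                                  strand = "+", tss = c(1, 101, 201, 301) * 10,
                                  tes = c(1, 101, 201, 301) * 10 + 2000,
                                  nascent = c(50, 49.9, 1000, NA)))
  kept <- filter_expressed(g)
  expect_equal(kept$gene, c("a", "c"))
  exc <- attr(kept, "excluded")
  expect_equal(exc$reason[exc$gene == "d"], "missing nascent count")
  empty <- filter_expressed(g[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("relative enrichment ratios and dispersion behave", {
  regions <- c("UAS", "promoter", "transcript", "utr3")
  ref <- matrix(runif(20, 1, 5), 5, 4,
                dimnames = list(paste0("g", 1:5), regions))
  same <- relative_region_enrichment(list(ref, ref, ref),
                                     list(ref, ref, ref))
  expect_equal(same$ratio, rep(1, 4))
  dbl <- relative_region_enrichment(list(2 * ref), list(ref))
  expect_equal(dbl$ratio, rep(2, 4))

  set.seed(5)
  facs <- lapply(1:3, function(i) ref * matrix(runif(20, 0.5, 1.5), 5, 4))
  noisy <- relative_region_enrichment(facs, list(ref, ref, ref))
  expect_true(all(noisy$se > 0))
  z <- enrichment_z(noisy, same)
  expect_true(all(is.finite(z$z)))
  expect_true(all(z$p >= 0 & z$p <= 1))

  zero <- ref; zero["g3", "promoter"] <- 0
  sk <- relative_region_enrichment(list(ref), list(zero))
  expect_equal(attr(sk, "skipped"), "g3")
})
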