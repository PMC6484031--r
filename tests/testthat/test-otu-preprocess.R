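test_that("filter_otus keeps exactly the OTUs at or above the threshold", {
  totals <- c(1100, 1150, 1199, 1200, 1201, 1300)
  counts <- rbind(totals - 500, rep(500, 6))
  tab <- tiny_otu_table(counts)
  kept <- filter_otus(tab, min_total = 1200)
  expect_equal(colSums(kept$counts), c(OTU004 = 1200, OTU005 = 1201,
                                       OTU006 = 1300))
  expect_equal(nrow(kept$counts), 2L)  # samples unchanged
  # min_total = 0 is the identity
  expect_equal(filter_otus(tab, 0)$counts, tab$counts)
  # all-zero OTUs always removed for positive thresholds
  counts0 <- cbind(counts, OTUZ = c(0L, 0L))
  expect_false("OTUZ" %in% colnames(filter_otus(tiny_otu_table(counts0),
                                                1)$counts))
  expect_warning(filter_otus(tab, 1e9), "no OTUs")
})

test_that("rarefy subsamples to exact depth and drops shallow samples", {
  set.seed(8)
  counts <- rbind(
    s1 = as.integer(rmultinom(1, 25000, c(0.5, 0.3, 0.15, 0.05))),
    s2 = as.integer(rmultinom(1, 9000, rep(0.25, 4))),
    s3 = as.integer(rmultinom(1, 10000, rep(0.25, 4))))
  tab <- tiny_otu_table(counts)
  expect_message(r <- rarefy(tab, depth = 10000, seed = 2), "dropped")
  expect_equal(unname(rowSums(r$counts)), c(10000, 10000))
  # a sample already exactly at depth is returned unchanged
  expect_equal(unname(r$counts[2, ]), unname(counts[3, ]))
  # subsample never exceeds the original counts
  expect_true(all(r$counts[1, ] <= counts[1, ]))
  # deterministic under a fixed seed
  r2 <- suppressMessages(rarefy(tab, depth = 10000, seed = 2))
  expect_identical(r$counts, r2$counts)
})

test_that("rarefaction preserves expected relative abundances", {
  counts <- matrix(as.integer(c(6000, 3000, 900, 100)), 1)
  tab <- tiny_otu_table(counts)
  props <- sapply(1:200, function(s) rarefy(tab, depth = 1000,
                                            seed = s)$counts[1, ] / 1000)
  target <- counts[1, ] / sum(counts)
  # hypergeometric mean proportion equals the source proportion; the SE
  # carries the finite-population correction for depth 1000 of 10000
  fpc <- sqrt((10000 - 1000) / (10000 - 1))
  mc_sem <- sqrt(target * (1 - target) / 1000) * fpc / sqrt(200)
  expect_true(all(abs(rowMeans(props) - target) < 3.5 * mc_sem + 1e-9))
})

test_that("filter then rarefy is equivariant under OTU relabeling", {
  set.seed(5)
  counts <- matrix(rpois(6 * 10, lambda = 300), 6, 10)
  tab <- tiny_otu_table(counts)
  perm <- sample(10)
  tab_p <- tiny_otu_table(counts[, perm])
  colnames(tab_p$counts) <- colnames(tab$counts)[perm]
  a <- rarefy(filter_otus(tab, 1500), depth = 1200, seed = 9)
  b <- rarefy(filter_otus(tab_p, 1500), depth = 1200, seed = 9)
  expect_equal(a$counts[, sort(colnames(a$counts))],
               b$counts[, sort(colnames(b$counts))])
})

test_that("to_relative returns unit-sum rows and preserves zeros", {
  tab <- tiny_otu_table(rbind(c(5000L, 5000L), c(10000L, 0L)))
  rel <- to_relative(tab)
  expect_equal(rel[1, ], c(OTU001 = 0.5, OTU002 = 0.5))
  expect_equal(rel[2, ], c(OTU001 = 1, OTU002 = 0))
  expect_equal(unname(rowSums(rel)), c(1, 1), tolerance = 1e-12)
  tab0 <- tiny_otu_table(rbind(c(1L, 1L), c(0L, 0L)))
  expect_error(to_relative(tab0), "zero-total")
})

test_that("build_W scales on the reference only, without leakage", {
  set.seed(4)
  counts <- matrix(rpois(40 * 6, 50), 40, 6)
  counts[, 6] <- 7L  # constant column
  tab <- tiny_otu_table(counts)
  ids <- rownames(tab$counts)
  sm_all <- build_W(tab)
  expect_equal(unname(colMeans(sm_all$W[, 1:5])), rep(0, 5),
               tolerance = 1e-12)
  expect_equal(unname(apply(sm_all$W[, 1:5], 2, sd)), rep(1, 5),
               tolerance = 1e-12)
  expect_true(sm_all$zero_variance[6])
  expect_equal(unname(sm_all$W[, 6]), rep(0, 40))

  ref <- ids[1:25]
  sm <- build_W(tab, reference = ref)
  # statistics computed on the reference rows only
  expect_equal(unname(colMeans(sm$W[1:25, 1:5])), rep(0, 5),
               tolerance = 1e-12)
  expect_equal(unname(sm$center[1:5]), unname(colMeans(counts[1:25, 1:5])))
  # a test sample equal to the reference mean profile maps to zero
  counts2 <- rbind(counts, round(colMeans(counts[1:25, ])))
  storage.mode(counts2) <- "integer"
  tab2 <- tiny_otu_table(counts2)
  sm2 <- build_W(tab2, reference = rownames(tab2$counts)[1:25])
  ref_mean_row <- (colMeans(counts[1:25, ]) - sm2$center) / sm2$scale
  expect_equal(unname(sm2$W[41, 1:5]),
               unname(((round(colMeans(counts[1:25, ])) - sm2$center) /
                         sm2$scale)[1:5]))
  expect_error(build_W(tab, reference = "nope"))
})

test_that("goods_coverage implements 1 - singletons/total", {
  counts <- rbind(c(rep(1L, 20), 9980L, rep(0L, 3)))
  tab <- tiny_otu_table(counts)
  expect_equal(unname(goods_coverage(tab)), 1 - 20 / 10000)
  tab2 <- tiny_otu_table(rbind(c(5L, 5L, 10L)))
  expect_equal(unname(goods_coverage(tab2)), 1)
  tab3 <- tiny_otu_table(rbind(c(1L, 1L, 1L)))
  expect_equal(unname(goods_coverage(tab3)), 0)
})
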