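test_that("positivity uses a strict threshold and half-up integer percent", {
  p <- positivityFraction(c(0.5, 1.2, 3, 0.9, 2), threshold = 1)
  expect_equal(p$k, 3L)
  expect_equal(p$n, 5L)
  expect_equal(p$percent, 60L)
  # values exactly at the threshold do not count
  expect_equal(positivityFraction(rep(1, 10), threshold = 1)$k, 0L)
  expect_error(positivityFraction(numeric(0)), "empty")
  expect_error(positivityPercent(5, 0), "n >= 1")
  expect_equal(positivityPercent(1, 8), 13L) # 12.5 rounds half-up
})

test_that("positivity percent reproduces the printed atlas fractions", {
  expect_equal(positivityPercent(96, 123), 78L)
  expect_equal(positivityPercent(113, 204), 55L)
  expect_equal(positivityPercent(29, 161), 18L)
  expect_equal(positivityPercent(8, 8), 100L)
})

test_that("positivity count is non-increasing in the threshold", {
  set.seed(30)
  v <- rlnorm(200, 1, 1)
  ks <- vapply(c(0, 0.5, 1, 2, 5, 10), function(th)
    positivityFraction(v, th)$k, integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("outlier flagging returns exactly the ids above threshold, sorted", {
  expect_equal(flagOutliers(c(1, 5, 3), c("b", "a", "c"), Inf), character(0))
  expect_equal(flagOutliers(c(1, 5, 3), c("b", "a", "c"), 0),
               c("a", "b", "c"))
  expect_equal(flagOutliers(c(100, 950, 20, 1200), paste0("s", 1:4), 900),
               c("s2", "s4"))
  expect_error(flagOutliers(1:3, "x", 1), "lengths differ")
})

test_that("proteasome summaries are subunit medians", {
  ps <- proteasomeSummary(10, 20, 30, 1, 2, 3)
  expect_equal(unname(ps["constitutive"]), 20)
  expect_equal(unname(ps["immuno"]), 2)
  expect_equal(unname(proteasomeSummary(7, 7, 7, 7, 7, 7)), c(7, 7))
  expect_equal(unname(proteasomeSummary(0, 0, 0, 5, 5, 5)), c(0, 5))
  expect_error(proteasomeSummary(-1, 0, 0, 0, 0, 0), "non-negative")
})

test_that("Spearman matches the independent average-rank oracle, with ties", {
  expect_equal(spearmanRho(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearmanRho(1:3, c(3, 2, 1))$rho, -1)
  x <- c(1, 2, 2, 4)
  y <- c(1, 3, 2, 4)
  expect_equal(spearmanRho(x, y)$rho, spearmanOracle(x, y))
  set.seed(31)
  for (i in 1:10) {
    a <- sample(1:6, 30, replace = TRUE) # heavy ties
    b <- a + sample(-2:2, 30, replace = TRUE)
    expect_equal(spearmanRho(a, b)$rho, spearmanOracle(a, b))
  }
  expect_error(spearmanRho(c(1, 1, 1), 1:3), "constant")
  expect_error(spearmanRho(1:4, 1:3), "lengths differ")
  expect_error(spearmanRho(1:2, 2:1), "at least 3")
})

test_that("Spearman is invariant under strictly increasing transforms", {
  set.seed(32)
  x <- rnorm(40)
  y <- x + rnorm(40)
  r0 <- spearmanRho(x, y)$rho
  expect_equal(spearmanRho(exp(x), y)$rho, r0)
  expect_equal(spearmanRho(x, y^3 + 5 * y)$rho, r0)
})

test_that("buildBodyMap aggregates medians, positivity and outliers per tissue", {
  cohort <- data.frame(
    sample = paste0("s", 1:6),
    tissue = rep(c("brain", "blood"), each = 3),
    classI_classical = c(10, 20, 30, 100, 1200, 300),
    hla_g = c(0.1, 0.2, 1.4, 2, 3, 0.5),
    stringsAsFactors = FALSE
  )
  bm <- buildBodyMap(cohort, positivityThreshold = 1,
                     outlierMetric = "classI_classical",
                     outlierThreshold = 900)
  med <- tissueMedians(bm)
  expect_equal(med$classI_classical[med$tissue == "brain"], 20)
  expect_equal(med$classI_classical[med$tissue == "blood"], 300)
  # medians lie between the per-tissue min and max
  expect_true(med$classI_classical[med$tissue == "blood"] >= 100 &&
              med$classI_classical[med$tissue == "blood"] <= 1200)
  pos <- tissuePositivity(bm)
  pg <- pos[pos$metric == "hla_g", ]
  expect_equal(pg$k[pg$tissue == "brain"], 1L)
  expect_equal(pg$percent[pg$tissue == "brain"], 33L)
  ol <- bodyMapOutliers(bm)
  expect_equal(ol$sample, "s5")
  expect_equal(ol$tissue, "blood")
})

test_that("monotone tissue effects give cross-tissue rho of 1; <3 tissues give NA", {
  cohort <- data.frame(
    sample = paste0("s", 1:5),
    tissue = paste0("t", 1:5),
    proteasome_immuno = c(1, 2, 3, 4, 5),
    classII_composite = c(10, 40, 90, 160, 250),
    stringsAsFactors = FALSE
  )
  bm <- buildBodyMap(cohort)
  cc <- bodyMapCorrelations(bm)
  row <- cc[cc$metric_x == "classII_composite" &
            cc$metric_y == "proteasome_immuno" |
            cc$metric_x == "proteasome_immuno" &
            cc$metric_y == "classII_composite", ]
  expect_equal(row$rho, 1)
  expect_equal(row$n, 5L)

  one <- buildBodyMap(cohort[1, ],
                      correlationPairs = matrix(c("proteasome_immuno",
                                                  "classII_composite"),
                                                ncol = 2))
  expect_true(is.na(bodyMapCorrelations(one)$rho))
})

test_that("a cohort of identical samples has flat medians and no outliers", {
  cohort <- data.frame(
    sample = paste0("s", 1:8),
    tissue = rep(c("a", "b"), 4),
    classI_classical = 55,
    hla_e = 12,
    stringsAsFactors = FALSE
  )
  bm <- buildBodyMap(cohort, outlierMetric = "classI_classical",
                     outlierThreshold = 60)
  expect_equal(tissueMedians(bm)$classI_classical, c(55, 55))
  expect_equal(tissueMedians(bm)$hla_e, c(12, 12))
  expect_equal(nrow(bodyMapOutliers(bm)), 0L)
})

test_that("body-map medians are invariant under sample permutation", {
  set.seed(33)
  cohort <- data.frame(
    sample = paste0("s", 1:30),
    tissue = sample(c("x", "y", "z"), 30, replace = TRUE),
    m1 = rlnorm(30, 2, 1), m2 = rlnorm(30, 1, 0.5),
    stringsAsFactors = FALSE
  )
  bm1 <- buildBodyMap(cohort)
  perm <- cohort[sample(nrow(cohort)), ]
  bm2 <- buildBodyMap(perm)
  expect_equal(tissueMedians(bm1), tissueMedians(bm2))
})

test_that("manifest handling: labels applied, unknown samples rejected", {
  cohort <- data.frame(sample = c("s1", "s2"), m = c(1, 2),
                       stringsAsFactors = FALSE)
  manifest <- data.frame(sample = c("s1", "s2"), tissue = c("t1", "t2"),
                         stringsAsFactors = FALSE)
  bm <- buildBodyMap(cohort, manifest)
  expect_equal(tissueMedians(bm)$tissue, c("t1", "t2"))
  badManifest <- rbind(manifest, data.frame(sample = "ghost", tissue = "t3"))
  expect_error(buildBodyMap(cohort, badManifest), "ghost")
  expect_error(buildBodyMap(cohort), "tissue")
})

test_that("rank-correlated tissue effects are recovered within 0.1", {
  med <- simulateCorrelatedMedians(nTissues = 30, rho = 0.9, seed = 91)
  sim <- simulateCohort(
    data.frame(tissue = med$tissue, proteasome_immuno = med$metricA,
               classII_composite = med$metricB, stringsAsFactors = FALSE),
    samplesPerTissue = 8, sdlog = 0.2, seed = 92)
  bm <- buildBodyMap(sim$cohort,
                     correlationPairs = matrix(c("proteasome_immuno",
                                                 "classII_composite"),
                                               ncol = 2))
  rho <- bodyMapCorrelations(bm)$rho
  expect_gte(rho, 0.8)
  expect_lte(rho, 1)
})

test_that("body-map tables write as TSVs", {
  cohort <- data.frame(sample = paste0("s", 1:4),
                       tissue = rep(c("a", "b"), 2),
                       m = c(1, 2, 3, 4), stringsAsFactors = FALSE)
  bm <- buildBodyMap(cohort)
  d <- tempfile("bm")
  writeBodyMap(bm, d)
  expect_true(all(file.exists(file.path(d, c("bodymap.tsv", "positivity.tsv",
                                             "correlations.tsv",
                                             "outliers.tsv")))))
  back <- read.delim(file.path(d, "bodymap.tsv"))
  expect_equal(back$m, c(2, 3)) # tissue a: median(1,3); tissue b: median(2,4)
})
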