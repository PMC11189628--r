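# Screen module: Welch test, candidate calling, classification rules,
# exclusions, and the packaged hits table.

test_that("Welch t statistic, df and p match the analytic values", {
  r <- welchT(c(1, 2, 3), c(2, 3, 4))
  # closed form: se = sqrt(1/3 + 1/3), t = -1/se, df = 4 (equal n, equal var)
  expect_equal(r$t, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-1 / sqrt(2 / 3), 4), tolerance = 1e-12)

  # identical samples -> t = 0, p = 1 (by the constant-sample convention)
  same <- welchT(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(welchT(rep(1, 3), rep(2, 3))$p, 0)
  expect_error(welchT(1, c(1, 2)), "at least 2")
})

test_that("Welch p agrees with a permutation oracle on random samples", {
  set.seed(11)
  for (r in 1:4) {
    x <- rnorm(10)
    y <- rnorm(10)
    pw <- welchT(x, y)$p
    pp <- permutationP(x, y, B = 20000)
    expect_lt(abs(pw - pp), 0.05)
  }
})

test_that("candidate calling applies the background-subtracted fold cutoff", {
  rec <- data.frame(strain_id = c("a", "b", "c"),
                    pre_mean = c(50, 40, 40),
                    post_mean = c(70, 42, 80))
  out <- callCandidates(rec, background = 10)
  expect_equal(out$fold_change, c(1.5, 32 / 30, 70 / 30))
  expect_identical(out$candidate, c(FALSE, TRUE, FALSE))

  # cutoff 1.1 exactly: fold 1.05 is a candidate
  o2 <- callCandidates(data.frame(strain_id = "d", pre_mean = 40,
                                  post_mean = 42), background = 0)
  expect_equal(o2$fold_change, 1.05)
  expect_true(o2$candidate)

  # background at or above the 30C mean: invalid, never a candidate
  o3 <- callCandidates(data.frame(strain_id = "e", pre_mean = 40,
                                  post_mean = 90), background = 45)
  expect_true(o3$invalid)
  expect_false(o3$candidate)
  expect_error(callCandidates(rec), "background")
})

test_that("fold change is invariant under a gain rescaling", {
  rec <- data.frame(strain_id = "a", pre_mean = 52, post_mean = 88)
  f1 <- callCandidates(rec, background = 7)$fold_change
  gain <- 3.7
  rec2 <- data.frame(strain_id = "a", pre_mean = 52 * gain,
                     post_mean = 88 * gain)
  f2 <- callCandidates(rec2, background = 7 * gain)$fold_change
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("mutant classification implements the two-test rule", {
  base <- list(ko30 = rep(c(1, 1.1), 25), wt30 = rep(c(1, 1.1), 25),
               pre = rep(c(10, 11), 25), post = rep(c(10, 11), 25))
  # identical everything: not Class1 (p = 1), Class2 (no increase)
  expect_identical(as.character(classifyMutant(base)), "Class2")

  set.seed(21)
  # 30C ratio shifted +5 within-sample SDs -> Class1
  c1 <- list(ko30 = rnorm(50, 2, 0.2), wt30 = rnorm(50, 1, 0.2),
             pre = rnorm(50, 10, 2), post = rnorm(50, 16, 2))
  expect_identical(as.character(classifyMutant(c1)), "Class1")
  # clear heat-shock response, no 30C phenotype -> Responsive
  resp <- list(ko30 = rnorm(50, 1, 0.2), wt30 = rnorm(50, 1, 0.2),
               pre = rnorm(50, 10, 2), post = rnorm(50, 20, 2))
  expect_identical(as.character(classifyMutant(resp)), "Responsive")
  # significant DECREASE after heat shock still counts as "no increase"
  dec <- list(ko30 = rnorm(50, 1, 0.2), wt30 = rnorm(50, 1, 0.2),
              pre = rnorm(50, 20, 2), post = rnorm(50, 10, 2))
  expect_identical(as.character(classifyMutant(dec)), "Class2")
  # a 30C DECREASE is not Class1 even if significant
  lo <- list(ko30 = rnorm(50, 0.5, 0.2), wt30 = rnorm(50, 1, 0.2),
             pre = rnorm(50, 10, 2), post = rnorm(50, 20, 2))
  expect_identical(as.character(classifyMutant(lo)), "Responsive")

  expect_error(classifyMutant(list(ko30 = 1, wt30 = c(1, 2),
                                   pre = c(1, 2), post = c(1, 2))),
               "ko30")
  # rank-sum alternative is available
  expect_identical(as.character(classifyMutant(c1, test = "wilcoxon")),
                   "Class1")
})

test_that("classifier error rates: type I bounded, power near one", {
  set.seed(31)
  labs <- vapply(1:1000, function(i) {
    v <- list(ko30 = rnorm(50, 1, 0.2), wt30 = rnorm(50, 1, 0.2),
              pre = rnorm(50, 10, 2), post = rnorm(50, 16, 2))
    as.character(classifyMutant(v))
  }, character(1))
  expect_lte(mean(labs == "Class1"), 1.5 * 0.01)

  # +3 SD Class1 effect at n = 50: sensitivity >= 0.95
  hits <- vapply(1:200, function(i) {
    v <- list(ko30 = rnorm(50, 1.6, 0.2), wt30 = rnorm(50, 1, 0.2),
              pre = rnorm(50, 10, 2), post = rnorm(50, 16, 2))
    as.character(classifyMutant(v)) == "Class1"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # no heat-shock increase: Class2 sensitivity >= 0.95
  c2 <- vapply(1:200, function(i) {
    v <- list(ko30 = rnorm(50, 1, 0.2), wt30 = rnorm(50, 1, 0.2),
              pre = rnorm(50, 10, 2), post = rnorm(50, 10, 2))
    as.character(classifyMutant(v)) == "Class2"
  }, logical(1))
  expect_gte(mean(c2), 0.95)
})

test_that("exclusion lists relabel known import-pathway genes", {
  labs <- c(s1 = "Class1", s2 = "Class2", s3 = "Responsive")
  expect_identical(applyExclusions(labs, character()), labs)
  out <- applyExclusions(labs, c("s2"))
  expect_identical(unname(out["s2"]), "Excluded")
  expect_identical(unname(out["s1"]), "Class1")
  expect_warning(applyExclusions(labs, c("s9")), "s9")
})

test_that("the packaged hits table counts by phenotype and rejects duplicates", {
  counts <- countByClass()
  expect_identical(unname(counts["Class 1"]), 5L)
  expect_identical(unname(counts["Class 2"]), 140L)

  empty <- data.frame(systematic_name = character(),
                      standard_name = character(),
                      magic_phenotype = character())
  expect_identical(countByClass(empty), integer(0))

  dup <- data.frame(systematic_name = c("YAL001C", "YAL001C"),
                    standard_name = c("A", "B"),
                    magic_phenotype = c("Class 1", "Class 2"))
  expect_error(countByClass(dup), "duplicated")
  expect_error(countByClass(data.frame(x = 1)), "columns")
})

test_that("screen classification recovers the simulated truth end to end", {
  cls <- makeClassAssignments(60, 3, 5)
  ds <- generateScreenDataset(60, cls, cellsPerStrain = 2000, seed = 17)
  res <- classifyScreen(ds, minEvents = 2000)
  expect_identical(nrow(res), 60L)
  expect_gte(balancedAccuracy(res$label, res$true_class), 0.9)
  # excluded strains override their test outcome
  res2 <- classifyScreen(ds, minEvents = 2000,
                         exclusionList = res$strain_id[2])
  expect_identical(res2$label[2], "Excluded")
})
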