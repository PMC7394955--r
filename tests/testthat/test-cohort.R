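test_that("read_cohort accepts a well-formed CSV and types its columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tiny_cohort_table(10), path, row.names = FALSE)
  co <- read_cohort(path, tiny_design())
  expect_s3_class(co, "longitudinal_cohort")
  expect_equal(nrow(co$table), 10)
  expect_true(is.numeric(co$table$bmi_w2))
})

test_that("read_cohort errors name missing columns, bad values and gaps", {
  d <- tiny_design()
  tab <- tiny_cohort_table(6)

  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab[, setdiff(names(tab), "inactive_w2")], path, row.names = FALSE)
  expect_error(read_cohort(path, d), "inactive_w2")

  tab2 <- tab
  tab2$bmi_w1 <- as.character(tab2$bmi_w1)
  tab2$bmi_w1[3] <- "abc"
  write.csv(tab2, path, row.names = FALSE)
  expect_error(read_cohort(path, d), "row 3")

  tab3 <- tab
  tab3$smoker_w4[2] <- NA
  write.csv(tab3, path, row.names = FALSE)
  expect_error(read_cohort(path, d), "missing value.*smoker_w4")

  tab4 <- tab
  tab4$male[5] <- 2
  write.csv(tab4, path, row.names = FALSE)
  expect_error(read_cohort(path, d), "non-binary.*male.*row 5")
})

test_that("obesity flag is BMI >= threshold, boundary inclusive", {
  d <- tiny_design()
  tab <- tiny_cohort_table(4)
  tab$bmi_w1 <- c(29.9, 30.0, 31.2, 28.0)
  co <- longitudinal_cohort(tab, d)
  ob <- derive_obesity(co)
  expect_equal(ob$table$obese_w1, c(0L, 1L, 1L, 0L))

  tab$bmi_w1 <- c(34, 36, 25, 25)
  co <- longitudinal_cohort(tab, d)
  expect_equal(derive_obesity(co, threshold = 35)$table$obese_w1,
               c(0L, 1L, 0L, 0L))

  tab$bmi_w1 <- rep(25, 4)
  co <- longitudinal_cohort(tab, d)
  expect_true(all(derive_obesity(co)$table$obese_w1 == 0L))

  tab$bmi_w2[1] <- -1
  co <- longitudinal_cohort(tab, d)
  expect_error(derive_obesity(co), "non-positive BMI")
  expect_error(derive_obesity(longitudinal_cohort(tiny_cohort_table(4), d),
                              threshold = 0),
               "positive")
})

test_that("derive_obesity is idempotent and monotone in the threshold", {
  d <- tiny_design()
  set.seed(31)
  tab <- tiny_cohort_table(50)
  for (t in 1:4) tab[[paste0("bmi_w", t)]] <- runif(50, 18, 42)
  co <- longitudinal_cohort(tab, d)
  once <- derive_obesity(co)
  expect_identical(derive_obesity(once)$table, once$table)
  counts <- vapply(c(25, 30, 35, 40), function(th) {
    sum(as.matrix(derive_obesity(co, th)$table[paste0("obese_w", 1:4)]))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("trajectory classes partition all 2^T sequences by onset wave", {
  for (T in 2:4) {
    grid <- expand.grid(rep(list(0:1), T))
    cls <- apply(grid, 1, classify_trajectory)
    onset <- apply(grid, 1, function(z) match(1, z))
    expect_equal(cls[is.na(onset)], rep("never", sum(is.na(onset))))
    expect_equal(cls[!is.na(onset) & onset == 1],
                 rep("persistent", sum(onset == 1, na.rm = TRUE)))
    k <- onset[!is.na(onset) & onset > 1]
    expect_equal(cls[!is.na(onset) & onset > 1], paste0("incident_w", k))
    # mutually exclusive and exhaustive by construction of the map
    expect_equal(length(cls), 2^T)
  }
  expect_equal(classify_trajectory(c(0, 0, 1, 1)), "incident_w3")
  expect_equal(classify_trajectory(c(1, 0, 0, 0)), "persistent")
  expect_equal(classify_trajectory(c(0, 0, 0, 0)), "never")
  expect_error(classify_trajectory(integer(0)), "empty")
  expect_error(classify_trajectory(c(0, 2)), "0/1")
})

test_that("onset wave shifts consistently when zeros are prepended", {
  set.seed(7)
  for (i in 1:20) {
    seq0 <- rbinom(3, 1, 0.4)
    cls <- classify_trajectory(seq0)
    shifted <- classify_trajectory(c(0, seq0))
    if (cls == "never") {
      expect_equal(shifted, "never")
    } else if (cls == "persistent") {
      expect_equal(shifted, "incident_w2")
    } else {
      k <- as.integer(sub("incident_w", "", cls))
      expect_equal(shifted, paste0("incident_w", k + 1L))
    }
  }
})

test_that("centile dichotomization uses the <=-threshold rule with tie inflation", {
  r <- dichotomize_outcome(1:10, rep(0, 10))
  expect_equal(unname(r$thresholds), 1)
  expect_equal(sum(r$flags), 1)

  r <- dichotomize_outcome(c(5, 5, 5, 7, 8, 9, 10, 11, 12, 13), rep(1, 10))
  expect_equal(unname(r$thresholds), 5)
  expect_equal(sum(r$flags), 3) # ties inflate 10% to 30%

  scores <- c(1:10, 101:110)
  gender <- rep(c(0, 1), each = 10)
  r <- dichotomize_outcome(scores, gender)
  expect_equal(unname(r$thresholds), c(1, 101))
  expect_equal(c(tapply(r$flags, gender, sum)), c(`0` = 1, `1` = 1))

  expect_error(dichotomize_outcome(1:10, rep(0, 10), centile = 0), "centile")
  expect_error(dichotomize_outcome(c(1, Inf), c(0, 0)), "finite")
  expect_warning(dichotomize_outcome(1:5, rep(0, 5)), "fewer than 10")
})

test_that("flagged proportion reaches the centile and is minimal over tie groups", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(20:120, 1)
    scores <- sample(40:80, n, replace = TRUE) # integer scores force ties
    gender <- rbinom(n, 1, 0.5)
    if (min(table(gender)) < 10) next
    r <- dichotomize_outcome(scores, gender)
    for (g in 0:1) {
      sel <- gender == g
      prop <- mean(r$flags[sel])
      expect_gte(prop, 0.10)
      thr <- r$thresholds[[as.character(g)]]
      # dropping the threshold tie group takes the proportion below 10%
      below <- mean(scores[sel] < thr)
      expect_lt(below, 0.10)
    }
  }
})

test_that("prevalence summary reports counts, percentages and partitions", {
  d <- tiny_design()
  tab <- tiny_cohort_table(10)
  tab$bmi_w1 <- c(rep(32, 3), rep(25, 7)) # 3 obese at wave 1
  co <- suppressWarnings(derive_cohort(longitudinal_cohort(tab, d)))
  ps <- prevalence_summary(co)
  ob1 <- ps[ps$block == "obesity" & ps$wave == 1 & ps$group == "all" &
            ps$stratum == "all", ]
  expect_equal(ob1$n, 3)
  expect_equal(ob1$pct, 30)
  for (g in c("male=0", "male=1")) {
    tr <- ps[ps$block == "trajectory" & ps$group == g, ]
    expect_equal(sum(tr$pct), 100, tolerance = 1e-6)
    expect_equal(sum(tr$n), unique(tr$total))
  }
})

test_that("derived cohort round-trips through CSV with provenance header", {
  d <- tiny_design()
  co <- suppressWarnings(derive_cohort(longitudinal_cohort(tiny_cohort_table(8), d)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path, c(seed = 1))
  expect_match(readLines(path, n = 1), "^# seed=1")
  back <- read_cohort(path, d)
  expect_equal(back$table$pf_score, co$table$pf_score)
})
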