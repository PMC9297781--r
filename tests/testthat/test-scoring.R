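# Patient-level FS and variant-level VFS.

test_that("patient FS is the mean per-fragment score and is seed-deterministic", {
  tab <- small_score_table()
  # constant-score pool: every fragment at one length -> fs == s(length)
  pool <- fragment_pool(rep(145L, 1000), sample_id = "const")
  fs <- patient_fs(pool, tab, n_sample = 5000, seed = 1)
  expect_equal(fs$fs, score_lookup(tab, 145L))
  expect_equal(fs$sample_id, "const")

  mixed <- sample_fragment_pool(nontumour_prof, 5e4, seed = 2)
  a <- patient_fs(mixed, tab, n_sample = 1e5, seed = 3)
  b <- patient_fs(mixed, tab, n_sample = 1e5, seed = 3)
  expect_equal(a, b)
  expect_error(patient_fs(fragment_pool(integer(0)), tab), "non-empty")
})

test_that("sampled FS agrees with its closed-form expectation within 3 SE", {
  tab <- small_score_table()
  pool <- sample_patient_pool(0.05, 2e5, seed = 7)
  mu <- patient_fs_expected(pool, tab)
  s_sd <- sqrt(sum(pool$count / pool_size(pool) *
                     (score_lookup(tab, pool$length) - mu)^2))
  for (seed in 11:16) {
    fs <- patient_fs(pool, tab, n_sample = 1e6, seed = seed)$fs
    expect_lt(abs(fs - mu), 3 * s_sd / 1000)
  }
})

test_that("FS sampling is unbiased across seeds", {
  tab <- small_score_table()
  pool <- sample_patient_pool(0.03, 1e5, seed = 8)
  mu <- patient_fs_expected(pool, tab)
  reps <- vapply(1:50, function(s) {
    patient_fs(pool, tab, n_sample = 1e4, seed = 100 + s)$fs
  }, numeric(1))
  s_sd <- sqrt(sum(pool$count / pool_size(pool) *
                     (score_lookup(tab, pool$length) - mu)^2))
  expect_lt(abs(mean(reps) - mu), 3 * s_sd / sqrt(50 * 1e4))
})

test_that("the FS threshold is mean plus two sample standard deviations", {
  expect_equal(fs_threshold(c(-0.7, -0.6, -0.65)), -0.55)
  expect_equal(fs_threshold(rep(-0.4, 5)), -0.4)
  expect_error(fs_threshold(-0.5), ">= 2")
})

test_that("FS calls use a strict inequality", {
  expect_false(fs_call(-0.55, -0.55))
  expect_true(fs_call(-0.55 + 1e-9, -0.55))
  expect_equal(fs_call(c(-1, 0), -0.5), c(FALSE, TRUE))
})

test_that("a control-distribution sample is called FS-positive only rarely", {
  tab <- small_score_table()
  thr_seeds <- 1:40
  hits <- vapply(thr_seeds, function(s) {
    withr::with_seed(s, {
      ctl_fs <- vapply(1:8, function(i) {
        p <- sample_fragment_pool(nontumour_prof, 2e4)
        patient_fs(p, tab, n_sample = 1e4)$fs
      }, numeric(1))
      test_fs <- patient_fs(sample_fragment_pool(nontumour_prof, 2e4),
                            tab, n_sample = 1e4)$fs
      fs_call(test_fs, fs_threshold(ctl_fs))
    })
  }, logical(1))
  # mean + 2 sd on Gaussian-ish FS values -> ~2.5% one-sided tail
  expect_lte(mean(hits), 0.10)
})

test_that("VFS averages supporting-fragment scores and pools pre/post compartments", {
  tab <- small_score_table()
  sup <- tibble::tibble(
    patient_id = "P1", compartment = c("preop_plasma", "postop_plasma"),
    chrom = "chr1", pos = 10L, ref = "A", alt = "T",
    fragment_length = c(140L, 145L))
  v <- variant_fs(sup, tab)
  expect_equal(v$n_reads, 2L)
  expect_equal(v$vfs, mean(score_lookup(tab, c(140L, 145L))))

  one <- variant_fs(sup[1, ], tab)
  expect_equal(one$vfs, score_lookup(tab, 140L))

  # merged VFS equals the count-weighted mean of per-compartment VFS
  sup2 <- tibble::tibble(
    patient_id = "P1",
    compartment = rep(c("preop_plasma", "postop_plasma"), c(3, 5)),
    chrom = "chr1", pos = 20L, ref = "A", alt = "T",
    fragment_length = c(140L, 150L, 160L, 135L, 145L, 155L, 165L, 175L))
  pre <- variant_fs(dplyr::filter(sup2, compartment == "preop_plasma"), tab)
  post <- variant_fs(dplyr::filter(sup2, compartment == "postop_plasma"), tab)
  both <- variant_fs(sup2, tab)
  expect_equal(both$vfs, (3 * pre$vfs + 5 * post$vfs) / 8)
})

test_that("VFS null thresholds behave like mean + 2 sd of null draws", {
  tab <- small_score_table()
  ctl <- sample_fragment_pool(nontumour_prof, 1e5, seed = 61)
  thr1 <- vfs_null_thresholds(ctl, tab, 1, n_iter = 4000, seed = 62)$threshold
  s <- score_lookup(tab, ctl$length)
  w <- ctl$count / pool_size(ctl)
  mu <- sum(w * s)
  sdev <- sqrt(sum(w * (s - mu)^2))
  expect_equal(thr1, mu + 2 * sdev, tolerance = 0.05)

  # CLT limit: threshold(n) ~ mu + 2 * sd / sqrt(n), shrinking to the pool mean
  for (n in c(100, 400)) {
    thr_n <- vfs_null_thresholds(ctl, tab, n, n_iter = 2000,
                                 seed = 63)$threshold
    expect_equal(thr_n, mu + 2 * sdev / sqrt(n), tolerance = 0.05)
  }
  expect_error(vfs_null_thresholds(ctl, tab, 5, n_iter = 1), "n_iter")
})

test_that("VFS null thresholds are non-increasing in read count, in expectation", {
  tab <- small_score_table()
  ctl <- sample_fragment_pool(nontumour_prof, 1e5, seed = 64)
  ns <- c(2, 4, 8, 16, 32, 64)
  thr <- rowMeans(vapply(1:5, function(s) {
    vfs_null_thresholds(ctl, tab, ns, n_iter = 1500,
                        seed = 700 + s)$threshold
  }, numeric(length(ns))))
  expect_true(all(diff(thr) <= 0.01))
  expect_true(thr[1] > thr[length(ns)])
})

test_that("variant classification is indeterminate below 8 reads and monotone in VFS", {
  tab <- small_score_table()
  ctl <- sample_fragment_pool(nontumour_prof, 1e5, seed = 65)
  vfs_tbl <- tibble::tibble(
    patient_id = "P1", chrom = "chr1", pos = c(1L, 2L, 3L, 4L),
    ref = "A", alt = "T",
    vfs = c(3, 3, -3, 0.0), n_reads = c(7L, 8L, 8L, 0L))
  cls <- classify_variants(vfs_tbl, ctl, tab, seed = 66)
  expect_equal(cls$classification,
               c("indeterminate", "tumour", "blood", "indeterminate"))

  thr8 <- cls$threshold[2]
  above <- classify_variants(dplyr::mutate(vfs_tbl[2, ], vfs = thr8 + 0.01),
                             ctl, tab, seed = 66)
  at <- classify_variants(dplyr::mutate(vfs_tbl[2, ], vfs = thr8),
                          ctl, tab, seed = 66)
  expect_equal(above$classification, "tumour")
  expect_equal(at$classification, "blood")  # strict inequality
})

test_that("tumour- and blood-derived synthetic variants are recovered above 8 reads", {
  tab <- small_score_table()
  ctl <- sample_fragment_pool(nontumour_prof, 1e5, seed = 71)
  dens_t <- profile_density(tumour_prof)
  dens_n <- profile_density(nontumour_prof)
  sup <- withr::with_seed(72L, {
    purrr::map(1:120, function(i) {
      origin <- if (i <= 60) "tumour" else "blood"
      n <- sample(8:25, 1)
      lens <- sample(1:600, n, replace = TRUE,
                     prob = if (origin == "tumour") dens_t else dens_n)
      tibble::tibble(patient_id = "P1", compartment = "postop_plasma",
                     chrom = "chr1", pos = i, ref = "A", alt = "T",
                     fragment_length = lens, origin = origin)
    }) |> purrr::list_rbind()
  })
  truth <- dplyr::distinct(sup, pos, origin)
  cls <- variant_fs(sup, tab) |>
    classify_variants(ctl, tab, seed = 73) |>
    dplyr::inner_join(truth, by = "pos")
  sens <- mean(cls$classification[cls$origin == "tumour"] == "tumour")
  spec <- mean(cls$classification[cls$origin == "blood"] == "blood")
  expect_gt(sens, 0.75)
  expect_gt(spec, 0.75)
})

test_that("the +1/-1/0 performance score matches hand counting", {
  expect_equal(vfs_performance_score(rep("tumour", 4), rep("tumour", 4)), 4L)
  expect_equal(vfs_performance_score(rep("indeterminate", 3),
                                     c("tumour", "blood", "tumour")), 0L)
  cls <- c("tumour", "blood", "tumour", "blood", "indeterminate",
           "indeterminate")
  tru <- c("tumour", "blood", "tumour", "tumour", "blood", "tumour")
  expect_equal(vfs_performance_score(cls, tru), 2L)
  expect_error(vfs_performance_score(cls[1:2], tru), "same length")
})
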