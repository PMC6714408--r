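test_that("boundary splitting matches hand-enumerated cut points", {
  calls <- data.frame(sample_id = c("A", "B"), chromosome = "1",
                      start = c(100, 150), end = c(200, 250),
                      copy_number = c(1L, 1L))
  sm <- segment_cnvs(calls, c("A", "B"))
  expect_equal(sm$segments$start, c(100, 150, 201))
  expect_equal(sm$segments$end, c(149, 200, 250))
  expect_equal(unname(sm$cn["A", ]), c(1L, 1L, 2L))
  expect_equal(unname(sm$cn["B", ]), c(2L, 1L, 1L))
})

test_that("a single call yields a single identical segment", {
  calls <- data.frame(sample_id = "A", chromosome = "7",
                      start = 5000, end = 9000, copy_number = 3L)
  sm <- segment_cnvs(calls, "A")
  expect_equal(nrow(sm$segments), 1)
  expect_equal(sm$segments$start, 5000)
  expect_equal(sm$segments$end, 9000)
  expect_equal(unname(sm$cn["A", 1]), 3L)
  expect_equal(sm$class, "duplication_only")
})

test_that("distant gaps produce no segments and conflicts raise errors", {
  calls <- data.frame(sample_id = c("A", "A"), chromosome = "1",
                      start = c(100, 10000), end = c(200, 10100),
                      copy_number = c(1L, 3L))
  sm <- segment_cnvs(calls, "A")
  expect_equal(nrow(sm$segments), 2)  # untouched middle is not a segment
  conflict <- data.frame(sample_id = c("A", "A"), chromosome = "1",
                         start = c(100, 150), end = c(200, 250),
                         copy_number = c(1L, 3L))
  expect_error(segment_cnvs(conflict, "A"), "conflicting.*sample A")
})

test_that("segmentation properties hold on random call sets", {
  set.seed(2024)
  for (rep in 1:20) {
    n_calls <- sample(2:12, 1)
    samples <- paste0("S", 1:4)
    st <- sample(seq(1, 5e4, by = 50), n_calls)
    calls <- data.frame(sample_id = sample(samples, n_calls, replace = TRUE),
                        chromosome = sample(c("1", "2"), n_calls, TRUE),
                        start = st, end = st + sample(100:5000, n_calls, TRUE),
                        copy_number = sample(c(0L, 1L, 3L, 4L), n_calls, TRUE))
    # collapse same-sample overlaps to a single CN to avoid conflicts
    sm <- tryCatch(segment_cnvs(calls, samples), error = function(e) NULL)
    if (is.null(sm)) next

    # partition: total segment length equals the length of the call union
    union_len <- sum(IRanges::width(IRanges::reduce(
      GenomicRanges::GRanges(calls$chromosome,
                             IRanges::IRanges(calls$start, calls$end)))))
    expect_equal(sum(sm$segments$length), union_len)

    # refinement: no segment straddles any call boundary
    for (i in seq_len(nrow(calls))) {
      seg <- sm$segments[sm$segments$chromosome == calls$chromosome[i], ]
      inside <- seg$start <= calls$end[i] & seg$end >= calls$start[i]
      expect_true(all(seg$start[inside] >= calls$start[i]))
      expect_true(all(seg$end[inside] <= calls$end[i]))
    }

    # idempotence: segmenting the segments returns the same tiling
    seg_calls <- do.call(rbind, lapply(seq_len(nrow(sm$segments)), function(j) {
      carriers <- sm$sample_ids[sm$cn[, j] != 2L]
      data.frame(sample_id = carriers,
                 chromosome = sm$segments$chromosome[j],
                 start = sm$segments$start[j], end = sm$segments$end[j],
                 copy_number = sm$cn[carriers, j])
    }))
    sm2 <- segment_cnvs(seg_calls, samples)
    expect_equal(sm2$segments[, c("chromosome", "start", "end")],
                 sm$segments[, c("chromosome", "start", "end")])
    expect_equal(sm2$cn, sm$cn)

    # monotonicity: adding a call never decreases the segment count
    extra <- data.frame(sample_id = "S1", chromosome = "1",
                        start = 60001, end = 60500, copy_number = 1L)
    sm3 <- segment_cnvs(rbind(calls, extra), samples)
    expect_gte(nrow(sm3$segments), nrow(sm$segments))
  }
})

test_that("segment classes follow the abnormal copy numbers present", {
  expect_equal(classify_segment(c(1L, 2L, 2L)), "deletion_only")
  expect_equal(classify_segment(c(1L, 2L, 3L)), "multi_class")
  expect_equal(classify_segment(c(3L, 4L, 2L)), "duplication_only")
  expect_equal(classify_segment(c(0L, 2L)), "deletion_only")
  expect_error(classify_segment(c(2L, 2L)), "no abnormal")
})

test_that("carrier frequencies count samples with abnormal copy number", {
  col <- c(rep(1L, 20), 3L, rep(2L, 336))
  expect_equal(carrier_frequency(col), 21 / 357)
  expect_equal(deletion_carrier_frequency(col), 20 / 357)
  expect_equal(carrier_frequency(rep(2L, 10)), 0)
  expect_equal(carrier_frequency(rep(1L, 10)), 1)
})

test_that("exact HWE test matches hand-computed and enumerated values", {
  # exact Hardy-Weinberg proportions (q = 0.1, n = 100): chi2 statistic 0
  expect_equal(hwe_test(c(rep(2L, 81), rep(1L, 18), 0L),
                        method = "chi2")$p_value, 1)
  # hand enumeration: (2,0,2) -> 6/70, (1,0,1) -> 1/3
  expect_equal(hwe_exact_p(2, 0, 2), 6 / 70, tolerance = 1e-12)
  expect_equal(hwe_exact_p(1, 0, 1), 1 / 3, tolerance = 1e-12)
  # extreme heterozygote deficit
  expect_lt(hwe_exact_p(25, 0, 25), 1e-12)
  # monomorphic segments are uninformative
  expect_equal(hwe_exact_p(50, 0, 0), 1)
  expect_equal(hwe_exact_p(0, 0, 50), 1)
  # deletion observed only as heterozygotes in a cohort of 357: retained
  expect_gt(hwe_exact_p(337, 20, 0), 0.05)
})

test_that("exact HWE equals full enumeration for all counts up to n = 50", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(2:50, 1)
    na <- sample(0:n, 1)
    naa <- sample(0:(na %/% 2), 1)
    nAa <- na - 2 * naa
    nAA <- n - nAa - naa
    expect_equal(hwe_exact_p(nAA, nAa, naa), hwe_enum_p(nAA, nAa, naa),
                 tolerance = 1e-9)
  }
})

test_that("hwe_test maps copy numbers to genotype counts by class", {
  del <- c(rep(2L, 30), rep(1L, 8), rep(0L, 2))
  r <- hwe_test(del)
  expect_equal(c(r$n_hom_ref, r$n_het, r$n_hom_alt), c(30L, 8L, 2L))
  dup <- c(rep(2L, 30), rep(3L, 8), rep(4L, 2))
  r2 <- hwe_test(dup)
  expect_equal(c(r2$n_hom_ref, r2$n_het, r2$n_hom_alt), c(30L, 8L, 2L))
  expect_equal(r$p_value, r2$p_value)  # symmetric mapping
  mc <- c(rep(2L, 30), rep(1L, 8), 3L)
  expect_true(is.na(hwe_test(mc)$p_value))
  rv <- hwe_test(mc, multi_class_as_deletion = TRUE)
  expect_equal(c(rv$n_hom_ref, rv$n_het, rv$n_hom_alt), c(30L, 8L, 0L))
})

test_that("segment filter applies frequency and HWE rules with strict bounds", {
  mk_sm <- function(cols) {
    n <- length(cols[[1]])
    calls <- do.call(rbind, lapply(seq_along(cols), function(j) {
      carriers <- which(cols[[j]] != 2L)
      data.frame(sample_id = paste0("S", carriers),
                 chromosome = "1",
                 start = j * 10000, end = j * 10000 + 999,
                 copy_number = cols[[j]][carriers])
    }))
    segment_cnvs(calls, paste0("S", 1:n))
  }
  n <- 1000
  col_at <- c(rep(1L, 50), rep(2L, 950))     # carrier freq exactly 0.050
  col_below <- c(rep(1L, 49), rep(2L, 951))  # 0.049
  sm <- mk_sm(list(col_at, col_below))
  f <- filter_segments(sm, min_carrier_freq = 0.05)
  expect_equal(nrow(f$segments), 1)
  expect_equal(f$segments$start, 10000)
  log <- attr(f, "filter_log")
  expect_equal(log$reason[2], "carrier_freq_below_threshold")

  # HWE exclusion is at p <= alpha: engineer a deletion-only column with
  # excess homozygotes and check it is dropped while a multi-class column
  # with the same imbalance is kept
  bad <- c(rep(0L, 30), rep(2L, 70))
  mc <- c(rep(0L, 30), rep(2L, 69), 3L)
  sm2 <- mk_sm(list(bad, mc))
  expect_lt(sm2$hwe_p[1], 0.05)
  f2 <- filter_segments(sm2)
  expect_equal(attr(f2, "filter_log")$reason,
               c("hwe_violation", "kept"))
})
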