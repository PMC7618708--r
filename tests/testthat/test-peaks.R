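gaussBump <- function(n, center, sigma = 20, height = 1) {
  height * exp(-(seq_len(n) - center)^2 / (2 * sigma^2))
}

test_that("peak calling finds isolated bumps and nothing on flat tracks", {
  expect_equal(length(findPeaks(rep(2, 1000))), 0L)
  one <- findPeaks(gaussBump(2000, 700), order = 45, window = 80)
  expect_equal(length(one), 1L)
  expect_lte(abs(one@positions - 700), 5)
  expect_gt(one@scores, 0)
})

test_that("the comparator half-width separates or merges nearby bumps", {
  two <- gaussBump(3000, 1000) + gaussBump(3000, 1300)
  pk2 <- findPeaks(two, order = 45, window = 80)
  expect_equal(length(pk2), 2L)
  close <- gaussBump(3000, 1000) + gaussBump(3000, 1040)
  pk1 <- findPeaks(close, order = 45, window = 80)
  expect_equal(length(pk1), 1L)
  expect_true(all(diff(pk2@positions) > 45))
})

test_that("peak positions are invariant under uniform scaling", {
  tr <- gaussBump(2000, 400) + 0.6 * gaussBump(2000, 1200)
  a <- findPeaks(tr, order = 45, window = 80, minHeight = 0.5)
  b <- findPeaks(tr * 1000, order = 45, window = 80, minHeight = 0.5)
  expect_identical(a@positions, b@positions)
})

test_that("the height floor and edge rule suppress spurious calls", {
  tr <- gaussBump(2000, 500, height = 10) + gaussBump(2000, 1500, height = 0.1)
  strict <- findPeaks(tr, order = 45, window = 80, minHeight = 1)
  expect_equal(strict@positions, strict@positions[abs(strict@positions - 500) < 50])
  # a maximum within `order` of the boundary is not callable
  edge <- gaussBump(300, 10, sigma = 5)
  expect_equal(length(findPeaks(edge, order = 45, window = 80)), 0L)
  expect_error(findPeaks(rep(1, 30), order = 45, window = 10), "order")
})

test_that("metaplots average the windows around peaks", {
  tr <- numeric(1000)
  tr[300] <- 1; tr[700] <- 1
  pk <- new("PeakSet", positions = c(300L, 700L), scores = c(1, 1),
            order = 45L, window = 1L)
  mp <- metaplot(tr, pk, flank = 50)
  expect_equal(mp$mean[mp$offset == 0], 1)
  expect_equal(sum(mp$mean), 1)            # impulses only at offset 0
  # a single peak copies its window
  single <- metaplot(tr, new("PeakSet", positions = 300L, scores = 1,
                             order = 45L, window = 1L), flank = 10)
  expect_equal(single$mean, tr[290:310])
  # two windows of different heights average elementwise
  tr2 <- numeric(1000); tr2[300] <- 2; tr2[700] <- 4
  mp2 <- metaplot(tr2, pk, flank = 5)
  expect_equal(mp2$mean[mp2$offset == 0], 3)
  # peaks without a full window are dropped and counted
  pkEdge <- new("PeakSet", positions = c(30L, 300L), scores = c(1, 1),
                order = 45L, window = 1L)
  mpe <- metaplot(tr, pkEdge, flank = 50)
  expect_equal(attr(mpe, "dropped"), 1L)
  expect_error(metaplot(tr, new("PeakSet", positions = 3L, scores = 1,
                                order = 45L, window = 1L), flank = 50),
               "no peak")
})

test_that("aligning a second track reports the offset of its maximum", {
  anchor <- gaussBump(4000, 1000) + gaussBump(4000, 2500)
  pk <- findPeaks(anchor, order = 45, window = 80)
  self <- alignTracksAtPeaks(pk, anchor, flank = 200)
  # even smoothing window: the called peak may sit half a bin off-center
  expect_lte(abs(self$offsetOfMax), 2)
  # a factor sitting 40 nt upstream of every anchor peak reports -40
  other <- gaussBump(4000, 1000 - 40, sigma = 10) +
    gaussBump(4000, 2500 - 40, sigma = 10)
  shifted <- alignTracksAtPeaks(pk, other, flank = 200)
  expect_lte(abs(shifted$offsetOfMax - (-40)), 5)
})

test_that("a peak blacklist removes only the designated feature", {
  pk <- new("PeakSet", positions = c(300L, 643L, 900L),
            scores = c(1, 2, 3), order = 45L, window = 80L)
  kept <- excludePeaks(pk, 643L)
  expect_equal(kept@positions, c(300L, 900L))
  near <- excludePeaks(pk, 645L, tol = 5L)
  expect_equal(near@positions, c(300L, 900L))
  expect_equal(excludePeaks(pk, 5000L)@positions, pk@positions)
})
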