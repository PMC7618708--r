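test_that("end profiles follow the strand conventions and multiplicities", {
  reads <- makeReads(list(c(11, 35)))        # 1-based [11, 35]
  p5 <- endProfile(reads, 100, mode = "five_prime")
  p3 <- endProfile(reads, 100, mode = "three_prime")
  expect_equal(which(p5@values > 0), 11)
  expect_equal(which(p3@values > 0), 35)
  minus <- makeReads(list(c(11, 35)), strand = "-")
  expect_equal(which(endProfile(minus, 100, "five_prime")@values > 0), 35)
  expect_equal(which(endProfile(minus, 100, "three_prime")@values > 0), 11)
  # multiplicity-weighted sum at a shared end
  two <- makeReads(list(c(5, 30), c(10, 30)), count = c(2L, 3L))
  expect_equal(endProfile(two, 100, "three_prime")@values[30], 5)
  cov <- endProfile(two, 100, "coverage")
  expect_equal(cov@values[20], 5)
  expect_equal(cov@values[7], 2)
  # total mass equals total multiplicity, one contribution per read
  expect_equal(sum(endProfile(two, 100, "five_prime")@values), 5)
  expect_error(endProfile(makeReads(list(c(90, 120))), 100, "coverage"),
               "off reference")
})

test_that("unit normalization yields fractions plus the pseudocount", {
  tr <- ProfileTrack(c(2, 2, 0, 0))
  nm <- normalizeUnit(tr)
  expect_equal(nm@values, c(0.5 + 1e-7, 0.5 + 1e-7, 1e-7, 1e-7))
  expect_equal(sum(nm@values), 1 + 4 * 1e-7)
  expect_error(normalizeUnit(nm), "already normalized")
  one <- normalizeUnit(ProfileTrack(c(0, 7, 0)))
  expect_equal(one@values[2], 1 + 1e-7)
  expect_error(normalizeUnit(ProfileTrack(numeric(5))), "zero total")
  # normalization is over the unit window only
  fl <- ProfileTrack(c(5, 1, 1, 5), unitStart = 2L, unitEnd = 3L)
  expect_equal(normalizeUnit(fl, pseudo = 0)@values, c(2.5, 0.5, 0.5, 2.5))
})

test_that("Blackman smoothing conserves signal and reproduces the kernel", {
  const <- smoothBlackman(rep(3, 200), 10)
  expect_equal(const, rep(3, 200), tolerance = 1e-12)
  imp <- numeric(101); imp[51] <- 1
  sm <- smoothBlackman(imp, 11)   # odd window: exactly centered
  k <- sm[46:56]
  expect_equal(sum(k), 1, tolerance = 1e-9)
  expect_equal(k, rev(k), tolerance = 1e-12)          # symmetric bump
  expect_equal(which.max(sm), 51)
  expect_equal(sum(sm), 1, tolerance = 1e-9)          # conserved off-edge
  expect_error(smoothBlackman(rep(1, 5), 10), "exceeds")
  expect_error(smoothBlackman(rep(1, 50), 2), "window")
})

test_that("replicate aggregation uses interpolated quartiles", {
  tracks <- list(c(1, 1), c(2, 2), c(3, 3), c(4, 4))
  agg <- aggregateReplicates(tracks)
  expect_equal(agg$median[1], 2.5)
  expect_equal(agg$q25[1], 1.75)
  expect_equal(agg$q75[1], 3.25)
  expect_equal(agg$min[1], 1)
  expect_equal(agg$max[1], 4)
  tri <- aggregateReplicates(list(1, 2, 3))
  expect_equal(tri$median, 2)
  same <- aggregateReplicates(list(c(5, 0), c(5, 0)))
  expect_true(all(same$q25 == same$max))
  expect_error(aggregateReplicates(list(1:3, 1:4)), "mismatched")
  expect_error(aggregateReplicates(list()), "at least one")
})

test_that("difference and cumulative maps flag disjoint replicate bands", {
  a <- aggregateReplicates(list(c(1, 1, 1), c(1, 1, 1)))
  same <- differenceAndCumulative(a, a)
  expect_equal(same$difference, c(0, 0, 0))
  expect_false(any(same$significant))
  expect_equal(same$cumulativeA, c(1, 2, 3))
  b <- aggregateReplicates(list(c(5, 5, 5), c(6, 6, 6)))
  apart <- differenceAndCumulative(b, a)
  expect_true(all(apart$significant))
  expect_equal(apart$cumulativeDifference, cumsum(apart$difference))
  expect_error(differenceAndCumulative(a, a[1:2, ]), "mismatched")
})

test_that("readthrough fractions match hand-computed toy tracks", {
  tr <- ProfileTrack(c(1, 1, 1, 1))
  expect_equal(readthroughFraction(tr, 2), 0.5)
  expect_equal(readthroughFraction(ProfileTrack(c(2, 2, 0, 0)), 2), 0)
  expect_equal(readthroughFraction(ProfileTrack(c(0, 0, 3, 3)), 2), 1)
  expect_equal(readthroughFraction(tr, 4), 0)     # nothing beyond the unit
  expect_equal(readthroughFraction(ProfileTrack(c(1, 0, 0, 3)), 1), 0.75)
  expect_error(readthroughFraction(ProfileTrack(numeric(4)), 2),
               "zero total")
  expect_error(readthroughFraction(tr, 9), "outside")
  # readthrough ignores flanking signal outside the unit window
  fl <- ProfileTrack(c(9, 1, 1, 9), unitStart = 2L, unitEnd = 3L)
  expect_equal(readthroughFraction(fl, 1), 0.5)
})

test_that("replicate readthrough groups are compared two-sided", {
  tst <- readthroughTest(c(0.10, 0.11, 0.12, 0.10),
                         c(0.30, 0.31, 0.29, 0.33))
  expect_equal(tst$alternative, "two.sided")
  expect_lt(tst$p.value, 0.05)
})

test_that("oligo(A) selection requires a terminal A-run", {
  tails <- c("AAA", "AA", "AAAT", "TAAA", "", "AAAAAA", "GAA")
  reads <- makeReads(rep(list(c(10, 30)), length(tails)), tail = tails)
  sel <- selectPolyA(reads, 3L)$reads
  expect_setequal(S4Vectors::mcols(sel)$tail, c("AAA", "TAAA", "AAAAAA"))
  # min_a = 0 selects everything
  expect_equal(length(selectPolyA(reads, 0L)$reads), length(reads))
  # strict mode: the whole tail must be adenosines
  strict <- selectPolyA(reads, 3L, tailAllA = TRUE)$reads
  expect_setequal(S4Vectors::mcols(strict)$tail, c("AAA", "AAAAAA"))
  bare <- makeReads(list(c(1, 5)))
  S4Vectors::mcols(bare) <- NULL
  expect_error(selectPolyA(bare, 3L), "tail")
})

test_that("the selector agrees with a brute-force tail scanner", {
  set.seed(99)
  n <- 10000
  tails <- vapply(seq_len(n), function(i) {
    len <- sample(0:8, 1)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, character(1))
  reads <- makeReads(rep(list(c(10, 40)), n), tail = tails)
  for (minA in c(1L, 3L, 5L)) {
    mine <- length(selectPolyA(reads, minA)$reads)
    brute <- sum(vapply(tails, bruteTerminalARun, integer(1)) >= minA)
    expect_identical(mine, brute)
  }
})

test_that("the adenylated-fraction track is a proper per-position fraction", {
  reads <- makeReads(list(c(1, 10), c(5, 10), c(2, 20)),
                     tail = c("AAAA", "T", "AAA"))
  frac <- selectPolyA(reads, 3L, refLength = 30)$fractionTrack@values
  expect_true(all(frac >= 0 & frac <= 1))
  expect_equal(frac[10], 0.5)
  expect_equal(frac[20], 1)
  expect_equal(frac[15], 0)
})

test_that("read-length statistics honour the 5' anchor", {
  reads <- makeReads(list(c(10, 29), c(10, 34), c(10, 39), c(50, 89)))
  all <- readLengthStats(reads)
  expect_equal(all$median, 27.5)
  anch <- readLengthStats(reads, anchor5p = 10)
  expect_equal(anch$median, 25)
  expect_equal(anch$n, 3)
  expect_equal(readLengthStats(reads, anchor5p = 50)$median, 40)
  expect_error(readLengthStats(reads, anchor5p = 999), "no reads")
})
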