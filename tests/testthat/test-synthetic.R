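test_that("the synthetic reference has the planted geometry", {
  map <- elementMap()
  ref <- makeReference(map, seed = 3)
  expect_equal(length(ref$sequence[[1]]), 7000 + 2 * 1300)
  anno <- ref$annotation
  nm <- S4Vectors::mcols(anno)$name
  b02 <- GenomicRanges::start(anno)[nm == "B0_2"]
  b2 <- GenomicRanges::start(anno)[nm == "B2"]
  t1 <- GenomicRanges::start(anno)[nm == "T1"]
  expect_equal(b02 - b2, 49L)
  expect_equal(t1 - b2, 93L)
  # T-rich run at the terminator
  s <- as.character(ref$sequence[[1]])
  expect_equal(substr(s, map@flank + map@t1, map@flank + map@t1 + 11L),
               strrep("T", 12))
  # same seed reproduces the sequence; different seed does not
  expect_identical(as.character(makeReference(map, seed = 3)$sequence),
                   as.character(ref$sequence))
  expect_false(identical(as.character(makeReference(map, seed = 4)$sequence),
                         as.character(ref$sequence)))
})

test_that("element maps with broken geometry are rejected", {
  expect_error(elementMap(b2 = 8290L), "fit within|increase")
  m <- elementMap()
  m@b01 <- m@b2 + 10L
  expect_error(validObject(m), "B0-1")
})

test_that("the cleavage class pins 5' ends at B0-2 with the planted median", {
  map <- elementMap()
  spec <- readSimSpec(nReads = 10000L, cleavage5pFraction = 1,
                      nReplicates = 1L, seed = 21L)
  reads <- simulateReads(spec, map)[[1]]
  p5 <- GenomicRanges::start(reads)
  expect_true(all(p5 == map@flank + map@b02))
  st <- readLengthStats(reads)
  expect_lte(abs(st$median - 25), 1)
})

test_that("read simulation respects replicate seeds and strand mode", {
  spec <- readSimSpec(nReads = 500L, nReplicates = 2L, seed = 7L)
  a <- simulateReads(spec)
  b <- simulateReads(spec)
  expect_identical(as.data.frame(a[[1]]), as.data.frame(b[[1]]))
  expect_false(identical(as.data.frame(a[[1]]), as.data.frame(a[[2]])))
  minus <- simulateReads(readSimSpec(nReads = 200L, nReplicates = 1L,
                                     cleavage5pFraction = 1, seed = 3L),
                         strand = "-")[[1]]
  map <- elementMap()
  # on the minus strand the biological 5' end is the interval end
  expect_true(all(GenomicRanges::end(minus) == map@flank + map@b02))
  expect_true(all(as.character(GenomicRanges::strand(minus)) == "-"))
  # empty request yields an empty, well-formed result
  empty <- simulateReads(readSimSpec(nReads = 0L, nReplicates = 1L))[[1]]
  expect_equal(length(empty), 0L)
  expect_true(all(c("tail", "count") %in%
                    names(S4Vectors::mcols(empty))))
})

test_that("disabling tailing removes every oligo(A) read", {
  spec <- readSimSpec(nReads = 2000L, polyABaseRate = 0, polyAPeakRate = 0,
                      junkTailRate = 0, nReplicates = 1L, seed = 5L)
  reads <- simulateReads(spec)[[1]]
  expect_equal(length(selectPolyA(reads, 3L)$reads), 0L)
})

test_that("planted peaks and tail enrichment survive the analysis round trip", {
  map <- elementMap()
  refLen <- map@unitLength + 2L * map@flank
  spec <- readSimSpec(nReads = 10000L, nReplicates = 1L, seed = 11L)
  reads <- simulateReads(spec, map)[[1]]
  tr <- endProfile(reads, refLen, mode = "three_prime",
                   unitStart = map@flank + 1L,
                   unitEnd = map@flank + map@unitLength)
  sm <- smoothBlackman(normalizeUnit(tr), 10L)
  pk <- findPeaks(sm, order = 45L, window = 80L, minHeight = 2)
  called <- pk@positions - map@flank
  planted <- c(spec@peakMixture$center, map@b02 + 25L)
  for (ctr in spec@peakMixture$center) {
    expect_true(min(abs(called - ctr)) <= 45 / 2 + 10,
                label = paste("peak near", ctr, "recovered"))
  }
  # oligo(A) fraction is higher at peak-proximal 3' ends than at background
  pa <- selectPolyA(reads, 3L, refLength = refLen)
  frac <- pa$fractionTrack@values
  e3 <- GenomicRanges::end(reads)
  occupied <- sort(unique(e3))
  nearPeak <- occupied[vapply(occupied, function(p)
    min(abs(p - (map@flank + planted))) <= 15, logical(1))]
  background <- occupied[vapply(occupied, function(p)
    min(abs(p - (map@flank + planted))) > 100, logical(1))]
  tst <- stats::wilcox.test(frac[nearPeak], frac[background],
                            alternative = "greater")
  expect_lt(tst$p.value, 0.01)
})
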