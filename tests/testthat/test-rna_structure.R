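test_that("nussinov_fold reproduces hand-checkable cases", {
  f <- nussinov_fold("GGGGAAAACCCC")
  expect_equal(f$max_pairs, 4L)
  expect_equal(f$max_pairs, bf_max_pairs("GGGGAAAACCCC"))
  expect_equal(nussinov_fold("AAAA")$max_pairs, 0L)
  expect_error(nussinov_fold("ACXGT"), "non-nucleotide")
})

test_that("nussinov_fold structures are well-formed and legal", {
  set.seed(3)
  for (i in 1:30) {
    s <- rand_dna(sample(5:40, 1))
    f <- nussinov_fold(s)
    expect_lte(f$max_pairs, floor(nchar(s) / 2))
    db <- strsplit(f$dot_bracket, "")[[1]]
    expect_equal(sum(db == "("), sum(db == ")"))
    expect_equal(nrow(f$pairs), f$max_pairs)
    if (nrow(f$pairs)) {
      chars <- strsplit(s, "")[[1]]
      expect_true(all(f$pairs$j - f$pairs$i > 3))
      expect_true(all(bf_pairable(chars[f$pairs$i], chars[f$pairs$j])))
    }
  }
})

test_that("nussinov_fold equals brute-force enumeration on short sequences", {
  set.seed(17)
  for (i in 1:60) {
    s <- rand_dna(sample(4:12, 1))
    expect_equal(nussinov_fold(s)$max_pairs, bf_max_pairs(s), info = s)
  }
})

test_that("find_stem_loops recovers a planted perfect hairpin exactly", {
  arm <- "GCTAGGCC"
  hp <- paste0(arm, "AAAAA", revcomp(arm)) # 8 bp stem, 5 nt loop
  left <- "CACCAACTAC"; right <- "CAACCATCAC" # non-pairing flanks
  s <- paste0(left, hp, right)
  found <- find_stem_loops(s, min_stem = 8)
  expect_gte(nrow(found), 1L)
  expect_equal(found$start[1], nchar(left) + 1L)
  expect_equal(found$end[1], nchar(left) + nchar(hp))
  expect_equal(found$stem_pairs[1], 8L)
  expect_equal(found$loop_len[1], 5L)

  # mirrored on the reverse strand (a hairpin is strand-symmetric); flank
  # bases may wobble-pair in the mirrored orientation, so check that the
  # exact mirrored stem is among the candidates
  rs <- revcomp(s)
  rfound <- find_stem_loops(rs, min_stem = 8, dedup = FALSE)
  expect_true(any(rfound$start == nchar(s) - found$end[1] + 1L &
                    rfound$end == nchar(s) - found$start[1] + 1L &
                    rfound$stem_pairs >= 8))
})

test_that("planted hairpin outscores dinucleotide-shuffled controls", {
  set.seed(23)
  arm <- "GCTAGGCCATGG" # 12 bp stem
  hp <- paste0(arm, "TTTTA", revcomp(arm))
  s <- paste0(rand_dna(30), hp, rand_dna(30))
  planted_score <- max(find_stem_loops(s, min_stem = 5)$score)
  wins <- 0L
  for (i in 1:100) {
    null_top <- find_stem_loops(dinuc_shuffle(s), min_stem = 5)
    top <- if (nrow(null_top)) max(null_top$score) else 0
    if (top < planted_score) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("pair_boxes measures antiparallel WC/GU pairing", {
  expect_equal(pair_boxes("ACCTAGG", revcomp("ACCTAGG")), 1)
  expect_equal(pair_boxes("ACCTAGG", "CCTCGGT"), 6 / 7)
  expect_error(pair_boxes("ACGT", "ACGTACGTAC"),
               class = "calintron_geometry_error")
})

test_that("random box pairing matches the enumerated expectation", {
  # exact per-column probability by enumeration over all ordered base pairs
  bases <- c("A", "C", "G", "T")
  p_exact <- mean(outer(bases, bases, Vectorize(bf_pairable)))
  expect_equal(p_exact, 6 / 16)
  set.seed(31)
  fr <- replicate(1000, pair_boxes(rand_dna(7), rand_dna(7)))
  se <- sqrt(p_exact * (1 - p_exact) / 7 / 1000)
  expect_lt(abs(mean(fr) - p_exact), 4 * se)
})
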