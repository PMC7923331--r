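tnp <- synthetic_tnp_panel()

make_is <- function(include_tnpB = TRUE) {
  hp <- fixture_palindrome()
  tnpA_nt <- back_translate(tnp$protein[tnp$class == "tnpA"][1])
  tnpB_nt <- back_translate(tnp$protein[tnp$class == "tnpB"][1])
  parts <- c("CACC", hp, "CCAC", revcomp(tnpA_nt), "CCAAC",
             if (include_tnpB) tnpB_nt, "CACC", hp, "CCAC")
  ends <- cumsum(nchar(parts))
  list(seq = paste(parts, collapse = ""),
       el_start = 5L, el_end = ends[length(ends) - 1L],
       tnpA = c(ends[3] + 1L, ends[4]),
       tnpB = if (include_tnpB) c(ends[5] + 1L, ends[6]))
}

test_that("a planted IS605-configuration element is called with exact ends", {
  set.seed(71)
  el <- make_is()
  s <- paste0(rand_dna(300), el$seq, rand_dna(300))
  found <- find_is_elements(s, tnp)
  expect_equal(nrow(found), 1L)
  expect_equal(found$group_call, "IS605_group")
  expect_equal(found$configuration, "opposite_orientation")
  expect_equal(found$start, 300L + el$el_start)
  expect_equal(found$end, 300L + el$el_end)
  expect_equal(found$tnpA_strand, "-")
  expect_equal(found$tnpB_strand, "+")
  expect_equal(found$left_stem, 12L)
  expect_equal(found$left_loop, 4L)
})

test_that("an element missing tnpB is partial; tnpA-only can be IS200-like", {
  set.seed(72)
  el <- make_is(include_tnpB = FALSE)
  s <- paste0(rand_dna(300), el$seq, rand_dna(300))
  found <- find_is_elements(s, tnp)
  expect_equal(nrow(found), 1L)
  expect_equal(found$configuration, "tnpA_only")
  expect_equal(found$group_call, "IS200_like")
  # decision table: tnpA only without any end hairpin -> partial
  hp_free <- paste0(strrep("CA", 150),
                    revcomp(back_translate(tnp$protein[tnp$class == "tnpA"][1])),
                    strrep("CA", 150))
  bare <- find_is_elements(hp_free, tnp)
  if (nrow(bare) == 1) expect_equal(bare$group_call, "partial")
  expect_error(find_is_elements(s, tnp[0, ]),
               class = "calintron_config_error")
})

test_that("detection mirrors under reverse complement of the landscape", {
  set.seed(73)
  el <- make_is()
  s <- paste0(rand_dna(200), el$seq, rand_dna(200))
  fwd <- find_is_elements(s, tnp)
  rev <- find_is_elements(revcomp(s), tnp)
  expect_equal(nrow(rev), 1L)
  n <- nchar(s)
  expect_equal(rev$start, n - fwd$end + 1L)
  expect_equal(rev$end, n - fwd$start + 1L)
  expect_equal(rev$group_call, "IS605_group")
  # orientation labels swap consistently
  expect_equal(rev$tnpA_strand, "+")
  expect_equal(rev$tnpB_strand, "-")
})

test_that("compare_elements quantifies identity and end congruence", {
  set.seed(74)
  el <- make_is()
  s <- paste0(rand_dna(200), el$seq, rand_dna(200))
  found <- find_is_elements(s, tnp)
  self <- compare_elements(found[1, ], found[1, ])
  expect_equal(self$nt_identity, 100)
  expect_true(all(self$ends$stem_diff == 0))
  expect_true(all(self$ends$seq_identity == 100))

  # ~2% substitutions: identity near 98 within binomial error
  mutant <- found[1, ]
  mutant$element_seq <- mutate_seq(found$element_seq[1], 0.02, seed = 99)
  cmp <- compare_elements(found[1, ], mutant)
  n <- nchar(found$element_seq[1])
  se <- 100 * sqrt(0.02 * 0.98 / n)
  expect_lt(abs(cmp$nt_identity - 98), 4 * se + 0.5)

  # unrelated sequence: identity near the random background
  unrel <- found[1, ]
  unrel$element_seq <- rand_dna(n)
  cmp2 <- compare_elements(found[1, ], unrel)
  expect_lt(cmp2$nt_identity, 80)
})
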