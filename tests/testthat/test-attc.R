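test_that("an exact-consensus attC site is detected with exact boxes", {
  fx <- fixture_attc()
  left <- rand_dna(80); right <- rand_dna(80)
  set.seed(101)
  s <- paste0(left, fx$seq, right)
  sites <- scan_attc(s, seq_id = "t")
  expect_equal(nrow(sites), 1L)
  off <- nchar(left)
  expect_equal(sites$r2_start, off + fx$offsets[["R2"]])
  expect_equal(sites$r2_end, off + fx$offsets[["R2"]] + 6L)
  expect_equal(sites$l2_start, off + fx$offsets[["L2"]])
  expect_equal(sites$l1_start, off + fx$offsets[["L1"]])
  expect_equal(sites$r1_start, off + fx$offsets[["R1"]])
  expect_equal(sites$r1_end, off + fx$offsets[["R1"]] + 6L)
  expect_equal(sites$strand, "+")
  expect_equal(sites$bs_strand, "-")
  expect_equal(sites$r_box_pairing, 6 / 7)
  expect_equal(sites$l_box_pairing, 1)
})

test_that("attC detection is strand-symmetric", {
  set.seed(102)
  fx <- fixture_attc()
  s <- paste0(rand_dna(60), fx$seq, rand_dna(60))
  fwd <- scan_attc(s, seq_id = "t")
  rev <- scan_attc(revcomp(s), seq_id = "t")
  expect_equal(nrow(rev), 1L)
  expect_equal(rev$strand, "-")
  expect_equal(rev$bs_strand, "+")
  n <- nchar(s)
  expect_equal(rev$start, n - fwd$end + 1L)
  expect_equal(rev$end, n - fwd$start + 1L)
  expect_equal(rev$r2_start, n - fwd$r2_end + 1L)
})

test_that("L'' mismatch budget gates detection", {
  set.seed(103)
  fx <- fixture_attc()
  # two substitutions in L'' that each break a pair (no GU rescue):
  # L'' = GACTGGC; T->C at box pos 4 (partner A), G->T at pos 5 (partner C)
  chars <- strsplit(fx$seq, "")[[1]]
  p <- fx$offsets[["L2"]]
  chars[p + 3] <- "C"; chars[p + 4] <- "T"
  mut <- paste(chars, collapse = "")
  s <- paste0(rand_dna(60), mut, rand_dna(60))
  lax <- scan_attc(s, attc_config(l_box_budget = 2), seq_id = "t")
  strict <- scan_attc(s, attc_config(l_box_budget = 1), seq_id = "t")
  expect_equal(nrow(lax), 1L)
  expect_equal(nrow(strict), 0L)
})

test_that("scan_attc stays silent on random background", {
  set.seed(104)
  fp <- vapply(1:10, function(i) nrow(scan_attc(rand_dna(5e4))), integer(1))
  expect_lte(sum(fp > 0), 1L)
})

test_that("cluster_attc applies the 8 kb gap rule at the boundary", {
  mk <- function(starts) {
    tibble::tibble(seq_id = "s", start = starts, end = starts + 45L)
  }
  # gap (bases strictly between sites) of 7999 joins, 8001 does not
  near <- mk(c(1L, 1L + 46L + 7999L))
  far <- mk(c(1L, 1L + 46L + 8001L))
  expect_equal(cluster_attc(near)$n_sites, 2L)
  expect_equal(nrow(cluster_attc(far)), 0L)
  chain <- mk(c(0L, 7000L, 14000L) + 1L)
  loci <- cluster_attc(chain)
  expect_equal(loci$n_sites, 3L)
})

test_that("cluster_attc equals the transitive-closure oracle", {
  set.seed(105)
  for (rep in 1:100) {
    n <- sample(2:12, 1)
    starts <- sort(sample.int(60000, n))
    sites <- tibble::tibble(seq_id = "s", start = starts, end = starts + 45L)
    thr <- sample(c(500L, 2000L, 8000L), 1)
    loci <- cluster_attc(sites, thr)
    comp <- cluster_oracle(sites$start, sites$end, thr)
    keep <- table(comp)
    expect_equal(nrow(loci), sum(keep >= 2))
    if (nrow(loci) > 0) {
      mine <- lapply(loci$sites, function(x) x$start)
      oracle <- unname(split(starts, comp))
      oracle <- oracle[vapply(oracle, length, 1L) >= 2]
      expect_equal(mine, unname(oracle))
    }
  }
  expect_error(
    cluster_attc(tibble::tibble(seq_id = c("a", "b"),
                                start = c(1L, 10L), end = c(5L, 20L))),
    class = "calintron_input_error")
})

test_that("delineate_cassettes builds leader plus inter-site segments", {
  starts <- c(5000L, 6000L, 7500L)
  sites <- tibble::tibble(seq_id = "s", start = starts, end = starts + 45L)
  loci <- cluster_attc(sites)
  orfs <- tibble::tibble(
    start = c(5100L, 5200L, 5300L, 5400L, 5500L, 5600L, 6100L, 6030L),
    end = c(5150L, 5250L, 5350L, 5450L, 5550L, 5650L, 6200L, 6090L),
    strand = "+", protein = "M")
  out <- delineate_cassettes(loci, orfs)
  cas <- out$cassettes[[1]]
  expect_equal(nrow(cas), 3L)
  # six ORFs land in the second cassette (between site 1 and site 2)
  expect_equal(cas$n_orfs[2], 6L)
  # ORF straddling the attC at 6000 is assigned by midpoint and flagged
  expect_equal(cas$n_orfs[3], 2L)
  straddler <- cas$orfs[[3]][cas$orfs[[3]]$start == 6030L, ]
  expect_true(straddler$boundary_spanning)
})

test_that("classify_locus separates complete integrons from CALINs", {
  intI <- synthetic_intI_panel()
  site_starts <- c(20000L, 21000L)
  sites <- tibble::tibble(seq_id = "s", start = site_starts,
                          end = site_starts + 45L)
  loci <- cluster_attc(sites)
  intI_orf <- tibble::tibble(start = 15000L, end = 15965L, strand = "+",
                             protein = intI$protein[1])
  far_orf <- tibble::tibble(start = 75000L, end = 75965L, strand = "+",
                            protein = intI$protein[1])
  junk <- tibble::tibble(start = 20500L, end = 20800L, strand = "+",
                         protein = paste(rep("M", 110), collapse = ""))
  expect_equal(classify_locus(loci, rbind(intI_orf, junk), intI)$classification,
               "complete_integron")
  expect_equal(classify_locus(loci, junk, intI)$classification, "CALIN")
  expect_equal(classify_locus(loci, rbind(far_orf, junk), intI)$classification,
               "CALIN")
  expect_error(classify_locus(loci, junk, intI[0, ]),
               class = "calintron_config_error")
})
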