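panel <- synthetic_iep_panel()

test_that("detect_iep recovers a panel reference with full domain coverage", {
  prot <- panel$protein[panel$class == "CL1"][1]
  orfs <- tibble::tibble(start = 1000L, end = 1000L + 3L * (nchar(prot) + 1) - 1L,
                         strand = "+", protein = prot)
  hits <- detect_iep(orfs, panel)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$class, "CL1")
  expect_equal(hits$identity, 100)
  expect_equal(hits$similarity, 100)
  expect_true(hits$yadd)
  dom <- hits$domains[[1]]
  expect_true(all(dom$status == "present"))
})

test_that("an N-terminally deleted IEP loses the RT0-RT4 domains", {
  prot <- panel$protein[panel$class == "E"][1]
  cut <- substr(prot, floor(0.4 * nchar(prot)) + 1, nchar(prot))
  orfs <- tibble::tibble(start = 1L, end = 3L * (nchar(cut) + 1),
                         strand = "+", protein = cut)
  hits <- detect_iep(orfs, panel)
  dom <- hits$domains[[1]]
  nterm <- dom$status[dom$domain %in% c("RT0", "RT1", "RT2")]
  cterm <- dom$status[dom$domain %in% c("RT5", "RT6", "RT7", "X")]
  expect_true(all(nterm %in% c("absent", "partial")))
  expect_true(all(cterm == "present"))
  expect_true(hits$yadd)
})

test_that("a mutated YADD motif is reported as absent", {
  prot <- panel$protein[panel$class == "A"][1]
  mut <- sub("YADD", "YAAA", prot, fixed = TRUE)
  orfs <- tibble::tibble(start = 1L, end = 3L * (nchar(mut) + 1),
                         strand = "+", protein = mut)
  hits <- detect_iep(orfs, panel)
  expect_false(hits$yadd)
  bad_panel <- panel
  bad_panel$domains <- replicate(nrow(panel), tibble::tibble(),
                                 simplify = FALSE)
  expect_error(detect_iep(orfs, bad_panel), class = "calintron_config_error")
})

test_that("classify_intron assigns classes with a margin and flags chimeras", {
  for (cl in unique(panel$class)) {
    p <- panel$protein[panel$class == cl][1]
    expect_equal(classify_intron(p, panel)$call, cl)
  }
  # leave-one-out: each member classifies to its own class via the sibling
  for (i in seq_len(nrow(panel))) {
    res <- classify_intron(panel$protein[i], panel[-i, ])
    expect_equal(res$call, panel$class[i])
  }
  a <- panel$protein[panel$class == "CL1"][1]
  b <- panel$protein[panel$class == "E"][1]
  half <- nchar(a) %/% 2
  chimera <- paste0(substr(a, 1, half), substr(b, half + 1, nchar(b)))
  res <- classify_intron(chimera, panel, margin = 15)
  expect_equal(res$call, "ambiguous")
  expect_setequal(c(res$best_class, res$runner_class), c("CL1", "E"))
  expect_lt(abs(res$best_identity - res$runner_identity), 15)
})

test_that("find_three_prime_end locates planted DV/DVI and the terminus", {
  set.seed(61)
  prot <- panel$protein[panel$class == "CL1"][1]
  orf_nt <- back_translate(prot)
  region <- fixture_three_prime_region("AGC")
  s <- paste0(rand_dna(50), orf_nt, region$seq, rand_dna(120))
  hit <- fixture_hit(51L, 50L + nchar(orf_nt))
  res <- find_three_prime_end(s, hit, intron_class = "CL1")
  off <- 50L + nchar(orf_nt)
  expect_equal(res$three_prime, off + region$terminus[2])
  expect_equal(res$dv$start, off + region$dv[1])
  expect_equal(res$dv$end, off + region$dv[2])
  expect_equal(res$dvi$start, off + region$dvi[1])
  expect_equal(res$dvi$end, off + region$dvi[2])
  expect_equal(res$terminus_tier, 1L)
  expect_false(res$deviant)
})

test_that("the catalytic triad is class-aware (CGC only for IIC)", {
  set.seed(62)
  prot <- panel$protein[panel$class == "C"][1]
  orf_nt <- back_translate(prot)
  region <- fixture_three_prime_region("CGC")
  s <- paste0(rand_dna(50), orf_nt, region$seq, rand_dna(120))
  hit <- fixture_hit(51L, 50L + nchar(orf_nt))
  iic <- find_three_prime_end(s, hit, intron_class = "C")
  expect_equal(iic$three_prime, 50L + nchar(orf_nt) + region$terminus[2])
  # an AGC-requiring class must not accept the CGC helix
  other <- find_three_prime_end(s, hit, intron_class = "CL1")
  expect_true(is.null(other) ||
                other$dv$start != 50L + nchar(orf_nt) + region$dv[1])
})

test_that("a deviant GU-style terminus needs the flagged relaxed mode", {
  set.seed(63)
  prot <- panel$protein[panel$class == "CL1"][1]
  orf_nt <- back_translate(prot)
  z8 <- "GATTCTAA"
  noterm <- paste0(z8, fixture_dv("AGC"), "CCCC", fixture_dvi(),
                   "GTCCGGCCGG") # no AXX(X)XRAY, no AY dinucleotide close by
  s <- paste0(rand_dna(50), orf_nt, noterm, "CCCCCCCC")
  hit <- fixture_hit(51L, 50L + nchar(orf_nt))
  strict <- find_three_prime_end(s, hit, intron_class = "CL1", relax = "none")
  relaxed <- find_three_prime_end(s, hit, intron_class = "CL1", relax = "any")
  expect_null(strict)
  expect_false(is.null(relaxed))
  expect_true(relaxed$deviant)
  expect_equal(relaxed$terminus_tier, 3L)
})

test_that("find_five_prime_end needs both the motif and target-site support", {
  set.seed(64)
  prot <- panel$protein[panel$class == "CL1"][1]
  orf_nt <- back_translate(prot)
  ibs2 <- "GAGTCC"; ibs1 <- "CTTGAC"
  di <- paste0("CCTACCATCACCTCCACA", revcomp(ibs2), "CCT", "CCCACCCC",
               revcomp(ibs1), rand_dna(60))
  s5 <- paste0(rand_dna(400), ibs2, ibs1, "GTGCG", di, rand_dna(80))
  orf_start <- nchar(s5) + 1L
  s <- paste0(s5, orf_nt, rand_dna(50))
  hit <- fixture_hit(orf_start, orf_start + nchar(orf_nt) - 1L)
  res <- find_five_prime_end(s, hit, intron_class = "CL1")
  expect_equal(res$position, 413L)
  expect_equal(res$mismatches, 0L)
  expect_false(res$deviant)
  expect_equal(res$support, 2L)

  # deviant boundary UUGCG-style: found with one mismatch, flagged
  s_dev <- sub("GTGCG", "TTGCG", s, fixed = TRUE)
  res_dev <- find_five_prime_end(s_dev, hit, intron_class = "CL1",
                                 max_mismatch = 1)
  expect_equal(res_dev$position, 413L)
  expect_true(res_dev$deviant)

  # deleted 5' region: no supported candidate
  s_del <- paste0(rand_dna(2000), orf_nt, rand_dna(50))
  hit_del <- fixture_hit(2001L, 2000L + nchar(orf_nt))
  expect_null(find_five_prime_end(s_del, hit_del, intron_class = "CL1"))
})

test_that("find_div_basal_stem respects the 200 bp upstream rule", {
  set.seed(65)
  z8 <- "GATTCTAA"
  partner <- revcomp(z8)
  # a neutral CA-repeat "ORF" region keeps the search space free of chance
  # complements so the placement rule is what decides
  orf_nt <- strrep("CA", 180)
  build <- function(upstream_gap) {
    pre <- paste0(rand_dna(300), partner, strrep("CA", upstream_gap / 2))
    s <- paste0(pre, orf_nt, z8, fixture_dv(), rand_dna(30))
    list(s = s, orf_start = nchar(pre) + 1L,
         dv_start = nchar(pre) + nchar(orf_nt) + nchar(z8) + 1L)
  }
  near <- build(150)
  hit <- fixture_hit(near$orf_start, near$orf_start + nchar(orf_nt) - 1L)
  res <- find_div_basal_stem(near$s, hit, list(start_c = near$dv_start))
  expect_equal(res$length, 8L)
  expect_equal(res$partner_c[1], near$orf_start - 150L - 8L)
  expect_equal(res$mismatches, 0L)
  far <- build(250)
  hit <- fixture_hit(far$orf_start, far$orf_start + nchar(orf_nt) - 1L)
  expect_null(find_div_basal_stem(far$s, hit, list(start_c = far$dv_start)))

  # a complementary stem planted inside the ORF is found in place
  orf2 <- paste0(strrep("CA", 80), partner, strrep("CA", 90))
  s2 <- paste0(rand_dna(300), orf2, z8, fixture_dv(), rand_dna(30))
  hit2 <- fixture_hit(301L, 300L + nchar(orf2))
  res2 <- find_div_basal_stem(s2, hit2,
                              list(start_c = 300L + nchar(orf2) + 9L))
  expect_equal(res2$partner_c[1], 300L + 160L + 1L)
})

test_that("map_ebs_ibs reports class-specific pairings", {
  ls1 <- generate_landscape(landscape_config(seed = 6))
  sites <- scan_attc(ls1$seq, seq_id = "L")
  models <- annotate_introns(ls1$seq, panel, seq_id = "L",
                             attc_sites = sites)
  cls <- vapply(models, function(m) m$class_call$call, "")
  iic <- models[[which(cls == "C")]]
  iib <- models[[which(cls == "CL1")]]
  expect_equal(iic$target_site$ibs1$matched_len, 4L)
  expect_null(iic$target_site$ibs2)
  expect_equal(iib$target_site$ibs1$matched_len, 6L)
  expect_false(is.null(iib$target_site$ibs2))
  expect_true(iib$target_site$ebs3$found)
  tr_e1 <- ls1$truth[ls1$truth$kind == "intron_iib" &
                       ls1$truth$feature == "ebs1", ]
  expect_equal(iib$target_site$ibs1$ebs1_start_c, tr_e1$start)
})

test_that("a missing EBS3 complement is reported as absent", {
  plants <- default_plants(1e5)
  plants$params[[which(plants$kind == "iib_intron")]] <-
    list(ebs3_present = FALSE)
  ls1 <- generate_landscape(landscape_config(seed = 7, plants = plants))
  models <- annotate_introns(ls1$seq, panel, seq_id = "L")
  cls <- vapply(models, function(m) m$class_call$call, "")
  iib <- models[[which(cls == "CL1")]]
  expect_false(iib$target_site$ebs3$found)
})

test_that("IIC-attC context flags insertion geometry", {
  ls1 <- generate_landscape(landscape_config(seed = 8))
  sites <- scan_attc(ls1$seq, seq_id = "L")
  models <- annotate_introns(ls1$seq, panel, seq_id = "L",
                             attc_sites = sites)
  cls <- vapply(models, function(m) m$class_call$call, "")
  iic <- models[[which(cls == "C")]]
  expect_true(iic$context$ttgt_junction)
  expect_true(iic$context$inside_attc_bs)
  expect_equal(iic$orientation_vs_cassettes, "opposite")
  iib <- models[[which(cls == "CL1")]]
  expect_true(iib$context$attc_adjacent)
  expect_false(iib$context$ttgt_junction)
  expect_equal(iib$orientation_vs_cassettes, "same")
  # no attC in reach: all flags off
  far <- check_iic_attc_context(iic, sites[sites$start > iic$end + 50000, ],
                                ls1$seq)
  expect_false(far$attc_adjacent)
})

test_that("integrity calls distinguish full, truncated and fragmented", {
  ls1 <- generate_landscape(landscape_config(seed = 9))
  models <- annotate_introns(ls1$seq, panel, seq_id = "L")
  integ <- vapply(models, function(m) m$integrity, "")
  cls <- vapply(models, function(m) m$class_call$call, "")
  expect_equal(unname(integ[cls == "CL1"]), "full")
  expect_equal(unname(integ[cls == "E"]), "five_prime_truncated")

  # an internal stop codon splits the IEP ORF: merged hit, fragmented call
  prot <- panel$protein[panel$class == "CL1"][1]
  broken <- paste0(substr(prot, 1, 150), "*", substr(prot, 151, nchar(prot)))
  orf_nt <- back_translate(broken, add_stop = TRUE)
  region <- fixture_three_prime_region("AGC")
  set.seed(66)
  s <- paste0(rand_dna(100), orf_nt, region$seq, rand_dna(120))
  orfs <- find_orfs(s, min_len = 300)
  hits <- detect_iep(orfs, panel)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$frame_disruptions, 1L)
  three <- find_three_prime_end(s, hits, intron_class = "CL1")
  model <- list(three_prime_coding = three$three_prime_coding,
                five_prime_coding = NULL)
  expect_equal(call_integrity(model, hits), "fragmented")
})
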