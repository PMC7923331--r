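test_that("generation is byte-reproducible from the seed", {
  a <- generate_landscape(landscape_config(seed = 12, length = 30000))
  b <- generate_landscape(landscape_config(seed = 12, length = 30000))
  expect_identical(a$seq, b$seq)
  expect_identical(a$truth, b$truth)
  c2 <- generate_landscape(landscape_config(seed = 13, length = 30000))
  expect_false(identical(a$seq, c2$seq))
})

test_that("truth anchors lie within their feature intervals", {
  ls1 <- generate_landscape(landscape_config(seed = 14))
  tr <- ls1$truth
  expect_true(all(tr$start <= tr$end))
  expect_true(all(tr$end <= nchar(ls1$seq)))
  for (pid in unique(tr$plant_id)) {
    sub <- tr[tr$plant_id == pid, ]
    feat <- sub[sub$feature %in% c("intron", "element", "site"), ]
    anchors <- sub[!sub$feature %in% c("intron", "element"), ]
    if (nrow(feat) == 0) next
    expect_true(all(anchors$start >= min(feat$start) - 1 &
                      anchors$end <= max(feat$end) + 1), label = pid)
  }
})

test_that("planted sequences match their truth coordinates", {
  ls1 <- generate_landscape(landscape_config(seed = 15))
  tr <- ls1$truth
  r2 <- tr[tr$feature == "box_r2", ]
  for (k in seq_len(nrow(r2))) {
    expect_equal(substr(ls1$seq, r2$start[k], r2$end[k]), "GCCTACC")
  }
  fp <- tr[tr$kind == "intron_iib" & tr$feature == "five_prime", ]
  expect_equal(substr(ls1$seq, fp$start, fp$start + 4L), "GTGCG")
  # IIC intron is on the minus strand: GUGYG reads on the bottom strand
  fpc <- tr[tr$kind == "intron_iic" & tr$feature == "five_prime", ]
  expect_equal(revcomp(substr(ls1$seq, fpc$start - 4L, fpc$start)), "GTGCG")
  # and its junction reads TTGT / intron / T on the bottom strand
  expect_equal(revcomp(substr(ls1$seq, fpc$start + 1L, fpc$start + 4L)),
               "TTGT")
})

test_that("mutate_seq applies the exact per-site model", {
  s <- rand_dna(500)
  expect_identical(mutate_seq(s, 0, seed = 1), s)
  all_changed <- mutate_seq(s, 1, seed = 1)
  expect_true(all(strsplit(all_changed, "")[[1]] != strsplit(s, "")[[1]]))
  # empirical substitution rate within 3 SD of binomial expectation
  set.seed(16)
  n <- 1e5
  big <- rand_dna(n)
  mut <- mutate_seq(big, 0.02)
  d <- sum(strsplit(big, "")[[1]] != strsplit(mut, "")[[1]])
  expect_lt(abs(d - n * 0.02), 3 * sqrt(n * 0.02 * 0.98))
})

test_that("substituted-site counts follow the binomial across seeds", {
  counts <- vapply(1:100, function(seed) {
    cfg <- landscape_config(seed = seed, length = 10000, mutation_rate = 0.02,
                            plants = tibble::tibble(
                              kind = character(), at = integer(),
                              params = list()))
    mu0 <- generate_landscape(landscape_config(
      seed = seed, length = 10000, mutation_rate = 0,
      plants = cfg$plants))
    mu <- generate_landscape(cfg)
    sum(strsplit(mu0$seq, "")[[1]] != strsplit(mu$seq, "")[[1]])
  }, integer(1))
  expect_lt(abs(mean(counts) - 200), 3 * sqrt(10000 * 0.02 * 0.98 / 100))
})

test_that("overlapping plants raise a placement error naming the pair", {
  plants <- tibble::tibble(
    kind = c("attc_array", "attc_array"),
    at = c(1000L, 1010L),
    params = list(list(n_sites = 2), list(n_sites = 2)))
  expect_error(
    generate_landscape(landscape_config(seed = 1, length = 20000,
                                        plants = plants)),
    "overlap", class = "calintron_placement_error")
})

test_that("export_landscape writes FASTA, GFF3 and JSON truth", {
  ls1 <- generate_landscape(landscape_config(seed = 17, length = 20000))
  dir <- withr::local_tempdir()
  paths <- export_landscape(ls1, dir)
  expect_true(all(file.exists(paths)))
  fa <- read_fasta(paths[["fasta"]])
  expect_equal(fa$residues, ls1$seq)
  expect_equal(readLines(paths[["gff3"]], n = 1), "##gff-version 3")
  js <- jsonlite::read_json(paths[["json"]])
  expect_equal(js$config$seed, 17)
})
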