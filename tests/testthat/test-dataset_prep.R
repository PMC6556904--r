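test_that("redundancy reduction collapses near-identical sequences", {
  set.seed(21)
  base <- paste(sample(aa20, 120, TRUE), collapse = "")
  variant <- base
  substr(variant, 5, 5) <- "G"  # single substitution: far above 70% identity
  other <- paste(sample(aa20, 100, TRUE), collapse = "")
  seqs <- c(a = base, b = variant, c = other)
  kept <- reduce_redundancy(seqs, 0.70)
  expect_equal(length(kept), 2L)
  expect_true("c" %in% names(kept))

  # identical pair
  expect_equal(length(reduce_redundancy(c(x = base, y = base))), 1L)
  # no shared 5-mers
  expect_equal(length(reduce_redundancy(c(x = strrep("A", 50),
                                          y = strrep("G", 50)))), 2L)
})

test_that("retained set is pairwise below the identity threshold", {
  set.seed(22)
  pool <- replicate(8, paste(sample(aa20, 90, TRUE), collapse = ""))
  # add mutated copies to force clustering
  mut <- vapply(pool[1:4], function(s) {
    ch <- strsplit(s, "")[[1]]
    ch[sample(90, 4)] <- sample(aa20, 4, TRUE)
    paste(ch, collapse = "")
  }, character(1))
  seqs <- setNames(c(pool, mut), paste0("q", 1:12))
  kept <- reduce_redundancy(seqs, 0.70)
  for (i in seq_along(kept)) {
    for (j in seq_along(kept)) {
      if (i < j) {
        expect_lt(sequence_identity(kept[[i]], kept[[j]]), 0.70)
      }
    }
  }
})

test_that("train/test split is substrate-level, disjoint and reproducible", {
  ids <- paste0("s", 1:6)
  sp <- split_train_test(ids, seed = 3)
  expect_equal(length(sp$train), 5L)
  expect_equal(length(sp$test), 1L)
  expect_identical(sort(c(sp$train, sp$test)), sort(ids))
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(sp, split_train_test(ids, seed = 3))
  expect_error(split_train_test("only_one"), "at least 2")
})

test_that("extract_window follows the P8-P8' convention with X padding", {
  s <- "ACDEFGHIKLMNPQRSTVWYACDEFG"  # 26 residues
  expect_equal(nchar(s), 26L)
  # p1 = 13: residues 6..21, no padding
  expect_identical(extract_window(s, 13), substr(s, 6, 21))
  # p1 = 3: 5 leading X, residues 1..3, then 4..11
  expect_identical(extract_window(s, 3),
                   paste0("XXXXX", substr(s, 1, 3), substr(s, 4, 11)))
  # p1 = 1 on a length-9 sequence: 7 X + residue 1 + residues 2..9
  s9 <- substr(s, 1, 9)
  expect_identical(extract_window(s9, 1),
                   paste0("XXXXXXX", substr(s9, 1, 1), substr(s9, 2, 9)))
  expect_error(extract_window(s, 0), "out of range")
  expect_error(extract_window(s, 26), "out of range")
})

test_that("extract_window is position-equivariant away from termini", {
  set.seed(23)
  s <- paste(sample(aa20, 60, TRUE), collapse = "")
  shifted <- substr(s, 2, 60)
  for (p1 in 10:50) {
    expect_identical(extract_window(s, p1), extract_window(shifted, p1 - 1))
  }
})

test_that("build_samples enforces the 1:3 ratio and per-protease exclusions", {
  set.seed(24)
  sim <- generate_substrates(10, length_range = c(60, 80),
                             sites_per_substrate = 2, seed = 31)
  samples <- build_samples(sim$sequences, sim$events, "X01.001", seed = 5)
  n_pos <- sum(samples$label == 1)
  expect_equal(n_pos, 20L)
  expect_equal(sum(samples$label == 0), 3L * n_pos)
  expect_true(all(nchar(samples$window) == 16L))
  # no negative shares (substrate, p1) with a positive of the same protease
  key <- paste(samples$substrate_id, samples$p1)
  expect_length(intersect(key[samples$label == 1], key[samples$label == 0]), 0L)
  # bit-reproducible under the seed
  expect_identical(samples,
                   build_samples(sim$sequences, sim$events, "X01.001", seed = 5))
  expect_error(build_samples(sim$sequences, sim$events, "NOPE"),
               "zero positive")
})

test_that("candidate exhaustion keeps all negatives with a warning", {
  sim <- generate_substrates(1, length_range = c(40, 40),
                             sites_per_substrate = 1, seed = 8)
  # a single 40-residue substrate has 39 bonds; 1 positive leaves 38 < 3*13
  ev <- sim$events
  ev <- rbind(ev, data.frame(substrate_id = ev$substrate_id[1],
                             protease_id = "X01.001",
                             p1 = setdiff(10:23, ev$p1)[1:12]))
  expect_warning(samples <- build_samples(sim$sequences, ev, "X01.001"),
                 "keeping all")
  expect_equal(sum(samples$label == 0), 39L - 13L)
})

test_that("solvent-accessibility filter restricts negatives to buried sites", {
  sim <- generate_substrates(6, length_range = c(60, 80),
                             sites_per_substrate = 1, tracks = TRUE, seed = 9)
  samples <- build_samples(sim$sequences, sim$events, "X01.001",
                           tracks = sim$tracks, seed = 2)
  negs <- samples[samples$label == 0, ]
  buried <- vapply(seq_len(nrow(negs)), function(i) {
    sim$tracks[[negs$substrate_id[i]]]$sa_state[negs$p1[i]]
  }, character(1))
  expect_true(all(buried == "buried"))
  expect_true(attr(samples, "provenance")$sa_filtered)

  # degenerate filter: everything exposed -> warned fallback
  all_exposed <- lapply(sim$tracks, function(tr) {
    tr$sa_state[] <- "exposed"
    tr
  })
  expect_warning(build_samples(sim$sequences, sim$events, "X01.001",
                               tracks = all_exposed, seed = 2),
                 "falling back")
})

test_that("sample sets round-trip through their TSV serialization", {
  sim <- generate_substrates(4, length_range = c(50, 60),
                             sites_per_substrate = 1, seed = 12)
  samples <- build_samples(sim$sequences, sim$events, "X01.001", seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_samples(samples, f)
  back <- read_samples(f)
  expect_equal(back$window, samples$window)
  expect_equal(back$label, samples$label)
})
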