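test_that("BINARY encoding is a position-wise one-hot over 21 letters", {
  v <- encode_binary(strrep("A", 16))
  expect_length(v, 336L)
  expect_equal(sum(v), 16)
  expect_true(all(v[grep("\\.A$", names(v))] == 1))

  padded <- paste0("XXX", strrep("C", 13))
  vp <- encode_binary(padded)
  expect_equal(unname(vp[paste0("BINARY.", c("P8", "P7", "P6"), ".X")]),
               rep(1, 3))
  expect_error(encode_binary(paste0("B", strrep("A", 15))), "alphabet")
})

test_that("CKSAAP counts k-spaced pairs normalized by L-(k+1)", {
  v0 <- encode_cksaap(strrep("A", 16))
  expect_length(v0, 2400L)
  expect_equal(unname(v0[["CKSAAP.k0.AA"]]), 1)
  expect_equal(sum(v0[grepl("^CKSAAP.k0", names(v0))]), 1)

  v <- encode_cksaap("ACACACACACACACAC")
  expect_equal(unname(v[["CKSAAP.k0.AC"]]), 8 / 15)
  expect_equal(unname(v[["CKSAAP.k0.CA"]]), 7 / 15)
  # k = 1 pairs skip one residue: A.A and C.C only
  expect_equal(unname(v[["CKSAAP.k1.AA"]]), 7 / 14)
  expect_equal(unname(v[["CKSAAP.k1.CC"]]), 7 / 14)
})

test_that("CKSAAP k-blocks sum to at most 1, exactly 1 without X", {
  set.seed(31)
  for (i in 1:20) {
    w <- random_window(with_x = (i %% 2 == 0))
    v <- encode_cksaap(w)
    for (k in 0:5) {
      s <- sum(v[grepl(paste0("^CKSAAP.k", k, "\\."), names(v))])
      if (grepl("X", w)) expect_lte(s, 1 + 1e-12) else
        expect_equal(s, 1, tolerance = 1e-12)
    }
  }
})

test_that("AAC is the residue composition over L = 16 with X uncounted", {
  v <- encode_aac(strrep("A", 16))
  expect_length(v, 20L)
  expect_equal(unname(v[["AAC.A"]]), 1)
  v2 <- encode_aac("ACDEFGHIKLMNPQRS")
  expect_equal(sum(v2 == 1 / 16), 16L)
  vx <- encode_aac(paste0(strrep("X", 8), strrep("A", 8)))
  expect_equal(sum(vx), 0.5)
})

test_that("clipped BLOSUM62 similarity matches hand-derived values", {
  expect_equal(knn_similarity("AC", "AC"), 4 + 9)
  expect_equal(knn_similarity("AC", "AD"), 4 + 0)
  expect_error(knn_similarity("AC", "ACD"), "length mismatch")
  # identical windows dominate any single substitution
  set.seed(32)
  w <- random_window()
  self <- knn_similarity(w, w)
  for (pos in c(1, 8, 16)) {
    for (aa in aa20) {
      mut <- w
      substr(mut, pos, pos) <- aa
      expect_lte(knn_similarity(w, mut), self)
    }
  }
})

test_that("KNN features match a brute-force full-sort oracle", {
  set.seed(33)
  refs <- vapply(1:200, function(i) random_window(), character(1))
  labels <- rep(c(1L, 0L), c(50L, 150L))
  ref <- knn_reference(refs, labels)
  oracle_knn <- function(query) {
    sims <- vapply(refs, function(r) knn_similarity(query, r), numeric(1))
    keep <- refs != query
    sims <- sims[keep]; labs <- labels[keep]
    ord <- order(-sims)
    vapply(c(0.01, 0.03, 0.05, 0.07, 0.09), function(f) {
      K <- max(1L, as.integer(floor(f * 200 + 0.5)))
      mean(labs[ord[seq_len(min(K, length(ord)))]])
    }, numeric(1))
  }
  for (q in c(refs[3], refs[77], random_window(), random_window())) {
    expect_equal(unname(encode_knn(q, ref)), oracle_knn(q))
  }
})

test_that("KNN degenerate references behave as expected", {
  pos_w <- strrep("D", 16)
  ref <- knn_reference(c(pos_w, strrep("K", 16)), c(1L, 0L),
                       fractions = c(0.01, 0.03, 0.05, 0.07, 0.09))
  # query identical to the positive: excluded from ranking, so the nearest
  # remaining reference decides; query similar to positive
  near_pos <- paste0(strrep("D", 15), "E")
  expect_equal(unname(encode_knn(near_pos, ref)), rep(1, 5))
  # all-negative neighbourhoods give zero components
  set.seed(34)
  refs <- vapply(1:40, function(i) random_window(), character(1))
  ref2 <- knn_reference(c(refs, strrep("W", 16)), c(rep(0L, 40), 1L))
  far_query <- strrep("G", 16)
  expect_equal(unname(encode_knn(far_query, ref2))[1], 0)
  expect_error(knn_reference(refs, rep(0L, 40)), "both")
})

test_that("PSSM encoding squashes scores and zeroes padded rows", {
  set.seed(35)
  s <- paste(sample(aa20, 30, TRUE), collapse = "")
  prof <- synthetic_pssm(s, seed = 4)
  v <- encode_pssm(prof, 15)
  expect_length(v, 320L)
  expect_equal(unname(v[1]), 1 / (1 + exp(-prof[8, 1])))
  # p1 near the N-terminus: the first 5 window positions are pads
  v2 <- encode_pssm(prof, 3)
  expect_true(all(v2[1:100] == 0))
  expect_true(all(v2[101:320] > 0))
  expect_error(encode_pssm(prof, 30), "out of range")
})

test_that("BLOSUM block stacks residue rows and aligns with BINARY one-hots", {
  b <- load_blosum62()
  v <- encode_blosum(strrep("A", 16))
  expect_length(v, 336L)
  expect_equal(unname(matrix(v, nrow = 21)[, 1]), unname(b["A", ]))
  set.seed(36)
  w <- random_window(with_x = TRUE)
  vb <- encode_binary(w)
  vB <- encode_blosum(w)
  for (p in 1:16) {
    onehot <- vb[(p - 1) * 21 + 1:21]
    row <- vB[(p - 1) * 21 + 1:21]
    aa <- procleave:::.AA21[which(onehot == 1)]
    expect_equal(unname(row), unname(b[aa, ]))
  }
})

test_that("AAindex encoding is position-major, scaled, with mean-imputed X", {
  tab <- synthetic_aaindex(n = 70, seed = 6)
  cfg <- aaindex_config(tab)
  expect_length(cfg$selected, 64L)
  w <- paste0("X", strrep("A", 15))
  v <- encode_aaindex(w, cfg)
  expect_length(v, 1024L)
  expect_true(all(v >= 0 & v <= 1))
  # first 64 components belong to the padded P8 position: per-index means
  expect_equal(unname(v[1:64]), unname(rowMeans(cfg$scaled[, 1:20])))
  expect_error(aaindex_config(tab, selected = rownames(tab)[1:10]),
               "exactly 64")
})

test_that("greedy AAindex subset choice is deterministic and diverse", {
  tab <- synthetic_aaindex(n = 70, seed = 6)
  s1 <- choose_aaindex_subset(tab, 64)
  s2 <- choose_aaindex_subset(tab[sample(nrow(tab)), ], 64)
  expect_identical(s1, s2)  # invariant to row order
  expect_length(unique(s1), 64L)
})

test_that("CHR computes charge, hydropathy and their ratio per segment", {
  v <- encode_chr(strrep("D", 16))
  expect_length(v, 9L)
  expect_equal(unname(v[c("CHR.N.charge", "CHR.C.charge", "CHR.full.charge")]),
               c(-8, -8, -16))
  vg <- encode_chr(strrep("G", 16))
  expect_equal(unname(vg[grep("charge", names(vg))]), c(0, 0, 0))
  expect_equal(unname(vg[grep("ratio", names(vg))]), c(0, 0, 0))
  # Kyte-Doolittle: G = -0.4 per residue
  expect_equal(unname(vg[["CHR.full.hydropathy"]]), -6.4)
})

test_that("structural encodings one-hot the tracks with uniform pad priors", {
  tr <- list(ss = rep("H", 30), sa_state = rep("buried", 30),
             sa_value = rep(0.1, 30), diso = rep(0.5, 30))
  vss <- encode_structural(tr, 15, "SS")
  expect_length(vss, 48L)
  expect_true(all(vss[grep("\\.H$", names(vss))] == 1))
  vsa <- encode_structural(tr, 15, "SA")
  expect_length(vsa, 32L)
  expect_true(all(vsa[grep("buried", names(vsa))] == 1))
  vd <- encode_structural(tr, 15, "DISO")
  expect_length(vd, 32L)
  expect_true(all(vd == 0.5))
  # pads take uniform priors
  vss2 <- encode_structural(tr, 3, "SS")
  expect_equal(unname(vss2[1:3]), rep(1 / 3, 3))
  expect_error(encode_structural(NULL, 15, "SS"), "tracks required")
})

test_that("the full 11-scheme vector has 4562 components with a manifest", {
  set.seed(37)
  s <- paste(sample(aa20, 40, TRUE), collapse = "")
  toy <- toy_window_set(10, 30)
  ctx <- encoding_context(
    schemes = names(scheme_dims()),
    knn_ref = knn_reference(toy$windows, toy$labels),
    aaindex = aaindex_config(synthetic_aaindex(70, seed = 6)),
    profiles = list(s1 = synthetic_pssm(s, seed = 2)),
    tracks = list(s1 = list(ss = rep("C", 40),
                            sa_state = rep("exposed", 40),
                            sa_value = rep(0.6, 40), diso = rep(0.2, 40))))
  v <- encode_window(extract_window(s, 20), ctx, "s1", 20)
  expect_length(v, 4562L)
  man <- feature_manifest(ctx)
  expect_equal(nrow(man), 4562L)
  expect_equal(unname(table(man$scheme)[names(scheme_dims())]),
               unname(scheme_dims()), ignore_attr = TRUE)
  # purity: identical inputs give identical outputs
  expect_identical(v, encode_window(extract_window(s, 20), ctx, "s1", 20))
})

test_that("sequence-only contexts concatenate the expected blocks", {
  ctx <- encoding_context(c("BINARY", "CKSAAP", "AAC", "BLOSUM", "AAINDEX",
                            "CHR"),
                          aaindex = aaindex_config(synthetic_aaindex(70, 6)))
  v <- encode_window(strrep("A", 16), ctx)
  expect_length(v, 336L + 2400L + 20L + 336L + 1024L + 9L)
  expect_error(encoding_context(c("BINARY", "WAVELET")), "unknown scheme")
  expect_error(encoding_context(c("BINARY", "KNN")), "missing providers")
})
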