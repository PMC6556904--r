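## The eleven feature encoding schemes and their concatenation into a
## (up to) 4562-component vector.
##
## Fixed block order and dimensions:
##   BINARY 336, CKSAAP 2400, KNN 5, AAC 20, PSSM 320, BLOSUM 336,
##   AAINDEX 1024, CHR 9, SS 48, SA 32, DISO 32  (total 4562).

.SCHEME_DIMS <- c(BINARY = 336L, CKSAAP = 2400L, KNN = 5L, AAC = 20L,
                  PSSM = 320L, BLOSUM = 336L, AAINDEX = 1024L, CHR = 9L,
                  SS = 48L, SA = 32L, DISO = 32L)

#' Feature scheme dimensions
#'
#' @return Named integer vector giving, in canonical concatenation order, the
#'   component count of each of the eleven feature schemes. The full
#'   11-scheme vector has `sum(scheme_dims())` = 4562 components.
#' @export
scheme_dims <- function() .SCHEME_DIMS

# ordered pair labels AA, AC, AD, ..., YY (first letter major)
.PAIR_LABELS <- paste0(rep(.AA20, each = 20L), rep(.AA20, 20L))

## ---- sequence-derived schemes ----------------------------------------------

#' One-hot (BINARY) window encoding
#'
#' Each of the 16 window positions is encoded as a 21-component one-hot block
#' in fixed alphabet order (`ACDEFGHIKLMNPQRSTVWY` then `X`).
#'
#' @param window 16-character window string.
#' @return Named numeric vector of length 336.
#' @export
encode_binary <- function(window) {
  .check_window(window)
  codes <- window_codes(window)
  m <- matrix(0, nrow = 21L, ncol = .WINDOW_SIZE)
  m[cbind(codes, seq_len(.WINDOW_SIZE))] <- 1
  v <- as.vector(m)
  names(v) <- paste0("BINARY.", rep(.POS_LABELS, each = 21L), ".",
                     rep(.AA21, .WINDOW_SIZE))
  v
}

#' Composition of k-spaced amino-acid pairs (CKSAAP)
#'
#' For each gap `k`, counts ordered residue pairs `(i, i + k + 1)` over the
#' 400 pair types of the 20-letter alphabet and divides by
#' `Ntotal = L - (k + 1)` with `L = 16`. Pairs involving `X` contribute to
#' `Ntotal` but to no pair type. Blocks are concatenated in ascending `k`.
#'
#' @param window 16-character window string.
#' @param k_values Gap sizes (default `0:5`, giving 400 x 6 = 2400 components).
#' @return Named numeric vector of length `400 * length(k_values)`.
#' @export
encode_cksaap <- function(window, k_values = 0:5) {
  .check_window(window)
  stopifnot(all(k_values >= 0L), all(k_values <= .WINDOW_SIZE - 2L))
  codes <- window_codes(window)
  blocks <- lapply(k_values, function(k) {
    i <- seq_len(.WINDOW_SIZE - k - 1L)
    a <- codes[i]
    b <- codes[i + k + 1L]
    valid <- a <= 20L & b <= 20L
    counts <- tabulate((a[valid] - 1L) * 20L + b[valid], nbins = 400L)
    v <- counts / (.WINDOW_SIZE - (k + 1L))
    names(v) <- paste0("CKSAAP.k", k, ".", .PAIR_LABELS)
    v
  })
  unlist(blocks)
}

#' Clipped BLOSUM62 similarity between two equal-length peptides
#'
#' Sum over positions of `max(BLOSUM62(a, b), 0)`.
#'
#' @param window_a,window_b Equal-length peptide strings over the 21-letter
#'   alphabet.
#' @param matrix Substitution matrix (default [load_blosum62()]).
#' @return Numeric similarity score.
#' @examples
#' knn_similarity("AC", "AC")  # 4 + 9 = 13
#' @export
knn_similarity <- function(window_a, window_b, matrix = load_blosum62()) {
  if (nchar(window_a) != nchar(window_b)) {
    stop("length mismatch: ", nchar(window_a), " vs ", nchar(window_b))
  }
  a <- match(strsplit(window_a, "", fixed = TRUE)[[1]], rownames(matrix))
  b <- match(strsplit(window_b, "", fixed = TRUE)[[1]], colnames(matrix))
  if (anyNA(a) || anyNA(b)) stop("characters outside the matrix alphabet")
  sum(pmax(matrix[cbind(a, b)], 0))
}

#' Reference set for KNN features
#'
#' Stores labelled reference windows and the K-fractions used by
#' [encode_knn()].
#'
#' @param windows Character vector of 16-residue reference windows.
#' @param labels 0/1 labels aligned to `windows` (both classes required).
#' @param fractions Strictly increasing K fractions in (0, 1); defaults to
#'   1, 3, 5, 7 and 9 percent of the reference size.
#' @return Object of class `knn_reference`.
#' @export
knn_reference <- function(windows, labels,
                          fractions = c(0.01, 0.03, 0.05, 0.07, 0.09)) {
  stopifnot(length(windows) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) < 2L) {
    stop("reference must contain both positive and negative windows")
  }
  if (any(diff(fractions) <= 0) || any(fractions <= 0) || any(fractions >= 1)) {
    stop("fractions must be strictly increasing within (0, 1)")
  }
  codes <- t(vapply(windows, window_codes, integer(.WINDOW_SIZE)))
  rownames(codes) <- NULL
  structure(list(windows = windows, labels = labels, fractions = fractions,
                 codes = codes),
            class = "knn_reference")
}

# similarity of one query window against every reference row (vectorized)
.knn_scores <- function(codes_q, ref, matrix) {
  clipped <- pmax(matrix, 0)
  s <- numeric(nrow(ref$codes))
  for (i in seq_len(.WINDOW_SIZE)) {
    s <- s + clipped[codes_q[i], ref$codes[, i]]
  }
  s
}

#' KNN features of a window against a labelled reference
#'
#' For each fraction `f`, `K = max(1, round(f * N))` with `N` the reference
#' size; reference windows are ranked by clipped-BLOSUM62 similarity
#' ([knn_similarity()]) to the query, descending, ties broken by stable
#' reference order; the component is the fraction of positives among the top
#' `K`. Reference entries identical to the query are excluded from the
#' ranking (so a training window never votes for itself).
#'
#' @param window 16-character query window.
#' @param ref [knn_reference()] object.
#' @param matrix Substitution matrix (default BLOSUM62).
#' @param exclude_self Drop reference entries whose window string equals the
#'   query (default `TRUE`).
#' @return Named numeric vector of length `length(ref$fractions)`.
#' @export
encode_knn <- function(window, ref, matrix = load_blosum62(),
                       exclude_self = TRUE) {
  .check_window(window)
  stopifnot(inherits(ref, "knn_reference"))
  scores <- .knn_scores(window_codes(window), ref, matrix)
  labels <- ref$labels
  keep <- rep(TRUE, length(scores))
  if (exclude_self) keep <- ref$windows != window
  scores <- scores[keep]
  labels <- labels[keep]
  n_total <- length(ref$labels)
  ord <- order(-scores)  # stable: ties keep reference order
  v <- vapply(ref$fractions, function(f) {
    K <- max(1L, as.integer(floor(f * n_total + 0.5)))
    K <- min(K, length(ord))
    mean(labels[ord[seq_len(K)]])
  }, numeric(1))
  names(v) <- paste0("KNN.f", formatC(round(ref$fractions * 100),
                                      format = "d"))
  v
}

#' Amino-acid composition (AAC) of a window
#'
#' Occurrence count of each of the 20 standard residues divided by the window
#' length `L = 16`; `X` counts toward `L` but toward no residue slot.
#'
#' @param window 16-character window string.
#' @return Named numeric vector of length 20.
#' @export
encode_aac <- function(window) {
  .check_window(window)
  codes <- window_codes(window)
  v <- tabulate(codes[codes <= 20L], nbins = 20L) / .WINDOW_SIZE
  names(v) <- paste0("AAC.", .AA20)
  v
}

## ---- evolutionary schemes --------------------------------------------------

#' PSSM window encoding
#'
#' Per window position the 20 position-specific scores of the substrate's
#' residue profile, squashed by the logistic function `1 / (1 + exp(-s))`.
#' Positions padded beyond the sequence termini contribute a zero row (the
#' logistic is not applied to pads).
#'
#' @param profile Residue profile matrix (rows = positions, 20 columns; see
#'   [parse_pssm()]).
#' @param p1 P1 position of the window on the profiled sequence.
#' @return Named numeric vector of length 320.
#' @export
encode_pssm <- function(profile, p1) {
  L <- nrow(profile)
  if (p1 < 1L || p1 >= L) stop("p1 out of range for profile of length ", L)
  pos <- (p1 - 7L):(p1 + 8L)
  block <- matrix(0, nrow = .WINDOW_SIZE, ncol = 20L)
  inside <- pos >= 1L & pos <= L
  block[inside, ] <- 1 / (1 + exp(-profile[pos[inside], , drop = FALSE]))
  v <- as.vector(t(block))
  names(v) <- paste0("PSSM.", rep(.POS_LABELS, each = 20L), ".",
                     rep(colnames(profile), .WINDOW_SIZE))
  v
}

#' BLOSUM62 row window encoding
#'
#' Per window position the 21-component BLOSUM62 row of its residue (the `X`
#' row is all zeros, covering padded positions).
#'
#' @param window 16-character window string.
#' @param matrix Substitution matrix (default [load_blosum62()]).
#' @return Named numeric vector of length 336.
#' @export
encode_blosum <- function(window, matrix = load_blosum62()) {
  .check_window(window)
  codes <- window_codes(window)
  v <- as.vector(t(matrix[codes, , drop = FALSE]))
  names(v) <- paste0("BLOSUM.", rep(.POS_LABELS, each = 21L),
                     ".", rep(colnames(matrix), .WINDOW_SIZE))
  v
}

## ---- physicochemical schemes -----------------------------------------------

#' Configure the AAindex feature block
#'
#' Selects (or accepts) the 64 physicochemical indices used by
#' [encode_aaindex()] and records a version label so trained models can refuse
#' feature vectors produced under a different index list.
#'
#' @param table AAindex value matrix from [parse_aaindex()].
#' @param selected Character vector of exactly 64 accessions, or `NULL` to
#'   choose them with [choose_aaindex_subset()].
#' @param version Version label stored with models (default: a label derived
#'   from the selected accessions).
#' @return Object of class `aaindex_config` with components `scaled` (64 x 21
#'   matrix in \[0, 1\], `X` column = per-index mean), `selected`, `version`.
#' @export
aaindex_config <- function(table, selected = NULL, version = NULL) {
  table <- table[order(rownames(table)), , drop = FALSE]
  if (anyNA(table)) stop("AAindex table contains missing values; drop those indices first")
  if (is.null(selected)) selected <- choose_aaindex_subset(table, 64L)
  if (length(selected) != 64L) {
    stop("exactly 64 AAindex accessions must be configured, got ",
         length(selected))
  }
  if (!all(selected %in% rownames(table))) {
    stop("unknown AAindex accessions: ",
         paste(setdiff(selected, rownames(table)), collapse = ", "))
  }
  sub <- table[selected, .AA20, drop = FALSE]
  rng <- apply(sub, 1, function(x) diff(range(x)))
  rng[rng == 0] <- 1
  scaled <- (sub - apply(sub, 1, min)) / rng
  scaled <- cbind(scaled, X = rowMeans(scaled))
  if (is.null(version)) {
    version <- sprintf("aaindex64-%08x",
                       sum(utf8ToInt(paste(selected, collapse = "")) *
                             seq_along(utf8ToInt(paste(selected, collapse = "")))) %%
                         .Machine$integer.max)
  }
  structure(list(scaled = scaled, selected = selected, version = version),
            class = "aaindex_config")
}

#' Deterministically choose a maximally diverse AAindex subset
#'
#' Greedy max-min selection: after min-max scaling each index over its 20
#' residue values, start from the pair of indices at maximum Euclidean
#' distance, then repeatedly add the index maximizing the minimum distance to
#' the chosen set; ties are broken by accession order.
#'
#' @param table AAindex value matrix (rows = indices).
#' @param n Number of indices to choose (default 64).
#' @return Character vector of `n` accessions, in accession order.
#' @export
choose_aaindex_subset <- function(table, n = 64L) {
  table <- table[order(rownames(table)), , drop = FALSE]
  if (nrow(table) < n) {
    stop("need at least ", n, " complete AAindex entries, have ", nrow(table))
  }
  rng <- apply(table, 1, function(x) diff(range(x)))
  rng[rng == 0] <- 1
  scaled <- (table - apply(table, 1, min)) / rng
  d <- as.matrix(stats::dist(scaled))
  # founding pair: maximum distance, ties by accession order of (i, j)
  mx <- max(d)
  hit <- which(d >= mx - 1e-12, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  chosen <- as.integer(hit[1, ])
  while (length(chosen) < n) {
    rest <- setdiff(seq_len(nrow(table)), chosen)
    mind <- apply(d[rest, chosen, drop = FALSE], 1, min)
    chosen <- c(chosen, rest[which.max(mind)])  # which.max: lowest index on tie
  }
  sort(rownames(table)[chosen])
}

#' AAindex physicochemical window encoding
#'
#' Per window position the 64 configured index values of its residue, each
#' index min-max scaled to \[0, 1\] over its 20 residue values; `X` takes the
#' per-index mean. Ordering is position-major (64 values for P8, then P7, ...).
#'
#' @param window 16-character window string.
#' @param aaindex [aaindex_config()] object.
#' @return Named numeric vector of length 1024.
#' @export
encode_aaindex <- function(window, aaindex) {
  .check_window(window)
  stopifnot(inherits(aaindex, "aaindex_config"))
  codes <- window_codes(window)
  block <- aaindex$scaled[, codes, drop = FALSE]  # 64 x 16
  v <- as.vector(block)
  names(v) <- paste0("AAINDEX.", rep(.POS_LABELS, each = 64L), ".",
                     rep(aaindex$selected, .WINDOW_SIZE))
  v
}

#' Charge/hydrophobicity-ratio (CHR) window encoding
#'
#' Over three segments (N-side P8-P1, C-side P1'-P8', and the full window)
#' computes the net charge (K, R, H: +1; D, E: -1), the summed Kyte-Doolittle
#' hydropathy (`X` contributes 0), and the ratio
#' `charge / (|hydropathy| + 1)` -- nine components.
#'
#' @param window 16-character window string.
#' @return Named numeric vector of length 9.
#' @export
encode_chr <- function(window) {
  .check_window(window)
  ch <- strsplit(window, "", fixed = TRUE)[[1]]
  segs <- list(N = 1:8, C = 9:16, full = 1:16)
  v <- unlist(lapply(names(segs), function(tag) {
    s <- ch[segs[[tag]]]
    charge <- sum(s %in% c("K", "R", "H")) - sum(s %in% c("D", "E"))
    hyd <- sum(.KD_HYDROPATHY[s], na.rm = TRUE)  # X -> NA -> 0
    c(charge = charge, hydropathy = hyd, ratio = charge / (abs(hyd) + 1))
  }))
  names(v) <- paste0("CHR.", rep(names(segs), each = 3L), ".",
                     rep(c("charge", "hydropathy", "ratio"), 3L))
  v
}

## ---- structural schemes ----------------------------------------------------

#' Structural-track window encoding (SS / SA / DISO)
#'
#' Slices the per-residue structural tracks over the 16 window positions.
#' `SS` yields a 3-state one-hot (H/E/C) per position (48 components); `SA` a
#' buried/exposed one-hot (32); `DISO` the pair (p, 1 - p) of the disorder
#' probability (32). Positions padded beyond the termini take uniform state
#' priors (1/3 or 1/2 per state).
#'
#' @param tracks Track list (see [parse_tracks()]) for the substrate.
#' @param p1 P1 position of the window.
#' @param kind One of `"SS"`, `"SA"`, `"DISO"`.
#' @return Named numeric vector of length 48 (SS) or 32 (SA/DISO).
#' @export
encode_structural <- function(tracks, p1, kind = c("SS", "SA", "DISO")) {
  kind <- match.arg(kind)
  if (is.null(tracks)) {
    stop("structural tracks required for the ", kind, " scheme but none ",
         "supplied; drop the scheme or provide a tracks provider")
  }
  L <- length(tracks$ss)
  pos <- (p1 - 7L):(p1 + 8L)
  inside <- pos >= 1L & pos <= L
  if (kind == "SS") {
    states <- c("H", "E", "C")
    block <- matrix(1 / 3, nrow = .WINDOW_SIZE, ncol = 3L)
    block[inside, ] <- 0
    block[cbind(which(inside), match(tracks$ss[pos[inside]], states))] <- 1
  } else if (kind == "SA") {
    states <- c("buried", "exposed")
    block <- matrix(1 / 2, nrow = .WINDOW_SIZE, ncol = 2L)
    block[inside, ] <- 0
    block[cbind(which(inside), match(tracks$sa_state[pos[inside]], states))] <- 1
  } else {
    states <- c("p", "q")
    block <- matrix(1 / 2, nrow = .WINDOW_SIZE, ncol = 2L)
    p <- tracks$diso[pos[inside]]
    block[inside, ] <- cbind(p, 1 - p)
  }
  v <- as.vector(t(block))
  names(v) <- paste0(kind, ".", rep(.POS_LABELS, each = length(states)), ".",
                     rep(states, .WINDOW_SIZE))
  v
}

## ---- context and concatenation ---------------------------------------------

#' Assemble the inputs needed by a set of feature schemes
#'
#' Bundles every provider the enabled schemes need so windows can be encoded
#' with a single call. Schemes are always applied in the canonical block
#' order (see [scheme_dims()]) regardless of the order given.
#'
#' @param schemes Character vector of scheme tags to enable (subset of
#'   `names(scheme_dims())`). Default: the sequence-only schemes that need no
#'   external providers.
#' @param blosum Substitution matrix (default [load_blosum62()]).
#' @param knn_ref [knn_reference()] object (required when `"KNN"` enabled).
#' @param aaindex [aaindex_config()] object (required when `"AAINDEX"`
#'   enabled).
#' @param profiles Residue-profile provider for `"PSSM"`: named list of
#'   matrices or `function(substrate_id)`.
#' @param tracks Structural-track provider for `"SS"`/`"SA"`/`"DISO"`: named
#'   list of track lists or `function(substrate_id)`.
#' @param k_values CKSAAP gap sizes (default `0:5`).
#' @return Object of class `encoding_context`.
#' @export
encoding_context <- function(schemes = c("BINARY", "CKSAAP", "AAC", "BLOSUM",
                                         "CHR"),
                             blosum = load_blosum62(), knn_ref = NULL,
                             aaindex = NULL, profiles = NULL, tracks = NULL,
                             k_values = 0:5) {
  unknown <- setdiff(schemes, names(.SCHEME_DIMS))
  if (length(unknown) > 0L) {
    stop("unknown scheme name(s): ", paste(unknown, collapse = ", "),
         "; choose from: ", paste(names(.SCHEME_DIMS), collapse = ", "))
  }
  schemes <- names(.SCHEME_DIMS)[names(.SCHEME_DIMS) %in% schemes]
  missing <- character(0)
  if ("KNN" %in% schemes && is.null(knn_ref)) missing <- c(missing, "knn_ref (KNN)")
  if ("AAINDEX" %in% schemes && is.null(aaindex)) missing <- c(missing, "aaindex (AAINDEX)")
  if ("PSSM" %in% schemes && is.null(profiles)) missing <- c(missing, "profiles (PSSM)")
  if (any(c("SS", "SA", "DISO") %in% schemes) && is.null(tracks)) {
    missing <- c(missing, "tracks (SS/SA/DISO)")
  }
  if (length(missing) > 0L) {
    stop("missing providers for enabled schemes: ",
         paste(missing, collapse = "; "))
  }
  structure(list(schemes = schemes, blosum = blosum, knn_ref = knn_ref,
                 aaindex = aaindex, profiles = profiles, tracks = tracks,
                 k_values = k_values),
            class = "encoding_context")
}

.provider_get <- function(provider, id) {
  if (is.null(provider)) return(NULL)
  if (is.function(provider)) provider(id) else provider[[id]]
}

#' Encode one candidate cleavage site as a feature vector
#'
#' Concatenates the enabled schemes' blocks in canonical order. With all
#' eleven schemes enabled the vector has 4562 components.
#'
#' @param window 16-character P8-P8' window.
#' @param context [encoding_context()] object.
#' @param substrate_id,p1 Required when profile- or track-based schemes
#'   (PSSM, SS, SA, DISO) are enabled, to locate the window on its substrate.
#' @return Named numeric vector; the names form the column manifest mapping
#'   every component to (scheme, position, residue/pair/index).
#' @export
encode_window <- function(window, context, substrate_id = NULL, p1 = NULL) {
  stopifnot(inherits(context, "encoding_context"))
  blocks <- lapply(context$schemes, function(s) {
    switch(s,
      BINARY = encode_binary(window),
      CKSAAP = encode_cksaap(window, context$k_values),
      KNN = encode_knn(window, context$knn_ref, context$blosum),
      AAC = encode_aac(window),
      PSSM = {
        prof <- .provider_get(context$profiles, substrate_id)
        if (is.null(prof)) stop("no residue profile available for substrate ",
                                substrate_id)
        encode_pssm(prof, p1)
      },
      BLOSUM = encode_blosum(window, context$blosum),
      AAINDEX = encode_aaindex(window, context$aaindex),
      CHR = encode_chr(window),
      SS = encode_structural(.provider_get(context$tracks, substrate_id), p1, "SS"),
      SA = encode_structural(.provider_get(context$tracks, substrate_id), p1, "SA"),
      DISO = encode_structural(.provider_get(context$tracks, substrate_id), p1, "DISO"))
  })
  dims <- vapply(blocks, length, integer(1))
  expected <- .SCHEME_DIMS[context$schemes]
  expected["CKSAAP"] <- 400L * length(context$k_values)
  bad <- dims != expected[context$schemes]
  if (any(bad)) {
    stop("internal consistency error: block dimension mismatch for ",
         paste(context$schemes[bad], collapse = ", "))
  }
  unlist(blocks)
}

#' Column manifest of an encoding context
#'
#' @param context [encoding_context()] object.
#' @return `data.frame` with columns `column` (component name) and `scheme`.
#' @export
feature_manifest <- function(context) {
  v <- encode_window(strrep("A", .WINDOW_SIZE), .manifest_context(context),
                     substrate_id = ".manifest", p1 = 8L)
  data.frame(column = names(v),
             scheme = sub("\\..*$", "", names(v)),
             stringsAsFactors = FALSE)
}

# context whose providers answer for the synthetic manifest probe
.manifest_context <- function(context) {
  dummy_profile <- matrix(0, nrow = .WINDOW_SIZE, ncol = 20L,
                          dimnames = list(NULL, .PSSM_COLS))
  dummy_tracks <- list(ss = rep("C", .WINDOW_SIZE),
                       sa_state = rep("exposed", .WINDOW_SIZE),
                       sa_value = rep(0.5, .WINDOW_SIZE),
                       diso = rep(0.5, .WINDOW_SIZE))
  context$profiles <- function(id) dummy_profile
  context$tracks <- function(id) dummy_tracks
  context
}

#' Encode a sample set as a feature matrix
#'
#' Applies [encode_window()] to every row of a sample `data.frame` (or to a
#' plain character vector of windows) and stacks the results.
#'
#' @param samples Sample `data.frame` from [build_samples()] (columns
#'   `substrate_id`, `p1`, `window`), or a character vector of windows.
#' @param context [encoding_context()] object.
#' @param sequences Optional named character vector of substrate sequences;
#'   when given, profile and track lengths are validated against it before
#'   encoding (the join is refused on mismatch).
#' @return Numeric matrix, one row per sample, with manifest column names.
#' @export
build_feature_matrix <- function(samples, context, sequences = NULL) {
  if (is.character(samples)) {
    samples <- data.frame(substrate_id = NA_character_, p1 = NA_integer_,
                          window = samples, stringsAsFactors = FALSE)
  }
  if (!is.null(sequences)) .validate_providers(samples, context, sequences)
  n <- nrow(samples)
  first <- encode_window(samples$window[1L], context,
                         samples$substrate_id[1L], samples$p1[1L])
  out <- matrix(0, nrow = n, ncol = length(first),
                dimnames = list(NULL, names(first)))
  out[1L, ] <- first
  if (n > 1L) {
    for (i in 2:n) {
      out[i, ] <- encode_window(samples$window[i], context,
                                samples$substrate_id[i], samples$p1[i])
    }
  }
  out
}

.validate_providers <- function(samples, context, sequences) {
  ids <- unique(samples$substrate_id)
  for (id in ids) {
    L <- nchar(sequences[[id]])
    if ("PSSM" %in% context$schemes) {
      prof <- .provider_get(context$profiles, id)
      if (is.null(prof) || nrow(prof) != L) {
        stop("residue profile for substrate ", id, " has ",
             if (is.null(prof)) 0L else nrow(prof),
             " rows but the sequence has ", L, " residues; join refused")
      }
    }
    if (any(c("SS", "SA", "DISO") %in% context$schemes)) {
      tr <- .provider_get(context$tracks, id)
      if (is.null(tr) || length(tr$ss) != L) {
        stop("structural tracks for substrate ", id, " have ",
             if (is.null(tr)) 0L else length(tr$ss),
             " positions but the sequence has ", L, " residues; join refused")
      }
    }
  }
  invisible(TRUE)
}

#' Write a feature matrix with its manifest header as TSV
#'
#' @param features Feature matrix from [build_feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  utils::write.table(as.data.frame(features), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
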