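## Homology reduction, substrate-level train/test split, P8-P8' window
## extraction, and positive/negative sample construction with down-sampling.

.seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Estimate pairwise sequence identity from shared k-mers
#'
#' Word-based identity estimate in the spirit of CD-HIT's short-word filter:
#' the fraction of distinct k-mers of the shorter sequence that also occur in
#' the longer one.
#'
#' @param a,b Sequences.
#' @param word_size k-mer length (default 5).
#' @return Identity estimate in \[0, 1\].
#' @export
sequence_identity <- function(a, b, word_size = 5L) {
  ka <- .seq_kmers(a, word_size)
  kb <- .seq_kmers(b, word_size)
  if (length(ka) == 0L || length(kb) == 0L) return(0)
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Greedy homology reduction of a sequence set
#'
#' Greedy incremental clustering, longest sequence first: a sequence joins the
#' first existing cluster whose representative it matches at or above
#' `identity_threshold` (by [sequence_identity()]); otherwise it founds a new
#' cluster. One representative (the founding, longest member) is retained per
#' cluster. The procedure is deterministic given the input.
#'
#' @param sequences Named character vector of sequences.
#' @param identity_threshold Identity ceiling; retained representatives are
#'   pairwise below it (default 0.70).
#' @param word_size k-mer length for the identity estimate.
#' @return The retained subset of `sequences`, in input order.
#' @export
reduce_redundancy <- function(sequences, identity_threshold = 0.70,
                              word_size = 5L) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (length(sequences) == 0L) return(sequences)
  ord <- order(-nchar(sequences))
  kept <- integer(0)
  kmer_cache <- lapply(sequences, .seq_kmers, k = word_size)
  for (i in ord) {
    ki <- kmer_cache[[i]]
    joins <- FALSE
    for (j in kept) {
      kj <- kmer_cache[[j]]
      if (length(ki) && length(kj) &&
          length(intersect(ki, kj)) / min(length(ki), length(kj)) >=
            identity_threshold) {
        joins <- TRUE
        break
      }
    }
    if (!joins) kept <- c(kept, i)
  }
  sequences[sort(kept)]
}

#' Split substrates into training and independent test sets
#'
#' The split is at substrate level (never at window level), disjoint, and
#' reproducible under `seed`. With the default fraction, 5 of every 6
#' substrates go to training.
#'
#' @param ids Character vector of substrate ids (or any identifiers).
#' @param train_fraction Fraction assigned to training (default 5/6).
#' @param seed Integer seed.
#' @return List with components `train` and `test` (disjoint, union = `ids`).
#' @export
split_train_test <- function(ids, train_fraction = 5 / 6, seed = 1L) {
  n <- length(ids)
  if (n < 2L) stop("need at least 2 substrates to split")
  stopifnot(train_fraction > 0, train_fraction < 1)
  n_train <- min(n - 1L, max(1L, as.integer(round(n * train_fraction))))
  set.seed(seed)
  idx <- sort(sample.int(n, n_train))
  list(train = ids[idx], test = ids[-idx])
}

#' Extract the P8-P8' window around a candidate scissile bond
#'
#' The window comprises residues `p1 - 7 .. p1` (P8..P1) followed by
#' `p1 + 1 .. p1 + 8` (P1'..P8'); positions beyond either terminus are filled
#' with `X`.
#'
#' @param sequence Substrate sequence.
#' @param p1 1-based index of the P1 residue; cleavage is between `p1` and
#'   `p1 + 1`, so `1 <= p1 < nchar(sequence)` is required.
#' @return 16-character window string.
#' @examples
#' extract_window("ABCDEFGHIKLMNPQRSTVWYACDEFG", 13)
#' @export
extract_window <- function(sequence, p1) {
  L <- nchar(sequence)
  if (length(p1) != 1L || is.na(p1) || p1 < 1L || p1 >= L) {
    stop("p1 out of range: need 1 <= p1 < sequence length (", L, ")")
  }
  extract_windows(sequence, p1)
}

#' Extract several windows from one sequence
#'
#' Vectorized form of [extract_window()].
#'
#' @param sequence Substrate sequence.
#' @param p1s Integer vector of P1 positions.
#' @return Character vector of 16-character windows.
#' @export
extract_windows <- function(sequence, p1s) {
  L <- nchar(sequence)
  if (any(p1s < 1L | p1s >= L)) {
    stop("p1 out of range: need 1 <= p1 < sequence length (", L, ")")
  }
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  offs <- c(-7:0, 1:8)
  vapply(p1s, function(p) {
    pos <- p + offs
    w <- rep("X", .WINDOW_SIZE)
    inside <- pos >= 1L & pos <= L
    w[inside] <- ch[pos[inside]]
    paste(w, collapse = "")
  }, character(1))
}

#' Build a labelled sample set for one protease
#'
#' Positives are the windows at every annotated P1 position of the protease.
#' Candidate negatives are all other bonds (positions `1..L-1`) of the given
#' substrates, excluding positions annotated as P1 for the *same* protease on
#' the same substrate (other proteases' sites may serve as negatives). If
#' solvent-accessibility tracks are supplied, candidates are restricted to
#' positions whose P1 residue is predicted buried (solvent inaccessible).
#' Candidates are then down-sampled uniformly at random, without replacement,
#' to `ratio_neg_per_pos` negatives per positive (all candidates, with a
#' warning, if fewer are available).
#'
#' @param sequences Named character vector of substrate sequences.
#' @param events Annotation `data.frame` (see [read_annotations()]).
#' @param protease_id Protease whose model is being built.
#' @param ratio_neg_per_pos Negatives retained per positive (default 3).
#' @param tracks Optional solvent-accessibility provider: a named list of
#'   track lists (see [parse_tracks()]) or a function `function(id)` returning
#'   one; `NULL` disables the filter (plain random down-sampling).
#' @param seed Integer seed for the down-sampling.
#' @return `data.frame` with columns `substrate_id`, `p1`, `window`, `label`
#'   (1 = cleavage, 0 = non-cleavage) and `protease_id`; provenance (seed,
#'   whether the accessibility filter was applied) is attached as attribute
#'   `provenance`.
#' @export
build_samples <- function(sequences, events, protease_id,
                          ratio_neg_per_pos = 3L, tracks = NULL, seed = 1L) {
  ev <- events[events$protease_id == protease_id, , drop = FALSE]
  if (nrow(ev) == 0L) {
    stop("zero positive cleavage events for protease ", protease_id)
  }
  get_tracks <- if (is.null(tracks)) NULL
                else if (is.function(tracks)) tracks
                else function(id) tracks[[id]]
  pos <- data.frame(substrate_id = ev$substrate_id, p1 = ev$p1,
                    stringsAsFactors = FALSE)
  neg_list <- lapply(names(sequences), function(id) {
    L <- nchar(sequences[[id]])
    cand <- setdiff(seq_len(L - 1L), ev$p1[ev$substrate_id == id])
    data.frame(substrate_id = rep(id, length(cand)), p1 = cand,
               stringsAsFactors = FALSE)
  })
  neg <- do.call(rbind, neg_list)
  sa_filtered <- FALSE
  if (!is.null(get_tracks)) {
    buried <- vapply(seq_len(nrow(neg)), function(i) {
      tr <- get_tracks(neg$substrate_id[i])
      if (is.null(tr)) return(NA)
      tr$sa_state[neg$p1[i]] == "buried"
    }, logical(1))
    if (!any(buried, na.rm = TRUE)) {
      warning("solvent-accessibility filter left no buried candidate ",
              "negatives; falling back to unfiltered candidates")
    } else {
      neg <- neg[!is.na(buried) & buried, , drop = FALSE]
      sa_filtered <- TRUE
    }
  }
  n_target <- as.integer(ratio_neg_per_pos) * nrow(pos)
  set.seed(seed)
  if (nrow(neg) <= n_target) {
    warning("only ", nrow(neg), " candidate negatives available for ",
            n_target, " requested; keeping all")
  } else {
    neg <- neg[sort(sample.int(nrow(neg), n_target)), , drop = FALSE]
  }
  pos$label <- 1L
  neg$label <- 0L
  out <- rbind(pos, neg)
  out$window <- vapply(seq_len(nrow(out)), function(i) {
    extract_windows(sequences[[out$substrate_id[i]]], out$p1[i])
  }, character(1))
  out$protease_id <- protease_id
  out <- out[c("substrate_id", "p1", "window", "label", "protease_id")]
  rownames(out) <- NULL
  attr(out, "provenance") <- list(seed = seed, sa_filtered = sa_filtered,
                                  ratio_neg_per_pos = as.integer(ratio_neg_per_pos))
  out
}

#' Serialize / read a sample set as TSV
#'
#' @param samples Sample `data.frame` from [build_samples()].
#' @param path File path.
#' @return `path` (write) or the sample `data.frame` (read).
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("substrate_id", "p1", "window", "label", "protease_id")
  if (!all(req %in% names(tab))) {
    stop("sample file must have columns: ", paste(req, collapse = ", "))
  }
  tab[req]
}
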