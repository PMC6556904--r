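## Generator of MEROPS-like synthetic substrate datasets with planted
## position-weight-matrix cleavage motifs and plausible structural tracks,
## so the whole pipeline can run and be tested without downloads.

#' Construct a cleavage-motif model
#'
#' @param name Motif name.
#' @param pwm 20 x 16 position weight matrix (rows = residues in
#'   `ACDEFGHIKLMNPQRSTVWY` order, columns = window positions P8..P8');
#'   every column must sum to 1.
#' @param strength Interpolation weight in \[0, 1\] between the uniform
#'   background (0) and the PWM (1) applied when sampling planted sites.
#' @return Object of class `motif_model`.
#' @export
motif_model <- function(name, pwm, strength = 0.9) {
  stopifnot(is.matrix(pwm), nrow(pwm) == 20L, ncol(pwm) == .WINDOW_SIZE,
            strength >= 0, strength <= 1)
  if (any(abs(colSums(pwm) - 1) > 1e-8) || any(pwm < 0)) {
    stop("every PWM column must be a probability distribution")
  }
  rownames(pwm) <- .AA20
  colnames(pwm) <- .POS_LABELS
  structure(list(name = name, pwm = pwm, strength = strength),
            class = "motif_model")
}

# start from uniform background and overwrite single-column preferences
.pwm_with <- function(prefs) {
  pwm <- matrix(1 / 20, nrow = 20L, ncol = .WINDOW_SIZE,
                dimnames = list(.AA20, .POS_LABELS))
  for (pos in names(prefs)) {
    pref <- prefs[[pos]]  # named weights summing to < 1
    rest <- (1 - sum(pref)) / (20L - length(pref))
    col <- rep(rest, 20L)
    names(col) <- .AA20
    col[names(pref)] <- pref
    pwm[, pos] <- col
  }
  pwm
}

#' Caspase-like cleavage motif
#'
#' Emulates the canonical DEVD|G caspase specificity: a near-absolute Asp
#' requirement at P1, a strong Asp preference at P4 (the DXXD motif), and
#' weaker Glu/Val/Gly preferences at P3, P2 and P1'.
#'
#' @param strength Motif strength (see [motif_model()]).
#' @return `motif_model` object.
#' @export
caspase_like_motif <- function(strength = 0.9) {
  motif_model("caspase_like", .pwm_with(list(
    P4 = c(D = 0.80),
    P3 = c(E = 0.55),
    P2 = c(V = 0.45),
    P1 = c(D = 0.95),
    P1p = c(G = 0.40, S = 0.20, A = 0.15)
  )), strength)
}

#' Glycine-rich cleavage motif
#'
#' Emulates an MMP-like specificity with Gly over-represented at the P7, P4,
#' P2, P1, P3' and P6' positions; all other columns are uniform background.
#'
#' @param strength Motif strength (see [motif_model()]).
#' @return `motif_model` object.
#' @export
gly_rich_motif <- function(strength = 0.9) {
  prefs <- stats::setNames(rep(list(c(G = 0.60)),
                               6L),
                           c("P7", "P4", "P2", "P1", "P3p", "P6p"))
  motif_model("gly_rich", .pwm_with(prefs), strength)
}

# simple first-order Markov chain over a state set
.markov_chain <- function(n, states, stay = 0.8) {
  out <- character(n)
  out[1L] <- sample(states, 1L)
  for (i in seq_len(n - 1L)) {
    out[i + 1L] <- if (stats::runif(1) < stay) out[i] else
      sample(setdiff(states, out[i]), 1L)
  }
  out
}

.synthetic_tracks <- function(L) {
  ss <- .markov_chain(L, c("H", "E", "C"), stay = 0.85)
  sa_state <- .markov_chain(L, c("buried", "exposed"), stay = 0.75)
  sa_value <- ifelse(sa_state == "buried", stats::runif(L, 0, 0.25),
                     stats::runif(L, 0.25, 1))
  diso_state <- .markov_chain(L, c("lo", "hi"), stay = 0.9)
  diso <- ifelse(diso_state == "lo", stats::runif(L, 0, 0.35),
                 stats::runif(L, 0.65, 1))
  list(ss = ss, sa_state = sa_state, sa_value = sa_value, diso = diso)
}

#' Generate synthetic substrates with planted cleavage motifs
#'
#' Background residues are drawn i.i.d. uniformly over the 20 standard
#' letters. For each planted site, an internal P1 is chosen such that the
#' full P8-P8' window lies inside the sequence and does not overlap another
#' planted window, and the 16 window residues are redrawn column-wise from
#' `strength * PWM + (1 - strength) * uniform`. Annotations record the
#' planted (protease, P1) events. Optional per-residue structural tracks are
#' drawn from simple Markov chains. Fully reproducible under `seed`.
#'
#' @param n Number of substrates (>= 1).
#' @param length_range Inclusive range of substrate lengths (min >= 40).
#' @param motif [motif_model()] (default [caspase_like_motif()]).
#' @param sites_per_substrate Planted cleavage sites per substrate.
#' @param protease_id Identifier recorded for planted events; the default
#'   `"X01.001"` is a reserved synthetic id so family mapping warns rather
#'   than mislabels.
#' @param tracks Also generate structural tracks (default `FALSE`).
#' @param seed Integer seed.
#' @return List with components `sequences` (named character vector),
#'   `events` (annotation `data.frame`), `tracks` (named list or `NULL`),
#'   `motif` and `seed`.
#' @export
generate_substrates <- function(n, length_range = c(120L, 240L),
                                motif = caspase_like_motif(),
                                sites_per_substrate = 2L,
                                protease_id = "X01.001", tracks = FALSE,
                                seed = 1L) {
  stopifnot(n >= 1L, length_range[1] >= 40L,
            length_range[2] >= length_range[1],
            inherits(motif, "motif_model"))
  set.seed(seed)
  eff <- motif$strength * motif$pwm + (1 - motif$strength) / 20
  seqs <- character(n)
  ids <- sprintf("SYN%04d", seq_len(n))
  ev <- list()
  trk <- if (tracks) stats::setNames(vector("list", n), ids) else NULL
  for (i in seq_len(n)) {
    lens <- seq(length_range[1], length_range[2])
    L <- lens[sample.int(length(lens), 1L)]
    ch <- sample(.AA20, L, replace = TRUE)
    rng <- 8:(L - 8L)
    placed <- FALSE
    p1s <- integer(0)
    # windows must lie inside the termini and not overlap each other; all
    # sites are redrawn together until a valid placement is found
    if (sites_per_substrate <= length(rng)) {
      for (try in seq_len(1000L)) {
        p1s <- sample(rng, sites_per_substrate)
        if (sites_per_substrate == 1L ||
            all(diff(sort(p1s)) >= .WINDOW_SIZE)) {
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      stop("cannot place ", sites_per_substrate, " non-overlapping sites ",
           "in a sequence of length ", L)
    }
    for (p1 in p1s) {
      for (j in seq_len(.WINDOW_SIZE)) {
        ch[p1 - 8L + j] <- sample(.AA20, 1L, prob = eff[, j])
      }
    }
    seqs[i] <- paste(ch, collapse = "")
    ev[[i]] <- data.frame(substrate_id = ids[i], protease_id = protease_id,
                          p1 = sort(p1s), stringsAsFactors = FALSE)
    if (tracks) trk[[ids[i]]] <- .synthetic_tracks(L)
  }
  names(seqs) <- ids
  list(sequences = seqs, events = do.call(rbind, ev), tracks = trk,
       motif = motif, seed = seed)
}

#' Write a synthetic substrate set to disk in pipeline formats
#'
#' Emits the same FASTA + annotation TSV (+ per-substrate tracks TSVs) the
#' real pipeline consumes.
#'
#' @param sim Result of [generate_substrates()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_substrate_fixtures <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$sequences, file.path(dir, "substrates.fasta"))
  write_annotations(sim$events, file.path(dir, "annotations.tsv"))
  if (!is.null(sim$tracks)) {
    tdir <- file.path(dir, "tracks")
    dir.create(tdir, showWarnings = FALSE)
    for (id in names(sim$tracks)) {
      write_tracks(sim$tracks[[id]], file.path(tdir, paste0(id, ".tsv")))
    }
  }
  invisible(dir)
}

#' Simulate a labelled feature matrix with planted informative columns
#'
#' Gaussian features; the informative columns get a mean shift of `effect`
#' standard deviations in the positive class. Used to test feature-selection
#' recovery.
#'
#' @param n_pos,n_neg Class sizes.
#' @param n_features Total number of columns.
#' @param n_informative Number of signal-carrying columns (planted at random
#'   positions).
#' @param effect Mean shift, in SD units, of informative columns.
#' @param seed Integer seed.
#' @return List with `features` (matrix, columns `F001`, ...), `labels`
#'   (0/1) and `informative` (indices of planted columns).
#' @export
simulate_labeled_features <- function(n_pos = 100L, n_neg = 300L,
                                      n_features = 50L, n_informative = 5L,
                                      effect = 1.5, seed = 1L) {
  stopifnot(n_informative <= n_features)
  set.seed(seed)
  n <- n_pos + n_neg
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  x <- matrix(stats::rnorm(n * n_features), nrow = n)
  informative <- sort(sample.int(n_features, n_informative))
  x[labels == 1L, informative] <- x[labels == 1L, informative] + effect
  colnames(x) <- sprintf("F%03d", seq_len(n_features))
  list(features = x, labels = labels, informative = informative)
}

#' Generate a synthetic AAindex table
#'
#' Random, reproducible physicochemical-style indices for exercising the
#' AAindex machinery without the real database. Values are standard-normal
#' draws; the table is labelled synthetic via its `SYN*` accessions.
#'
#' @param n Number of indices.
#' @param seed Integer seed.
#' @return Numeric matrix (rows `SYN0001`...; 20 residue columns).
#' @export
synthetic_aaindex <- function(n = 80L, seed = 1L) {
  set.seed(seed)
  out <- matrix(stats::rnorm(n * 20L), nrow = n,
                dimnames = list(sprintf("SYN%04d", seq_len(n)), .AA20))
  out
}

#' Generate a synthetic residue profile for a sequence
#'
#' PSSM-like log-odds scores: background noise plus a positive bonus on each
#' position's own residue, mimicking a conserved profile. Labelled synthetic
#' by construction; for tests and demonstrations only.
#'
#' @param sequence Amino-acid sequence.
#' @param bonus Score bonus on the position's own residue.
#' @param seed Integer seed.
#' @return Numeric matrix (length x 20, PSI-BLAST column order).
#' @export
synthetic_pssm <- function(sequence, bonus = 5, seed = 1L) {
  set.seed(seed)
  L <- nchar(sequence)
  out <- matrix(stats::rnorm(L * 20L, sd = 2), nrow = L,
                dimnames = list(seq_len(L), .PSSM_COLS))
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- match(ch, .PSSM_COLS)
  ok <- !is.na(hit)
  out[cbind(which(ok), hit[ok])] <- out[cbind(which(ok), hit[ok])] + bonus
  round(out)
}
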