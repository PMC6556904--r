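## Full-sequence scanning with one or more trained models, ranked outputs,
## and protease family mapping.

#' Protease family from a MEROPS-style identifier
#'
#' The leading letter of a MEROPS identifier encodes the catalytic type:
#' `A` aspartic, `C` cysteine, `M` metallo, `S` serine. Any other initial
#' letter maps to `"other"` with a warning.
#'
#' @param protease_id MEROPS-style identifier(s), e.g. `"C14.003"`.
#' @return Character vector of family names.
#' @examples
#' family_of("C14.003")  # cysteine (caspase-3)
#' family_of("M10.003")  # metallo (MMP-2)
#' @export
family_of <- function(protease_id) {
  map <- c(A = "aspartic", C = "cysteine", M = "metallo", S = "serine")
  first <- substr(protease_id, 1L, 1L)
  fam <- unname(map[first])
  unknown <- is.na(fam)
  if (any(unknown)) {
    warning("unrecognized protease family letter(s): ",
            paste(unique(first[unknown]), collapse = ", "),
            "; mapped to 'other'")
    fam[unknown] <- "other"
  }
  fam
}

# P4-P4' display segment with '|' at the scissile bond, X-padded near termini
.display_segment <- function(sequence, p1) {
  L <- nchar(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pos <- c((p1 - 3L):p1, (p1 + 1L):(p1 + 4L))
  w <- rep("X", 8L)
  inside <- pos >= 1L & pos <= L
  w[inside] <- ch[pos[inside]]
  paste0(paste(w[1:4], collapse = ""), "|", paste(w[5:8], collapse = ""))
}

#' Scan full-length sequences for candidate cleavage sites
#'
#' Every bond (positions `1..L-1`) of every sequence is treated as a
#' candidate P1 for every supplied model. Scores are computed from the full
#' 16-residue P8-P8' feature window; the reported display segment covers
#' P4-P4' with `|` marking the scissile bond. Records are sorted by score,
#' descending, within each protease, then by sequence id and position for
#' determinism.
#'
#' @param sequences Named character vector of sequences to scan.
#' @param bundles One `protease_model` or a list of them.
#' @param context [encoding_context()] providing every scheme the bundles
#'   were trained with.
#' @param min_score Only records with `score >= min_score` are returned
#'   (default 0: all candidates).
#' @param seq_cap Soft cap on the number of sequences per scan (default 50,
#'   mirroring typical server limits); exceeding it warns but all sequences
#'   are still processed.
#' @return `data.frame` with columns `sequence_id`, `p1`, `segment`,
#'   `n_fragment_size` (= p1), `c_fragment_size` (= length - p1), `score`,
#'   `protease_id`, `family`.
#' @export
scan_sequences <- function(sequences, bundles, context, min_score = 0,
                           seq_cap = 50L) {
  if (inherits(bundles, "protease_model")) bundles <- list(bundles)
  if (length(bundles) == 0L) stop("no model bundles supplied")
  stopifnot(all(vapply(bundles, inherits, logical(1), "protease_model")))
  if (length(sequences) > seq_cap) {
    warning(length(sequences), " sequences exceed the default cap of ",
            seq_cap, "; processing all of them")
  }
  out <- list()
  for (id in names(sequences)) {
    s <- sequences[[id]]
    L <- nchar(s)
    if (L < 2L) next
    p1s <- seq_len(L - 1L)
    samples <- data.frame(substrate_id = id, p1 = p1s,
                          window = extract_windows(s, p1s),
                          stringsAsFactors = FALSE)
    feats <- build_feature_matrix(samples, context)
    segs <- vapply(p1s, function(p) .display_segment(s, p), character(1))
    for (b in bundles) {
      scores <- predict_scores(b, feats)
      out[[length(out) + 1L]] <- data.frame(
        sequence_id = id, p1 = p1s, segment = segs,
        n_fragment_size = p1s, c_fragment_size = L - p1s,
        score = scores, protease_id = b$protease_id,
        family = suppressWarnings(family_of(b$protease_id)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[res$score >= min_score, , drop = FALSE]
  res <- res[order(res$protease_id, -res$score, res$sequence_id, res$p1), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write scan predictions as TSV or JSON
#'
#' @param predictions `data.frame` from [scan_sequences()].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(predictions, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
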