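## Readers/writers for the external formats the pipeline touches, plus the
## embedded BLOSUM62 reference matrix.

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and normalized to the 21-letter alphabet used
#' throughout the package: the 20 standard residues plus `X`. Non-standard
#' letters (`B`, `Z`, `U`, `O`, `J`), `*` and `-` are mapped to `X` with a
#' warning.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return Named character vector of sequences; names are the FASTA ids
#'   (first whitespace-delimited token of each header).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACDE"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("input error: no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("input error: empty sequence for record(s): ",
         paste(ids[empty], collapse = ", "))
  }
  seqs <- normalize_sequences(seqs)
  if (anyDuplicated(ids)) {
    stop("input error: duplicated record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Normalize amino-acid sequences to the 21-letter alphabet
#'
#' @param seqs Character vector of (uppercase) sequences.
#' @return The sequences with every character outside `ACDEFGHIKLMNPQRSTVWYX`
#'   replaced by `X`; warns with the number of replaced characters.
#' @export
normalize_sequences <- function(seqs) {
  pattern <- "[^ACDEFGHIKLMNPQRSTVWYX]"
  n_bad <- sum(vapply(gregexpr(pattern, seqs),
                      function(m) sum(m > 0L), integer(1)))
  if (n_bad > 0L) {
    warning(n_bad, " non-standard residue character(s) mapped to 'X'")
    seqs <- gsub(pattern, "X", seqs)
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read cleavage-site annotations and join them against a sequence set
#'
#' The annotation file is a headered TSV with columns `substrate_id`,
#' `protease_id` and `p1` (1-based index of the P1 residue; cleavage is
#' between `p1` and `p1 + 1`, so `p1` must be strictly less than the sequence
#' length). Rows referencing unknown substrates are dropped with a warning;
#' duplicated (substrate, protease, p1) rows are deduplicated with a warning;
#' an out-of-range `p1` is a validation error.
#'
#' @param path Path to the TSV file.
#' @param sequences Named character vector of substrate sequences (see
#'   [read_fasta()]).
#' @return `data.frame` with columns `substrate_id`, `protease_id`, `p1`.
#' @export
read_annotations <- function(path, sequences) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("substrate_id", "protease_id", "p1")
  if (!all(req %in% names(tab))) {
    stop("annotation file must have columns: ", paste(req, collapse = ", "))
  }
  tab <- tab[req]
  tab$p1 <- as.integer(tab$p1)
  unknown <- !(tab$substrate_id %in% names(sequences))
  if (any(unknown)) {
    warning(sum(unknown), " annotation row(s) reference unknown substrate ",
            "ids and were dropped: ",
            paste(unique(tab$substrate_id[unknown]), collapse = ", "))
    tab <- tab[!unknown, , drop = FALSE]
  }
  len <- nchar(sequences[tab$substrate_id])
  bad <- is.na(tab$p1) | tab$p1 < 1L | tab$p1 >= len
  if (any(bad)) {
    stop("validation error: p1 out of range (must satisfy 1 <= p1 < length, ",
         "so that a P1' residue exists) for rows: ",
         paste(which(bad), collapse = ", "))
  }
  dup <- duplicated(tab)
  if (any(dup)) {
    warning(sum(dup), " duplicated annotation row(s) removed")
    tab <- tab[!dup, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Write cleavage-site annotations
#'
#' @param events `data.frame` with columns `substrate_id`, `protease_id`, `p1`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path) {
  utils::write.table(events[c("substrate_id", "protease_id", "p1")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' BLOSUM62 over the 21-letter alphabet
#'
#' The standard BLOSUM62 substitution matrix restricted to the 20 standard
#' residues, extended with an all-zero `X` row/column so that clipped
#' similarity scores are well-defined on padded windows.
#'
#' @return 21 x 21 integer matrix with dimnames `ACDEFGHIKLMNPQRSTVWY` + `X`.
#' @examples
#' b <- load_blosum62()
#' b["A", "A"]  # 4
#' @export
load_blosum62 <- function() {
  if (!is.null(.pkg_cache$blosum62)) return(.pkg_cache$blosum62)
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  out <- matrix(0L, 21L, 21L, dimnames = list(.AA21, .AA21))
  out[.AA20, .AA20] <- env$BLOSUM62[.AA20, .AA20]
  storage.mode(out) <- "integer"
  .pkg_cache$blosum62 <- out
  out
}

#' Parse an AAindex flat file (aaindex1 dialect)
#'
#' Reads `H` (accession) and `I` (index data) records. Indices with any
#' missing (`NA`) value are excluded, with a message reporting the count.
#'
#' @param path Path to an aaindex1-format file.
#' @return Numeric matrix, one row per retained index (rownames = accessions),
#'   20 columns in `ACDEFGHIKLMNPQRSTVWY` order.
#' @export
parse_aaindex <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  lines <- readLines(path)
  # order of residues on the two I-record value lines
  row1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  row2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  acc <- NA_character_
  vals <- list()
  n_dropped <- 0L
  i <- 1L
  while (i <= length(lines)) {
    line <- lines[[i]]
    if (startsWith(line, "H ")) {
      acc <- trimws(sub("^H ", "", line))
    } else if (startsWith(line, "I ")) {
      if (i + 2L > length(lines)) {
        stop("parse error at line ", i, ": truncated I record")
      }
      tok <- c(strsplit(trimws(lines[[i + 1L]]), "\\s+")[[1]],
               strsplit(trimws(lines[[i + 2L]]), "\\s+")[[1]])
      if (length(tok) != 20L) {
        stop("parse error at line ", i + 1L, ": expected 20 index values, got ",
             length(tok))
      }
      if (is.na(acc)) stop("parse error at line ", i, ": I record before H")
      v <- suppressWarnings(as.numeric(tok))
      names(v) <- c(row1, row2)
      if (anyNA(v)) {
        n_dropped <- n_dropped + 1L
      } else {
        vals[[acc]] <- v[.AA20]
      }
      acc <- NA_character_
      i <- i + 2L
    }
    i <- i + 1L
  }
  if (n_dropped > 0L) {
    message(n_dropped, " AAindex entr", if (n_dropped == 1L) "y" else "ies",
            " with missing values excluded")
  }
  if (length(vals) == 0L) stop("parse error: no complete AAindex entries in ", path)
  out <- do.call(rbind, vals)
  colnames(out) <- .AA20
  out
}

#' Write an AAindex table in aaindex1 flat-file format
#'
#' Inverse of [parse_aaindex()] for tables produced or consumed by this
#' package (only `H` and `I` records are written).
#'
#' @param table Numeric matrix, rows = indices (rownames = accessions),
#'   columns named with the 20 standard residues.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aaindex <- function(table, path) {
  row1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  row2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  con <- file(path, "w")
  on.exit(close(con))
  for (acc in rownames(table)) {
    v <- table[acc, ]
    writeLines(c(
      paste0("H ", acc),
      paste0("D synthetic or user-supplied amino acid index ", acc),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste0("  ", paste(formatC(v[row1], format = "f", digits = 3, width = 7),
                         collapse = " ")),
      paste0("  ", paste(formatC(v[row2], format = "f", digits = 3, width = 7),
                         collapse = " ")),
      "//"
    ), con)
  }
  invisible(path)
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the first 20 score columns (log-odds block) of the classic
#' PSI-BLAST `-out_ascii_pssm` format.
#'
#' @param path Path to the ASCII PSSM file.
#' @return Numeric matrix with one row per residue position and 20 columns in
#'   PSI-BLAST order (`ARNDCQEGHILKMFPSTWYV`); the residue letters are
#'   attached as attribute `residues`. Row count is checked against the
#'   substrate sequence at join time, not here.
#' @export
parse_pssm <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  lines <- readLines(path)
  rows <- list()
  res <- character(0)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(tok) == 0L || is.na(suppressWarnings(as.integer(tok[1L])))) next
    if (length(tok) < 22L) {
      stop("parse error at line ", i, ": expected at least 22 columns ",
           "(position, residue, 20 scores), got ", length(tok))
    }
    scores <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(scores)) {
      stop("parse error at line ", i, ": non-numeric score column")
    }
    rows[[length(rows) + 1L]] <- scores
    res <- c(res, tok[2L])
  }
  if (length(rows) == 0L) stop("parse error: no PSSM rows in ", path)
  out <- do.call(rbind, rows)
  colnames(out) <- .PSSM_COLS
  rownames(out) <- seq_len(nrow(out))
  attr(out, "residues") <- paste(res, collapse = "")
  out
}

#' Write a residue profile in PSI-BLAST ASCII PSSM layout
#'
#' @param profile Numeric matrix, rows = positions, 20 columns in PSI-BLAST
#'   order (`ARNDCQEGHILKMFPSTWYV`).
#' @param sequence The substrate sequence the profile is aligned to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, sequence, path) {
  stopifnot(nrow(profile) == nchar(sequence), ncol(profile) == 20L)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed",
               paste0("            ", paste(.PSSM_COLS, collapse = "   "))),
             con)
  for (i in seq_len(nrow(profile))) {
    writeLines(paste(format(i, width = 5), ch[i],
                     paste(formatC(round(profile[i, ]), format = "d",
                                   width = 4), collapse = "")),
               con)
  }
  invisible(path)
}

#' Parse per-residue structural tracks
#'
#' Reads a headered TSV with columns `pos`, `ss` (3-state secondary structure
#' H/E/C), `sa_state` (`buried`/`exposed`), `sa_value` (relative solvent
#' accessibility in \[0, 1\]) and `diso` (disorder probability in \[0, 1\]).
#'
#' @param path Path to the tracks TSV.
#' @return List with components `ss`, `sa_state` (character vectors),
#'   `sa_value`, `diso` (numeric vectors), all of equal length; length is
#'   checked against the substrate sequence at join time.
#' @export
parse_tracks <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("pos", "ss", "sa_state", "sa_value", "diso")
  if (!all(req %in% names(tab))) {
    stop("tracks file must have columns: ", paste(req, collapse = ", "))
  }
  tab <- tab[order(tab$pos), ]
  if (!identical(as.integer(tab$pos), seq_len(nrow(tab)))) {
    stop("parse error: track positions must be 1..L without gaps")
  }
  if (!all(tab$ss %in% c("H", "E", "C"))) {
    stop("parse error: secondary-structure states must be H, E or C")
  }
  if (!all(tab$sa_state %in% c("buried", "exposed"))) {
    stop("parse error: solvent-accessibility states must be buried/exposed")
  }
  if (any(tab$sa_value < 0 | tab$sa_value > 1, na.rm = TRUE) ||
      any(tab$diso < 0 | tab$diso > 1)) {
    stop("parse error: sa_value and diso must lie in [0, 1]")
  }
  list(ss = tab$ss, sa_state = tab$sa_state,
       sa_value = tab$sa_value, diso = tab$diso)
}

#' Write per-residue structural tracks
#'
#' @param tracks List as returned by [parse_tracks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  tab <- data.frame(pos = seq_along(tracks$ss), ss = tracks$ss,
                    sa_state = tracks$sa_state, sa_value = tracks$sa_value,
                    diso = tracks$diso)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
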