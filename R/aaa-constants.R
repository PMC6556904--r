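## Shared internal constants (file name keeps these first in collation order).

# 20 standard residues in alphabetical one-letter order; 'X' is the 21st
# gap-filling/unknown letter used for window padding and normalized non-standard
# residues.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.AA21 <- c(.AA20, "X")

# PSI-BLAST PSSM column order.
.PSSM_COLS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte-Doolittle hydropathy scale.
.KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Window position labels P8..P1 then P1'..P8' ("p" suffix for primed).
.POS_LABELS <- c(paste0("P", 8:1), paste0("P", 1:8, "p"))

.WINDOW_SIZE <- 16L

.pkg_cache <- new.env(parent = emptyenv())

# Map a window string to integer codes 1..21 over .AA21; errors on characters
# outside the alphabet (normalization should have removed them).
window_codes <- function(window) {
  ch <- strsplit(window, "", fixed = TRUE)[[1]]
  codes <- match(ch, .AA21)
  if (anyNA(codes)) {
    stop("window contains characters outside the 21-letter alphabet: ",
         paste(unique(ch[is.na(codes)]), collapse = ", "))
  }
  codes
}

.check_window <- function(window) {
  if (!is.character(window) || length(window) != 1L ||
      nchar(window) != .WINDOW_SIZE) {
    stop("expected a single ", .WINDOW_SIZE, "-character window string")
  }
  invisible(window)
}
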