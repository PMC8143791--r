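#' Standard 64-channel montage labels (BioSemi A1-A32, B1-B32 ordering)
#'
#' @return character vector of 64 electrode labels in acquisition order.
#' @export
biosemi64_labels <- function() {
  c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3",
    "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
    "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz",
    "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
    "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4",
    "C6", "T8", "TP8", "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8",
    "P10", "PO8", "PO4", "O2")
}

#' Hemisphere of each electrode in a montage
#'
#' Follows the 10-20 convention: odd electrode numbers lie over the left
#' hemisphere, even numbers over the right, and `z` labels on the midline.
#'
#' @param labels electrode labels; defaults to [biosemi64_labels()].
#' @return character vector of `"left"`, `"right"` or `"mid"`.
#' @export
channel_side <- function(labels = biosemi64_labels()) {
  vapply(labels, function(lb) {
    tail_ch <- sub("^[A-Za-z]+", "", lb)
    if (tail_ch == "" || grepl("z$", lb)) return("mid")
    num <- suppressWarnings(as.integer(tail_ch))
    if (is.na(num)) return("mid")
    if (num %% 2 == 1) "left" else "right"
  }, character(1), USE.NAMES = FALSE)
}
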