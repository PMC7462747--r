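#' Does a 5' UTR point change create an upstream ATG?
#'
#' Single-nucleotide changes in a 5' UTR can create an upstream translation
#' initiation codon (uATG). An out-of-frame uATG opens an upstream ORF that
#' can suppress translation of the main ORF, a recognised loss-of-function
#' mechanism for UTR variants.
#'
#' The edit is applied to the supplied UTR sequence and every trinucleotide
#' window overlapping the edited base is compared before and after: the edit
#' creates a uATG iff a window that was not `ATG` before the edit is `ATG`
#' after it. The reading frame is assessed relative to the main ORF: the new
#' ATG is in frame iff the distance from its A to the main ATG's A is a
#' multiple of 3.
#'
#' @param utr_sequence Uppercase A/C/G/T string: the 5' UTR (or any window
#'   around the edit lying strictly 5' of the main ORF start).
#' @param position 0-based offset of the edited base within `utr_sequence`.
#' @param ref,alt Single reference and alternate bases; `ref` must match the
#'   sequence at `position`.
#' @param cds_offset Distance in bases from the edited position to the A of
#'   the main-ORF ATG (positive; e.g. 9 for a variant at c.-9).
#'
#' @return A list with `creates_uatg` (logical), `in_frame_with_main_orf`
#'   (logical, NA when no uATG is created) and `uatg_offset` (0-based offset
#'   of the new ATG's A in the edited sequence, NA when none).
#' @export
#' @examples
#' # edit turning "ATC" into "ATG": creates an out-of-frame uATG
#' detect_upstream_atg("CCATCGGCC", position = 4, ref = "C", alt = "G",
#'                     cds_offset = 9)
detect_upstream_atg <- function(utr_sequence, position, ref, alt, cds_offset) {
  bases <- strsplit(utr_sequence, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("utr_sequence must contain only uppercase A, C, G, T", call. = FALSE)
  }
  for (b in c(ref, alt)) {
    if (!is.character(b) || nchar(b) != 1L || !b %in% c("A", "C", "G", "T")) {
      stop("ref and alt must be single uppercase A/C/G/T bases", call. = FALSE)
    }
  }
  position <- as.integer(position)
  if (is.na(position) || position < 0L || position >= length(bases)) {
    stop("position must be a 0-based offset within the sequence", call. = FALSE)
  }
  if (bases[position + 1L] != ref) {
    stop("reference base mismatch: sequence has '", bases[position + 1L],
         "' at offset ", position, ", expected '", ref, "'", call. = FALSE)
  }
  cds_offset <- as.integer(cds_offset)
  if (is.na(cds_offset) || cds_offset < 1L) {
    stop("the edit must lie strictly 5' of the main-ORF start (cds_offset >= 1)",
         call. = FALSE)
  }

  edited <- bases
  edited[position + 1L] <- alt
  # trinucleotide windows overlapping the edited base
  starts <- (position - 2L):position
  starts <- starts[starts >= 0L & starts + 2L < length(bases)]
  uatg_offset <- NA_integer_
  for (s in starts) {
    idx <- (s + 1L):(s + 3L)
    was_atg <- identical(bases[idx], c("A", "T", "G"))
    is_atg <- identical(edited[idx], c("A", "T", "G"))
    if (is_atg && !was_atg) {
      uatg_offset <- s
      break
    }
  }
  if (is.na(uatg_offset)) {
    return(list(creates_uatg = FALSE, in_frame_with_main_orf = NA,
                uatg_offset = NA_integer_))
  }
  main_atg_offset <- position + cds_offset
  distance <- main_atg_offset - uatg_offset
  list(
    creates_uatg = TRUE,
    in_frame_with_main_orf = (distance %% 3L) == 0L,
    uatg_offset = uatg_offset
  )
}
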