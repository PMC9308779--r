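# SBS96 channel definitions shared across the package.

SBS_SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
DNA_BASES <- c("A", "C", "G", "T")

#' SBS96 channel labels
#'
#' Returns the 96 single-base-substitution channel labels in the standard
#' pyrimidine-centric order: the six substitution classes C>A, C>G, C>T,
#' T>A, T>C, T>G, each expanded over the 16 combinations of 5' and 3'
#' flanking bases. Labels follow the COSMIC convention, e.g. `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs96_channels())
sbs96_channels <- function() {
  unlist(lapply(SBS_SUBSTITUTIONS, function(sub) {
    outer(DNA_BASES, DNA_BASES, function(p5, p3) {
      paste0(p5, "[", sub, "]", p3)
    })
  }))
}

revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Assign an SNV to its SBS96 channel
#'
#' Maps a single-nucleotide variant, given the reference trinucleotide
#' centered on it, to the pyrimidine-centric SBS96 channel. Variants whose
#' reference base is a purine are reverse-complemented first, collapsing
#' both strands onto the 96 canonical channels.
#'
#' @param context Reference trinucleotide (character, length-3 strings)
#'   centered on the variant position.
#' @param ref,alt Reference and alternate alleles (single bases).
#' @return Character vector of channel labels; `NA` where the context
#'   contains a base outside ACGT or the center base disagrees with `ref`.
#' @export
#' @examples
#' sbs96_channel("ACA", "C", "A")
#' sbs96_channel("AGC", "G", "T")  # purine ref, collapses to G[C>A]T
sbs96_channel <- function(context, ref, alt) {
  stopifnot(length(context) == length(ref), length(ref) == length(alt))
  context <- toupper(context)
  ref <- toupper(ref)
  alt <- toupper(alt)
  purine <- ref %in% c("A", "G")
  context[purine] <- revcomp(context[purine])
  ref[purine] <- chartr("AG", "TC", ref[purine])
  alt[purine] <- chartr("ACGT", "TGCA", alt[purine])
  ok <- nchar(context) == 3 &
    !grepl("[^ACGT]", context) &
    substr(context, 2, 2) == ref &
    alt %in% DNA_BASES & ref != alt
  out <- rep(NA_character_, length(ref))
  out[ok] <- paste0(
    substr(context[ok], 1, 1), "[", ref[ok], ">", alt[ok], "]",
    substr(context[ok], 3, 3)
  )
  bad <- !is.na(out) & !(out %in% sbs96_channels())
  out[bad] <- NA_character_
  out
}

# Decompose a channel label into context / ref / alt.
channel_parts <- function(channel) {
  tibble::tibble(
    channel = channel,
    context = paste0(substr(channel, 1, 1), substr(channel, 3, 3),
                     substr(channel, 7, 7)),
    ref = substr(channel, 3, 3),
    alt = substr(channel, 5, 5)
  ) |>
    dplyr::mutate(context = paste0(substr(.data$channel, 1, 1),
                                   .data$ref,
                                   substr(.data$channel, 7, 7)))
}
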