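# Alanine masking of multiple sequence alignments, the preparation step that
# biases template-guided structure prediction toward a chosen conformational
# state of the active-site region.

#' Read an aligned FASTA or A3M file
#'
#' @param file path to the alignment.
#' @return named character vector of aligned sequences (A3M lowercase
#'   insertion states preserved).
#' @export
read_alignment <- function(file) {
  ss <- Biostrings::readBStringSet(file)
  stats::setNames(as.character(ss), names(ss))
}

#' Write an alignment as FASTA/A3M
#' @param aln named character vector.
#' @param file output path.
#' @export
write_alignment <- function(aln, file) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln), file)
  invisible(file)
}

# per-sequence indices of match-state positions: uppercase letters and '-'
# (A3M convention: lowercase letters are insertion states and do not occupy
# alignment columns)
match_state_positions <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  which(chars == "-" | (chars %in% LETTERS))
}

#' Mask an alignment region to alanine
#'
#' Replaces the amino acids in the alignment columns spanned by target
#' residues \code{start_res}..\code{end_res} with alanine. Residue numbering
#' counts the target's non-gap positions (1-based, UniProt-style for a
#' full-length target). Gaps are untouched; A3M lowercase insertion states
#' are untouched and do not occupy columns. By default every sequence is
#' masked in the targeted columns (the stronger conformational bias);
#' \code{all_sequences = FALSE} restricts masking to the target itself.
#'
#' @param alignment named character vector (see \code{\link{read_alignment}})
#'   or a file path.
#' @param target_id name of the target sequence in the alignment.
#' @param start_res,end_res 1-based residue range on the target (defaults
#'   276 and 336, the catalytic-loop region Q276..C336 of transglutaminase).
#' @param expected_letters optional named checks on target residues, e.g.
#'   \code{c("276" = "Q", "336" = "C")} (the default); a mismatch aborts,
#'   guarding against off-by-one numbering.
#' @param all_sequences mask every sequence (default) or only the target.
#' @return masked alignment, same shape, with attribute
#'   \code{masked_columns} (alignment column indices masked).
#' @export
mask_msa_alanine <- function(alignment, target_id, start_res = 276L,
                             end_res = 336L,
                             expected_letters = c("276" = "Q", "336" = "C"),
                             all_sequences = TRUE) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment)) {
    alignment <- read_alignment(alignment)
  }
  if (!target_id %in% names(alignment)) {
    stop("target sequence ", sQuote(target_id), " not in alignment")
  }
  stopifnot(start_res >= 1L, start_res <= end_res)

  tgt <- strsplit(alignment[[target_id]], "")[[1]]
  res_pos <- which(tgt != "-")   # target residue -> target string position
  if (end_res > length(res_pos)) {
    stop("residue range ", start_res, "..", end_res,
         " exceeds target length ", length(res_pos))
  }
  for (nm in names(expected_letters)) {
    rno <- as.integer(nm)
    if (rno >= 1L && rno <= length(res_pos)) {
      got <- toupper(tgt[res_pos[rno]])
      if (got != toupper(expected_letters[[nm]])) {
        stop("target residue ", rno, " is ", sQuote(got), ", expected ",
             sQuote(expected_letters[[nm]]), "; numbering looks off")
      }
    }
  }

  range_pos <- res_pos[start_res:end_res]   # positions in the target string

  tgt_match <- match_state_positions(alignment[[target_id]])
  widths <- vapply(alignment, function(s) length(match_state_positions(s)),
                   integer(1))
  aligned_mode <- all(widths == widths[[1]])
  if (!aligned_mode) {
    stop("sequences disagree on match-state count (",
         paste(range(widths), collapse = " vs "),
         "); not a consistent alignment")
  }

  # alignment columns (match-state index) covered by the target range
  masked_cols <- match(intersect(range_pos, tgt_match), tgt_match)
  # target residues that sit in insertion states are masked on the target only
  tgt_only_pos <- setdiff(range_pos, tgt_match)

  out <- alignment
  seqs_to_mask <- if (all_sequences) names(alignment) else target_id
  for (nm in seqs_to_mask) {
    chars <- strsplit(out[[nm]], "")[[1]]
    pos <- match_state_positions(out[[nm]])[masked_cols]
    sel <- pos[chars[pos] %in% LETTERS]   # leave gaps alone
    chars[sel] <- "A"
    out[[nm]] <- paste(chars, collapse = "")
  }
  if (length(tgt_only_pos)) {
    chars <- strsplit(out[[target_id]], "")[[1]]
    sel <- tgt_only_pos[chars[tgt_only_pos] %in% c(LETTERS, letters)]
    chars[sel] <- ifelse(chars[sel] %in% letters, "a", "A")
    out[[target_id]] <- paste(chars, collapse = "")
  }
  attr(out, "masked_columns") <- masked_cols
  out
}
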